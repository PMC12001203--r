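#' @title mzML input/output for chromatogram runs
#' @description A `crm_run` holds one sample's MS1 scans: a scans tibble with
#'   retention time and per-scan centroided spectra as list-columns. Files
#'   are read and written through Bioconductor's mzR (proteowizard-backed),
#'   so both indexed and plain mzML are accepted.
#' @name mzml-io
NULL

new_crm_run <- function(sample_id, scans, metadata = character()) {
  stopifnot(is.data.frame(scans),
            all(c("scan", "rt", "mz", "intensity") %in% names(scans)))
  if (!nrow(scans)) abort_crm("run has no MS1 scans", "crm_mzml_error")
  if (is.unsorted(scans$rt)) {
    scans <- scans[order(scans$rt), , drop = FALSE]
    scans$scan <- seq_len(nrow(scans))
  }
  for (i in seq_len(nrow(scans))) {
    mz <- scans$mz[[i]]; it <- scans$intensity[[i]]
    if (length(mz) != length(it)) {
      abort_crm(sprintf("scan %d: mz/intensity length mismatch", i),
                "crm_mzml_error")
    }
    if (length(mz) > 1 && any(diff(mz) <= 0)) {
      o <- order(mz)
      scans$mz[[i]] <- mz[o]; scans$intensity[[i]] <- it[o]
    }
    if (any(!is.finite(it)) || any(it < 0)) {
      abort_crm(sprintf("scan %d: non-finite or negative intensities", i),
                "crm_mzml_error")
    }
  }
  structure(list(sample_id = sample_id, scans = tibble::as_tibble(scans),
                 metadata = metadata),
            class = "crm_run")
}

#' @export
print.crm_run <- function(x, ...) {
  cat("<crm_run>", x$sample_id, "-", nrow(x$scans), "MS1 scans, rt",
      sprintf("%.1f-%.1f s\n", min(x$scans$rt), max(x$scans$rt)))
  invisible(x)
}

#' Read an mzML run
#'
#' Loads all MS1 scans of an mzML file in retention-time order; higher MS
#' levels are ignored. Profile-mode spectra are rejected unless
#' `accept_profile = TRUE` (centroiding is expected upstream).
#'
#' @param path Path to an mzML file.
#' @param sample_id Sample identifier (default: file name without extension).
#' @param accept_profile Keep spectra flagged as profile mode (default FALSE).
#' @return A `crm_run`.
#' @export
read_run <- function(path, sample_id = NULL, accept_profile = FALSE) {
  if (!file.exists(path)) {
    abort_crm(paste0("mzML file not found: ", path), "crm_mzml_error")
  }
  sample_id <- sample_id %||% sub("\\.mzML$", "", basename(path),
                                  ignore.case = TRUE)
  handle <- tryCatch(mzR::openMSfile(path),
                     error = function(e) {
                       abort_crm(paste0("malformed mzML '", path, "': ",
                                        conditionMessage(e)),
                                 "crm_mzml_error")
                     })
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::header(handle)
  if (!nrow(hdr)) abort_crm("empty mzML run", "crm_mzml_error")
  ms1 <- which(hdr$msLevel == 1L)
  if (!length(ms1)) abort_crm("run contains no MS1 scans", "crm_mzml_error")
  if (!accept_profile && any(!is.na(hdr$centroided[ms1]) &
                             !hdr$centroided[ms1])) {
    abort_crm(paste0("profile-mode MS1 spectra in '", path,
                     "'; centroid upstream or set accept_profile = TRUE"),
              "crm_mzml_error")
  }
  if (any(is.na(hdr$retentionTime[ms1]))) {
    abort_crm("MS1 scan without retention time", "crm_mzml_error")
  }
  pk <- mzR::peaks(handle, ms1)
  if (is.matrix(pk)) pk <- list(pk)
  ord <- order(hdr$retentionTime[ms1])
  scans <- tibble::tibble(
    scan = seq_along(ms1),
    rt = hdr$retentionTime[ms1][ord],
    mz = purrr::map(pk[ord], function(m) as.numeric(m[, 1])),
    intensity = purrr::map(pk[ord], function(m) as.numeric(m[, 2]))
  )
  new_crm_run(sample_id, scans,
              metadata = c(file = basename(path)))
}

#' Write a run to mzML
#'
#' @param run A `crm_run`.
#' @param path Output mzML path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  stopifnot(inherits(run, "crm_run"))
  n <- nrow(run$scans)
  pks <- purrr::map(seq_len(n), function(i) {
    cbind(mz = run$scans$mz[[i]], intensity = run$scans$intensity[[i]])
  })
  tic <- vnum(pks, function(m) sum(m[, 2]))
  bp <- purrr::map(pks, function(m) {
    if (nrow(m)) m[which.max(m[, 2]), ] else c(mz = 0, intensity = 0)
  })
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    retentionTime = run$scans$rt, polarity = 1L,
    peaksCount = vnum(pks, nrow), totIonCurrent = tic,
    basePeakMZ = vnum(bp, `[[`, 1), basePeakIntensity = vnum(bp, `[[`, 2),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vnum(pks, function(m) if (nrow(m)) min(m[, 1]) else 0),
    highMZ = vnum(pks, function(m) if (nrow(m)) max(m[, 1]) else 0),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = "",
    spectrumId = sprintf("scan=%d", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE
  )
  mzR::writeMSData(pks, path, header = hdr, outformat = "mzml")
  invisible(path)
}
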