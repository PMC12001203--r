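#' @title CCP4/MRC density-grid input/output
#' @description Minimal reader/writer for mode-2 (float32) CCP4/MRC density
#'   maps with the standard column/row/section = x/y/z axis order.
#'   Orthogonal cells only: event-map analysis in this package samples
#'   Cartesian probes, and the Cartesian-to-grid transform is implemented
#'   for 90-degree cells (a triclinic transform would slot into
#'   `grid_to_frac()`).
#' @name density-io
NULL

#' Construct a density grid
#'
#' @param values 3D numeric array of density values, x fastest axis.
#' @param cell Cell lengths in Angstrom (length 3, orthogonal cell assumed;
#'   or length 6 with all angles 90).
#' @param origin Cartesian origin of voxel `[1,1,1]` in Angstrom
#'   (default `c(0,0,0)`).
#' @return A `crm_density_grid`.
#' @export
density_grid <- function(values, cell, origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3, all(dim(values) >= 2),
            all(is.finite(values)))
  if (length(cell) == 6) {
    if (any(abs(cell[4:6] - 90) > 1e-4)) {
      abort_crm("only orthogonal cells (90-degree angles) are supported",
                "crm_map_error")
    }
    cell <- cell[1:3]
  }
  stopifnot(length(cell) == 3, all(cell > 0), length(origin) == 3)
  structure(list(values = values, cell = as.numeric(cell),
                 origin = as.numeric(origin)),
            class = "crm_density_grid")
}

#' @export
print.crm_density_grid <- function(x, ...) {
  d <- dim(x$values)
  cat("<crm_density_grid>", paste(d, collapse = " x "), "voxels, cell",
      paste(sprintf("%.2f", x$cell), collapse = " x "), "A, spacing",
      paste(sprintf("%.3f", x$cell / d), collapse = "/"), "A\n")
  invisible(x)
}

grid_spacing <- function(grid) grid$cell / dim(grid$values)

#' Write a density grid as a CCP4/MRC map
#'
#' Mode 2 (float32), little-endian, x/y/z axis order, origin recorded in the
#' MRC2014 ORIGIN fields (Angstrom).
#'
#' @param grid A `crm_density_grid`.
#' @param path Output path (conventionally `.ccp4` or `.map`).
#' @return `path`, invisibly.
#' @export
write_ccp4 <- function(grid, path) {
  stopifnot(inherits(grid, "crm_density_grid"))
  d <- dim(grid$values)
  v <- as.numeric(grid$values)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                       # NC NR NS
  wi(2L)                      # MODE 2 = float32
  wi(c(0L, 0L, 0L))           # NCSTART NRSTART NSSTART
  wi(d)                       # NX NY NZ sampling
  wf(c(grid$cell, 90, 90, 90))
  wi(c(1L, 2L, 3L))           # MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v)))
  wi(1L)                      # ISPG P1
  wi(0L)                      # NSYMBT
  wi(rep(0L, 25))             # EXTRA (words 26-50)... words 25..49
  wf(grid$origin)             # ORIGIN x y z (words 50-52)
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(v))            # RMS
  wi(0L)                      # NLABL
  writeBin(raw(800), con)     # 10 empty 80-char labels
  wf(v)
  invisible(path)
}

#' Read a CCP4/MRC map into a density grid
#'
#' Accepts mode-2 maps with MAPC/MAPR/MAPS = 1/2/3 and orthogonal cells.
#' The origin is taken from the MRC2014 ORIGIN record when set, otherwise
#' from the NCSTART offsets times the voxel spacing.
#'
#' @param path Map file path.
#' @return A `crm_density_grid`.
#' @export
read_ccp4 <- function(path) {
  if (!file.exists(path)) {
    abort_crm(paste0("map file not found: ", path), "crm_map_error")
  }
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  nc <- ri(3)
  mode <- ri(1)
  if (mode != 2L) {
    abort_crm(paste0("unsupported map mode ", mode, " (only mode 2)"),
              "crm_map_error")
  }
  nstart <- ri(3)
  nxyz <- ri(3)
  cell <- rf(6)
  mapcrs <- ri(3)
  if (!identical(mapcrs, c(1L, 2L, 3L))) {
    abort_crm("unsupported axis order (MAPC/MAPR/MAPS must be 1/2/3)",
              "crm_map_error")
  }
  rf(3)        # min/max/mean
  ri(1)        # ISPG
  nsymbt <- ri(1)
  ri(25)       # EXTRA
  origin <- rf(3)
  maptag <- readChar(con, 4, useBytes = TRUE)
  if (!identical(substr(maptag, 1, 3), "MAP")) {
    abort_crm("missing MAP signature: not a CCP4/MRC map", "crm_map_error")
  }
  readBin(con, "raw", 4)  # machine stamp
  rf(1)        # RMS
  ri(1)        # NLABL
  readBin(con, "raw", 800 + nsymbt)
  v <- rf(prod(nc))
  if (length(v) != prod(nc)) {
    abort_crm("truncated map data block", "crm_map_error")
  }
  spacing <- cell[1:3] / nxyz
  if (all(origin == 0) && any(nstart != 0)) origin <- nstart * spacing
  # cell lengths of the stored block (may be a sub-block of the full cell)
  density_grid(array(v, dim = nc), cell = c(nc * spacing, cell[4:6]),
               origin = origin)
}
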