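#' Tanimoto similarity of two fingerprint bit sets
#'
#' `|A n B| / |A u B|` over on-bit index sets, defined as 1 when both sets
#' are empty. Fingerprints carrying generation parameters (`radius`/`nbits`
#' attributes, as produced per-set by [morgan_fingerprints()]) must agree,
#' otherwise comparison is refused.
#'
#' @param a,b Integer vectors of on-bit indices.
#' @return Similarity in `[0, 1]`.
#' @examples
#' tanimoto(c(1L, 2L, 3L), c(2L, 3L, 4L))  # 0.5
#' @export
tanimoto <- function(a, b) {
  pa <- c(attr(a, "radius"), attr(a, "nbits"))
  pb <- c(attr(b, "radius"), attr(b, "nbits"))
  if (length(pa) && length(pb) && !identical(pa, pb)) {
    abort_crm("fingerprints were generated with different parameters",
              "crm_fingerprint_error")
  }
  a <- unique(as.integer(a)); b <- unique(as.integer(b))
  if (!length(a) && !length(b)) return(1.0)
  length(intersect(a, b)) / length(union(a, b))
}

# Pairwise 1 - Tanimoto over a fingerprint list (as from morgan_fingerprints)
tanimoto_dist <- function(fps) {
  n <- length(fps)
  d <- matrix(0, n, n, dimnames = list(names(fps), names(fps)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- 1 - tanimoto(fps[[i]], fps[[j]])
    }
  }
  stats::as.dist(d)
}

#' Cluster products by fingerprint similarity
#'
#' Agglomerative (average-linkage) clustering over 1 - Tanimoto distance of
#' circular fingerprints, the standard view of which reaction products are
#' chemically related — e.g. to ask whether an unusual binding pose tracks
#' with a shared substitution.
#'
#' @param targets Product table with `target_id` and `smiles` columns
#'   (at least 2 rows).
#' @param radius,nbits Fingerprint parameters (defaults 2 and 2048).
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return A `crm_dendrogram`: list with the `hclust` tree, the distance
#'   matrix and the fingerprint parameters.
#' @export
cluster_products <- function(targets, radius = 2, nbits = 2048,
                             linkage = "average") {
  stopifnot(is.data.frame(targets))
  if (nrow(targets) < 2) {
    abort_crm("clustering needs at least two products", "crm_cluster_error")
  }
  fps <- morgan_fingerprints(stats::setNames(targets$smiles,
                                             targets$target_id),
                             radius = radius, nbits = nbits)
  if (any(vlgl(fps, is.null))) {
    abort_crm("fingerprint failed for some products", "crm_cluster_error")
  }
  d <- tanimoto_dist(fps)
  structure(
    list(hclust = stats::hclust(d, method = linkage), dist = d,
         params = list(type = "morgan", radius = radius, nbits = nbits,
                       linkage = linkage)),
    class = "crm_dendrogram"
  )
}

#' @export
print.crm_dendrogram <- function(x, ...) {
  cat("<crm_dendrogram>", length(x$hclust$labels), "products,",
      x$params$linkage, "linkage on 1 - Tanimoto (radius",
      paste0(x$params$radius, ","), x$params$nbits, "bits)\n")
  invisible(x)
}

#' Export a product dendrogram as Newick
#'
#' @param dendro A `crm_dendrogram` from [cluster_products()].
#' @param path Output file; when `NULL` the Newick string is returned.
#' @return The path (invisibly) or the Newick string.
#' @export
write_newick <- function(dendro, path = NULL) {
  stopifnot(inherits(dendro, "crm_dendrogram"))
  phy <- ape::as.phylo(dendro$hclust)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Plot a product similarity dendrogram
#'
#' @param object A `crm_dendrogram`.
#' @param ... Unused.
#' @return A ggplot object (leaves on the x axis, merge height = 1 - Tanimoto
#'   on the y axis).
#' @export
autoplot.crm_dendrogram <- function(object, ...) {
  hc <- object$hclust
  dd <- stats::as.dendrogram(hc)
  seg <- dendro_segments(dd, environment())
  ggplot2::ggplot(seg$segments) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = seq_along(hc$labels[hc$order]),
                                labels = hc$labels[hc$order]) +
    ggplot2::labs(x = NULL, y = "1 - Tanimoto similarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1, vjust = .5))
}

# flatten a dendrogram into plottable segments (x = leaf order position)
dendro_segments <- function(dd, env) {
  segs <- list()
  walk <- function(node) {
    if (is.leaf(node)) {
      return(c(x = attr(node, "x_pos"), y = 0))
    }
    kids <- lapply(seq_along(node), function(i) walk(node[[i]]))
    xs <- vnum(kids, `[[`, "x"); ys <- vnum(kids, `[[`, "y")
    h <- attr(node, "height")
    segs[[length(segs) + 1]] <<- data.frame(
      x = c(xs, min(xs)), y = c(ys, h),
      xend = c(xs, max(xs)), yend = c(h, h)
    )
    c(x = mean(range(xs)), y = h)
  }
  pos <- 0
  assign_x <- function(node) {
    if (is.leaf(node)) {
      pos <<- pos + 1
      attr(node, "x_pos") <- pos
      return(node)
    }
    for (i in seq_along(node)) node[[i]] <- assign_x(node[[i]])
    node
  }
  dd <- assign_x(dd)
  walk(dd)
  list(segments = do.call(rbind, segs))
}
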