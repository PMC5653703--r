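#' Define a set of regions of interest with homotopic pairing
#'
#' A `roi_set` records the ordered ROI labels and which index pairs are
#' homotopic (mirror-image regions in opposite hemispheres). The homotopic
#' pairing drives the synthetic network template, where left-right pairs
#' carry the strongest partial correlations, and the dominance report of the
#' group analysis.
#'
#' @param labels Character vector of unique ROI names (length `d >= 2`).
#' @param homotopic_pairs Two-column integer matrix; each row is a
#'   (left index, right index) pair. Every index must be valid and may appear
#'   in at most one pair. May have zero rows.
#' @return An object of class `roi_set` with elements `labels` and
#'   `homotopic_pairs`.
#' @seealso [default_roi_set()] for the 14-region subcortical set.
#' @export
roi_set <- function(labels, homotopic_pairs = matrix(integer(), ncol = 2)) {
  labels <- as.character(labels)
  d <- length(labels)
  if (d < 2) stop("roi_set needs at least 2 ROI labels", call. = FALSE)
  if (anyDuplicated(labels)) stop("ROI labels must be unique", call. = FALSE)
  hp <- matrix(as.integer(homotopic_pairs), ncol = 2)
  if (nrow(hp) > 0) {
    idx <- as.vector(hp)
    if (any(idx < 1L | idx > d))
      stop("homotopic pair index out of range", call. = FALSE)
    if (anyDuplicated(idx))
      stop("each ROI may appear in at most one homotopic pair",
           call. = FALSE)
    if (any(hp[, 1] == hp[, 2]))
      stop("a homotopic pair must join two distinct ROIs", call. = FALSE)
  }
  structure(list(labels = labels, homotopic_pairs = hp), class = "roi_set")
}

#' The 14-region subcortical ROI set
#'
#' Left and right nucleus accumbens, amygdala, caudate nucleus, hippocampus,
#' putamen, pallidum and thalamus: 14 regions forming 7 homotopic pairs and
#' 91 possible connections.
#'
#' @return A [roi_set()] with `d = 14`.
#' @export
#' @examples
#' rs <- default_roi_set()
#' n_possible_edges(rs)
default_roi_set <- function() {
  structures <- c("Accumbens", "Amygdala", "Caudate", "Hippocampus",
                  "Putamen", "Pallidum", "Thalamus")
  labels <- as.vector(t(outer(structures, c("L", "R"),
                              function(s, h) paste(h, s, sep = "_"))))
  pairs <- cbind(seq(1, 13, by = 2), seq(2, 14, by = 2))
  roi_set(labels, pairs)
}

#' A small synthetic ROI set for reduced-size experiments
#'
#' Builds `n_pairs` artificial left/right region pairs (`d = 2 * n_pairs`),
#' mirroring the homotopic layout of the full subcortical set at a size where
#' simulation studies are cheap.
#'
#' @param n_pairs Number of homotopic pairs.
#' @return A [roi_set()] with `d = 2 * n_pairs`.
#' @export
synthetic_roi_set <- function(n_pairs = 3) {
  stopifnot(n_pairs >= 1)
  labels <- as.vector(t(outer(paste0("Region", seq_len(n_pairs)),
                              c("L", "R"),
                              function(s, h) paste(h, s, sep = "_"))))
  pairs <- cbind(seq(1, 2 * n_pairs - 1, by = 2), seq(2, 2 * n_pairs, by = 2))
  roi_set(labels, pairs)
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("ROI set: %d regions, %d homotopic pairs, %d possible edges\n",
              length(x$labels), nrow(x$homotopic_pairs),
              n_possible_edges(length(x$labels))))
  cat(paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}
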