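#' Tidy a behavior clustering
#'
#' One row per cluster: behavior label, size, within-cluster sum of squares
#' and the centroid's per-round means as `round_*` columns.
#'
#' @param x A `crd_clusters` object.
#' @param ... Unused.
#' @return A tibble with `x$k` rows.
#' @export
tidy.crd_clusters <- function(x, ...) {
  centers <- as.data.frame(x$centers)
  names(centers) <- paste0("round_", seq_len(ncol(centers)))
  dplyr::bind_cols(
    tibble(
      cluster = seq_len(x$k),
      behavior = x$labels,
      size = as.integer(tabulate(x$cluster, nbins = x$k)),
      withinss = x$withinss
    ),
    as_tibble(centers)
  )
}

#' One-row summary of a behavior clustering
#'
#' @inheritParams tidy.crd_clusters
#' @return A tibble with columns k, n, tot_withinss.
#' @export
glance.crd_clusters <- function(x, ...) {
  tibble(
    k = x$k,
    n = length(x$cluster),
    tot_withinss = x$tot_withinss
  )
}
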