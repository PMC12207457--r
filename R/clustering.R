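#' K-means clustering of round-by-round action vectors
#'
#' Clusters 10-element contribution sequences with Lloyd's algorithm on the
#' raw (unscaled) vectors under Euclidean distance — all coordinates share
#' units (ECoins per round), and standardization would distort the
#' fair-share anchor at 2. The best of `n_init` random initializations by
#' total within-cluster sum of squares is kept; results are deterministic
#' given `seed`. Game 1 and Game 2 vectors are intended to be pooled before
#' clustering, on the assumption that individuals follow the same heuristics
#' in both games even if their behavior changes.
#'
#' @param vectors A numeric matrix (or data frame) with one action sequence
#'   per row.
#' @param k Number of clusters; there must be at least `k` distinct rows.
#' @param seed Integer seed for the initializations.
#' @param n_init Number of random restarts.
#' @return An object of class `crd_clusters`: a list with `cluster` (row
#'   assignments), `centers` (k x rounds centroid matrix), `labels`
#'   (behavioral name per centroid from [name_clusters()]), `tot_withinss`
#'   and `k`. [tidy()][generics::tidy] returns one row per centroid,
#'   [glance()][generics::glance] a one-row model summary, and
#'   [autoplot()][ggplot2::autoplot] the centroid trajectories.
#' @export
cluster_actions <- function(vectors, k = 4, seed = NULL, n_init = 10) {
  x <- as.matrix(vectors)
  storage.mode(x) <- "double"
  if (nrow(unique(x)) < k) {
    abort(sprintf("need at least %d distinct vectors to form %d clusters.", k, k))
  }
  fit <- with_seed_(
    seed,
    stats::kmeans(x, centers = k, nstart = n_init, iter.max = 100,
                  algorithm = "Lloyd")
  )
  structure(
    list(
      cluster = fit$cluster,
      centers = fit$centers,
      labels = name_clusters(fit$centers),
      withinss = fit$withinss,
      tot_withinss = fit$tot.withinss,
      k = k
    ),
    class = "crd_clusters"
  )
}

#' @export
print.crd_clusters <- function(x, ...) {
  cat("<crd_clusters> k =", x$k, "| total within-SS =",
      signif(x$tot_withinss, 5), "\n")
  cat("labels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Elbow-based choice of the number of clusters
#'
#' Computes the within-cluster sum of squares (inertia) across `k_range` and
#' returns the k at the elbow of the inertia curve. While genuine clusters
#' are still being separated the inertia decays roughly geometrically, and
#' once k exceeds the number of clusters it plateaus at the noise floor;
#' the elbow is therefore formalized as the maximum curvature (second
#' difference) of *log*-inertia, which detects the collapse in relative
#' improvement and, unlike a second difference on the raw curve, is not
#' dominated by the always-large absolute drop away from k = 1. If some k
#' attains (numerically) zero inertia, the smallest such k is returned:
#' the data admit a perfect clustering there.
#'
#' @inheritParams cluster_actions
#' @param k_range Candidate cluster counts (at least 3 values within 1-10).
#' @return The selected k, with the inertia curve attached as attribute
#'   `"inertia"` (a tibble with columns k and inertia) for inspection.
#' @export
select_k_elbow <- function(vectors, k_range = 1:8, seed = NULL, n_init = 10) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 3) {
    abort("`k_range` must contain at least 3 candidate values.")
  }
  if (any(k_range < 1) || any(k_range > 10)) {
    abort("`k_range` must lie within [1, 10].")
  }
  x <- as.matrix(vectors)
  storage.mode(x) <- "double"
  seeds <- split_seeds(seed, length(k_range))
  inertia <- vapply(seq_along(k_range), function(i) {
    k <- k_range[i]
    if (nrow(unique(x)) < k) {
      return(0) # fewer distinct points than centers: perfect fit
    }
    # a plain inertia sweep: empty-cluster restarts at k beyond the true
    # structure are expected and uninformative here
    fit <- with_seed_(seeds[i], suppressWarnings(
      stats::kmeans(x, centers = k, nstart = n_init, iter.max = 100,
                    algorithm = "Lloyd")
    ))
    fit$tot.withinss
  }, numeric(1))

  curve <- tibble(k = k_range, inertia = inertia)
  best <-
    if (any(zero <- inertia <= 1e-8 * max(inertia[1], 1))) {
      k_range[which(zero)[1]]
    } else {
      d2 <- diff(log(inertia), differences = 2)
      k_range[which.max(d2) + 1L]
    }
  attr(best, "inertia") <- curve
  best
}

#' Name cluster centroids as behavioral profiles
#'
#' Applies the verbal profile definitions to each centroid: with
#' `m` the overall centroid mean and `d` the first-half minus second-half
#' mean, a centroid is *early* when it front-loads (`d > delta`, first-half
#' mean above 2, second-half mean below 2); otherwise *high* when
#' `m > 2 + eps`, *low* when `m < 2 - eps`, and *fair* in the band around
#' the per-round fair share of 2. Duplicate names are permitted but
#' flagged with a warning.
#'
#' @param centroids A matrix with one centroid per row (k x rounds).
#' @param delta Minimum front-loading contrast for the early label.
#' @param eps Half-width of the fair band around 2.
#' @return A character vector of labels, one per centroid row.
#' @examples
#' name_clusters(rbind(c(4, 4, 4, 4, 4, 0, 0, 0, 0, 0), rep(2, 10)))
#' @export
name_clusters <- function(centroids, delta = 1, eps = 0.5) {
  centroids <- as.matrix(centroids)
  n <- ncol(centroids)
  half1 <- seq_len(ceiling(n / 2))
  labels <- apply(centroids, 1, function(cen) {
    m <- mean(cen)
    m1 <- mean(cen[half1])
    m2 <- mean(cen[-half1])
    if ((m1 - m2) > delta && m1 > 2 && m2 < 2) {
      "early"
    } else if (m > 2 + eps) {
      "high"
    } else if (m < 2 - eps) {
      "low"
    } else {
      "fair"
    }
  })
  if (anyDuplicated(labels)) {
    warn(paste0(
      "duplicate behavior labels across centroids: ",
      paste(labels, collapse = ", ")
    ))
  }
  labels
}

#' Extract per-individual action matrices from a study table
#'
#' One row per (player, game), columns round_1..round_rounds, plus the key
#' columns; the input to the clustering functions.
#'
#' @inheritParams group_metrics
#' @return A tibble; the round columns form the action matrix.
#' @export
action_vectors <- function(study) {
  study |>
    dplyr::select(
      "player_id", "game", "group_id", "treatment_choices",
      "treatment_delegation", "round", "contribution"
    ) |>
    tidyr::pivot_wider(
      names_from = "round", values_from = "contribution",
      names_prefix = "round_"
    )
}

#' Cluster and label every individual-game behavior in a study
#'
#' The full behavioral-profiling pipeline: extract the per-(player, game)
#' action vectors, pool the two games, cluster with k-means and name the
#' clusters. By default each choice condition (3 vs 5 actions) is clustered
#' separately, since the two treatments live on different action grids;
#' `by_choices = FALSE` pools the whole study into one clustering.
#'
#' @inheritParams group_metrics
#' @inheritParams cluster_actions
#' @param by_choices Cluster the 3- and 5-choice conditions separately.
#' @return A tibble keyed by (player_id, game) with cluster index and
#'   behavior label.
#' @export
label_behaviors <- function(study, k = 4, seed = NULL, n_init = 10,
                            by_choices = TRUE) {
  av <- action_vectors(study)
  round_cols <- grep("^round_", names(av), value = TRUE)
  parts <- if (by_choices) split(av, av$treatment_choices) else list(av)
  seeds <- split_seeds(seed, length(parts))
  out <- purrr::map(seq_along(parts), function(i) {
    part <- parts[[i]]
    cl <- cluster_actions(part[round_cols], k = k, seed = seeds[i],
                          n_init = n_init)
    dplyr::mutate(
      part[c("player_id", "game", "group_id", "treatment_choices",
             "treatment_delegation")],
      cluster = cl$cluster,
      behavior = cl$labels[cl$cluster]
    )
  })
  dplyr::bind_rows(out)
}
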