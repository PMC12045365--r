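#' Draw one digital avatar of a sample
#'
#' A digital avatar keeps every cell position, every distance, and the
#' stroma geometry of the sample, and redistributes the marker labels
#' uniformly at random among the tumor cells while preserving the
#' positive count K: a uniformly random size-K subset is flagged positive.
#'
#' @param profile a `distance_profile`.
#' @param seed integer seed.
#' @return Logical marker vector of the same length with exactly
#'   `sum(profile$marker)` positives.
#' @export
make_avatar <- function(profile, seed) {
  stopifnot(inherits(profile, "distance_profile"))
  n <- length(profile$distance)
  k <- sum(profile$marker)
  flags <- rep(FALSE, n)
  if (k == 0L) return(flags)
  if (k == n) return(rep(TRUE, n))
  with_seed(seed, flags[sample.int(n, k)] <- TRUE)
  flags
}

#' Closed-form expected null ECDF
#'
#' Under the avatar null the positive subset is a uniformly random size-K
#' subset of the cells, so the expected value of the positive-subset ECDF
#' at any threshold is exactly the all-cell ECDF at that threshold. This is
#' the R -> infinity limit of averaging avatar ECDFs, with no sampling
#' noise.
#'
#' @param profile a `distance_profile` with at least one cell.
#' @return A `tissue_ecdf` over all tumor-cell distances.
#' @export
expected_null_ecdf <- function(profile) {
  stopifnot(inherits(profile, "distance_profile"))
  if (length(profile$distance) == 0L) stop("empty profile", call. = FALSE)
  ecdf_step(profile$distance)
}

#' Ensemble of digital-avatar null statistics
#'
#' Draws `R` independent avatars of one sample and records, per replicate,
#' the positive-subset median and mean distance and the KS statistic of the
#' avatar positives against all cells. Replicates are seeded by a counter
#' derived from `seed`, so replicate r is identical whether R = 100 or
#' R = 1000, and ensembles can be extended reproducibly.
#'
#' @param profile a `distance_profile` with K >= 1 positives.
#' @param R number of replicates (>= 1). The default 1000 gives empirical
#'   p-values on a 1/1001 grid; use [expected_null_ecdf()] wherever the
#'   expectation alone suffices.
#' @param seed integer seed.
#' @param ecdf_grid quantile grid (probabilities) at which the mean null
#'   ECDF is recorded; evaluated at the corresponding all-cell distance
#'   quantiles.
#' @return An object of class `avatar_ensemble`: data frame `replicates`
#'   (`replicate`, `median_um`, `mean_um`, `ks_d`), `null_ecdf` (grid
#'   distances and mean avatar ECDF there), and provenance `R`, `seed`,
#'   `K`, `N`.
#' @export
null_ensemble <- function(profile, R = 1000, seed, ecdf_grid = seq(0.1, 0.9,
                                                                   by = 0.1)) {
  stopifnot(inherits(profile, "distance_profile"))
  stopifnot_scalar(R, "R", min = 1, integer = TRUE)
  d <- profile$distance
  n <- length(d)
  k <- sum(profile$marker)
  if (k == 0L) stop("no marker-positive cells", call. = FALSE)
  grid_q <- as.numeric(stats::quantile(d, probs = ecdf_grid, type = 1))
  med <- mea <- ksd <- numeric(R)
  ecdf_sum <- numeric(length(grid_q))
  for (r in seq_len(R)) {
    flags <- make_avatar(profile, seed = derive_seed(seed, r))
    stopifnot(sum(flags) == k)  # count conservation, asserted on every draw
    dr <- d[flags]
    med[r] <- stats::median(dr)
    mea[r] <- mean(dr)
    ksd[r] <- ks_statistic(dr, d)$statistic
    ecdf_sum <- ecdf_sum + vapply(grid_q, function(q) mean(dr <= q), 0)
  }
  structure(list(
    replicates = data.frame(replicate = seq_len(R), median_um = med,
                            mean_um = mea, ks_d = ksd),
    null_ecdf = data.frame(distance_um = grid_q, prob = ecdf_sum / R),
    R = as.integer(R), seed = as.integer(seed), K = k, N = n
  ), class = "avatar_ensemble")
}

#' @export
print.avatar_ensemble <- function(x, ...) {
  cat(sprintf(
    "<avatar_ensemble> R=%d replicates, K=%d of N=%d positive, null median %.2f um (seed %d)\n",
    x$R, x$K, x$N, mean(x$replicates$median_um), x$seed))
  invisible(x)
}

#' Write an avatar ensemble to CSV + JSON header
#'
#' @param ensemble an `avatar_ensemble`.
#' @param path CSV path; a `.json` sidecar with R, seed, K, N is written
#'   next to it.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "avatar_ensemble"))
  utils::write.csv(ensemble$replicates, path, row.names = FALSE)
  jsonlite::write_json(ensemble[c("R", "seed", "K", "N")],
                       sub("\\.csv$", ".json", path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Empirical permutation p-value (add-one estimator)
#'
#' `p = (1 + #null as-or-more-extreme) / (R + 1)`; never exactly 0. For the
#' left tail (proximity bias: observed smaller than null), "as or more
#' extreme" means `null <= observed`.
#'
#' @param observed observed statistic.
#' @param null_values vector of null-replicate statistics, or an
#'   `avatar_ensemble` (then `statistic` selects the column).
#' @param tail `"left"`, `"right"` or `"two-sided"` (the latter is
#'   `min(1, 2 min(left, right))`).
#' @param statistic ensemble column when `null_values` is an ensemble.
#' @return p-value in `(0, 1]`.
#' @export
empirical_pvalue <- function(observed, null_values,
                             tail = c("left", "right", "two-sided"),
                             statistic = c("median_um", "mean_um", "ks_d")) {
  tail <- match.arg(tail)
  if (inherits(null_values, "avatar_ensemble")) {
    statistic <- match.arg(statistic)
    null_values <- null_values$replicates[[statistic]]
  }
  if (length(null_values) == 0L) stop("empty null ensemble", call. = FALSE)
  R <- length(null_values)
  left <- (1 + sum(null_values <= observed)) / (R + 1)
  right <- (1 + sum(null_values >= observed)) / (R + 1)
  switch(tail,
         left = left,
         right = right,
         `two-sided` = min(1, 2 * min(left, right)))
}
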