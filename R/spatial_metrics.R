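# Exact Euclidean distance (in pixels) from every pixel center to the
# nearest TRUE pixel center. EBImage::distmap measures foreground pixels to
# the nearest background pixel, so the target mask is inverted.
pixel_distance_map <- function(target) {
  target <- as_mask(target, "target")
  if (!any(target)) stop("distance map undefined: no stroma pixels",
                         call. = FALSE)
  if (all(target)) return(matrix(0, nrow(target), ncol(target)))
  m <- EBImage::distmap(matrix(as.numeric(!target), nrow(target),
                               ncol(target)), metric = "euclidean")
  matrix(as.numeric(m), nrow(target), ncol(target))
}

#' Distance map to the nearest stroma pixel
#'
#' Exact Euclidean distance from each pixel center to the nearest
#' stroma-pixel center, converted to microns. Stroma pixels map to 0.
#'
#' @param stroma a [stroma_geometry] or binary matrix with at least one
#'   stroma pixel.
#' @param pixel_size microns per pixel.
#' @return Numeric matrix of distances in microns, same shape as the mask.
#' @export
distance_map <- function(stroma, pixel_size) {
  if (inherits(stroma, "stroma_geometry")) stroma <- stroma$raster
  stopifnot_scalar(pixel_size, "pixel_size", min = .Machine$double.xmin)
  pixel_distance_map(stroma) * pixel_size
}

#' Per-cell distance-to-nearest-stroma profile
#'
#' Assigns every tumor cell the distance-map value of its containing pixel
#' (centroid-to-pixel-center on the rasterized geometry; the discretization
#' error is bounded by `pixel_size / sqrt(2)`).
#'
#' @param sample a [tissue_sample].
#' @return An object of class `distance_profile`: `distance` (microns,
#'   aligned with the sample's cell order), `marker` (logical),
#'   `pixel_size`, `sample_id`.
#' @export
cell_distances <- function(sample) {
  stopifnot(inherits(sample, "tissue_sample"))
  H <- nrow(sample$stroma); W <- ncol(sample$stroma)
  x <- sample$cells$x; y <- sample$cells$y
  bad <- which(!is.finite(x) | !is.finite(y) | x < 0 | x > W | y < 0 | y > H)
  if (length(bad)) {
    stop(sprintf("cell(s) outside grid bounds at index: %s",
                 paste(utils::head(bad, 20), collapse = ", ")), call. = FALSE)
  }
  dmap <- distance_map(sample$stroma, sample$pixel_size)
  d <- dmap[cbind(coord_to_row(y, H), coord_to_col(x, W))]
  structure(list(distance = d, marker = sample$cells$marker,
                 pixel_size = sample$pixel_size,
                 sample_id = sample$sample_id),
            class = "distance_profile")
}

#' @export
print.distance_profile <- function(x, ...) {
  cat(sprintf(
    "<distance_profile '%s'> %d cells (%d marker+), median %.2f um\n",
    x$sample_id, length(x$distance), sum(x$marker),
    stats::median(x$distance)))
  invisible(x)
}

#' Export a distance profile as a data frame
#'
#' @param x a `distance_profile`.
#' @param ... unused.
#' @return Data frame with `cell_id`, `distance_um`, `marker`.
#' @export
as.data.frame.distance_profile <- function(x, ...) {
  data.frame(cell_id = seq_along(x$distance), distance_um = x$distance,
             marker = x$marker)
}

#' Empirical cumulative distribution function
#'
#' Right-continuous step ECDF with tied values merged.
#'
#' @param values nonempty numeric vector.
#' @return An object of class `tissue_ecdf` with `support` (sorted unique
#'   values), `prob` (cumulative probabilities, ending at 1) and `n`.
#' @export
ecdf_step <- function(values) {
  if (length(values) == 0L) stop("ECDF of an empty sample", call. = FALSE)
  if (anyNA(values)) stop("ECDF input contains NA", call. = FALSE)
  support <- sort(unique(values))
  counts <- cumsum(tabulate(match(sort(values), support)))
  structure(list(support = support, prob = counts / length(values),
                 n = length(values)), class = "tissue_ecdf")
}

#' Evaluate a `tissue_ecdf` at arbitrary points
#'
#' @param e a `tissue_ecdf`.
#' @param q numeric vector of evaluation points.
#' @return `P(X <= q)` for each point.
#' @export
eval_ecdf <- function(e, q) {
  stopifnot(inherits(e, "tissue_ecdf"))
  c(0, e$prob)[findInterval(q, e$support) + 1L]
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' `D` is the supremum over the pooled support of the absolute difference
#' between the two ECDFs; the two-sided p-value is asymptotic, from the
#' Kolmogorov distribution at effective size `n = n_a n_b / (n_a + n_b)`
#' (the same approximation `stats::ks.test` uses). At histology-scale n the
#' p-value underflows toward zero, so `D` is the effect size of record.
#'
#' @param a,b nonempty numeric vectors.
#' @return List with `statistic` (D in `[0, 1]`) and `p.value`.
#' @export
ks_statistic <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("KS statistic of an empty sample", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  o <- order(pooled)
  steps <- c(rep(1 / na, na), rep(-1 / nb, nb))[o]
  cdf_diff <- cumsum(steps)
  ps <- pooled[o]
  last_of_tie <- c(ps[-1] != ps[-length(ps)], TRUE)
  D <- max(abs(cdf_diff[last_of_tie]))
  n_eff <- as.numeric(na) * nb / (na + nb)
  list(statistic = D, p.value = kolmogorov_sf(sqrt(n_eff) * D))
}

# Two-sided Kolmogorov survival function Q(t) = 2 * sum (-1)^(k-1) exp(-2k^2 t^2)
kolmogorov_sf <- function(t) {
  if (t < 0.2) return(1)
  k <- 1:100
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
}

#' Summarize a distance profile subset
#'
#' Median (midpoint of the two central order statistics for even n) and
#' arithmetic mean of the selected cells' distances.
#'
#' @param profile a `distance_profile`.
#' @param subset `"positive"`, `"negative"` or `"all"`.
#' @return List with `median`, `mean` (microns) and `n`.
#' @export
summarize_profile <- function(profile, subset = c("positive", "all",
                                                  "negative")) {
  stopifnot(inherits(profile, "distance_profile"))
  subset <- match.arg(subset)
  d <- switch(subset,
              all = profile$distance,
              positive = profile$distance[profile$marker],
              negative = profile$distance[!profile$marker])
  if (length(d) == 0L) {
    stop(switch(subset,
                positive = "no marker-positive cells",
                negative = "no marker-negative cells",
                "empty profile"), call. = FALSE)
  }
  list(median = stats::median(d), mean = mean(d), n = length(d))
}
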