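#' Configuration for a synthetic tumor cross-section
#'
#' Defines the geometry and labeling model of a simulated tissue section:
#' strand-like stroma grown by thickened correlated random walks, tumor-cell
#' centroids placed uniformly outside stroma and necrosis, and marker
#' positivity assigned with an optional exponential distance-dependent bias.
#'
#' The labeling model draws exactly `K = round(f * N)` positive cells without
#' replacement with weights `w_i = exp(-d_i / lambda)`, where `d_i` is the
#' cell's distance to the nearest stroma pixel in microns. `bias_length =
#' Inf` gives uniform weights, i.e. labels carry no spatial information: the
#' simulated sample is then one draw from its own digital-avatar null.
#'
#' Defaults emulate a whole tumor cross-section at segmentation scale: a
#' 1536 x 1536 grid at 2 um/pixel (a ~3 x 3 mm section), ~15% stroma area in
#' strands ~16 um wide, and 80,000 tumor cells (about one centroid per
#' 10 um), with a 10% marker-positive fraction.
#'
#' @param width,height raster size in pixels.
#' @param pixel_size microns per pixel (> 0).
#' @param n_stroma_seeds number of independent stroma strands (>= 0).
#' @param stroma_thickness strand thickness in pixels (>= 1).
#' @param target_stroma_fraction target stroma area fraction in `[0, 1)`;
#'   the generator stops once the realized fraction is within 20% (relative)
#'   of this value.
#' @param n_cells number of tumor-cell centroids (>= 0).
#' @param positive_fraction marker-positive fraction `f` in `[0, 1]`.
#' @param bias_length labeling bias length scale `lambda` in microns (> 0,
#'   may be `Inf` for no bias).
#' @param necrosis_fraction area fraction of a single elliptical necrotic
#'   region in `[0, 1)`; excluded from cell placement and from analysis.
#' @param seed integer seed; all generator randomness derives from it.
#'
#' @return An object of class `synthetic_config`.
#' @seealso [generate_dataset()]
#' @export
#' @examples
#' cfg <- synthetic_config(width = 256, height = 256, n_cells = 1000, seed = 1)
synthetic_config <- function(width = 1536, height = 1536, pixel_size = 2,
                             n_stroma_seeds = 12, stroma_thickness = 8,
                             target_stroma_fraction = 0.15,
                             n_cells = 80000, positive_fraction = 0.1,
                             bias_length = Inf, necrosis_fraction = 0,
                             seed = 1) {
  stopifnot_scalar(width, "width", min = 1, integer = TRUE)
  stopifnot_scalar(height, "height", min = 1, integer = TRUE)
  stopifnot_scalar(pixel_size, "pixel_size", min = .Machine$double.xmin)
  stopifnot_scalar(n_stroma_seeds, "n_stroma_seeds", min = 0, integer = TRUE)
  stopifnot_scalar(stroma_thickness, "stroma_thickness", min = 1)
  stopifnot_scalar(target_stroma_fraction, "target_stroma_fraction",
                   min = 0, max = 1 - 1e-12)
  stopifnot_scalar(n_cells, "n_cells", min = 0, integer = TRUE)
  stopifnot_scalar(positive_fraction, "positive_fraction", min = 0, max = 1)
  stopifnot_scalar(bias_length, "bias_length", min = .Machine$double.xmin,
                   allow_inf = TRUE)
  stopifnot_scalar(necrosis_fraction, "necrosis_fraction", min = 0,
                   max = 1 - 1e-12)
  stopifnot_scalar(seed, "seed", integer = TRUE)
  if (target_stroma_fraction + necrosis_fraction >= 1) {
    stop("target_stroma_fraction + necrosis_fraction must be < 1",
         call. = FALSE)
  }
  structure(list(
    width = as.integer(width), height = as.integer(height),
    pixel_size = pixel_size,
    n_stroma_seeds = as.integer(n_stroma_seeds),
    stroma_thickness = stroma_thickness,
    target_stroma_fraction = target_stroma_fraction,
    n_cells = as.integer(n_cells),
    positive_fraction = positive_fraction,
    bias_length = bias_length,
    necrosis_fraction = necrosis_fraction,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Generate strand-like stroma geometry
#'
#' Grows `n_stroma_seeds` correlated random walks over the raster and
#' thickens each path to `stroma_thickness` pixels (by thresholding the
#' exact Euclidean distance map of the path), adding steps until the
#' realized stroma area fraction is within 20% (relative) of
#' `target_stroma_fraction`. Strand-shaped stroma gives the broad range of
#' cell-to-stroma distances that peristromal analyses probe; compact blobs
#' would not.
#'
#' @param config a [synthetic_config()].
#' @return A [stroma_geometry] whose raster has `config$height` rows and
#'   `config$width` columns. Deterministic given `config$seed`.
#' @export
generate_stroma <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  W <- config$width; H <- config$height
  target <- config$target_stroma_fraction
  thick <- config$stroma_thickness
  nseed <- config$n_stroma_seeds
  if (nseed == 0L || target == 0) {
    return(stroma_geometry(matrix(FALSE, H, W)))
  }
  with_seed(config$seed, {
    path <- matrix(FALSE, H, W)
    pos_x <- runif(nseed, 0, W); pos_y <- runif(nseed, 0, H)
    ang <- runif(nseed, 0, 2 * pi)
    realized <- 0; iter <- 0L; max_iter <- 60L
    # each new strand pays a one-off disc end-cap on top of length x thickness
    cap_px <- nseed * pi * (thick / 2)^2
    if (cap_px > 1.2 * target * W * H) {
      stop(sprintf(
        "stroma generation failed: %d strands of thickness %g cover at least %.4f of the grid vs target %.4f (+/-20%%)",
        nseed, thick, cap_px / (W * H), target), call. = FALSE)
    }
    repeat {
      iter <- iter + 1L
      need_px <- (target - realized) * W * H - if (iter == 1L) cap_px else 0
      steps <- max(4L, ceiling(0.7 * max(need_px, 0) / thick / nseed))
      for (s in seq_len(nseed)) {
        a <- ang[s] + cumsum(rnorm(steps, 0, 0.25))
        x <- pos_x[s] + cumsum(cos(a))
        y <- pos_y[s] + cumsum(sin(a))
        # reflect walks at the tissue border (triangle fold into [0, W]x[0, H])
        x <- x %% (2 * W); x <- ifelse(x > W, 2 * W - x, x)
        y <- y %% (2 * H); y <- ifelse(y > H, 2 * H - y, y)
        ci <- pmin(pmax(floor(x) + 1L, 1L), W)
        ri <- pmin(pmax(floor(y) + 1L, 1L), H)
        path[cbind(ri, ci)] <- TRUE
        pos_x[s] <- x[steps]; pos_y[s] <- y[steps]; ang[s] <- a[steps]
      }
      stroma <- pixel_distance_map(path) <= thick / 2
      realized <- mean(stroma)
      if (realized >= 0.8 * target && realized <= 1.2 * target) break
      if (realized > 1.2 * target || iter >= max_iter) {
        stop(sprintf(
          "stroma generation failed: realized fraction %.4f vs target %.4f (+/-20%%)",
          realized, target), call. = FALSE)
      }
    }
    stroma_geometry(stroma)
  })
}

#' Place tumor-cell centroids uniformly outside stroma and exclusion
#'
#' Samples `n_cells` pixels uniformly (with replacement) among pixels that
#' are neither stroma nor excluded, then jitters each point uniformly within
#' its pixel so coordinates are continuous, like centroid exports from
#' segmentation platforms. Coordinates are image coordinates: origin at the
#' top-left corner, x rightward, y downward; pixel (row i, col j) covers
#' `x` in `[j-1, j)` and `y` in `[i-1, i)`.
#'
#' @param geometry a [stroma_geometry] (or binary matrix).
#' @param exclusion optional binary matrix of excluded (necrotic) pixels,
#'   same shape; `NULL` means none.
#' @param n_cells number of centroids.
#' @param seed integer seed.
#' @return A data frame with columns `x`, `y` (continuous pixel coordinates).
#' @export
place_cells <- function(geometry, exclusion = NULL, n_cells, seed) {
  stroma <- if (inherits(geometry, "stroma_geometry")) geometry$raster
            else as_mask(geometry, "geometry")
  stopifnot_scalar(n_cells, "n_cells", min = 0, integer = TRUE)
  if (is.null(exclusion)) exclusion <- matrix(FALSE, nrow(stroma), ncol(stroma))
  exclusion <- as_mask(exclusion, "exclusion")
  if (!identical(dim(stroma), dim(exclusion))) {
    stop("stroma and exclusion must have the same shape", call. = FALSE)
  }
  if (n_cells == 0L) return(data.frame(x = numeric(0), y = numeric(0)))
  admissible <- which(!stroma & !exclusion)
  if (length(admissible) == 0L) stop("no admissible pixels", call. = FALSE)
  if (n_cells > length(admissible)) {
    stop(sprintf("cannot place %d cells in %d admissible pixels",
                 n_cells, length(admissible)), call. = FALSE)
  }
  H <- nrow(stroma)
  with_seed(seed, {
    px <- admissible[sample.int(length(admissible), n_cells, replace = TRUE)]
    ri <- ((px - 1L) %% H) + 1L
    ci <- ((px - 1L) %/% H) + 1L
    data.frame(x = (ci - 1L) + runif(n_cells),
               y = (ri - 1L) + runif(n_cells))
  })
}

#' Assign marker positivity with a distance-dependent bias
#'
#' Flags exactly `K = round(f * N)` cells positive, drawn without
#' replacement with weights `w_i = exp(-d_i / lambda)` (successive draws
#' proportional to remaining weights, realized via exponential race keys in
#' log space so small weights never underflow). `lambda = Inf` gives uniform
#' weights, i.e. a uniformly random size-K subset -- exactly one draw from
#' the digital-avatar null.
#'
#' @param distances per-cell distances to nearest stroma, microns.
#' @param f positive fraction in `[0, 1]`.
#' @param lambda bias length scale in microns (> 0 or `Inf`).
#' @param seed integer seed.
#' @return Logical vector of length `length(distances)` with exactly
#'   `round(f * length(distances))` `TRUE` entries.
#' @export
assign_marker <- function(distances, f, lambda, seed) {
  stopifnot_scalar(f, "f", min = 0, max = 1)
  stopifnot_scalar(lambda, "lambda", min = .Machine$double.xmin,
                   allow_inf = TRUE)
  if (length(distances) && (anyNA(distances) || any(distances < 0))) {
    stop("`distances` must be non-negative and non-missing", call. = FALSE)
  }
  n <- length(distances)
  k <- round(f * n)
  flags <- rep(FALSE, n)
  if (k == 0L || n == 0L) return(flags)
  if (k >= n) return(rep(TRUE, n))
  with_seed(seed, {
    # exponential race: arrival time Exp(1)/w_i; K smallest arrivals win.
    # log-arrival = log(E_i) + d_i/lambda avoids exp(-d/lambda) underflow.
    key <- log(rexp(n)) + if (is.finite(lambda)) distances / lambda else 0
    flags[order(key)[seq_len(k)]] <- TRUE
  })
  flags
}

#' Generate a complete synthetic tissue sample with known truth
#'
#' Composes [generate_stroma()], an optional single elliptical necrotic
#' region, [place_cells()] and [assign_marker()] into a validated
#' [tissue_sample], and records the generator truth (the config used, the
#' realized stroma fraction, and the realized positive count) for
#' parameter-recovery tests.
#'
#' @param config a [synthetic_config()].
#' @param sample_id,treatment,host_model labels stored on the sample.
#' @return A list with elements `sample` (a [tissue_sample]) and `truth`
#'   (class `synthetic_truth`: `config`, `stroma_fraction`,
#'   `necrosis_fraction`, `k_positive`).
#' @export
generate_dataset <- function(config, sample_id = "synthetic",
                             treatment = "none", host_model = "synthetic") {
  stopifnot(inherits(config, "synthetic_config"))
  geom <- generate_stroma(config)
  exclusion <- if (config$necrosis_fraction > 0) {
    necrosis_ellipse(config)
  } else {
    matrix(FALSE, config$height, config$width)
  }
  coords <- place_cells(geom, exclusion, config$n_cells,
                        seed = derive_seed(config$seed, 1L))
  # distances for labeling use the same stroma targets the analysis will see
  # (necrotic stroma pixels are not distance targets)
  target <- geom$raster & !exclusion
  if (!any(target)) stop("no stroma outside exclusion", call. = FALSE)
  dmap <- pixel_distance_map(target) * config$pixel_size
  ri <- pmin(pmax(floor(coords$y) + 1L, 1L), config$height)
  ci <- pmin(pmax(floor(coords$x) + 1L, 1L), config$width)
  d_um <- dmap[cbind(ri, ci)]
  marker <- assign_marker(d_um, config$positive_fraction, config$bias_length,
                          seed = derive_seed(config$seed, 2L))
  cells <- data.frame(x = coords$x, y = coords$y,
                      cell_class = rep("tumor", nrow(coords)),
                      marker = marker)
  sample <- assemble_sample(cells, geom, exclusion,
                            pixel_size = config$pixel_size,
                            sample_id = sample_id, treatment = treatment,
                            host_model = host_model, quiet = TRUE)
  truth <- structure(list(
    config = config,
    stroma_fraction = mean(geom$raster),
    necrosis_fraction = mean(exclusion),
    k_positive = sum(marker)
  ), class = "synthetic_truth")
  list(sample = sample, truth = truth)
}

# Single random ellipse with area ~= necrosis_fraction * W * H (2:1 axes,
# random orientation and center; clipping at borders can shrink it).
necrosis_ellipse <- function(config) {
  W <- config$width; H <- config$height
  with_seed(derive_seed(config$seed, 3L), {
    b <- sqrt(config$necrosis_fraction * W * H / (2 * pi))
    a <- 2 * b
    cx <- runif(1, 0.2 * W, 0.8 * W)
    cy <- runif(1, 0.2 * H, 0.8 * H)
    th <- runif(1, 0, pi)
    xs <- matrix(rep(seq_len(W) - 0.5, each = H), H, W) - cx
    ys <- matrix(rep(seq_len(H) - 0.5, W), H, W) - cy
    u <- xs * cos(th) + ys * sin(th)
    v <- -xs * sin(th) + ys * cos(th)
    (u / a)^2 + (v / b)^2 <= 1
  })
}
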