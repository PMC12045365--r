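# Brute-force oracles and small fixture builders shared across tests.
# Oracles are deliberately naive and independent of the package internals.

# distance (pixels) from every pixel center to the nearest TRUE pixel,
# by minimizing over all TRUE pixels
brute_distance_map <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) {
    for (cc in seq_len(ncol(mask))) {
      out[r, cc] <- sqrt(min((idx[, 1] - r)^2 + (idx[, 2] - cc)^2))
    }
  }
  out
}

# sup |F_a - F_b| over the pooled support, by direct ECDF evaluation
brute_ks_d <- function(a, b) {
  support <- sort(unique(c(a, b)))
  fa <- vapply(support, function(q) mean(a <= q), 0)
  fb <- vapply(support, function(q) mean(b <= q), 0)
  max(abs(fa - fb))
}

# even-odd point-in-polygon with boundary counted inside; `rings` is a
# list of n x 2 matrices
brute_point_in_rings <- function(px, py, rings) {
  crossings <- 0L
  on_boundary <- FALSE
  for (ring in rings) {
    n <- nrow(ring)
    for (e in seq_len(n)) {
      x1 <- ring[e, 1]; y1 <- ring[e, 2]
      x2 <- ring[e %% n + 1, 1]; y2 <- ring[e %% n + 1, 2]
      seg_len2 <- (x2 - x1)^2 + (y2 - y1)^2
      cr <- (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1)
      if (seg_len2 > 0 && abs(cr) < 1e-9 &&
          px >= min(x1, x2) - 1e-9 && px <= max(x1, x2) + 1e-9 &&
          py >= min(y1, y2) - 1e-9 && py <= max(y1, y2) + 1e-9) {
        on_boundary <- TRUE
      }
      if ((y1 <= py) != (y2 <= py)) {
        xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
        if (px < xint) crossings <- crossings + 1L
      }
    }
  }
  on_boundary || (crossings %% 2L == 1L)
}

brute_rasterize <- function(polygons, shape) {
  H <- shape[1]; W <- shape[2]
  out <- matrix(FALSE, H, W)
  for (r in seq_len(H)) {
    for (cc in seq_len(W)) {
      for (p in polygons) {
        if (brute_point_in_rings(cc - 0.5, r - 0.5, p)) {
          out[r, cc] <- TRUE
          break
        }
      }
    }
  }
  out
}

# compact synthetic config used throughout the tests (geometry scaled down
# from the whole-section defaults for speed; same structure)
small_config <- function(seed, n_cells = 2000, bias_length = Inf,
                         positive_fraction = 0.1, width = 192, height = 192,
                         ...) {
  synthetic_config(width = width, height = height, pixel_size = 2,
                   n_stroma_seeds = 5, stroma_thickness = 5,
                   target_stroma_fraction = 0.15, n_cells = n_cells,
                   positive_fraction = positive_fraction,
                   bias_length = bias_length, seed = seed, ...)
}

# hand-built sample: explicit masks and cell positions, no randomness
toy_sample <- function(stroma, cells_xy, marker, pixel_size = 1,
                       exclusion = NULL) {
  cells <- data.frame(x = cells_xy[, 1], y = cells_xy[, 2],
                      cell_class = "tumor", marker = marker)
  assemble_sample(cells, stroma, exclusion, pixel_size = pixel_size,
                  sample_id = "toy", quiet = TRUE)
}
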