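#' Stroma geometry container
#'
#' A binary raster of stroma pixels, optionally retaining the source
#' polygons for provenance. Row `i`, column `j` of the raster is the pixel
#' whose center lies at image coordinate `(j - 0.5, i - 0.5)` (origin
#' top-left, x rightward, y downward).
#'
#' @param raster logical (or 0/1) matrix, `TRUE` = stroma pixel.
#' @param polygons optional `tissue_polygons` the raster was derived from.
#' @return An object of class `stroma_geometry`.
#' @export
stroma_geometry <- function(raster, polygons = NULL) {
  raster <- as_mask(raster, "raster")
  if (nrow(raster) == 0L || ncol(raster) == 0L) {
    stop("stroma raster must be a non-empty grid", call. = FALSE)
  }
  structure(list(raster = raster, polygons = polygons),
            class = "stroma_geometry")
}

#' Column mapping for segmentation cell tables
#'
#' Names the columns of a delimited cell-table export and the vocabularies
#' used for the cell-class and marker columns. Defaults match the bundled
#' writer: columns `x,y,class,marker`, classes `tumor`/`other`, marker
#' `pos`/`neg`.
#'
#' @param x,y,cell_class,marker column names in the file header.
#' @param tumor_classes,other_classes character vectors of class values to
#'   treat as tumor cells / non-tumor cells. Any other value is an error.
#' @param positive_values,negative_values marker values meaning positive /
#'   negative. Any other value is an error.
#' @return A list of class `cell_table_mapping`.
#' @export
cell_table_mapping <- function(x = "x", y = "y", cell_class = "class",
                               marker = "marker",
                               tumor_classes = "tumor",
                               other_classes = "other",
                               positive_values = "pos",
                               negative_values = "neg") {
  structure(list(x = x, y = y, cell_class = cell_class, marker = marker,
                 tumor_classes = tumor_classes, other_classes = other_classes,
                 positive_values = positive_values,
                 negative_values = negative_values),
            class = "cell_table_mapping")
}

#' Read a per-cell segmentation table
#'
#' Parses a delimited text export of cell centroids with class and marker
#' labels. Non-tumor classes are retained but flagged (they are dropped at
#' assembly). Rows with missing or non-numeric coordinates are rejected
#' with a warning listing their row numbers; unknown class or marker values
#' are an error.
#'
#' @param path path to a delimited text file with a header row.
#' @param mapping a [cell_table_mapping()].
#' @param sep field separator (default comma).
#' @return A data frame with columns `x`, `y`, `cell_class`
#'   (`"tumor"`/`"other"`) and `marker` (logical).
#' @export
read_cell_table <- function(path, mapping = cell_table_mapping(), sep = ",") {
  stopifnot(inherits(mapping, "cell_table_mapping"))
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE)
  for (col in c(mapping$x, mapping$y, mapping$cell_class, mapping$marker)) {
    if (!col %in% names(raw)) {
      stop(sprintf("cell table %s is missing mapped column '%s'", path, col),
           call. = FALSE)
    }
  }
  x <- suppressWarnings(as.numeric(raw[[mapping$x]]))
  y <- suppressWarnings(as.numeric(raw[[mapping$y]]))
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad)) {
    warning(sprintf("rejected %d malformed row(s): %s", length(bad),
                    paste(utils::head(bad, 20), collapse = ", ")),
            call. = FALSE)
    keep <- setdiff(seq_along(x), bad)
  } else keep <- seq_along(x)

  cls <- as.character(raw[[mapping$cell_class]])[keep]
  unknown <- setdiff(unique(cls), c(mapping$tumor_classes,
                                    mapping$other_classes))
  if (length(unknown)) {
    stop(sprintf("unmappable cell-class value(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  mk <- as.character(raw[[mapping$marker]])[keep]
  unknown <- setdiff(unique(mk), c(mapping$positive_values,
                                   mapping$negative_values))
  if (length(unknown)) {
    stop(sprintf("unmappable marker value(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  data.frame(
    x = x[keep], y = y[keep],
    cell_class = ifelse(cls %in% mapping$tumor_classes, "tumor", "other"),
    marker = mk %in% mapping$positive_values
  )
}

#' Read stroma or exclusion geometry
#'
#' Auto-detects the format from the file extension: `.geojson`/`.json`
#' (RFC 7946 Polygon/MultiPolygon features), `.wkt`/`.txt` (WKT POLYGON or
#' MULTIPOLYGON), or `.png`/`.tif`/`.tiff` single-channel masks (any
#' nonzero value = foreground; platforms export 1/255 inconsistently).
#' Polygon coordinates are taken as image coordinates (pixels, origin
#' top-left). Self-intersecting rings are an error; no silent repair.
#'
#' @param path path to a geometry file.
#' @return For mask files, a logical matrix. For polygon files, a
#'   `tissue_polygons` object: a list of polygons, each a list of rings,
#'   each ring an n x 2 matrix of `(x, y)` vertices.
#' @export
read_geometry <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("png", "tif", "tiff")) {
    img <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]  # first channel
    return(as_mask(img > 0, "mask"))
  }
  polys <- if (ext %in% c("geojson", "json")) {
    parse_geojson(path)
  } else if (ext %in% c("wkt", "txt")) {
    parse_wkt(paste(readLines(path, warn = FALSE), collapse = " "))
  } else {
    stop(sprintf("unsupported geometry extension '.%s'", ext), call. = FALSE)
  }
  for (p in polys) for (ring in p) check_simple_ring(ring)
  structure(polys, class = "tissue_polygons")
}

# GeoJSON -> list of polygons (list of rings; ring = n x 2 matrix).
parse_geojson <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  geoms <- switch(g$type,
    FeatureCollection = lapply(g$features, `[[`, "geometry"),
    Feature = list(g$geometry),
    list(g))
  out <- list()
  for (geom in geoms) {
    ring_mat <- function(r) {
      m <- do.call(rbind, lapply(r, function(pt) c(pt[[1]], pt[[2]])))
      # GeoJSON rings repeat the first vertex; drop the closing copy
      if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
      colnames(m) <- c("x", "y"); m
    }
    if (identical(geom$type, "Polygon")) {
      out <- c(out, list(lapply(geom$coordinates, ring_mat)))
    } else if (identical(geom$type, "MultiPolygon")) {
      out <- c(out, lapply(geom$coordinates, function(p) lapply(p, ring_mat)))
    } else {
      stop(sprintf("unsupported GeoJSON geometry type '%s'", geom$type),
           call. = FALSE)
    }
  }
  out
}

# Minimal WKT reader for POLYGON and MULTIPOLYGON.
parse_wkt <- function(text) {
  text <- trimws(text)
  type <- toupper(sub("\\s*\\(.*$", "", text))
  body <- sub("^[A-Za-z ]+", "", text)
  ring_mat <- function(s) {
    toks <- strsplit(trimws(strsplit(s, ",")[[1]]), "\\s+")
    m <- do.call(rbind, lapply(toks, function(t) as.numeric(t[1:2])))
    if (anyNA(m)) stop("malformed WKT coordinates", call. = FALSE)
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    colnames(m) <- c("x", "y"); m
  }
  # split a parenthesized list at top-level commas
  split_groups <- function(s) {
    s <- trimws(s)
    stopifnot(startsWith(s, "("), endsWith(s, ")"))
    s <- substr(s, 2, nchar(s) - 1)
    depth <- 0L; start <- 1L; parts <- character(0)
    chars <- strsplit(s, "")[[1]]
    for (i in seq_along(chars)) {
      if (chars[i] == "(") depth <- depth + 1L
      if (chars[i] == ")") depth <- depth - 1L
      if (chars[i] == "," && depth == 0L) {
        parts <- c(parts, substr(s, start, i - 1L)); start <- i + 1L
      }
    }
    c(parts, substr(s, start, nchar(s)))
  }
  strip <- function(s) { s <- trimws(s); substr(s, 2, nchar(s) - 1) }
  if (type == "POLYGON") {
    list(lapply(split_groups(body), function(r) ring_mat(strip(r))))
  } else if (type == "MULTIPOLYGON") {
    lapply(split_groups(body), function(p)
      lapply(split_groups(trimws(p)), function(r) ring_mat(strip(r))))
  } else {
    stop(sprintf("unsupported WKT type '%s'", type), call. = FALSE)
  }
}

# Error if a ring's non-adjacent edges intersect (self-intersection).
check_simple_ring <- function(ring) {
  n <- nrow(ring)
  if (n < 3L) stop("polygon ring has fewer than 3 vertices", call. = FALSE)
  seg <- cbind(ring, ring[c(2:n, 1), , drop = FALSE])  # x1 y1 x2 y2
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j == i + 1L || (i == 1L && j == n)) next  # adjacent edges share a vertex
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- cross(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- cross(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- cross(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0)) &&
          d1 != 0 && d2 != 0 && d3 != 0 && d4 != 0) {
        stop("self-intersecting polygon ring", call. = FALSE)
      }
    }
  }
  invisible(ring)
}

#' Rasterize polygons onto a pixel grid
#'
#' A pixel is foreground iff its center lies inside any ring under the
#' even-odd rule (so holes subtract); a center lying exactly on a ring edge
#' is resolved as inside. Polygons entirely outside the grid contribute no
#' pixels and raise a warning.
#'
#' @param polygons a `tissue_polygons` object (from [read_geometry()]) or a
#'   bare list of rings.
#' @param shape grid shape `c(height, width)` in pixels.
#' @return Logical matrix of the given shape.
#' @export
rasterize_polygons <- function(polygons, shape) {
  stopifnot(length(shape) == 2L, all(shape >= 1))
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  if (inherits(polygons, "tissue_polygons")) polygons <- unclass(polygons)
  if (length(polygons) && is.matrix(polygons[[1]])) polygons <- list(polygons)
  crossings <- matrix(0L, H, W)
  boundary <- matrix(FALSE, H, W)
  yc <- seq_len(H) - 0.5
  tol <- 1e-9
  for (p in seq_along(polygons)) {
    rings <- polygons[[p]]
    allv <- do.call(rbind, rings)
    if (all(allv[, 1] < 0) || all(allv[, 1] > W) ||
        all(allv[, 2] < 0) || all(allv[, 2] > H)) {
      warning(sprintf("polygon %d lies entirely outside the grid", p),
              call. = FALSE)
      next
    }
    for (ring in rings) {
      n <- nrow(ring)
      nxt <- c(2:n, 1)
      for (e in seq_len(n)) {
        x1 <- ring[e, 1]; y1 <- ring[e, 2]
        x2 <- ring[nxt[e], 1]; y2 <- ring[nxt[e], 2]
        # even-odd crossing: half-open in y so shared vertices count once
        if (y1 != y2) {
          lo <- min(y1, y2); hi <- max(y1, y2)
          rows <- which(yc >= lo & yc < hi)
          if (length(rows)) {
            xint <- x1 + (yc[rows] - y1) * (x2 - x1) / (y2 - y1)
            # center (r, j) has x = j - 0.5; count columns with center left of xint
            m <- pmin(pmax(floor(xint + 0.5), 0), W)
            has <- m > 0L
            crossings[cbind(rows[has], m[has])] <-
              crossings[cbind(rows[has], m[has])] + 1L
          }
        }
        # boundary centers: collinear with the edge and inside its bbox
        rlo <- max(1L, floor(min(y1, y2) + 0.5 - tol) + 1L)
        rhi <- min(H, ceiling(max(y1, y2) + 0.5 + tol))
        if (rlo <= rhi) {
          for (r in rlo:rhi) {
            ycr <- r - 0.5
            xs <- seq_len(W) - 0.5
            on <- abs((x2 - x1) * (ycr - y1) - (xs - x1) * (y2 - y1)) <= tol &
              xs >= min(x1, x2) - tol & xs <= max(x1, x2) + tol &
              ycr >= min(y1, y2) - tol & ycr <= max(y1, y2) + tol
            boundary[r, on] <- TRUE
          }
        }
      }
    }
  }
  # "crossings at columns <= m" accumulated at column m: suffix-sum rightward
  parity <- t(apply(crossings, 1, function(v) rev(cumsum(rev(v))))) %% 2L
  if (H == 1L) parity <- matrix(parity, 1L, W)
  (parity == 1L) | boundary
}

#' Assemble a validated tissue sample
#'
#' Builds the analysis-ready object from parsed parts: keeps tumor-class
#' cells only, drops cells on excluded (necrotic) pixels, keeps cells that
#' fall on stroma pixels (they get distance 0 -- rasterization coarsens
#' boundaries, and dropping them would bias against the peristromal
#' signal), and, by default, removes necrotic stroma pixels from the stroma
#' raster so they are not distance targets. Dropped/retained counts are
#' reported via [message()].
#'
#' @param cells data frame with `x`, `y`, `cell_class`, `marker` (as from
#'   [read_cell_table()]); `cell_class` may be omitted, in which case all
#'   cells are taken as tumor.
#' @param stroma a [stroma_geometry], binary matrix, or `tissue_polygons`
#'   (rasterized to `shape`).
#' @param exclusion optional binary matrix (or `tissue_polygons`) of
#'   necrotic pixels; `NULL` means none.
#' @param pixel_size microns per pixel (> 0).
#' @param sample_id,treatment,host_model sample labels.
#' @param exclude_necrotic_stroma if `TRUE` (default), stroma pixels inside
#'   the exclusion mask are not used as distance targets.
#' @param shape grid shape `c(height, width)`, required only when `stroma`
#'   is given as polygons.
#' @param quiet suppress count messages.
#' @return An object of class `tissue_sample`: `cells` (tumor cells only,
#'   columns `x`, `y`, `marker`), `stroma` (logical matrix of distance
#'   targets), `exclusion`, `pixel_size`, `sample_id`, `treatment`,
#'   `host_model`.
#' @export
assemble_sample <- function(cells, stroma, exclusion = NULL, pixel_size,
                            sample_id = "sample", treatment = NA_character_,
                            host_model = NA_character_,
                            exclude_necrotic_stroma = TRUE, shape = NULL,
                            quiet = FALSE) {
  stopifnot_scalar(pixel_size, "pixel_size", min = .Machine$double.xmin)
  pixel_size <- as.numeric(pixel_size)
  if (inherits(stroma, "tissue_polygons")) {
    if (is.null(shape)) stop("`shape` is required for polygon stroma",
                             call. = FALSE)
    stroma <- rasterize_polygons(stroma, shape)
  }
  if (inherits(stroma, "stroma_geometry")) stroma <- stroma$raster
  stroma <- as_mask(stroma, "stroma")
  H <- nrow(stroma); W <- ncol(stroma)
  if (is.null(exclusion)) {
    exclusion <- matrix(FALSE, H, W)
  } else if (inherits(exclusion, "tissue_polygons")) {
    exclusion <- rasterize_polygons(exclusion, c(H, W))
  }
  exclusion <- as_mask(exclusion, "exclusion")
  if (!identical(dim(stroma), dim(exclusion))) {
    stop("stroma and exclusion grids must have the same shape", call. = FALSE)
  }

  if (!is.data.frame(cells) || !all(c("x", "y") %in% names(cells))) {
    stop("`cells` must be a data frame with columns x and y", call. = FALSE)
  }
  if (!"cell_class" %in% names(cells)) cells$cell_class <- "tumor"
  if (!"marker" %in% names(cells)) {
    stop("`cells` must have a logical `marker` column", call. = FALSE)
  }
  bad <- which(!is.finite(cells$x) | !is.finite(cells$y) |
               cells$x < 0 | cells$x > W | cells$y < 0 | cells$y > H)
  if (length(bad)) {
    stop(sprintf("cell coordinates out of bounds at row(s): %s",
                 paste(utils::head(bad, 20), collapse = ", ")), call. = FALSE)
  }

  n_other <- sum(cells$cell_class != "tumor")
  cells <- cells[cells$cell_class == "tumor", , drop = FALSE]
  ri <- coord_to_row(cells$y, H)
  ci <- coord_to_col(cells$x, W)
  on_excl <- exclusion[cbind(ri, ci)]
  n_excl <- sum(on_excl)
  cells <- cells[!on_excl, , drop = FALSE]
  ri <- ri[!on_excl]; ci <- ci[!on_excl]
  if (nrow(cells) == 0L) stop("zero tumor cells after filtering",
                              call. = FALSE)
  n_on_stroma <- sum(stroma[cbind(ri, ci)])

  if (exclude_necrotic_stroma) stroma <- stroma & !exclusion
  if (!any(stroma)) stop("no stroma pixels outside exclusion", call. = FALSE)

  if (!quiet) {
    message(sprintf(
      "sample '%s': %d tumor cells retained (%d non-tumor dropped, %d on necrosis dropped, %d on stroma kept with distance 0)",
      sample_id, nrow(cells), n_other, n_excl, n_on_stroma))
  }
  structure(list(
    cells = data.frame(x = cells$x, y = cells$y,
                       marker = as.logical(cells$marker)),
    stroma = stroma, exclusion = exclusion, pixel_size = pixel_size,
    sample_id = sample_id, treatment = treatment, host_model = host_model,
    n_dropped_other = n_other, n_dropped_excluded = n_excl,
    n_on_stroma = n_on_stroma
  ), class = "tissue_sample")
}

# continuous image coordinate -> 1-based pixel index; the far border
# (x == W, y == H) belongs to the last pixel
coord_to_col <- function(x, W) pmin(floor(x) + 1L, W)
coord_to_row <- function(y, H) pmin(floor(y) + 1L, H)

#' @export
print.tissue_sample <- function(x, ...) {
  cat(sprintf(
    "<tissue_sample '%s'> %d tumor cells (%d marker+), %dx%d grid @ %g um/px, stroma %.1f%%\n",
    x$sample_id, nrow(x$cells), sum(x$cells$marker),
    nrow(x$stroma), ncol(x$stroma), x$pixel_size, 100 * mean(x$stroma)))
  invisible(x)
}

#' Write a tissue sample bundle to a directory
#'
#' The bundle is `cells.csv` (columns `x,y,class,marker`, marker as
#' `pos`/`neg`), `stroma.png`, `exclusion.png` (only when any pixel is
#' excluded) and `sample.json` (pixel size and labels).
#'
#' @param sample a [tissue_sample].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sample <- function(sample, dir) {
  stopifnot(inherits(sample, "tissue_sample"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cells <- data.frame(x = sample$cells$x, y = sample$cells$y,
                      class = "tumor",
                      marker = ifelse(sample$cells$marker, "pos", "neg"))
  utils::write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE,
                   quote = FALSE)
  png::writePNG(sample$stroma * 1, file.path(dir, "stroma.png"))
  if (any(sample$exclusion)) {
    png::writePNG(sample$exclusion * 1, file.path(dir, "exclusion.png"))
  }
  jsonlite::write_json(list(pixel_size = sample$pixel_size,
                            sample_id = sample$sample_id,
                            treatment = sample$treatment,
                            host_model = sample$host_model),
                       file.path(dir, "sample.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a tissue sample bundle
#'
#' Reads a directory written by [write_sample()] (or assembled by hand in
#' the same layout) and re-runs assembly validation.
#'
#' @param dir bundle directory.
#' @param mapping a [cell_table_mapping()] for `cells.csv`.
#' @param quiet suppress assembly messages.
#' @return A [tissue_sample].
#' @export
read_sample <- function(dir, mapping = cell_table_mapping(), quiet = FALSE) {
  meta <- jsonlite::fromJSON(file.path(dir, "sample.json"))
  cells <- read_cell_table(file.path(dir, "cells.csv"), mapping)
  stroma <- read_geometry(file.path(dir, "stroma.png"))
  excl_path <- file.path(dir, "exclusion.png")
  exclusion <- if (file.exists(excl_path)) read_geometry(excl_path) else NULL
  assemble_sample(cells, stroma, exclusion,
                  pixel_size = meta$pixel_size,
                  sample_id = meta$sample_id %||% basename(dir),
                  treatment = meta$treatment %||% NA_character_,
                  host_model = meta$host_model %||% NA_character_,
                  quiet = quiet)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
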