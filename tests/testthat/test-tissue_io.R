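test_that("cell tables parse with configurable column mapping", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cx,cy,kind,brdu",
               "1.5,2.5,tumor,pos",
               "3.0,4.0,tumor,neg",
               "5.5,0.5,other,neg"), path)
  mp <- cell_table_mapping(x = "cx", y = "cy", cell_class = "kind",
                           marker = "brdu")
  cells <- read_cell_table(path, mp)
  expect_identical(nrow(cells), 3L)
  expect_identical(cells$cell_class, c("tumor", "tumor", "other"))
  expect_identical(cells$marker, c(TRUE, FALSE, FALSE))
  expect_identical(cells$x, c(1.5, 3.0, 5.5))
})

test_that("missing columns and unknown vocabularies are errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,class", "1,2,tumor"), path)
  expect_error(read_cell_table(path), "marker")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,class,marker", "1,2,stroma_cell,pos"), path2)
  expect_error(read_cell_table(path2), "stroma_cell")

  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,class,marker", "1,2,tumor,maybe"), path3)
  expect_error(read_cell_table(path3), "maybe")
})

test_that("malformed coordinate rows are rejected with their row numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,class,marker",
               "1,2,tumor,pos",
               "oops,3,tumor,neg",
               "4,5,tumor,neg"), path)
  expect_warning(cells <- read_cell_table(path), "2")
  expect_identical(nrow(cells), 2L)
})

test_that("large cell tables parse and assemble", {
  # scale of a whole tumor cross-section export
  n <- 400000L
  path <- withr::local_tempfile(fileext = ".csv")
  set.seed(1)
  df <- data.frame(x = runif(n, 0, 256), y = runif(n, 0, 256),
                   class = "tumor",
                   marker = sample(c("pos", "neg"), n, replace = TRUE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  cells <- read_cell_table(path)
  expect_identical(nrow(cells), n)
  stroma <- matrix(FALSE, 256, 256); stroma[100:110, ] <- TRUE
  s <- assemble_sample(cells, stroma, pixel_size = 2, quiet = TRUE)
  expect_identical(nrow(s$cells), n - s$n_dropped_excluded)
})

test_that("geometry formats are auto-detected and parsed", {
  gj <- withr::local_tempfile(fileext = ".geojson")
  writeLines(jsonlite::toJSON(list(
    type = "Feature",
    geometry = list(type = "Polygon",
                    coordinates = list(list(list(0, 0), list(4, 0),
                                            list(4, 4), list(0, 4),
                                            list(0, 0))))
  ), auto_unbox = TRUE), gj)
  polys <- read_geometry(gj)
  expect_s3_class(polys, "tissue_polygons")
  expect_identical(length(polys), 1L)
  expect_identical(nrow(polys[[1]][[1]]), 4L)  # closing vertex dropped

  wkt <- withr::local_tempfile(fileext = ".wkt")
  writeLines("MULTIPOLYGON (((0 0, 2 0, 2 2, 0 2, 0 0)), ((5 5, 8 5, 8 8, 5 8, 5 5)))",
             wkt)
  mp <- read_geometry(wkt)
  expect_identical(length(mp), 2L)
  expect_identical(vapply(mp, function(p) nrow(p[[1]]), 0L), c(4L, 4L))

  mask <- matrix(0, 10, 10); mask[sample(100, 37)] <- 1
  pngf <- withr::local_tempfile(fileext = ".png")
  png::writePNG(mask, pngf)
  m <- read_geometry(pngf)
  expect_identical(sum(m), 37L)

  expect_error(read_geometry("stroma.svg"), "unsupported")
})

test_that("self-intersecting polygons are refused, not repaired", {
  wkt <- withr::local_tempfile(fileext = ".wkt")
  writeLines("POLYGON ((0 0, 4 4, 4 0, 0 4, 0 0))", wkt)  # bow-tie
  expect_error(read_geometry(wkt), "self-intersecting")
})

test_that("rasterization matches brute-force point-in-polygon", {
  expect_false(any(rasterize_polygons(structure(list(),
                                                class = "tissue_polygons"),
                                      c(4, 4))))

  square <- list(list(cbind(x = c(0.5, 2.5, 2.5, 0.5),
                            y = c(0.5, 0.5, 2.5, 2.5))))
  got <- rasterize_polygons(square, c(4, 4))
  expect_identical(got, brute_rasterize(square, c(4, 4)))

  whole <- list(list(cbind(x = c(-1, 9, 9, -1), y = c(-1, -1, 9, 9))))
  expect_true(all(rasterize_polygons(whole, c(6, 6))))

  # random simple polygons (convex hulls of random points) incl. a hole
  set.seed(7)
  for (rep in 1:12) {
    n <- sample(3:8, 1)
    px <- runif(n, 0, 20); py <- runif(n, 0, 20)
    h <- grDevices::chull(px, py)
    ring <- cbind(x = px[h], y = py[h])
    poly <- list(list(ring, ring * 0.4 + 5))  # inner ring = even-odd hole
    shape <- c(sample(8:32, 1), sample(8:32, 1))
    expect_identical(rasterize_polygons(poly, shape),
                     brute_rasterize(poly, shape))
  }

  expect_warning(rasterize_polygons(
    list(list(cbind(x = c(100, 110, 110), y = c(100, 100, 110)))), c(8, 8)),
    "outside")
})

test_that("assembly filters classes and necrotic cells with counts", {
  stroma <- matrix(FALSE, 6, 6); stroma[1, ] <- TRUE
  excl <- matrix(FALSE, 6, 6); excl[5:6, 5:6] <- TRUE
  cells <- data.frame(
    x = c(1.5, 2.5, 3.5, 4.5, 5.5, 0.5, 1.2, 2.2, 3.2, 4.2),
    y = c(2.5, 2.5, 2.5, 5.5, 5.5, 0.5, 3.5, 3.5, 3.5, 3.5),
    cell_class = c(rep("tumor", 10)),
    marker = rep(c(TRUE, FALSE), 5))
  msgs <- capture_messages(
    s <- assemble_sample(cells, stroma, excl, pixel_size = 1))
  expect_match(msgs, "2 on necrosis dropped", all = FALSE)
  expect_identical(nrow(s$cells), 8L)
  expect_identical(s$n_dropped_excluded, 2L)

  # cells on stroma pixels are retained (distance 0), and counted
  expect_match(msgs, "1 on stroma kept", all = FALSE)

  only_other <- data.frame(x = 1, y = 1, cell_class = "other", marker = FALSE)
  expect_error(assemble_sample(only_other, stroma, pixel_size = 1,
                               quiet = TRUE), "zero tumor cells")

  # no exclusion mask supplied: all-false assumed, nothing dropped
  s2 <- assemble_sample(cells, stroma, NULL, pixel_size = 1, quiet = TRUE)
  expect_identical(nrow(s2$cells), 10L)

  # necrotic stroma is not a distance target by default
  stroma2 <- stroma; stroma2[1, 1] <- TRUE
  excl2 <- matrix(FALSE, 6, 6); excl2[1, 1:3] <- TRUE
  s3 <- assemble_sample(cells, stroma2, excl2, pixel_size = 1, quiet = TRUE)
  expect_false(any(s3$stroma[1, 1:3]))
  s4 <- assemble_sample(cells, stroma2, excl2, pixel_size = 1, quiet = TRUE,
                        exclude_necrotic_stroma = FALSE)
  expect_true(all(s4$stroma[1, ]))

  all_excl <- matrix(TRUE, 6, 6)
  expect_error(assemble_sample(cells, stroma, all_excl, pixel_size = 1,
                               quiet = TRUE), "zero tumor cells|no stroma")
})

test_that("class and exclusion filters commute", {
  set.seed(9)
  stroma <- matrix(FALSE, 12, 12); stroma[6, ] <- TRUE
  excl <- matrix(runif(144) < 0.3, 12, 12)
  cells <- data.frame(x = runif(60, 0, 12), y = runif(60, 0, 12),
                      cell_class = sample(c("tumor", "other"), 60, TRUE),
                      marker = runif(60) < 0.5)
  ri <- floor(cells$y) + 1L; ci <- floor(cells$x) + 1L
  a <- cells[cells$cell_class == "tumor", ][
    !excl[cbind(ri, ci)][cells$cell_class == "tumor"], ]
  b <- cells[!excl[cbind(ri, ci)], ]
  b <- b[b$cell_class == "tumor", ]
  expect_identical(a, b)
  s <- assemble_sample(cells, stroma, excl, pixel_size = 1, quiet = TRUE)
  expect_identical(s$cells$x, a$x)
})
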