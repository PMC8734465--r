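test_that("stem table round-trips through CSV with fields intact", {
  cen <- tiny_census()
  path <- withr::local_tempfile(fileext = ".csv")
  write_stem_table(cen, path)
  back <- read_stem_table(path, cen$window)
  expect_equal(nrow(back$stems), 6)
  expect_equal(back$stems$x, cen$stems$x)
  expect_equal(back$stems$dbh, cen$stems$dbh)
  expect_equal(back$stems$species_code, cen$stems$species_code)
  # multi-stemmed plant: one individual, two stems
  qr <- back$stems[back$stems$individual_id == "i2", ]
  expect_equal(nrow(qr), 2)
  expect_equal(length(unique(back$stems$individual_id)), 5)
})

test_that("column mapping works and missing columns give a schema error", {
  cen <- tiny_census()
  path <- withr::local_tempfile(fileext = ".csv")
  df <- cen$stems
  names(df) <- c("TreeTag", "PlantID", "sp", "gx", "gy", "DBH_cm", "state")
  write.csv(df, path, row.names = FALSE)
  back <- read_stem_table(path, cen$window,
                          column_map = c(tag = "TreeTag", individual = "PlantID",
                                         species = "sp", x = "gx", y = "gy",
                                         dbh = "DBH_cm", status = "state"))
  expect_equal(back$stems$dbh, cen$stems$dbh)
  # drop the dbh column entirely
  write.csv(df[, names(df) != "DBH_cm"], path, row.names = FALSE)
  expect_error(read_stem_table(path, cen$window,
                               column_map = c(tag = "TreeTag", individual = "PlantID",
                                              species = "sp", x = "gx", y = "gy",
                                              status = "state")),
               "schema error.*dbh")
})

test_that("unparseable numerics are reported with their line", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("tag,individual,species,x,y,dbh,status",
               "t1,i1,A,1,2,3.5,live",
               "t2,i2,A,1,2,abc,live"), path)
  expect_error(read_stem_table(path, plot_window(10, 10)), "line 2")
})

test_that("validate_census flags protocol violations without modifying input", {
  w <- plot_window(100, 100)
  stems <- data.frame(
    stem_tag = c("a", "b", "c", "d", "d"),
    individual_id = c("i1", "i2", "i3", "i4", "i5"),
    species_code = "A",
    x = c(5, 5, -1, 5, 6), y = c(5, 5, 5, 5, 6),
    dbh = c(0.5, 4, 10, 10, 10),
    status = c("live", "dead", "live", "alive", "live"),
    stringsAsFactors = FALSE)
  cen <- census(stems, w)
  rep <- validate_census(cen)
  expect_false(all_valid(rep))
  expect_true(any(rep$rule == "live_min_dbh" & rep$stem_tag == "a"))
  expect_true(any(rep$rule == "dead_min_dbh" & rep$stem_tag == "b"))
  expect_true(any(rep$rule == "inside_window" & rep$stem_tag == "c"))
  expect_true(any(rep$rule == "status_vocabulary" & rep$stem_tag == "d"))
  expect_true(any(rep$rule == "unique_tag"))
  expect_identical(cen$stems, stems[names(cen$stems)])
  expect_true(all_valid(validate_census(tiny_census())))
})

test_that("quadrat assignment follows the half-open convention with closed plot edge", {
  w <- plot_window(500, 700)
  grid <- quadrat_grid(w, 20)
  expect_equal(c(grid$n_cols, grid$n_rows), c(25, 35))
  stems <- data.frame(stem_tag = c("a", "b", "c"),
                      individual_id = c("a", "b", "c"), species_code = "A",
                      x = c(0.1, 20.0, 500.0), y = c(0.1, 0.0, 700.0),
                      dbh = 5, status = "live", stringsAsFactors = FALSE)
  q <- assign_quadrats(census(stems, w), grid)
  expect_equal(q$col, c(0, 1, 24))
  expect_equal(q$row, c(0, 0, 34))
})

test_that("quadrat assignment partitions random censuses", {
  set.seed(11)
  cen <- random_census(300)
  grid <- quadrat_grid(cen$window, 20)
  q <- assign_quadrats(cen, grid)
  expect_equal(nrow(q), 300)
  expect_true(all(q$col >= 0 & q$col < grid$n_cols))
  expect_true(all(q$row >= 0 & q$row < grid$n_rows))
  expect_equal(sum(table(q$cell)), 300)
  # a stem outside the window is an error naming the tag
  cen$stems$x[1] <- 200
  expect_error(assign_quadrats(cen, grid), "s0001")
})

test_that("ESRI ASCII raster round-trips, including nodata cells", {
  m <- matrix(c(1.5, 2, -9999, 4), 2, 2, byrow = TRUE)
  m[m == -9999] <- NA
  r <- covariate_raster(m, cell_size = 10, xll = 0, yll = 0)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_raster(r, path)
  back <- read_ascii_raster(path)
  expect_equal(back$values, r$values)
  expect_equal(back$cell_size, 10)
  expect_true(is.na(back$values[1, 1]) == is.na(r$values[1, 1]))
  # malformed: ncols mismatch
  lines <- readLines(path)
  lines[7] <- "1.5"
  writeLines(lines, path)
  expect_error(read_ascii_raster(path), "format error")
})

test_that("raster sampling uses the shared half-open cell rule", {
  vals <- matrix(1:4, 2, 2, byrow = TRUE)  # row 1 = north: cells 1,2 / 3,4
  r <- covariate_raster(vals, cell_size = 10)
  # cell centres
  expect_equal(sample_raster_at_points(r, 5, 5), 3)
  expect_equal(sample_raster_at_points(r, 15, 15), 2)
  # shared edge x = 10 goes to the higher column; top edge folds in
  expect_equal(sample_raster_at_points(r, 10, 5), 4)
  expect_equal(sample_raster_at_points(r, 5, 20), 1)
  expect_error(sample_raster_at_points(r, 25, 5), "outside")
  r$values[1, 1] <- NA
  expect_warning(v <- sample_raster_at_points(r, 5, 15), "nodata")
  expect_true(is.na(v))
})
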