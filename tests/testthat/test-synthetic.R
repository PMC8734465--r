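test_that("Thomas simulation hits its expected count and is deterministic", {
  w <- plot_window(500, 700)
  tp <- thomas_params(1e-4, 50, 10)
  set.seed(401)
  counts <- replicate(20, simulate_thomas(tp, w)$n)
  expected <- 1e-4 * w$area * 50       # 1750
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
  set.seed(77); a <- simulate_thomas(tp, w)
  set.seed(77); b <- simulate_thomas(tp, w)
  expect_identical(a$x, b$x)
})

test_that("very large dispersal converges to CSR (g ~ 1)", {
  w <- plot_window(500, 700)
  set.seed(402)
  pat <- simulate_thomas(thomas_params(1e-4, 60, 500), w)
  g <- pcf_estimate(pat, lag_spec(r = seq(10, 50, 10)))$value
  expect_true(all(abs(g - 1) < 0.15))
  # and the closed form agrees: clustering excess 1/(4 pi rho sigma^2) -> 0
  expect_lt(thomas_pcf(10, thomas_params(1e-4, 60, 500)) - 1, 0.005)
})

test_that("iid marks give kmm ~ 1; crowding marks depress kmm at short lags", {
  w <- plot_window(300, 300)
  set.seed(403)
  base <- simulate_thomas(thomas_params(2e-4, 40, 8), w)
  iid <- attach_marks(base, mark_model("iid_lognormal"))
  k_iid <- mark_correlation(iid, lag_spec(r = c(5, 10, 20)))$value
  expect_true(all(abs(k_iid - 1) < 0.12))
  crowd <- attach_marks(base, mark_model("crowding", radius = 10, beta = 0.08))
  k_crowd <- mark_correlation(crowd, lag_spec(r = c(3, 6, 9)))$value
  expect_true(all(k_crowd < 1))
})

test_that("shared gradients in two species give positive Schlather I", {
  w <- plot_window(500, 700)
  set.seed(404)
  p1 <- attach_marks(simulate_csr(300, w),
                     mark_model("gradient", base = 5, slope = 0.05, noise_sd = 1))
  p2 <- attach_marks(simulate_csr(300, w),
                     mark_model("gradient", base = 8, slope = 0.05, noise_sd = 1))
  i_shared <- schlather_I(p1, p2, lag_spec(r = c(5, 10, 15)))$value
  expect_true(all(i_shared > 0.5))
  # gradient marks are strictly positive by construction
  expect_true(all(p1$marks > 0))
})

test_that("mosaic is a deterministic partition into the declared classes", {
  w <- plot_window(200, 200)
  set.seed(405)
  m1 <- generate_landuse_mosaic(w, n_patches = 6, classes = 1:3)
  set.seed(405)
  m2 <- generate_landuse_mosaic(w, n_patches = 6, classes = 1:3)
  expect_identical(m1$values, m2$values)
  expect_true(all(m1$values %in% 1:3))
  expect_equal(dim(m1$values), c(10, 10))
  # one patch -> constant raster
  set.seed(1)
  mc <- generate_landuse_mosaic(w, n_patches = 1, classes = 1:3)
  expect_equal(length(unique(as.vector(mc$values))), 1)
  expect_error(generate_landuse_mosaic(w, 3, integer(0)), "classes")
})

test_that("synthetic censuses validate, honour affinities, and regenerate bit-identically", {
  w <- plot_window(200, 200)
  aff0 <- c("1" = 0.9, "2" = 0)       # class 2 fully excluded
  truth <- synthetic_truth(
    window = w,
    species = list(
      A = list(thomas = thomas_params(2e-4, 40, 10), marks = mark_model("iid_lognormal"),
               affinity = aff0),
      B = list(thomas = thomas_params(2e-4, 30, 10), marks = mark_model("crowding"),
               affinity = c("1" = 0.5, "2" = 0.5))),
    n_patches = 4, classes = 1:2, cell_size = 20, seed = 11)
  gen <- generate_synthetic_census(truth)
  expect_true(all_valid(validate_census(gen$census)))
  # zero-affinity class holds zero stems of species A
  sA <- gen$census$stems[gen$census$stems$species_code == "A", ]
  clsA <- sample_raster_at_points(gen$mosaic, sA$x, sA$y)
  expect_true(all(clsA == 1))
  # regeneration from serialised truth is identical
  path <- withr::local_tempfile(fileext = ".yml")
  write_truth(truth, path)
  gen2 <- generate_synthetic_census(read_truth(path))
  expect_identical(gen$census$stems, gen2$census$stems)
  expect_identical(gen$mosaic$values, gen2$mosaic$values)
})

test_that("species totals match the thinned-process expectation", {
  w <- plot_window(300, 300)
  aff <- c("1" = 0.8, "2" = 0.2)
  mk_truth <- function(seed) synthetic_truth(
    window = w,
    species = list(A = list(thomas = thomas_params(2e-4, 40, 5),
                            marks = mark_model("iid_lognormal", meanlog = log(8)),
                            affinity = aff)),
    n_patches = 5, classes = 1:2, cell_size = 20, seed = seed)
  gens <- lapply(1:15, function(s) generate_synthetic_census(mk_truth(s)))
  counts <- vapply(gens, function(g) nrow(g$census$stems), 0)
  # expectation: rho * |W| * mu_off * E[affinity] * P(mark >= 1); the mark
  # threshold loss is negligible at meanlog log(8), sdlog 0.6
  exp_counts <- vapply(gens, function(g) {
    cls <- as.vector(g$mosaic$values)
    2e-4 * w$area * 40 * mean(aff[as.character(cls)])
  }, 0)
  se <- sd(counts - exp_counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts - exp_counts)), 3 * se + 10)
})

test_that("generated patterns reproduce their Thomas pcf (estimator vs theory)", {
  w <- plot_window(500, 700)
  tp <- thomas_params(1e-4, 50, 10)
  r <- c(5, 10, 20, 35, 50)
  set.seed(406)
  nrep <- 30
  vals <- replicate(nrep, {
    pat <- simulate_thomas(tp, w)
    pcf_estimate(pat, lag_spec(r = r))$value
  })
  m <- rowMeans(vals)
  se <- apply(vals, 1, sd) / sqrt(nrep)
  expect_true(all(abs(m - thomas_pcf(r, tp)) < 3 * se))
})
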