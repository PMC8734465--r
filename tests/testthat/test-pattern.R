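test_that("marked_pattern enforces its invariants", {
  w <- plot_window(10, 10)
  expect_error(marked_pattern(c(1, 11), c(1, 1), w), "outside")
  expect_error(marked_pattern(1, 1, w, marks = c(1, 2)), "align")
  expect_error(marked_pattern(1, 1, w, marks = NaN), "finite")
  p <- marked_pattern(numeric(0), numeric(0), w)
  expect_equal(p$n, 0)
})

test_that("all three estimators agree with the brute-force O(n^2) oracle", {
  set.seed(101)
  w <- plot_window(120, 80)
  r <- c(5, 10, 20); h <- 4
  spec <- lag_spec(r = r, h = h)
  p <- simulate_csr(200, w, marks = rlnorm(200, log(10), 0.4))
  expect_equal(pcf_estimate(p, spec)$value, pcf_oracle(p, r, h),
               tolerance = 1e-10)
  expect_equal(mark_correlation(p, spec)$value, kmm_oracle(p, r, h),
               tolerance = 1e-10)
  p2 <- simulate_csr(150, w, marks = rlnorm(150, log(20), 0.3))
  expect_equal(schlather_I(p, p2, spec)$value, schlather_oracle(p, p2, r, h),
               tolerance = 1e-10)
  # and without edge correction
  spec0 <- lag_spec(r = r, h = h, edge_correction = "none")
  expect_equal(pcf_estimate(p, spec0)$value,
               pcf_oracle(p, r, h, edge = "none"), tolerance = 1e-10)
})

test_that("estimators are invariant to point ordering", {
  set.seed(102)
  w <- plot_window(100, 100)
  p <- simulate_csr(120, w, marks = rlnorm(120, 2, 0.5))
  spec <- lag_spec(r = c(8, 16), h = 5)
  perm <- sample(120)
  q <- marked_pattern(p$x[perm], p$y[perm], w, marks = p$marks[perm])
  expect_equal(pcf_estimate(p, spec)$value, pcf_estimate(q, spec)$value,
               tolerance = 1e-12)
  expect_equal(mark_correlation(p, spec)$value,
               mark_correlation(q, spec)$value, tolerance = 1e-12)
})

test_that("g(r) on a 20-m lattice is zero at 10 m (no pairs in kernel reach)", {
  w <- plot_window(100, 100)
  g <- expand.grid(x = seq(0, 100, 20), y = seq(0, 100, 20))
  p <- marked_pattern(g$x, g$y, w)
  expect_warning(cur <- pcf_estimate(p, lag_spec(r = 10, h = 5)), "no pairs")
  expect_equal(cur$value, 0)
})

test_that("kmm is exactly 1 for constant marks and ~1 for iid marks", {
  set.seed(103)
  w <- plot_window(200, 200)
  p <- simulate_csr(400, w, marks = rep(7, 400))
  v <- mark_correlation(p, lag_spec(r = c(10, 20, 40)))$value
  expect_equal(v, rep(1, 3), tolerance = 1e-12)
  # iid marks on a clustered pattern stay near 1
  pat <- simulate_thomas(thomas_params(2e-4, 30, 8), w)
  pat$marks <- rlnorm(pat$n, log(10), 0.6)
  v2 <- mark_correlation(pat, lag_spec(r = c(5, 10, 20)))$value
  expect_true(all(abs(v2 - 1) < 0.1))
})

test_that("kmm rescaling invariance and Schlather affine equivariance", {
  set.seed(104)
  w <- plot_window(100, 100)
  p <- simulate_csr(150, w, marks = rlnorm(150, 2, 0.4))
  spec <- lag_spec(r = c(10, 25), h = 5)
  k1 <- mark_correlation(p, spec)$value
  p_scaled <- p; p_scaled$marks <- p$marks * 3.7
  expect_equal(mark_correlation(p_scaled, spec)$value, k1, tolerance = 1e-12)
  p2 <- simulate_csr(130, w, marks = rlnorm(130, 1, 0.5))
  i1 <- schlather_I(p, p2, spec)$value
  p2a <- p2; p2a$marks <- 2.5 * p2$marks + 4       # positive affine: unchanged
  expect_equal(schlather_I(p, p2a, spec)$value, i1, tolerance = 1e-10)
  p2b <- p2; p2b$marks <- -1.5 * p2$marks + 60     # negative slope: sign flips
  expect_equal(schlather_I(p, p2b, spec)$value, -i1, tolerance = 1e-10)
})

test_that("Schlather I tracks shared and opposed spatial gradients", {
  set.seed(105)
  w <- plot_window(500, 700)
  p1 <- simulate_csr(200, w); p2 <- simulate_csr(200, w)
  p1$marks <- p1$x + rnorm(200, 0, 5)
  p2$marks <- p2$x + rnorm(200, 0, 5)
  spec <- lag_spec(r = c(5, 10), h = 5)
  shared <- schlather_I(p1, p2, spec)$value
  expect_true(all(shared > 0.8))
  p2$marks <- max(p2$x) - p2$x + rnorm(200, 0, 5)
  opposed <- schlather_I(p1, p2, spec)$value
  expect_true(all(opposed < -0.8))
  # independent marks give I ~ 0 at all lags
  p1$marks <- rnorm(200); p2$marks <- rnorm(200)
  indep <- schlather_I(p1, p2, lag_spec(r = c(10, 50, 100), h = 10,
                                        allow_large_r = TRUE))$value
  expect_true(all(abs(indep) < 0.25))
})

test_that("zero mark variance and missing marks are contract errors", {
  w <- plot_window(50, 50)
  p <- simulate_csr(20, w)
  expect_error(mark_correlation(p, lag_spec(r = 5)), "marks")
  p$marks <- rep(3, 20)
  q <- p
  expect_error(schlather_I(p, q, lag_spec(r = 5)), "variance")
  expect_error(pcf_estimate(marked_pattern(1, 1, w), lag_spec(r = 5)),
               "at least 2")
})

test_that("max lag beyond half the short side is refused unless overridden", {
  w <- plot_window(100, 200)
  p <- simulate_csr(50, w)
  expect_error(pcf_estimate(p, lag_spec(r = c(10, 60))), "half")
  expect_silent(suppressWarnings(
    pcf_estimate(p, lag_spec(r = c(10, 60), allow_large_r = TRUE))))
})

test_that("census_pattern keeps one point per individual with the largest stem", {
  cen <- tiny_census()
  pat <- census_pattern(cen, species = "QURU")
  expect_equal(pat$n, 1)
  expect_equal(pat$marks, 8.0)   # the larger of the 6- and 8-cm stems
  pat2 <- census_pattern(cen, species = "QURU", per = "stem")
  expect_equal(pat2$n, 2)
})
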