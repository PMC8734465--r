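test_that("basal area follows the closed form and rejects bad dbh", {
  expect_equal(stem_basal_area(10), pi * 0.05^2, tolerance = 1e-12)
  expect_equal(stem_basal_area(1), 7.854e-05, tolerance = 1e-4)
  # hand sum over three stems of 10, 20, 30 cm
  expect_equal(sum(stem_basal_area(c(10, 20, 30))), 0.109956, tolerance = 1e-5)
  expect_error(stem_basal_area(0), "positive")
})

test_that("biomass forms are interchangeable and guard their domain", {
  allo <- allometry_table(data.frame(
    species_code = c("POW", "LOG"), form = c("power_law", "log_linear"),
    a = c(0.1, log(0.1)), b = c(2.4, 2.4)))
  expect_equal(stem_biomass(10, "POW", allo), 0.1 * 10^2.4, tolerance = 1e-12)
  expect_equal(stem_biomass(10, "POW", allo), 25.119, tolerance = 1e-4)
  expect_equal(stem_biomass(10, "LOG", allo), stem_biomass(10, "POW", allo),
               tolerance = 1e-12)
  expect_error(stem_biomass(0, "POW", allo), "positive")
  expect_error(stem_biomass(10, "UNKNOWN", allo), "fallback")
  # with a '*' fallback the lookup succeeds
  allo2 <- flat_allometry()
  expect_equal(stem_biomass(10, "ANY", allo2), 25.1189, tolerance = 1e-4)
})

test_that("species summary collapses multi-stemmed individuals for density only", {
  cen <- tiny_census()
  s <- species_summary(cen, flat_allometry())
  qr <- s[s$species_code == "QURU", ]
  # stems 6 and 8 cm share an individual
  expect_equal(qr$n_individuals, 1)
  expect_equal(qr$n_stems, 2)
  expect_equal(qr$basal_area_m2, sum(stem_basal_area(c(6, 8))), tolerance = 1e-12)
  # dead stem excluded under the default live filter
  expect_equal(s[s$species_code == "TSCA", "n_stems"], 1)
  # per-ha = total / area
  expect_equal(s$density_per_ha, s$n_individuals / cen$window$area_ha)
})

test_that("whole-plot basal area equals the sum over species (conservation)", {
  set.seed(21)
  cen <- random_census(400)
  s <- species_summary(cen, flat_allometry())
  expect_equal(sum(s$basal_area_m2),
               sum(stem_basal_area(cen$stems$dbh[cen$stems$status == "live"])),
               tolerance = 1e-10)
  expect_equal(s$density_per_ha * cen$window$area_ha, as.numeric(s$n_individuals),
               tolerance = 1e-12)
})

test_that("diameter distribution partitions stems with the stated bin conventions", {
  w <- plot_window(50, 50)
  stems <- data.frame(stem_tag = as.character(1:4), individual_id = as.character(1:4),
                      species_code = "A", x = 1:4, y = 1:4,
                      dbh = c(1.0, 1.5, 9.9, 5.0), status = "live",
                      stringsAsFactors = FALSE)
  cen <- census(stems, w)
  dd <- diameter_distribution(cen, bin_edges = c(1, 5, 10))
  expect_equal(dd$count, c(2, 2))  # 1.0, 1.5 | 5.0 (boundary -> 2nd bin), 9.9
  expect_error(diameter_distribution(cen, bin_edges = c(1, 1, 5)), "increasing")
  # partition property on random data, incl. the closed top edge
  set.seed(5)
  cen2 <- random_census(300)
  edges <- seq(1, max(cen2$stems$dbh), length.out = 8)
  dd2 <- diameter_distribution(cen2, bin_edges = edges)
  expect_equal(sum(dd2$count), sum(cen2$stems$dbh >= 1 & cen2$stems$dbh <= max(edges)))
  # empty species gives an empty histogram, not an error
  expect_equal(sum(diameter_distribution(cen2, species = "ZZZ")$count), 0)
})

test_that("size-distribution classification matches its definition", {
  expect_equal(classify_size_distribution(c(100, 40, 10, 2)), "reverse_J")
  expect_equal(classify_size_distribution(c(5, 40, 20, 3)), "unimodal")
  expect_equal(classify_size_distribution(c(10, 5, 8, 2)), "other")
  expect_error(classify_size_distribution(c(3, 2, 0, 0)), "3 nonempty bins")
})

test_that("lognormal synthetic diameters bin to a reverse-J distribution", {
  set.seed(31)
  w <- plot_window(200, 200)
  pat <- attach_marks(simulate_csr(2000, w), mark_model("iid_lognormal"))
  keep <- pat$marks >= 1
  stems <- data.frame(stem_tag = as.character(seq_len(sum(keep))),
                      individual_id = as.character(seq_len(sum(keep))),
                      species_code = "A", x = pat$x[keep], y = pat$y[keep],
                      dbh = pat$marks[keep], status = "live",
                      stringsAsFactors = FALSE)
  dd <- diameter_distribution(census(stems, w), bin_edges = seq(1, 41, 5))
  expect_equal(classify_size_distribution(dd), "reverse_J")
})
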