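# In-code fixtures shared across test files.

# A tiny hand-checkable census: 5 live stems (two share an individual),
# one dead stem.
tiny_census <- function() {
  w <- plot_window(100, 100)
  stems <- data.frame(
    stem_tag      = c("t1", "t2", "t3", "t4", "t5", "t6"),
    individual_id = c("i1", "i2", "i2", "i3", "i4", "i5"),
    species_code  = c("ACRU", "QURU", "QURU", "ACRU", "TSCA", "TSCA"),
    x    = c(10, 20, 20.5, 55, 70, 90),
    y    = c(10, 30, 30.5, 60, 20, 90),
    dbh  = c(12.0, 6.0, 8.0, 30.0, 2.5, 40.0),
    status = c("live", "live", "live", "live", "live", "dead"),
    stringsAsFactors = FALSE
  )
  census(stems, w)
}

# Random valid census for property-style tests.
random_census <- function(n = 200, w = plot_window(100, 100),
                          species = c("A", "B", "C")) {
  data.frame(
    stem_tag      = sprintf("s%04d", seq_len(n)),
    individual_id = sprintf("i%04d", seq_len(n)),
    species_code  = sample(species, n, replace = TRUE),
    x = runif(n, w$x0, w$x0 + w$width),
    y = runif(n, w$y0, w$y0 + w$height),
    dbh = round(rlnorm(n, log(8), 0.5) + 1, 1),
    status = "live", stringsAsFactors = FALSE
  ) |> census(window = w)
}

flat_allometry <- function(a = 0.1, b = 2.4) {
  allometry_table(data.frame(species_code = "*", form = "power_law",
                             a = a, b = b))
}
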