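# Independent brute-force oracles: direct O(n^2) double loops over all
# ordered pairs, no pair pruning, no shared code with the package internals
# beyond the statistic definitions themselves.

epa_oracle <- function(u, h) ifelse(abs(u) < h, 0.75 * (1 - (u / h)^2) / h, 0)

pcf_oracle <- function(pat, r, h, edge = "translation") {
  n <- pat$n; w <- pat$window
  lambda <- n / w$area
  vals <- numeric(length(r))
  for (k in seq_along(r)) {
    acc <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      dx <- abs(pat$x[i] - pat$x[j]); dy <- abs(pat$y[i] - pat$y[j])
      d <- sqrt(dx^2 + dy^2)
      kk <- epa_oracle(d - r[k], h)
      if (kk == 0) next
      wij <- if (edge == "translation")
        w$area / ((w$width - dx) * (w$height - dy)) else 1
      acc <- acc + kk * wij
    }
    vals[k] <- acc / (lambda^2 * w$area * 2 * pi * r[k])
  }
  vals
}

kmm_oracle <- function(pat, r, h) {
  n <- pat$n; m <- pat$marks; mu <- mean(m)
  vals <- numeric(length(r))
  for (k in seq_along(r)) {
    num <- 0; den <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((pat$x[i] - pat$x[j])^2 + (pat$y[i] - pat$y[j])^2)
      kk <- epa_oracle(d - r[k], h)
      num <- num + kk * m[i] * m[j]
      den <- den + kk
    }
    vals[k] <- if (den > 0) (num / den) / mu^2 else 0
  }
  vals
}

schlather_oracle <- function(p1, p2, r, h) {
  m1 <- p1$marks; m2 <- p2$marks
  mu1 <- mean(m1); mu2 <- mean(m2); s1 <- sd(m1); s2 <- sd(m2)
  vals <- numeric(length(r))
  for (k in seq_along(r)) {
    num <- 0; den <- 0
    for (i in seq_len(p1$n)) for (j in seq_len(p2$n)) {
      d <- sqrt((p1$x[i] - p2$x[j])^2 + (p1$y[i] - p2$y[j])^2)
      kk <- epa_oracle(d - r[k], h)
      num <- num + kk * (m1[i] - mu1) * (m2[j] - mu2)
      den <- den + kk
    }
    vals[k] <- if (den > 0) num / (s1 * s2 * den) else 0
  }
  vals
}

neighborhood_oracle <- function(census, radius = 10) {
  pat <- census_pattern(census)
  n <- pat$n
  out <- data.frame(n_within = integer(n), mean_dbh = NA_real_,
                    cv_dbh = NA_real_, mean_dist = NA_real_,
                    cv_dist = NA_real_)
  for (i in seq_len(n)) {
    d <- sqrt((pat$x - pat$x[i])^2 + (pat$y - pat$y[i])^2)
    nb <- which(d <= radius & seq_len(n) != i)
    out$n_within[i] <- length(nb)
    if (length(nb) >= 1) {
      out$mean_dbh[i] <- mean(pat$marks[nb])
      out$mean_dist[i] <- mean(d[nb])
    }
    if (length(nb) >= 2) {
      out$cv_dbh[i] <- sd(pat$marks[nb]) / mean(pat$marks[nb])
      out$cv_dist[i] <- sd(d[nb]) / mean(d[nb])
    }
  }
  out
}
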