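#' Marked point pattern
#'
#' A set of tree locations in a rectangular window, optionally carrying one
#' quantitative mark per tree (dbh, cm) and a species label.
#'
#' @param x,y Coordinates in metres; all points must lie in `window`.
#' @param window A [plot_window()].
#' @param marks Optional numeric marks, one per point, finite.
#' @param species Optional character species labels, one per point.
#' @return An object of class `"marked_pattern"`.
#' @export
marked_pattern <- function(x, y, window, marks = NULL, species = NULL) {
  stopifnot(length(x) == length(y))
  if (length(x)) {
    out <- x < window$x0 | x > window$x0 + window$width |
           y < window$y0 | y > window$y0 + window$height
    if (any(out)) stop(sum(out), " point(s) outside the window")
  }
  if (!is.null(marks)) {
    if (length(marks) != length(x)) stop("marks must align 1:1 with points")
    if (any(!is.finite(marks))) stop("marks must be finite")
  }
  if (!is.null(species) && length(species) != length(x))
    stop("species labels must align 1:1 with points")
  structure(list(x = as.numeric(x), y = as.numeric(y), window = window,
                 marks = marks, species = species, n = length(x)),
            class = "marked_pattern")
}

#' @export
print.marked_pattern <- function(x, ...) {
  cat(sprintf("marked pattern: %d points in %g x %g m window%s%s\n", x$n,
              x$window$width, x$window$height,
              if (!is.null(x$marks)) ", with marks" else "",
              if (!is.null(x$species))
                sprintf(", %d species", length(unique(x$species))) else ""))
  invisible(x)
}

#' Extract a marked pattern from a census
#'
#' One point per individual by default (the census convention for spatial
#' analysis): multi-stemmed plants collapse to the location and dbh of their
#' largest stem. Set `per = "stem"` to keep every stem as a point.
#'
#' @param census A [census()].
#' @param species Species code(s) to keep, or `NULL` for all.
#' @param status Stem status to keep (default `"live"`).
#' @param per `"individual"` (default) or `"stem"`.
#' @return A [marked_pattern()] with dbh marks and species labels.
#' @export
census_pattern <- function(census, species = NULL, status = "live",
                           per = c("individual", "stem")) {
  per <- match.arg(per)
  s <- census$stems[census$stems$status %in% status, , drop = FALSE]
  if (!is.null(species)) s <- s[s$species_code %in% species, , drop = FALSE]
  if (per == "individual" && nrow(s)) {
    ord <- order(s$individual_id, -s$dbh)
    s <- s[ord, , drop = FALSE]
    s <- s[!duplicated(s$individual_id), , drop = FALSE]
  }
  marked_pattern(s$x, s$y, census$window, marks = s$dbh,
                 species = s$species_code)
}

#' Spatial lag specification
#'
#' Lags and kernel bandwidth at which the spatial statistics are evaluated.
#' Defaults follow the package's analysis convention: 1-m spaced lags with an
#' Epanechnikov kernel of bandwidth 5 m, and translation edge correction
#' (exact for rectangular windows).
#'
#' @param r Strictly increasing positive lag distances in metres.
#' @param h Kernel bandwidth in metres.
#' @param edge_correction `"translation"` or `"none"`.
#' @param allow_large_r Permit `max(r)` beyond half the shorter window side.
#' @return An object of class `"lag_spec"`.
#' @export
lag_spec <- function(r = 1:50, h = 5,
                     edge_correction = c("translation", "none"),
                     allow_large_r = FALSE) {
  edge_correction <- match.arg(edge_correction)
  if (any(r <= 0) || any(diff(r) <= 0))
    stop("lags must be positive and strictly increasing")
  if (h <= 0) stop("bandwidth must be positive")
  structure(list(r = as.numeric(r), h = h, edge_correction = edge_correction,
                 allow_large_r = allow_large_r), class = "lag_spec")
}

.check_lags <- function(spec, window) {
  if (!spec$allow_large_r && max(spec$r) > min(window$width, window$height) / 2)
    stop("max lag exceeds half the shorter window side; ",
         "set allow_large_r = TRUE to override")
}

# Epanechnikov kernel, bandwidth h
.epa <- function(u, h) ifelse(abs(u) < h, 0.75 * (1 - (u / h)^2) / h, 0)

# All unordered pairs (i < j) within distance rmax, computed in row blocks to
# bound memory. Returns i, j, d, and |dx|, |dy| for the translation weight.
.pair_set <- function(x, y, rmax, block = 256L) {
  n <- length(x)
  ii <- jj <- integer(0); dd <- adx <- ady <- numeric(0)
  res_i <- list(); res_j <- list(); res_d <- list(); res_dx <- list(); res_dy <- list()
  nb <- 0L
  for (s in seq(1L, n - 1L, by = block)) {
    e <- min(s + block - 1L, n - 1L)
    for (i in s:e) {
      j <- (i + 1L):n
      dx <- abs(x[j] - x[i]); dy <- abs(y[j] - y[i])
      keep <- dx <= rmax & dy <= rmax
      if (!any(keep)) next
      dx <- dx[keep]; dy <- dy[keep]; j <- j[keep]
      d <- sqrt(dx^2 + dy^2)
      keep2 <- d <= rmax
      if (!any(keep2)) next
      nb <- nb + 1L
      res_i[[nb]] <- rep.int(i, sum(keep2)); res_j[[nb]] <- j[keep2]
      res_d[[nb]] <- d[keep2]; res_dx[[nb]] <- dx[keep2]; res_dy[[nb]] <- dy[keep2]
    }
  }
  list(i = unlist(res_i) %||% integer(0), j = unlist(res_j) %||% integer(0),
       d = unlist(res_d) %||% numeric(0), adx = unlist(res_dx) %||% numeric(0),
       ady = unlist(res_dy) %||% numeric(0))
}

# Cross pairs between two point sets within rmax (every (i in 1, j in 2) once).
.cross_pair_set <- function(x1, y1, x2, y2, rmax, block = 256L) {
  n1 <- length(x1)
  res_i <- list(); res_j <- list(); res_d <- list(); nb <- 0L
  for (i in seq_len(n1)) {
    dx <- abs(x2 - x1[i]); dy <- abs(y2 - y1[i])
    keep <- dx <= rmax & dy <= rmax
    if (!any(keep)) next
    d <- sqrt(dx[keep]^2 + dy[keep]^2)
    j <- which(keep)
    k2 <- d <= rmax
    if (!any(k2)) next
    nb <- nb + 1L
    res_i[[nb]] <- rep.int(i, sum(k2)); res_j[[nb]] <- j[k2]; res_d[[nb]] <- d[k2]
  }
  list(i = unlist(res_i) %||% integer(0), j = unlist(res_j) %||% integer(0),
       d = unlist(res_d) %||% numeric(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.translation_weight <- function(adx, ady, window) {
  window$area / ((window$width - adx) * (window$height - ady))
}

.estimator_curve <- function(statistic, r, values, n_pairs, n_points,
                             mark_mean = NA_real_, mark_sd = NA_real_) {
  out <- data.frame(r = r, value = values, n_pairs = n_pairs)
  class(out) <- c("estimator_curve", "data.frame")
  attr(out, "statistic") <- statistic
  attr(out, "n_points") <- n_points
  attr(out, "mark_mean") <- mark_mean
  attr(out, "mark_sd") <- mark_sd
  out
}

#' @export
print.estimator_curve <- function(x, ...) {
  cat(sprintf("%s(r) over %d lags [%g, %g] m, %s points\n",
              attr(x, "statistic"), nrow(x), min(x$r), max(x$r),
              paste(attr(x, "n_points"), collapse = "+")))
  print.data.frame(utils::head(x, 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' @export
plot.estimator_curve <- function(x, ..., ylab = NULL) {
  stat <- attr(x, "statistic")
  ref <- if (stat == "I") 0 else 1
  if (is.null(ylab)) ylab <- sprintf("%s(r)", stat)
  graphics::plot(x$r, x$value, type = "l", col = "blue", lwd = 2,
                 xlab = "r (m)", ylab = ylab, ...)
  graphics::abline(h = ref, lty = 2)
  invisible(x)
}

#' Pair-correlation function estimate
#'
#' Kernel estimator of the pair-correlation function g(r): the density of
#' point pairs at separation r relative to a homogeneous Poisson process of
#' the same intensity. Values above 1 indicate clustering at that lag, below
#' 1 overdispersion.
#'
#' The estimator is
#' \deqn{\hat g(r) = \sum_{i \ne j} k_h(r - d_{ij})\, w_{ij} /
#'       (\lambda^2 |W| 2 \pi r)}
#' with Epanechnikov kernel \eqn{k_h}, translation edge weights
#' \eqn{w_{ij} = |W| / ((W_x - |dx|)(W_y - |dy|))} (exact for rectangles) and
#' intensity \eqn{\lambda = n/|W|}. Lags whose kernel window contains no pair
#' return 0 (with a warning) so downstream envelope machinery stays total.
#'
#' @param pattern A [marked_pattern()] with at least 2 points.
#' @param spec A [lag_spec()].
#' @return An `"estimator_curve"` data.frame: `r`, `value`, `n_pairs`.
#' @export
pcf_estimate <- function(pattern, spec = lag_spec()) {
  if (pattern$n < 2) stop("need at least 2 points to estimate g(r)")
  .check_lags(spec, pattern$window)
  w <- pattern$window
  ps <- .pair_set(pattern$x, pattern$y, max(spec$r) + spec$h)
  wt <- if (spec$edge_correction == "translation")
    .translation_weight(ps$adx, ps$ady, w) else rep(1, length(ps$d))
  lambda <- pattern$n / w$area
  vals <- numeric(length(spec$r)); npairs <- integer(length(spec$r))
  for (k in seq_along(spec$r)) {
    r <- spec$r[k]
    keep <- abs(ps$d - r) < spec$h
    npairs[k] <- 2L * sum(keep)
    # x2: each unordered pair stands for the two ordered pairs (i,j), (j,i)
    num <- 2 * sum(.epa(ps$d[keep] - r, spec$h) * wt[keep])
    vals[k] <- num / (lambda^2 * w$area * 2 * pi * r)
  }
  if (any(npairs == 0))
    warning("no pairs within kernel support at ", sum(npairs == 0),
            " lag(s); returning 0 there")
  .estimator_curve("g", spec$r, vals, npairs, pattern$n)
}

#' Univariate mark-correlation function estimate
#'
#' Kernel estimator of kmm(r): the mean product of the marks of r-separated
#' pairs, normalised by the squared mean mark,
#' \deqn{\hat k_{mm}(r) = \frac{\sum_{i \ne j} k_h(r - d_{ij})\, m_i m_j}
#'       {\sum_{i \ne j} k_h(r - d_{ij})} \Big/ \mu^2 .}
#' Values below 1 mean trees at that separation are smaller than expected
#' under mark independence — the classic signature of intraspecific
#' competition when marks are dbh.
#'
#' @param pattern A [marked_pattern()] with marks and at least 2 points.
#' @param spec A [lag_spec()]. Edge weights cancel in this ratio and are not
#'   applied.
#' @return An `"estimator_curve"` data.frame; lags with no pairs give 0.
#' @export
mark_correlation <- function(pattern, spec = lag_spec()) {
  if (is.null(pattern$marks)) stop("pattern has no marks")
  if (pattern$n < 2) stop("need at least 2 points")
  .check_lags(spec, pattern$window)
  mu <- mean(pattern$marks)
  if (mu == 0) stop("mean mark is zero; kmm normalisation undefined")
  ps <- .pair_set(pattern$x, pattern$y, max(spec$r) + spec$h)
  .kmm_from_pairs(ps, pattern$marks, spec, mu, pattern$n)
}

.kmm_from_pairs <- function(ps, marks, spec, mu, n) {
  mm <- marks[ps$i] * marks[ps$j]
  vals <- numeric(length(spec$r)); npairs <- integer(length(spec$r))
  for (k in seq_along(spec$r)) {
    keep <- abs(ps$d - spec$r[k]) < spec$h
    npairs[k] <- 2L * sum(keep)
    if (!any(keep)) { vals[k] <- 0; next }
    kk <- .epa(ps$d[keep] - spec$r[k], spec$h)
    vals[k] <- (sum(kk * mm[keep]) / sum(kk)) / mu^2
  }
  if (any(npairs == 0))
    warning("no pairs within kernel support at ", sum(npairs == 0),
            " lag(s); returning 0 there")
  .estimator_curve("kmm", spec$r, vals, npairs, n,
                   mark_mean = mu, mark_sd = stats::sd(marks))
}

#' Schlather's Moran's-I bivariate mark correlation
#'
#' Correlation-type statistic of the marks of two point patterns at
#' separation r:
#' \deqn{\hat I_{m_1 m_2}(r) = \frac{\sum_{i,j} k_h(r - d_{ij})
#'       (m_{1i} - \mu_1)(m_{2j} - \mu_2)}{\sigma_1 \sigma_2
#'       \sum_{i,j} k_h(r - d_{ij})}}
#' over cross pairs (i in the focal pattern, j in the other), where
#' \eqn{\mu, \sigma} are each pattern's marginal mark mean and sd. Values lie
#' in [-1, 1] up to estimation noise; positive values mean the two species
#' are larger (or smaller) than average together at that separation.
#'
#' @param focal,other [marked_pattern()]s with marks, in the same window.
#' @param spec A [lag_spec()].
#' @return An `"estimator_curve"` data.frame; lags with no cross pairs give 0.
#' @export
schlather_I <- function(focal, other, spec = lag_spec()) {
  if (is.null(focal$marks) || is.null(other$marks))
    stop("both patterns need marks")
  if (focal$n < 1 || other$n < 1) stop("both patterns must be non-empty")
  .check_lags(spec, focal$window)
  s1 <- stats::sd(focal$marks); s2 <- stats::sd(other$marks)
  if (is.na(s1) || is.na(s2) || s1 == 0 || s2 == 0)
    stop("zero mark variance; Schlather's I normalisation undefined")
  ps <- .cross_pair_set(focal$x, focal$y, other$x, other$y, max(spec$r) + spec$h)
  .schlather_from_pairs(ps, focal$marks, other$marks, spec,
                        c(focal$n, other$n))
}

.schlather_from_pairs <- function(ps, m1, m2, spec, n_points) {
  mu1 <- mean(m1); mu2 <- mean(m2)
  s1 <- stats::sd(m1); s2 <- stats::sd(m2)
  z <- (m1[ps$i] - mu1) * (m2[ps$j] - mu2)
  vals <- numeric(length(spec$r)); npairs <- integer(length(spec$r))
  for (k in seq_along(spec$r)) {
    keep <- abs(ps$d - spec$r[k]) < spec$h
    npairs[k] <- sum(keep)
    if (!any(keep)) { vals[k] <- 0; next }
    kk <- .epa(ps$d[keep] - spec$r[k], spec$h)
    vals[k] <- sum(kk * z[keep]) / (s1 * s2 * sum(kk))
  }
  if (any(npairs == 0))
    warning("no cross pairs within kernel support at ", sum(npairs == 0),
            " lag(s); returning 0 there")
  .estimator_curve("I", spec$r, vals, npairs, n_points,
                   mark_mean = c(mu1, mu2), mark_sd = c(s1, s2))
}

#' Write an estimator curve to CSV
#'
#' @param curve An `"estimator_curve"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
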