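# Seeding: one master seed spawns L'Ecuyer-CMRG substreams, one per
# replicate, so replicate k is reproducible regardless of nsim and replicates
# never share a stream.
.substream_states <- function(seed, n) {
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  states <- vector("list", n)
  s <- get(".Random.seed", envir = globalenv())
  for (k in seq_len(n)) {
    s <- parallel::nextRNGSubStream(s)
    states[[k]] <- s
  }
  states
}

# Evaluate expr with the RNG positioned at a given substream state.
.with_rng_state <- function(state, expr) {
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  assign(".Random.seed", state, envir = globalenv())
  expr
}

#' Null-model specification for envelope tests
#'
#' @param model `"csr"` (complete spatial randomness: re-draw point
#'   locations, for g), `"shuffle_marks_all"` (random labelling: fix
#'   locations, permute all marks, for kmm) or `"shuffle_marks_nonfocal"`
#'   (permute only the non-focal pattern's marks, for Schlather's I).
#' @param nsim Number of null simulations (default 199).
#' @param rank Envelope rank k: lower/upper envelopes are the k-th smallest/
#'   largest simulated values per lag (default 5, giving a nominal pointwise
#'   two-sided level 2k/(nsim+1) = 0.05 for the defaults).
#' @param seed Master seed for the replicate substreams.
#' @return An object of class `"null_spec"`.
#' @export
null_spec <- function(model = c("csr", "shuffle_marks_all", "shuffle_marks_nonfocal"),
                      nsim = 199, rank = 5, seed = 1) {
  model <- match.arg(model)
  if (rank < 1 || rank > nsim / 2) stop("need 1 <= rank <= nsim/2")
  structure(list(model = model, nsim = as.integer(nsim), rank = as.integer(rank),
                 seed = as.integer(seed),
                 level = 2 * rank / (nsim + 1)),
            class = "null_spec")
}

#' Simulate complete spatial randomness
#'
#' `n` points uniform iid on the window (a binomial process: CSR conditioned
#' on the observed count, matching null simulations "of the tree map").
#'
#' @param n Number of points.
#' @param window A [plot_window()].
#' @param marks Optional marks to carry over (attached in order).
#' @return A [marked_pattern()].
#' @export
simulate_csr <- function(n, window, marks = NULL) {
  marked_pattern(stats::runif(n, window$x0, window$x0 + window$width),
                 stats::runif(n, window$y0, window$y0 + window$height),
                 window, marks = marks)
}

#' Shuffle marks over points (random labelling)
#'
#' Point coordinates are untouched; the multiset of marks within the scope
#' is permuted uniformly at random. With `scope = "nonfocal"` only points
#' whose species differs from `focal_species` take part; focal marks are
#' bitwise unchanged.
#'
#' @param pattern A [marked_pattern()] with marks.
#' @param scope `"all"` or `"nonfocal"`.
#' @param focal_species Species label defining the focal set (required for
#'   `scope = "nonfocal"`; the pattern must carry species labels).
#' @return A [marked_pattern()] with permuted marks.
#' @export
shuffle_marks <- function(pattern, scope = c("all", "nonfocal"),
                          focal_species = NULL) {
  scope <- match.arg(scope)
  if (is.null(pattern$marks)) stop("pattern has no marks to shuffle")
  idx <- if (scope == "all") seq_len(pattern$n) else {
    if (is.null(pattern$species)) stop("scope 'nonfocal' needs species labels")
    if (is.null(focal_species)) stop("scope 'nonfocal' needs focal_species")
    which(pattern$species != focal_species)
  }
  if (!length(idx)) stop("shuffle scope selects zero points")
  m <- pattern$marks
  m[idx] <- m[idx[sample.int(length(idx))]]
  pattern$marks <- m
  pattern
}

#' Monte Carlo envelope test for a spatial statistic
#'
#' Recomputes the chosen statistic under `nsim` draws from the null model
#' and builds pointwise rank envelopes: at each lag the lower/upper bounds
#' are the k-th smallest/largest simulated values, a two-sided pointwise
#' test at nominal level 2k/(nsim+1). The observed curve is classified
#' `below`, `within` or `above` the envelope at each lag.
#'
#' Statistic/null pairings follow their definitions: `g` with `csr`
#' (locations are random), `kmm` with `shuffle_marks_all` (locations fixed,
#' sizes shuffled over all trees) and `I` with `shuffle_marks_nonfocal`
#' (only the non-focal species' sizes shuffled). Mark-shuffling nulls reuse
#' the observed pair geometry across replicates, so only mark sums are
#' recomputed.
#'
#' @param pattern Observed [marked_pattern()] (the focal pattern for `"I"`).
#' @param statistic `"g"`, `"kmm"` or `"I"`.
#' @param spec A [lag_spec()].
#' @param null A [null_spec()]; the model must be compatible with the
#'   statistic.
#' @param other Second pattern for `statistic = "I"`.
#' @return An `"envelope_result"` data.frame: `r`, `observed`, `lower`,
#'   `upper`, `call`, with the simulated curves in
#'   `attr(, "simulations")`.
#' @export
envelope_test <- function(pattern, statistic = c("g", "kmm", "I"),
                          spec = lag_spec(), null = null_spec(), other = NULL) {
  statistic <- match.arg(statistic)
  ok <- switch(statistic, g = "csr", kmm = "shuffle_marks_all",
               I = "shuffle_marks_nonfocal")
  if (null$model != ok)
    stop(sprintf("statistic '%s' requires null model '%s', got '%s'",
                 statistic, ok, null$model))
  if (statistic == "I" && is.null(other))
    stop("statistic 'I' needs the 'other' pattern")
  states <- .substream_states(null$seed, null$nsim)
  rmax <- max(spec$r) + spec$h

  if (statistic == "g") {
    observed <- pcf_estimate(pattern, spec)
    sims <- vapply(states, function(st) .with_rng_state(st, {
      p <- simulate_csr(pattern$n, pattern$window)
      suppressWarnings(pcf_estimate(p, spec)$value)
    }), numeric(length(spec$r)))
  } else if (statistic == "kmm") {
    if (is.null(pattern$marks)) stop("pattern has no marks")
    ps <- .pair_set(pattern$x, pattern$y, rmax)
    mu <- mean(pattern$marks)
    observed <- suppressWarnings(
      .kmm_from_pairs(ps, pattern$marks, spec, mu, pattern$n))
    sims <- vapply(states, function(st) .with_rng_state(st, {
      m <- pattern$marks[sample(pattern$n)]
      suppressWarnings(.kmm_from_pairs(ps, m, spec, mean(m), pattern$n)$value)
    }), numeric(length(spec$r)))
  } else {
    ps <- .cross_pair_set(pattern$x, pattern$y, other$x, other$y, rmax)
    observed <- suppressWarnings(
      .schlather_from_pairs(ps, pattern$marks, other$marks, spec,
                            c(pattern$n, other$n)))
    sims <- vapply(states, function(st) .with_rng_state(st, {
      m2 <- other$marks[sample(other$n)]
      suppressWarnings(.schlather_from_pairs(ps, pattern$marks, m2, spec,
                                             c(pattern$n, other$n))$value)
    }), numeric(length(spec$r)))
  }
  sims <- matrix(sims, nrow = length(spec$r))
  sorted <- apply(sims, 1, sort)                     # nsim x nlags
  lower <- sorted[null$rank, ]
  upper <- sorted[null$nsim - null$rank + 1L, ]
  call <- ifelse(observed$value < lower, "below",
                 ifelse(observed$value > upper, "above", "within"))
  out <- data.frame(r = spec$r, observed = observed$value,
                    lower = lower, upper = upper, call = call,
                    stringsAsFactors = FALSE)
  class(out) <- c("envelope_result", "data.frame")
  attr(out, "statistic") <- statistic
  attr(out, "null") <- null
  attr(out, "simulations") <- sims
  out
}

#' @export
print.envelope_result <- function(x, ...) {
  nl <- attr(x, "null")
  cat(sprintf("envelope test: %s(r) vs %s, nsim = %d, rank = %d (pointwise level %.3f)\n",
              attr(x, "statistic"), nl$model, nl$nsim, nl$rank, nl$level))
  cat(sprintf("  lags above/within/below envelope: %d/%d/%d\n",
              sum(x$call == "above"), sum(x$call == "within"),
              sum(x$call == "below")))
  invisible(x)
}

#' @export
plot.envelope_result <- function(x, ..., main = NULL) {
  stat <- attr(x, "statistic")
  ref <- if (stat == "I") 0 else 1
  ylim <- range(x$observed, x$lower, x$upper, ref, finite = TRUE)
  graphics::plot(x$r, x$observed, type = "n", xlab = "r (m)",
                 ylab = sprintf("%s(r)", stat), ylim = ylim, main = main, ...)
  graphics::polygon(c(x$r, rev(x$r)), c(x$lower, rev(x$upper)),
                    col = "grey85", border = NA)
  graphics::lines(x$r, x$lower, col = "black"); graphics::lines(x$r, x$upper, col = "black")
  graphics::abline(h = ref, lty = 2)
  graphics::lines(x$r, x$observed, col = "blue", lwd = 2)
  invisible(x)
}

#' Write an envelope result to CSV
#'
#' @param envelope An `"envelope_result"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_envelope <- function(envelope, path) {
  utils::write.csv(as.data.frame(envelope), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
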