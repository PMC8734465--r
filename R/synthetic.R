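#' Thomas cluster process parameters
#'
#' A Poisson cluster process: parents form a homogeneous Poisson process of
#' intensity `rho`, each parent spawns a Poisson(`mu_off`) number of
#' offspring displaced by an isotropic Gaussian of sd `sigma_disp`, and only
#' offspring are retained. Its pair-correlation function has the closed form
#' \deqn{g(r) = 1 + \exp(-r^2 / (4 \sigma^2)) / (4 \pi \rho \sigma^2),}
#' which makes generated patterns an analytic test surface for the g(r)
#' estimator.
#'
#' @param rho Parent intensity, points per m^2.
#' @param mu_off Mean offspring per parent.
#' @param sigma_disp Offspring dispersal sd, metres.
#' @return An object of class `"thomas_params"`.
#' @export
thomas_params <- function(rho, mu_off, sigma_disp) {
  stopifnot(rho > 0, mu_off > 0, sigma_disp > 0)
  structure(list(rho = rho, mu_off = mu_off, sigma_disp = sigma_disp),
            class = "thomas_params")
}

#' Theoretical pair-correlation function of a Thomas process
#'
#' @param r Lag distances, metres.
#' @param params A [thomas_params()].
#' @return g(r) values.
#' @export
thomas_pcf <- function(r, params) {
  1 + exp(-r^2 / (4 * params$sigma_disp^2)) /
    (4 * pi * params$rho * params$sigma_disp^2)
}

#' Simulate a Thomas cluster process
#'
#' Parents are drawn on the window buffered by `4 * sigma_disp` on every
#' side (so offspring intensity has no edge deficit inside the window);
#' offspring are displaced isotropically and clipped to the window.
#'
#' @param params A [thomas_params()].
#' @param window A [plot_window()].
#' @return A [marked_pattern()] (no marks).
#' @export
simulate_thomas <- function(params, window) {
  buf <- 4 * params$sigma_disp
  bw <- window$width + 2 * buf; bh <- window$height + 2 * buf
  n_par <- stats::rpois(1, params$rho * bw * bh)
  px <- stats::runif(n_par, window$x0 - buf, window$x0 + window$width + buf)
  py <- stats::runif(n_par, window$y0 - buf, window$y0 + window$height + buf)
  n_off <- stats::rpois(n_par, params$mu_off)
  cx <- rep(px, n_off) + stats::rnorm(sum(n_off), 0, params$sigma_disp)
  cy <- rep(py, n_off) + stats::rnorm(sum(n_off), 0, params$sigma_disp)
  keep <- cx >= window$x0 & cx <= window$x0 + window$width &
          cy >= window$y0 & cy <= window$y0 + window$height
  marked_pattern(cx[keep], cy[keep], window)
}

#' Mark model for synthetic diameters
#'
#' Three generative models for dbh marks:
#' * `iid_lognormal`: exchangeable lognormal marks (right-skewed, like real
#'   diameter distributions): `exp(rnorm(meanlog, sdlog))`.
#' * `crowding`: local competition — `exp(beta0 - beta * n_R + noise)` where
#'   `n_R` counts neighbours within `radius`; expected mark decreases with
#'   crowding, which drives kmm(r) below 1 at short lags.
#' * `gradient`: a linear spatial trend `base + slope * proj + noise` where
#'   `proj` projects the location on `direction` (radians); shared gradients
#'   across species drive Schlather's I towards +1, opposed ones towards -1.
#'   Non-positive marks have their noise resampled.
#'
#' @param kind `"iid_lognormal"`, `"crowding"` or `"gradient"`.
#' @param meanlog,sdlog Lognormal parameters (iid_lognormal; defaults give a
#'   median near 5 cm).
#' @param beta0,beta,radius Crowding intercept (log scale), penalty per
#'   neighbour, and neighbourhood radius in metres.
#' @param noise_sd Noise sd (log scale for crowding, mark scale for
#'   gradient).
#' @param base,slope,direction Gradient parameters.
#' @return An object of class `"mark_model"`.
#' @export
mark_model <- function(kind = c("iid_lognormal", "crowding", "gradient"),
                       meanlog = log(5), sdlog = 0.6,
                       beta0 = log(25), beta = 0.08, radius = 10,
                       noise_sd = 0.2, base = 10, slope = 0.05, direction = 0) {
  kind <- match.arg(kind)
  structure(list(kind = kind, meanlog = meanlog, sdlog = sdlog, beta0 = beta0,
                 beta = beta, radius = radius, noise_sd = noise_sd,
                 base = base, slope = slope, direction = direction),
            class = "mark_model")
}

#' Attach marks to a point pattern under a mark model
#'
#' @param pattern A [marked_pattern()] (existing marks are replaced).
#' @param model A [mark_model()].
#' @return The pattern with positive marks attached.
#' @export
attach_marks <- function(pattern, model) {
  n <- pattern$n
  if (n == 0) { pattern$marks <- numeric(0); return(pattern) }
  marks <- switch(model$kind,
    iid_lognormal = stats::rlnorm(n, model$meanlog, model$sdlog),
    crowding = {
      cnt <- .count_within(pattern$x, pattern$y, model$radius)
      exp(model$beta0 - model$beta * cnt + stats::rnorm(n, 0, model$noise_sd))
    },
    gradient = {
      proj <- pattern$x * cos(model$direction) + pattern$y * sin(model$direction)
      m <- model$base + model$slope * proj + stats::rnorm(n, 0, model$noise_sd)
      bad <- which(m <= 0)
      tries <- 0
      while (length(bad) && tries < 100) {
        m[bad] <- model$base + model$slope * proj[bad] +
          stats::rnorm(length(bad), 0, model$noise_sd)
        bad <- which(m <= 0); tries <- tries + 1
      }
      if (length(bad)) {
        message(length(bad), " gradient mark(s) still non-positive; clamped")
        m[bad] <- .Machine$double.eps
      }
      m
    })
  pattern$marks <- marks
  pattern
}

# Neighbour counts within radius via grid bucketing.
.count_within <- function(x, y, radius) {
  n <- length(x)
  cx <- floor(x / radius); cy <- floor(y / radius)
  key <- paste(cx, cy)
  buckets <- split(seq_len(n), key)
  cnt <- integer(n)
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      b <- buckets[[paste(cx[i] + dx, cy[i] + dy)]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    cand <- cand[cand != i]
    if (length(cand))
      cnt[i] <- sum((x[cand] - x[i])^2 + (y[cand] - y[i])^2 <= radius^2)
  }
  cnt
}

#' Generate a synthetic land-use mosaic
#'
#' A Voronoi partition of the plot into contiguous patches: patch centres
#' are dropped uniformly at random, every grid cell takes the class of its
#' nearest centre. Emulates the blocky historical land-use maps (fields by
#' abandonment date, stand types) that drive species distributions.
#'
#' @param window A [plot_window()].
#' @param n_patches Number of Voronoi patches (>= 1).
#' @param classes Integer class codes to assign (recycled over patches in
#'   random order).
#' @param cell_size Raster resolution, metres (default 20).
#' @return A categorical [covariate_raster()].
#' @export
generate_landuse_mosaic <- function(window, n_patches, classes, cell_size = 20) {
  if (n_patches < 1) stop("n_patches must be >= 1")
  if (!length(classes)) stop("classes must be non-empty")
  grid <- quadrat_grid(window, cell_size)
  px <- stats::runif(n_patches, window$x0, window$x0 + window$width)
  py <- stats::runif(n_patches, window$y0, window$y0 + window$height)
  pc <- rep_len(sample(classes), n_patches)
  # cell centres, matrix row 1 = north
  xs <- window$x0 + (seq_len(grid$n_cols) - 0.5) * cell_size
  ys <- window$y0 + (grid$n_rows:1 - 0.5) * cell_size
  m <- matrix(0L, grid$n_rows, grid$n_cols)
  for (i in seq_len(grid$n_rows)) {
    d2 <- (matrix(px, n_patches, grid$n_cols) -
           matrix(xs, n_patches, grid$n_cols, byrow = TRUE))^2 + (py - ys[i])^2
    m[i, ] <- pc[apply(d2, 2, which.min)]
  }
  covariate_raster(m, cell_size = cell_size, xll = window$x0, yll = window$y0,
                   kind = "categorical", classes = sort(unique(pc)))
}

#' Ground truth for a synthetic census
#'
#' Everything needed to regenerate a synthetic census bit-identically: the
#' window, the mosaic configuration, per-species cluster-process parameters,
#' mark models and mosaic class-affinity weights, and the master seed.
#'
#' @param window A [plot_window()] (default the 500 x 700 m plot).
#' @param species Named list; each element a list with components `thomas`
#'   ([thomas_params()]), `marks` ([mark_model()]) and `affinity` (named
#'   numeric in `[0, 1]` per mosaic class: retention probability of a stem
#'   falling on that class).
#' @param n_patches,classes,cell_size Mosaic configuration.
#' @param seed Master seed.
#' @return An object of class `"synthetic_truth"`.
#' @export
synthetic_truth <- function(window = plot_window(500, 700), species,
                            n_patches = 12, classes = 1:4, cell_size = 20,
                            seed = 1) {
  for (sp in species) {
    stopifnot(inherits(sp$thomas, "thomas_params"),
              inherits(sp$marks, "mark_model"),
              all(sp$affinity >= 0), all(sp$affinity <= 1),
              all(as.character(classes) %in% names(sp$affinity)))
  }
  structure(list(window = window, species = species, n_patches = n_patches,
                 classes = classes, cell_size = cell_size,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Default synthetic stand configuration
#'
#' The generator's reference conditions emulate a 35-ha temperate-forest
#' census: a 500 x 700 m window, about fifty species totalling on the order
#' of 1e5 stems, strongly clustered species tied to a 12-patch land-use
#' mosaic of 4 classes, and right-skewed lognormal diameters with a
#' crowding penalty for the common species. Species abundances span three
#' orders of magnitude (log-spaced mean offspring counts), as in real
#' stands where a handful of species dominate. `scale` shrinks expected
#' stem counts for desk-scale work without changing the structure.
#'
#' @param n_species Number of species (default 50).
#' @param scale Multiplier on expected stems per species (default 1).
#' @param seed Master seed recorded in the truth.
#' @param window Plot geometry (default the 500 x 700 m plot).
#' @return A [synthetic_truth()].
#' @export
default_synthetic_truth <- function(n_species = 50, scale = 1, seed = 1,
                                    window = plot_window(500, 700)) {
  classes <- 1:4
  # expected retained fraction under affinities ~ 0.55; tune mu_off so the
  # expected census totals ~ 1e5 stems at scale = 1
  mu <- exp(seq(log(40), log(0.4), length.out = n_species)) * 130 * scale
  species <- list()
  for (k in seq_len(n_species)) {
    aff <- stats::setNames(rep(0.15, length(classes)), as.character(classes))
    aff[as.character(classes[(k - 1) %% length(classes) + 1])] <- 0.95
    mm <- if (k <= 8) mark_model("crowding") else mark_model("iid_lognormal")
    species[[sprintf("sp%02d", k)]] <-
      list(thomas = thomas_params(rho = 1e-4, mu_off = mu[k], sigma_disp = 15),
           marks = mm, affinity = aff)
  }
  synthetic_truth(window, species, n_patches = 12, classes = classes,
                  cell_size = 20, seed = seed)
}

#' Generate a synthetic census from ground truth
#'
#' Per species: a Thomas cluster pattern is thinned by the mosaic
#' class-affinity weights (independent retention with the probability of
#' the land-use class under each stem), then dbh marks are attached from
#' the species' mark model. Marks below the 1-cm census threshold are
#' dropped, mimicking the census protocol. The result passes
#' [validate_census()] by construction. Regeneration from the same truth is
#' bit-identical.
#'
#' @param truth A [synthetic_truth()].
#' @return List with components `census` (a [census()]), `mosaic` (the
#'   categorical [covariate_raster()]) and `truth`.
#' @export
generate_synthetic_census <- function(truth) {
  states <- .substream_states(truth$seed, length(truth$species) + 1L)
  mosaic <- .with_rng_state(states[[1]],
    generate_landuse_mosaic(truth$window, truth$n_patches, truth$classes,
                            truth$cell_size))
  rows <- list()
  for (k in seq_along(truth$species)) {
    code <- names(truth$species)[k]
    sp <- truth$species[[k]]
    rows[[k]] <- .with_rng_state(states[[k + 1L]], {
      pat <- simulate_thomas(sp$thomas, truth$window)
      if (pat$n > 0) {
        cls <- sample_raster_at_points(mosaic, pat$x, pat$y)
        keep <- stats::runif(pat$n) < sp$affinity[as.character(cls)]
        pat <- marked_pattern(pat$x[keep], pat$y[keep], truth$window)
      }
      pat <- attach_marks(pat, sp$marks)
      keep <- pat$marks >= 1              # census threshold: live dbh >= 1 cm
      if (pat$n == 0 || !any(keep)) NULL else
        data.frame(species_code = code, x = pat$x[keep], y = pat$y[keep],
                   dbh = round(pat$marks[keep], 1), stringsAsFactors = FALSE)
    })
  }
  rows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  n <- nrow(rows)
  stems <- data.frame(stem_tag = sprintf("T%06d", seq_len(n)),
                      individual_id = sprintf("I%06d", seq_len(n)),
                      species_code = rows$species_code,
                      x = rows$x, y = rows$y, dbh = pmax(rows$dbh, 1),
                      status = "live", stringsAsFactors = FALSE)
  list(census = census(stems, truth$window), mosaic = mosaic, truth = truth)
}

#' Serialise / restore synthetic ground truth
#'
#' Plain-text (YAML) round trip of a [synthetic_truth()], sufficient to
#' regenerate its census bit-identically.
#'
#' @param truth A [synthetic_truth()].
#' @param path Output path.
#' @return `path` / the restored `"synthetic_truth"`.
#' @export
write_truth <- function(truth, path) {
  obj <- list(window = truth$window[c("width", "height", "x0", "y0")],
              n_patches = truth$n_patches, classes = truth$classes,
              cell_size = truth$cell_size, seed = truth$seed,
              species = lapply(truth$species, function(sp) list(
                thomas = unclass(sp$thomas),
                marks = unclass(sp$marks),
                affinity = as.list(sp$affinity))))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- yaml::read_yaml(path)
  species <- lapply(obj$species, function(sp) list(
    thomas = do.call(thomas_params, sp$thomas),
    marks = do.call(mark_model, sp$marks),
    affinity = unlist(sp$affinity)))
  synthetic_truth(window = plot_window(obj$window$width, obj$window$height,
                                       obj$window$x0, obj$window$y0),
                  species = species, n_patches = obj$n_patches,
                  classes = obj$classes, cell_size = obj$cell_size,
                  seed = obj$seed)
}
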