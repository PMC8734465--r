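#' Read a pipeline run configuration
#'
#' A YAML file with blocks: `paths` (census CSV, allometry CSV, raster
#' files, or `synthetic: true` with a truth file), `lags` (`r_max`, `h`),
#' `null` (`nsim`, `rank`), `features` (`radius`, `cell_size`), `ensemble`
#' (`n_iter`, `subsample`, `alpha`), `species` (focal species codes, or
#' `top_n`), and `seed`. Missing keys fall back to package defaults.
#'
#' @param path Path to the YAML config.
#' @return A named list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    seed = 1,
    window = list(width = 500, height = 700),
    lags = list(r_max = 50, h = 5),
    null = list(nsim = 199, rank = 5),
    features = list(radius = 10, cell_size = 20),
    ensemble = list(n_iter = 500, subsample = 0.632, alpha = 0.05,
                    min_node = 20),
    species = list(top_n = 3),
    paths = list()
  )
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]))
      for (k in names(defaults[[nm]]))
        if (is.null(cfg[[nm]][[k]])) cfg[[nm]][[k]] <- defaults[[nm]][[k]]
  }
  structure(cfg, class = c("run_config", "list"))
}

.write_manifest <- function(dir, cfg, inputs, outputs, seed) {
  manifest <- list(
    seed = seed,
    config = unclass(cfg),
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(outputs, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))),
    versions = list(standmarks = as.character(utils::packageVersion("standmarks")),
                    R = paste(R.version$major, R.version$minor, sep = "."))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the full analysis pipeline
#'
#' Chains the package end to end: load (or synthesise) a census, validate
#' it, write species summaries and diameter distributions, estimate g(r),
#' kmm(r) and Schlather's I with Monte Carlo envelopes for the focal
#' species, build the predictor table and run ensemble permutation
#' importance. Every artefact lands in `out_dir` together with a
#' machine-readable `manifest.json` recording the seed, configuration and
#' input/output checksums; rerunning the same config reproduces the
#' artefacts byte for byte.
#'
#' @param config A `"run_config"` (see [read_run_config()]) or a path to
#'   one.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of the config seed.
#' @return Invisibly, the output directory path.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- character(0)

  window <- plot_window(cfg$window$width, cfg$window$height)
  if (isTRUE(cfg$paths$synthetic)) {
    truth <- if (!is.null(cfg$paths$truth)) {
      inputs <- c(inputs, cfg$paths$truth)
      read_truth(cfg$paths$truth)
    } else default_synthetic_truth(
      n_species = cfg$paths$n_species %||% 12,
      scale = cfg$paths$scale %||% 0.02, seed = cfg$seed, window = window)
    gen <- generate_synthetic_census(truth)
    cen <- gen$census
    rasters <- list(landuse_class = gen$mosaic)
    write_truth(truth, file.path(out_dir, "truth.yml"))
    write_stem_table(cen, file.path(out_dir, "census.csv"))
  } else {
    inputs <- c(inputs, cfg$paths$census)
    cen <- read_stem_table(cfg$paths$census, window,
                           column_map = cfg$paths$column_map)
    rasters <- list()
    for (nm in names(cfg$paths$rasters %||% list())) {
      inputs <- c(inputs, cfg$paths$rasters[[nm]])
      rasters[[nm]] <- read_ascii_raster(cfg$paths$rasters[[nm]],
                                         kind = "categorical")
    }
  }
  if (max(1, cfg$lags$r_max) > min(window$width, window$height) / 2)
    stop("config error: max lag ", cfg$lags$r_max,
         " exceeds half the shorter window side (",
         min(window$width, window$height) / 2, " m)")

  rep <- validate_census(cen)
  if (!all_valid(rep)) {
    utils::write.csv(as.data.frame(rep),
                     file.path(out_dir, "validation_report.csv"),
                     row.names = FALSE)
    stop("stage 'validate' failed: census has ", nrow(rep),
         " protocol violation(s); see validation_report.csv")
  }

  allo <- if (!is.null(cfg$paths$allometry)) {
    inputs <- c(inputs, cfg$paths$allometry)
    read_allometry(cfg$paths$allometry)
  } else allometry_table(data.frame(species_code = "*", form = "power_law",
                                    a = 0.1, b = 2.4))
  summ <- species_summary(cen, allo)
  write_species_summary(summ, file.path(out_dir, "species_summary.csv"))

  focal <- cfg$species$codes %||%
    utils::head(summ$species_code, cfg$species$top_n)
  lspec <- lag_spec(r = seq_len(cfg$lags$r_max), h = cfg$lags$h)
  outputs <- file.path(out_dir, "species_summary.csv")

  for (i in seq_along(focal)) {
    sp <- focal[i]
    pat <- census_pattern(cen, species = sp)
    dd <- diameter_distribution(cen, species = sp)
    p <- file.path(out_dir, paste0("diam_", sp, ".csv"))
    utils::write.csv(dd, p, row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, p)
    if (pat$n < 30) next
    env_g <- envelope_test(pat, "g", lspec,
                           null_spec("csr", cfg$null$nsim, cfg$null$rank,
                                     seed = cfg$seed + 101 * i))
    env_k <- envelope_test(pat, "kmm", lspec,
                           null_spec("shuffle_marks_all", cfg$null$nsim,
                                     cfg$null$rank, seed = cfg$seed + 101 * i + 1))
    for (nm in c("g", "kmm")) {
      env <- if (nm == "g") env_g else env_k
      p <- file.path(out_dir, paste0("envelope_", nm, "_", sp, ".csv"))
      write_envelope(env, p)
      outputs <- c(outputs, p)
    }
    if (i > 1) {
      pat1 <- census_pattern(cen, species = focal[1])
      env_i <- envelope_test(pat1, "I", lspec,
                             null_spec("shuffle_marks_nonfocal", cfg$null$nsim,
                                       cfg$null$rank, seed = cfg$seed + 101 * i + 2),
                             other = pat)
      p <- file.path(out_dir, paste0("envelope_I_", focal[1], "_", sp, ".csv"))
      write_envelope(env_i, p)
      outputs <- c(outputs, p)
    }
  }

  # importance for the most abundant focal species
  ft <- feature_table(cen, focal[1], rasters = rasters,
                      radius = cfg$features$radius,
                      cell_size = cfg$features$cell_size)
  imp <- ensemble_importance(ft, n_iter = cfg$ensemble$n_iter,
                             subsample = cfg$ensemble$subsample,
                             alpha = cfg$ensemble$alpha,
                             min_node = cfg$ensemble$min_node,
                             seed = cfg$seed + 7)
  p <- file.path(out_dir, paste0("importance_", focal[1], ".csv"))
  write_importance(imp, p)
  outputs <- c(outputs, p)

  .write_manifest(out_dir, cfg, inputs, outputs, cfg$seed)
  invisible(out_dir)
}

#' Write a species summary to CSV
#' @param summary A `"species_summary"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_species_summary <- function(summary, path) {
  utils::write.csv(as.data.frame(summary), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Render a run directory into a summary report
#'
#' Collects the artefacts of a completed [run_pipeline()] run into a
#' markdown report (`report.md`) with the species-summary table and, for
#' each envelope CSV, a PNG panel of the observed curve against its
#' envelope, plus importance bar charts.
#'
#' @param run_dir A completed run directory.
#' @return Path to `report.md`, invisibly.
#' @export
make_report <- function(run_dir) {
  need <- file.path(run_dir, c("manifest.json", "species_summary.csv"))
  miss <- need[!file.exists(need)]
  if (length(miss))
    stop("incomplete run; missing artefact(s): ",
         paste(basename(miss), collapse = ", "))
  lines <- c("# standmarks run report", "")
  man <- jsonlite::read_json(file.path(run_dir, "manifest.json"))
  lines <- c(lines, sprintf("Seed %s; standmarks %s.", man$seed,
                            man$versions$standmarks), "")
  summ <- utils::read.csv(file.path(run_dir, "species_summary.csv"))
  lines <- c(lines, "## Species summary", "",
             paste(names(summ), collapse = " | "),
             paste(rep("---", ncol(summ)), collapse = " | "),
             apply(utils::head(summ, 15), 1, paste, collapse = " | "), "")
  envs <- list.files(run_dir, pattern = "^envelope_.*\\.csv$", full.names = TRUE)
  if (length(envs)) lines <- c(lines, "## Envelope tests", "")
  for (p in sort(envs)) {
    df <- utils::read.csv(p, stringsAsFactors = FALSE)
    stat <- sub("^envelope_([^_]+)_.*$", "\\1", basename(p))
    png <- sub("\\.csv$", ".png", p)
    grDevices::png(png, width = 600, height = 400)
    ref <- if (stat == "I") 0 else 1
    ylim <- range(df$observed, df$lower, df$upper, ref, finite = TRUE)
    graphics::plot(df$r, df$observed, type = "n", xlab = "r (m)",
                   ylab = paste0(stat, "(r)"), ylim = ylim,
                   main = sub("\\.csv$", "", basename(p)))
    graphics::polygon(c(df$r, rev(df$r)), c(df$lower, rev(df$upper)),
                      col = "grey85", border = NA)
    graphics::abline(h = ref, lty = 2)
    graphics::lines(df$r, df$observed, col = "blue", lwd = 2)
    grDevices::dev.off()
    lines <- c(lines, sprintf("- `%s`: %d/%d lags above/below the envelope (![](%s))",
                              basename(p), sum(df$call == "above"),
                              sum(df$call == "below"), basename(png)))
  }
  imps <- list.files(run_dir, pattern = "^importance_.*\\.csv$", full.names = TRUE)
  if (length(imps)) lines <- c(lines, "", "## Variable importance", "")
  for (p in sort(imps)) {
    df <- utils::read.csv(p, stringsAsFactors = FALSE)
    df <- df[order(-df$importance), ]
    png <- sub("\\.csv$", ".png", p)
    grDevices::png(png, width = 600, height = 400)
    graphics::par(mar = c(4, 10, 2, 1))
    graphics::barplot(rev(df$importance), names.arg = rev(df$predictor),
                      horiz = TRUE, las = 1,
                      xlab = "mean decrease in prediction accuracy")
    grDevices::dev.off()
    lines <- c(lines, sprintf("- `%s`: top predictor **%s** (![](%s))",
                              basename(p), df$predictor[1], basename(png)))
  }
  out <- file.path(run_dir, "report.md")
  writeLines(lines, out)
  invisible(out)
}
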