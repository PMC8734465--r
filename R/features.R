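#' Focal-window mean abundance surface
#'
#' Counts stems of a species per grid cell (20-m cells by default), then
#' smooths with a 3x3 moving focal mean. At plot edges the window truncates:
#' the mean is taken over the cells that exist (4 at corners, 6 on edges).
#' Sampling this surface at tree locations gives the per-tree local
#' abundance response used in the importance models.
#'
#' @param census A [census()].
#' @param species Species code(s) to count, or `NULL` for all stems.
#' @param cell_size Cell resolution in metres (default 20).
#' @param fw Focal window side in cells (odd; default 3).
#' @param status Stem status to count (default `"live"`).
#' @param per Count `"individual"`s (default) or `"stem"`s per cell.
#' @return A continuous [covariate_raster()] aligned to the plot window.
#' @export
focal_abundance_surface <- function(census, species = NULL, cell_size = 20,
                                    fw = 3, status = "live",
                                    per = c("individual", "stem")) {
  per <- match.arg(per)
  if (fw %% 2 != 1 || fw < 1) stop("focal window side must be odd and >= 1")
  w <- census$window
  grid <- quadrat_grid(w, cell_size)
  pat <- census_pattern(census, species = species, status = status, per = per)
  col <- .cell_index(pat$x, w$x0, cell_size, grid$n_cols)
  row <- .cell_index(pat$y, w$y0, cell_size, grid$n_rows)
  counts <- matrix(0, nrow = grid$n_rows, ncol = grid$n_cols)  # row 1 = south
  if (length(col)) {
    t <- table(factor(row, levels = 0:(grid$n_rows - 1)),
               factor(col, levels = 0:(grid$n_cols - 1)))
    counts <- matrix(as.numeric(t), nrow = grid$n_rows)
  }
  half <- (fw - 1L) / 2L
  sm <- matrix(0, grid$n_rows, grid$n_cols)
  for (i in seq_len(grid$n_rows)) {
    ri <- max(1, i - half):min(grid$n_rows, i + half)
    for (j in seq_len(grid$n_cols)) {
      cj <- max(1, j - half):min(grid$n_cols, j + half)
      sm[i, j] <- mean(counts[ri, cj])
    }
  }
  # covariate_raster stores row 1 = north
  covariate_raster(sm[grid$n_rows:1, , drop = FALSE], cell_size = cell_size,
                   xll = w$x0, yll = w$y0, kind = "continuous")
}

#' Neighbourhood features within a fixed radius
#'
#' For every tree, summarises the other trees within `radius` metres
#' (Euclidean): their count, the mean and coefficient of variation of their
#' dbh, and the mean and CV of the distances to them. CV is the sample
#' standard deviation over the mean, so it is undefined (`NA`) with fewer
#' than 2 neighbours; all dbh/distance features are `NA` for isolated trees.
#' Trees closer than `radius` to a plot edge carry `border = TRUE` since
#' their neighbourhood is censored by the window.
#'
#' Neighbour search uses grid bucketing (cells of side `radius`), giving the
#' same result as the all-pairs scan at much lower cost.
#'
#' @param census A [census()].
#' @param radius Neighbourhood radius in metres (default 10).
#' @param status Stem status to include (default `"live"`).
#' @param per `"individual"` (default) or `"stem"`.
#' @return data.frame, one row per tree in [census_pattern()] order:
#'   `x`, `y`, `dbh`, `species_code`, `n_within`, `mean_dbh`, `cv_dbh`,
#'   `mean_dist`, `cv_dist`, `border`.
#' @export
neighborhood_features <- function(census, radius = 10, status = "live",
                                  per = c("individual", "stem")) {
  per <- match.arg(per)
  pat <- census_pattern(census, status = status, per = per)
  n <- pat$n
  w <- census$window
  res <- data.frame(x = pat$x, y = pat$y, dbh = pat$marks,
                    species_code = pat$species,
                    n_within = integer(n), mean_dbh = NA_real_,
                    cv_dbh = NA_real_, mean_dist = NA_real_,
                    cv_dist = NA_real_,
                    border = pat$x - w$x0 < radius |
                             w$x0 + w$width - pat$x < radius |
                             pat$y - w$y0 < radius |
                             w$y0 + w$height - pat$y < radius,
                    stringsAsFactors = FALSE)
  if (n == 0) return(res)
  cx <- floor((pat$x - w$x0) / radius)
  cy <- floor((pat$y - w$y0) / radius)
  key <- paste(cx, cy)
  buckets <- split(seq_len(n), key)
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      b <- buckets[[paste(cx[i] + dx, cy[i] + dy)]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    cand <- cand[cand != i]
    if (!length(cand)) next
    d <- sqrt((pat$x[cand] - pat$x[i])^2 + (pat$y[cand] - pat$y[i])^2)
    keep <- d <= radius
    k <- sum(keep)
    res$n_within[i] <- k
    if (k >= 1) {
      dd <- d[keep]; mm <- pat$marks[keep2 <- cand[keep]]
      res$mean_dbh[i] <- mean(mm)
      res$mean_dist[i] <- mean(dd)
      if (k >= 2) {
        res$cv_dbh[i] <- stats::sd(mm) / mean(mm)
        res$cv_dist[i] <- stats::sd(dd) / mean(dd)
      }
    }
  }
  res
}

#' Build the per-tree predictor table for importance modelling
#'
#' Assembles one modelling row per tree of the focal species: the response
#' (sampled focal abundance or dbh), raster covariates sampled at the tree
#' (categorical classes as factors), and the five neighbourhood features.
#'
#' @param census A [census()].
#' @param species Focal species code.
#' @param rasters Named list of [covariate_raster()]s to sample.
#' @param response `"abundance"` (3x3 focal mean of the species' counts,
#'   sampled at each tree) or `"dbh"`.
#' @param radius Neighbourhood radius (default 10 m).
#' @param cell_size Abundance surface resolution (default 20 m).
#' @param drop_border Drop trees flagged as border trees instead of keeping
#'   them flagged (default FALSE).
#' @return data.frame of class `"feature_table"`: `response`, predictor
#'   columns, `border`.
#' @export
feature_table <- function(census, species, rasters = list(),
                          response = c("abundance", "dbh"),
                          radius = 10, cell_size = 20, drop_border = FALSE) {
  response <- match.arg(response)
  nf <- neighborhood_features(census, radius = radius)
  keep <- nf$species_code == species
  tab <- nf[keep, , drop = FALSE]
  resp <- if (response == "dbh") tab$dbh else {
    surf <- focal_abundance_surface(census, species = species,
                                    cell_size = cell_size)
    sample_raster_at_points(surf, tab$x, tab$y)
  }
  out <- data.frame(response = resp,
                    mean_dbh_10m = tab$mean_dbh, cv_dbh_10m = tab$cv_dbh,
                    n_within_10m = tab$n_within, mean_dist_10m = tab$mean_dist,
                    cv_dist_10m = tab$cv_dist, stringsAsFactors = FALSE)
  for (nm in names(rasters)) {
    v <- sample_raster_at_points(rasters[[nm]], tab$x, tab$y)
    out[[nm]] <- if (rasters[[nm]]$kind == "categorical") factor(v) else v
  }
  out$border <- tab$border
  if (drop_border) out <- out[!out$border, , drop = FALSE]
  if (anyNA(out$response)) stop("missing responses in feature table")
  class(out) <- c("feature_table", "data.frame")
  out
}
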