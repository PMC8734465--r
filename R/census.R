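#' Rectangular plot window
#'
#' Defines the study window as a rectangle in plot coordinates (metres from
#' the southwest corner). The Harvard Forest ForestGEO plot is 500 x 700 m
#' (35 ha); that geometry is the default elsewhere in the package but any
#' rectangle is accepted.
#'
#' @param width,height Side lengths in metres; must be positive.
#' @param x0,y0 Coordinates of the southwest corner (default 0, 0).
#' @return An object of class `"plot_window"` with fields `width`, `height`,
#'   `x0`, `y0`, `area` (m^2) and `area_ha`.
#' @examples
#' w <- plot_window(500, 700)
#' w$area_ha  # 35
#' @export
plot_window <- function(width, height, x0 = 0, y0 = 0) {
  stopifnot(is.numeric(width), is.numeric(height), width > 0, height > 0)
  structure(list(width = width, height = height, x0 = x0, y0 = y0,
                 area = width * height, area_ha = width * height / 1e4),
            class = "plot_window")
}

#' @export
print.plot_window <- function(x, ...) {
  cat(sprintf("plot window: %g x %g m (%.2f ha), origin (%g, %g)\n",
              x$width, x$height, x$area_ha, x$x0, x$y0))
  invisible(x)
}

.canonical_cols <- c("tag", "individual", "species", "x", "y", "dbh", "status")

#' Construct a census object
#'
#' Bundles a stem table with its plot window and an optional species lookup
#' table. Stem records carry one row per tagged stem; multi-stemmed
#' individuals share an `individual_id`.
#'
#' @param stems data.frame with columns `stem_tag`, `individual_id`,
#'   `species_code`, `x`, `y`, `dbh` (cm), `status` (`"live"`/`"dead"`).
#' @param window A [plot_window()].
#' @param species_table Optional named character vector mapping species codes
#'   to scientific names.
#' @return An object of class `"census"`.
#' @export
census <- function(stems, window, species_table = NULL) {
  needed <- c("stem_tag", "individual_id", "species_code", "x", "y", "dbh", "status")
  missing <- setdiff(needed, names(stems))
  if (length(missing))
    stop("stem table lacks column(s): ", paste(missing, collapse = ", "))
  stems <- as.data.frame(stems)[needed]
  structure(list(window = window, stems = stems, species_table = species_table),
            class = "census")
}

#' @export
print.census <- function(x, ...) {
  cat(sprintf("census: %d stems, %d individuals, %d species in a %g x %g m window\n",
              nrow(x$stems), length(unique(x$stems$individual_id)),
              length(unique(x$stems$species_code)), x$window$width, x$window$height))
  invisible(x)
}

#' Read a stem census table from CSV
#'
#' Reads a ForestGEO-style stem table. Column names in the file are mapped to
#' the canonical fields via `column_map`; numeric columns are parsed with a
#' locale-independent decimal point.
#'
#' @param path Path to a CSV file with a header row (UTF-8).
#' @param window A [plot_window()] giving the plot geometry.
#' @param column_map Named character vector mapping canonical names
#'   (`tag`, `individual`, `species`, `x`, `y`, `dbh`, `status`) to the file's
#'   column names. Defaults to the identity mapping.
#' @param species_table Optional species code -> name lookup.
#' @return A [census()] object with one row per stem, rows in file order.
#' @export
read_stem_table <- function(path, window, column_map = NULL, species_table = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  map <- stats::setNames(.canonical_cols, .canonical_cols)
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  missing <- map[!(map %in% names(raw))]
  if (length(missing))
    stop("schema error: missing column(s) ",
         paste(sprintf("'%s' (for %s)", missing, names(missing)), collapse = ", "))
  num <- function(field) {
    txt <- raw[[map[[field]]]]
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(val) & !is.na(txt) & nzchar(trimws(txt)))
    if (length(bad))
      stop(sprintf("unparseable numeric in column '%s' (field %s) at data line %s",
                   map[[field]], field, paste(bad, collapse = ", ")))
    val
  }
  stems <- data.frame(
    stem_tag      = raw[[map[["tag"]]]],
    individual_id = raw[[map[["individual"]]]],
    species_code  = raw[[map[["species"]]]],
    x             = num("x"),
    y             = num("y"),
    dbh           = num("dbh"),
    status        = raw[[map[["status"]]]],
    stringsAsFactors = FALSE
  )
  census(stems, window, species_table)
}

#' Write a census stem table to CSV
#'
#' Inverse of [read_stem_table()] under the identity column map.
#'
#' @param census A [census()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stem_table <- function(census, path) {
  out <- census$stems
  names(out) <- c("tag", "individual", "species", "x", "y", "dbh", "status")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a census against the census protocol invariants
#'
#' Checks each stem against the plot protocol: live stems enter the census at
#' dbh >= 1 cm, standing dead stems at dbh >= 5 cm, coordinates must fall in
#' the window, stem tags must be unique, status must be `"live"` or `"dead"`,
#' and all stems of one individual must share a species. Violations are
#' reported, never thrown, and the census is not modified.
#'
#' @param census A [census()].
#' @return A `"validation_report"`: data.frame with columns `stem_tag`,
#'   `rule`, `message`; zero rows means a clean census. `all_valid()` gives
#'   the corresponding logical.
#' @export
validate_census <- function(census) {
  s <- census$stems
  w <- census$window
  flags <- list()
  add <- function(idx, rule, msg) {
    if (length(idx))
      flags[[length(flags) + 1]] <<- data.frame(
        stem_tag = s$stem_tag[idx], rule = rule, message = msg,
        stringsAsFactors = FALSE)
  }
  add(which(!is.finite(s$dbh) | s$dbh <= 0), "dbh_positive", "dbh must be > 0")
  add(which(s$status == "live" & is.finite(s$dbh) & s$dbh < 1),
      "live_min_dbh", "live stem below 1-cm census threshold")
  add(which(s$status == "dead" & is.finite(s$dbh) & s$dbh < 5),
      "dead_min_dbh", "dead stem below 5-cm census threshold")
  add(which(!(s$status %in% c("live", "dead"))), "status_vocabulary",
      "status must be 'live' or 'dead'")
  out <- s$x < w$x0 | s$x > w$x0 + w$width | s$y < w$y0 | s$y > w$y0 + w$height |
    !is.finite(s$x) | !is.finite(s$y)
  add(which(out), "inside_window", "coordinates outside plot window")
  add(which(duplicated(s$stem_tag)), "unique_tag", "duplicated stem tag")
  nsp <- tapply(s$species_code, s$individual_id, function(z) length(unique(z)))
  bad_ind <- names(nsp)[nsp > 1]
  add(which(s$individual_id %in% bad_ind), "one_species_per_individual",
      "individual spans multiple species codes")
  if (!is.null(census$species_table))
    add(which(!(s$species_code %in% names(census$species_table))),
        "species_resolves", "species code absent from species table")
  rep <- if (length(flags)) do.call(rbind, flags) else
    data.frame(stem_tag = character(), rule = character(), message = character(),
               stringsAsFactors = FALSE)
  class(rep) <- c("validation_report", "data.frame")
  rep
}

#' @rdname validate_census
#' @param report A `"validation_report"`.
#' @export
all_valid <- function(report) nrow(report) == 0L

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0) cat("census valid: no protocol violations\n")
  else {
    cat(sprintf("census invalid: %d violation(s)\n", nrow(x)))
    print.data.frame(utils::head(x, 20))
  }
  invisible(x)
}

#' Quadrat grid over a plot window
#'
#' The standard census grid of contiguous square quadrats (20 x 20 m by
#' default). Cells are half-open `[a, a+cell) x [b, b+cell)` except along the
#' plot's maximal edges, which are closed so the grid partitions the window.
#'
#' @param window A [plot_window()].
#' @param cell_size Quadrat side in metres (default 20).
#' @return An object of class `"quadrat_grid"` with `n_cols`, `n_rows`.
#' @export
quadrat_grid <- function(window, cell_size = 20) {
  stopifnot(cell_size > 0)
  structure(list(window = window, cell_size = cell_size,
                 n_cols = as.integer(ceiling(window$width / cell_size)),
                 n_rows = as.integer(ceiling(window$height / cell_size))),
            class = "quadrat_grid")
}

# Shared half-open cell indexing: floor((u - u0)/cell), with the plot's outer
# maximal edge folded into the last cell.
.cell_index <- function(u, u0, cell, n_cells) {
  i <- floor((u - u0) / cell)
  pmin(as.integer(i), n_cells - 1L)
}

#' Assign stems to quadrats
#'
#' Each stem gets the 0-based (column, row) index of its quadrat under the
#' half-open convention: a stem exactly on a shared cell boundary belongs to
#' the higher-index cell, except on the plot's outer maximal edges which fold
#' into the last cell. The assignment partitions the stems.
#'
#' @param census A [census()]; all stems must lie in the window.
#' @param grid A [quadrat_grid()].
#' @return data.frame with columns `stem_tag`, `col`, `row`, `cell`
#'   (`cell = row * n_cols + col`, 0-based).
#' @export
assign_quadrats <- function(census, grid) {
  s <- census$stems
  w <- grid$window
  out <- s$x < w$x0 | s$x > w$x0 + w$width | s$y < w$y0 | s$y > w$y0 + w$height
  if (any(out))
    stop("stems outside window: ", paste(s$stem_tag[out], collapse = ", "))
  col <- .cell_index(s$x, w$x0, grid$cell_size, grid$n_cols)
  row <- .cell_index(s$y, w$y0, grid$cell_size, grid$n_rows)
  data.frame(stem_tag = s$stem_tag, col = col, row = row,
             cell = row * grid$n_cols + col, stringsAsFactors = FALSE)
}
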