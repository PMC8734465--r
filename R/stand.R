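#' Basal area of a stem
#'
#' Cross-sectional area at breast height, `pi * (dbh/200)^2`, in square
#' metres for dbh in centimetres.
#'
#' @param dbh Diameter at breast height, cm; must be positive.
#' @return Basal area in m^2.
#' @examples
#' stem_basal_area(10)  # 0.007853982
#' @export
stem_basal_area <- function(dbh) {
  if (any(!is.finite(dbh) | dbh <= 0)) stop("dbh must be positive and finite")
  pi * (dbh / 200)^2
}

#' Read an allometry coefficient table
#'
#' Species-specific aboveground biomass equations are supplied as data, one
#' row per species code with a two-parameter form: either `power_law`
#' (`a * dbh^b`) or `log_linear` (`exp(a + b * log(dbh))`). The two forms are
#' mathematically interchangeable (`a_log = log(a_pow)`); the table declares
#' which parameterisation each row carries. A row with species code `"*"`
#' acts as the fallback for species without their own entry.
#'
#' @param path CSV with columns `species_code`, `form`, `a`, `b`.
#' @return data.frame of class `"allometry_table"`.
#' @export
read_allometry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  allometry_table(tab)
}

#' @rdname read_allometry
#' @param table data.frame with columns `species_code`, `form`, `a`, `b`.
#' @export
allometry_table <- function(table) {
  need <- c("species_code", "form", "a", "b")
  if (!all(need %in% names(table)))
    stop("allometry table needs columns: ", paste(need, collapse = ", "))
  if (!all(table$form %in% c("power_law", "log_linear")))
    stop("allometry form must be 'power_law' or 'log_linear'")
  bad <- table$form == "power_law" & table$a <= 0
  if (any(bad)) stop("power-law coefficient a must be positive")
  if (anyDuplicated(table$species_code)) stop("duplicated species_code in allometry table")
  class(table) <- c("allometry_table", "data.frame")
  table
}

.allometry_lookup <- function(allometry, species) {
  i <- match(species, allometry$species_code)
  fb <- match("*", allometry$species_code)
  i[is.na(i)] <- fb
  if (anyNA(i))
    stop("no allometry entry (and no '*' fallback) for species: ",
         paste(unique(species[is.na(i)]), collapse = ", "))
  i
}

#' Aboveground biomass of a stem from dbh
#'
#' Evaluates the species' allometric equation at the stem's dbh.
#'
#' @param dbh Diameter at breast height, cm; positive.
#' @param species Species code(s), recycled against `dbh`.
#' @param allometry An [allometry_table()].
#' @return Biomass in kg.
#' @export
stem_biomass <- function(dbh, species, allometry) {
  if (any(!is.finite(dbh) | dbh <= 0)) stop("dbh must be positive and finite")
  i <- .allometry_lookup(allometry, species)
  a <- allometry$a[i]; b <- allometry$b[i]
  ifelse(allometry$form[i] == "power_law", a * dbh^b, exp(a + b * log(dbh)))
}

#' Per-species stand summary
#'
#' Density counts individuals (multi-stemmed plants collapse to one), while
#' basal area and biomass sum over every qualifying stem — the census
#' convention for multi-stemmed plants. Per-hectare columns divide totals by
#' the window area.
#'
#' @param census A [census()].
#' @param allometry An [allometry_table()], or `NULL` to skip biomass.
#' @param status Which stems to summarise (default `"live"`).
#' @return data.frame of class `"species_summary"`, one row per species:
#'   `species_code`, `n_individuals`, `n_stems`, `basal_area_m2`,
#'   `biomass_Mg`, and `_per_ha` versions, sorted by descending
#'   `n_individuals`.
#' @export
species_summary <- function(census, allometry = NULL, status = "live") {
  s <- census$stems[census$stems$status %in% status, , drop = FALSE]
  area_ha <- census$window$area_ha
  ba <- stem_basal_area(s$dbh)
  bm <- if (!is.null(allometry)) stem_biomass(s$dbh, s$species_code, allometry)
        else rep(NA_real_, nrow(s))
  sp <- sort(unique(s$species_code))
  rows <- lapply(sp, function(code) {
    k <- s$species_code == code
    data.frame(species_code = code,
               n_individuals = length(unique(s$individual_id[k])),
               n_stems = sum(k),
               basal_area_m2 = sum(ba[k]),
               biomass_Mg = sum(bm[k]) / 1000,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$density_per_ha <- out$n_individuals / area_ha
  out$basal_area_m2_per_ha <- out$basal_area_m2 / area_ha
  out$biomass_Mg_per_ha <- out$biomass_Mg / area_ha
  out <- out[order(-out$n_individuals, out$species_code), ]
  rownames(out) <- NULL
  class(out) <- c("species_summary", "data.frame")
  attr(out, "area_ha") <- area_ha
  out
}

#' Published whole-plot stand totals for the 35-ha Harvard Forest plot
#'
#' The published per-species live-stem totals (individual counts, basal
#' area in m^2, aboveground biomass in Mg) for the 500 x 700 m (35 ha)
#' ForestGEO census, shipped as package data. Combined with
#' [stand_totals_per_ha()], these reproduce the reported per-hectare
#' figures.
#'
#' @return data.frame: `scientific_name`, `n_individuals`,
#'   `basal_area_m2`, `biomass_Mg`.
#' @export
published_stand_totals <- function() {
  utils::read.csv(system.file("extdata", "hf_published_stand_totals.csv",
                              package = "standmarks"),
                  stringsAsFactors = FALSE)
}

#' Per-hectare figures and dominance shares from plot totals
#'
#' Derives per-hectare density, basal area and biomass from whole-plot
#' species totals, plus each species' percentage share of the plot total.
#'
#' @param totals data.frame as returned by [published_stand_totals()].
#' @param area_ha Plot area in hectares (default 35).
#' @return `totals` with added columns `density_per_ha`,
#'   `basal_area_m2_per_ha`, `biomass_Mg_per_ha`, `basal_area_share_pct`,
#'   `biomass_share_pct`.
#' @export
stand_totals_per_ha <- function(totals, area_ha = 35) {
  totals$density_per_ha <- totals$n_individuals / area_ha
  totals$basal_area_m2_per_ha <- totals$basal_area_m2 / area_ha
  totals$biomass_Mg_per_ha <- totals$biomass_Mg / area_ha
  totals$basal_area_share_pct <- 100 * totals$basal_area_m2 / sum(totals$basal_area_m2)
  totals$biomass_share_pct <- 100 * totals$biomass_Mg / sum(totals$biomass_Mg)
  totals
}

#' Diameter distribution of a species
#'
#' Bins stem dbh into diameter classes. Bins are left-closed, right-open,
#' with the last bin closed on the right, so the counts partition the stems
#' whose dbh falls in `[min(bin_edges), max(bin_edges)]`. Default edges are
#' 5-cm classes from 1 cm.
#'
#' @param census A [census()].
#' @param species Species code, or `NULL` for all species pooled.
#' @param bin_edges Strictly increasing numeric vector of class edges (cm).
#' @param status Stem status to include (default `"live"`).
#' @return data.frame with columns `lower`, `upper`, `count`.
#' @export
diameter_distribution <- function(census, species = NULL,
                                  bin_edges = seq(1, 101, by = 5),
                                  status = "live") {
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be strictly increasing")
  s <- census$stems[census$stems$status %in% status, , drop = FALSE]
  if (!is.null(species)) s <- s[s$species_code %in% species, , drop = FALSE]
  d <- s$dbh[s$dbh >= bin_edges[1] & s$dbh <= bin_edges[length(bin_edges)]]
  # left-closed bins; findInterval with the top edge folded into the last bin
  idx <- findInterval(d, bin_edges, rightmost.closed = TRUE, left.open = FALSE)
  nb <- length(bin_edges) - 1L
  counts <- tabulate(idx, nbins = nb)
  data.frame(lower = bin_edges[-length(bin_edges)], upper = bin_edges[-1],
             count = counts)
}

#' Classify the shape of a diameter distribution
#'
#' The classic reverse-J (monotonically declining) size distribution signals
#' continuous regeneration; a unimodal distribution (rising to a single
#' interior mode then falling) signals an even-aged cohort. The
#' classification is made on the binned counts: `reverse_J` iff counts never
#' increase across bins, `unimodal` iff they rise then fall around one
#' interior mode, `other` otherwise.
#'
#' @param distribution Output of [diameter_distribution()], or a numeric
#'   vector of bin counts.
#' @return `"reverse_J"`, `"unimodal"` or `"other"`.
#' @export
classify_size_distribution <- function(distribution) {
  counts <- if (is.data.frame(distribution)) distribution$count else distribution
  if (sum(counts > 0) < 3) stop("need at least 3 nonempty bins to classify")
  counts <- counts[seq(which(counts > 0)[1], max(which(counts > 0)))]
  d <- diff(counts)
  if (all(d <= 0)) return("reverse_J")
  up <- which(d > 0); down <- which(d < 0)
  # unimodal: every rise precedes every fall, with an interior mode
  if (length(up) && length(down) && max(up) < min(down)) return("unimodal")
  "other"
}
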