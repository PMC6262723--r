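#' @useDynLib standdyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate coef cor logLik pnorm qlogis plogis quantile
#'   rbinom rexp rmultinom rnorm rpois runif sd setNames
#' @importFrom utils read.csv write.csv
"_PACKAGE"

## status vocabulary --------------------------------------------------------

#' Tree status codes
#'
#' Census status codes for a tagged stem. `alive`; the three death modes
#' recorded at the first census after death (`standing_dead`, `stem_broken`,
#' `uprooted` — standing dead is read as senescence/suppression, the other two
#' as mechanical disturbance); `prior_dead` for censuses after the death
#' record; `not_recruited` before a stem reaches the 2.0 cm threshold.
#'
#' @format Character vector of the six admissible codes.
#' @export
STATUS_CODES <- c("alive", "standing_dead", "stem_broken", "uprooted",
                  "prior_dead", "not_recruited")

DEATH_MODES <- c("standing_dead", "stem_broken", "uprooted")

#' Minimum DBH for a stem to enter the census, cm
#' @export
CENSUS_THRESHOLD_CM <- 2.0

## census_table -------------------------------------------------------------

#' Construct a stem-mapped multi-census table
#'
#' The pipeline's universal input: one row per tree per census, with mapped
#' coordinates and DBH. Validation enforces the census protocol: stems enter
#' at 2.0 cm DBH, coordinates lie inside the plot, a tree never returns to
#' life after a death record, and DBH is present exactly for live stems and
#' stems recorded dead at that census.
#'
#' @param trees data.frame with columns `tree_id`, `species`, `growth_form`
#'   (one of `"EC"`, `"DH"`, `"EH"`), `x`, `y` (m), `census_year`, `dbh` (cm,
#'   `NA` when not measurable), `status` (see [STATUS_CODES]), and optionally
#'   `sprout_parent_id`.
#' @param plot_width,plot_height plot dimensions in metres (default the
#'   50 x 100 m reference geometry).
#' @param census_years ascending integer census years; defaults to the years
#'   present in `trees`.
#' @return An object of class `census_table`: a list with elements `trees`,
#'   `plot_width`, `plot_height`, `census_years`, `area_ha`.
#' @export
census_table <- function(trees, plot_width = 50, plot_height = 100,
                         census_years = NULL) {
  req <- c("tree_id", "species", "growth_form", "x", "y", "census_year",
           "dbh", "status")
  miss <- setdiff(req, names(trees))
  if (length(miss))
    stop("trees is missing columns: ", paste(miss, collapse = ", "))
  if (!"sprout_parent_id" %in% names(trees))
    trees$sprout_parent_id <- NA_character_
  trees <- trees[, c(req, "sprout_parent_id")]
  trees$tree_id <- as.character(trees$tree_id)
  trees$species <- as.character(trees$species)
  trees$growth_form <- as.character(trees$growth_form)
  trees$census_year <- as.integer(trees$census_year)
  trees$dbh <- as.numeric(trees$dbh)
  trees$status <- as.character(trees$status)
  trees$sprout_parent_id <- as.character(trees$sprout_parent_id)
  if (is.null(census_years))
    census_years <- sort(unique(trees$census_year))
  census_years <- as.integer(census_years)
  if (is.unsorted(census_years, strictly = TRUE))
    stop("census_years must be strictly increasing")
  ord <- order(trees$tree_id, trees$census_year)
  trees <- trees[ord, , drop = FALSE]
  rownames(trees) <- NULL
  obj <- structure(list(trees = trees,
                        plot_width = as.numeric(plot_width),
                        plot_height = as.numeric(plot_height),
                        census_years = census_years,
                        area_ha = plot_width * plot_height / 1e4),
                   class = "census_table")
  validate_census(obj)
  obj
}

validate_census <- function(tab) {
  tr <- tab$trees
  problems <- character(0)
  note <- function(rows, msg) {
    if (length(rows))
      problems <<- c(problems,
                     paste0(msg, " [rows ",
                            paste(utils::head(rows, 5L), collapse = ", "),
                            if (length(rows) > 5L) ", ..." else "", "]"))
  }
  note(which(!tr$status %in% STATUS_CODES), "invalid status code")
  note(which(!tr$census_year %in% tab$census_years),
       "census_year not in census_years")
  dup <- duplicated(tr[, c("tree_id", "census_year")])
  note(which(dup), "duplicate (tree_id, census_year)")
  bad_xy <- which(!is.finite(tr$x) | !is.finite(tr$y) |
                  tr$x < 0 | tr$x > tab$plot_width |
                  tr$y < 0 | tr$y > tab$plot_height)
  note(bad_xy, "coordinates outside plot")
  alive <- tr$status == "alive"
  note(which(alive & (is.na(tr$dbh) | tr$dbh < CENSUS_THRESHOLD_CM)),
       "alive stem with DBH missing or < 2.0 cm")
  note(which(tr$status %in% DEATH_MODES & is.na(tr$dbh)),
       "dead-at-census stem without DBH")
  note(which(tr$status %in% c("prior_dead", "not_recruited") & !is.na(tr$dbh)),
       "DBH recorded for prior_dead/not_recruited stem")
  ## dead-then-alive: rows are sorted by (tree_id, census_year)
  dead_like <- tr$status %in% c(DEATH_MODES, "prior_dead")
  same_tree <- c(FALSE, tr$tree_id[-1] == tr$tree_id[-nrow(tr)])
  seen_dead <- stats::ave(dead_like, tr$tree_id, FUN = function(z)
    cummax(as.integer(z))) > 0
  resurrected <- which(alive & seen_dead & same_tree & !dead_like)
  if (length(resurrected))
    problems <- c(problems,
                  paste0("alive record after death for tree(s) ",
                         paste(unique(tr$tree_id[resurrected]), collapse = ", ")))
  if (length(problems))
    stop("invalid census table:\n  ", paste(problems, collapse = "\n  "))
  invisible(tab)
}

#' @exportS3Method print census_table
print.census_table <- function(x, ...) {
  cat("census_table: ", x$plot_width, "x", x$plot_height, "m (",
      x$area_ha, "ha), censuses ",
      paste(x$census_years, collapse = ", "), "\n", sep = "")
  cat("  ", length(unique(x$trees$tree_id)), " trees, ",
      nrow(x$trees), " records, ",
      length(unique(x$trees$species)), " species\n", sep = "")
  invisible(x)
}

## I/O ----------------------------------------------------------------------

#' Read a plot configuration file
#'
#' Flat key-value text (`key value` or `key = value` per line, `#` comments):
#' keys `plot_width_m`, `plot_height_m`, `census_years` (comma-separated).
#'
#' @param path file path.
#' @return list with `plot_width`, `plot_height`, `census_years`.
#' @export
read_plot_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)[ =:]+(.*)$", lines))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  getv <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) stop("plot config missing key: ", k)
    vals[i]
  }
  list(plot_width = as.numeric(getv("plot_width_m")),
       plot_height = as.numeric(getv("plot_height_m")),
       census_years = as.integer(strsplit(getv("census_years"), ",")[[1]]))
}

#' Read a long-format census file
#'
#' @param path CSV with header `tree_id, species, growth_form, x, y,
#'   census_year, dbh, status, sprout_parent_id` (empty fields are `NA`).
#' @param plot_config either a list as returned by [read_plot_config()] or a
#'   path to a plot config file.
#' @return a validated [census_table()].
#' @export
read_census <- function(path, plot_config) {
  if (is.character(plot_config)) plot_config <- read_plot_config(plot_config)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(tree_id = "character", species = "character",
                                growth_form = "character",
                                sprout_parent_id = "character"),
                 na.strings = c("", "NA"))
  census_table(df,
               plot_width = plot_config$plot_width,
               plot_height = plot_config$plot_height,
               census_years = plot_config$census_years)
}

#' Write a census table to CSV
#'
#' Rows are ordered by (`tree_id`, `census_year`) and numeric fields are
#' written at 0.01 precision (cm / m, the census measurement precision), so
#' two writes of one table are byte-identical and tables produced by
#' [simulate_stand()] round-trip exactly through [read_census()].
#'
#' @param table a [census_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_census <- function(table, path) {
  stopifnot(inherits(table, "census_table"))
  tr <- table$trees
  out <- data.frame(tree_id = tr$tree_id, species = tr$species,
                    growth_form = tr$growth_form,
                    x = sprintf("%.2f", tr$x), y = sprintf("%.2f", tr$y),
                    census_year = tr$census_year,
                    dbh = ifelse(is.na(tr$dbh), "", sprintf("%.2f", tr$dbh)),
                    status = tr$status,
                    sprout_parent_id = ifelse(is.na(tr$sprout_parent_id), "",
                                              tr$sprout_parent_id),
                    stringsAsFactors = FALSE)
  con <- file(path, open = "wb")  # fixed EOL across platforms
  on.exit(close(con))
  write.csv(out, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Write the matching plot config for a census table
#' @param table a [census_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plot_config <- function(table, path) {
  writeLines(c(paste("plot_width_m", table$plot_width),
               paste("plot_height_m", table$plot_height),
               paste("census_years",
                     paste(table$census_years, collapse = ","))),
             path)
  invisible(path)
}

## summaries ----------------------------------------------------------------

ba_cm2 <- function(dbh) pi * (dbh / 2)^2   # cm^2 per stem

alive_at <- function(table, year) {
  tr <- table$trees
  tr[tr$census_year == year & tr$status == "alive", , drop = FALSE]
}

#' Species-level density, basal area and maximum DBH at one census
#'
#' Density is stems/ha, basal area m2/ha (from per-stem pi*(DBH/2)^2,
#' cm2 converted), and max DBH the largest DBH the species reached in any
#' census (live or at death). Growth-form subtotals and the grand total are
#' included so composition identities can be checked without re-aggregation.
#'
#' @param table a [census_table()].
#' @param year a census year.
#' @return list of class `species_summary` with data.frames `species`,
#'   `growth_form`, `total` plus `year` and `area_ha`.
#' @export
summarize_species <- function(table, year) {
  if (!year %in% table$census_years)
    stop("year ", year, " was not censused")
  al <- alive_at(table, year)
  if (nrow(al) == 0L)
    stop("no alive stems at ", year)
  area <- table$area_ha
  tr <- table$trees
  max_dbh_all <- tapply(tr$dbh, tr$species, max, na.rm = TRUE)
  agg <- aggregate(cbind(n = rep(1, nrow(al)), ba = ba_cm2(al$dbh)),
                   by = list(species = al$species,
                             growth_form = al$growth_form), FUN = sum)
  sp <- data.frame(species = agg$species, growth_form = agg$growth_form,
                   n = agg$n,
                   density = agg$n / area,
                   basal_area = agg$ba * 1e-4 / area,
                   max_dbh = as.numeric(max_dbh_all[agg$species]),
                   stringsAsFactors = FALSE)
  sp <- sp[order(match(sp$growth_form, c("EC", "DH", "EH")),
                 -sp$basal_area), , drop = FALSE]
  rownames(sp) <- NULL
  gf <- aggregate(cbind(n = sp$n, density = sp$density,
                        basal_area = sp$basal_area),
                  by = list(growth_form = sp$growth_form), FUN = sum)
  gf <- gf[order(match(gf$growth_form, c("EC", "DH", "EH"))), , drop = FALSE]
  rownames(gf) <- NULL
  tot <- data.frame(n = sum(sp$n), density = sum(sp$density),
                    basal_area = sum(sp$basal_area))
  structure(list(species = sp, growth_form = gf, total = tot,
                 year = year, area_ha = area),
            class = "species_summary")
}

#' Growth-form share of density or basal area
#'
#' @param summaries a `species_summary` from [summarize_species()], or any
#'   data.frame with columns `growth_form` and the chosen metric.
#' @param metric `"density"` or `"basal_area"`.
#' @return data.frame with exact percentage shares (summing to 100) and
#'   integer-rounded shares for reporting.
#' @export
dominance_share <- function(summaries, metric = c("density", "basal_area")) {
  metric <- match.arg(metric)
  gf <- if (inherits(summaries, "species_summary")) summaries$growth_form
        else summaries
  v <- gf[[metric]]
  if (length(v) == 0L || sum(v) <= 0) stop("empty plot")
  data.frame(growth_form = gf$growth_form,
             share_pct = 100 * v / sum(v),
             share_pct_rounded = round(100 * v / sum(v)),
             stringsAsFactors = FALSE)
}

#' Warmth and cold indices from monthly mean temperatures
#'
#' WI = sum of (m - 5) over months with mean above 5 degC; CI = -sum of
#' (5 - m) over months below 5 degC (degC months). Months at exactly 5 degC
#' contribute to neither.
#'
#' @param monthly_means numeric vector of 12 monthly mean temperatures, degC.
#' @return list of class `site_climate` with `monthly_means`, `WI`, `CI`.
#' @export
climate_indices <- function(monthly_means) {
  if (length(monthly_means) != 12L || any(!is.finite(monthly_means)))
    stop("monthly_means must be 12 finite values")
  structure(list(monthly_means = monthly_means,
                 WI = sum(pmax(monthly_means - 5, 0)[monthly_means > 5]),
                 CI = -sum(pmax(5 - monthly_means, 0)[monthly_means < 5])),
            class = "site_climate")
}
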