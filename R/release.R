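## Dendroecological release detection by percent growth change between
## adjacent 10-year mean windows: M1 = mean of the 10 ring widths ending at
## and including the target year, M2 = mean of the 10 widths after it,
## pgc = (M2 - M1)/M1 * 100. Thresholds 25% (moderate) and 50% (major).

#' Construct an annual ring-width series
#'
#' @param tree_id,species identifiers.
#' @param first_year calendar year of the first ring.
#' @param widths positive annual ring widths, mm, consecutive years.
#' @return object of class `ring_series`.
#' @export
ring_series <- function(tree_id, species, first_year, widths) {
  stopifnot(length(widths) >= 1L, all(is.finite(widths)), all(widths > 0))
  structure(list(tree_id = as.character(tree_id),
                 species = as.character(species),
                 first_year = as.integer(first_year),
                 widths = as.numeric(widths)),
            class = "ring_series")
}

series_years <- function(series) {
  series$first_year + seq_along(series$widths) - 1L
}

#' Read ring-width series from CSV
#'
#' Expects columns `tree_id, species, year, width_mm`; years within a tree
#' must be consecutive. When a tree appears with more than one core the
#' convention is one core per tree, so the input must already be reduced.
#'
#' @param path CSV path.
#' @return list of [ring_series()].
#' @export
read_rings <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(tree_id = "character", species = "character"))
  lapply(split(df, df$tree_id), function(d) {
    d <- d[order(d$year), ]
    if (any(diff(d$year) != 1L))
      stop("non-consecutive years for tree ", d$tree_id[1])
    ring_series(d$tree_id[1], d$species[1], d$year[1], d$width_mm)
  })
}

#' Write ring-width series to CSV
#' @param series list of [ring_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rings <- function(series, path) {
  df <- do.call(rbind, lapply(series, function(s)
    data.frame(tree_id = s$tree_id, species = s$species,
               year = series_years(s), width_mm = s$widths,
               stringsAsFactors = FALSE)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.csv(df, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Percent growth change at one year
#'
#' Defined only where both 10-year windows are complete: the series must
#' reach 10 years up to and including `year` and 10 years after it.
#'
#' @param series a [ring_series()].
#' @param year target calendar year.
#' @return percent growth change, or `NA` (annotated) when a window is
#'   incomplete.
#' @export
percent_growth_change <- function(series, year) {
  yrs <- series_years(series)
  i <- match(year, yrs)
  if (is.na(i) || i < 10L || i + 10L > length(yrs))
    return(structure(NA_real_, undefined = "incomplete 10-yr window"))
  M1 <- mean(series$widths[(i - 9L):i])
  M2 <- mean(series$widths[(i + 1L):(i + 10L)])
  (M2 - M1) / M1 * 100
}

## all evaluable years at once (vectorized via filter)
pgc_profile <- function(series) {
  w <- series$widths
  n <- length(w)
  if (n < 20L)
    return(data.frame(year = integer(0), pgc = numeric(0)))
  cs <- cumsum(c(0, w))
  idx <- 10:(n - 10L)                      # evaluable positions
  M1 <- (cs[idx + 1L] - cs[idx - 9L]) / 10
  M2 <- (cs[idx + 11L] - cs[idx + 1L]) / 10
  data.frame(year = series$first_year + idx - 1L,
             pgc = (M2 - M1) / M1 * 100)
}

#' Detect growth releases in a ring-width series
#'
#' Years with percent growth change at or above the moderate threshold are
#' grouped into runs of consecutive years; each run yields one release event
#' at its peak-pgc year (earliest year on ties), classified `moderate`
#' (below the major threshold) or `major` (at or above it).
#'
#' @param series a [ring_series()].
#' @param moderate,major thresholds in percent, `0 < moderate < major`.
#' @return data.frame with `tree_id`, `species`, `year`, `pgc`, `magnitude`;
#'   zero rows (with a warning) when the series is too short to evaluate.
#' @export
detect_releases <- function(series, moderate = 25, major = 50) {
  stopifnot(moderate > 0, major > moderate)
  empty <- data.frame(tree_id = character(0), species = character(0),
                      year = integer(0), pgc = numeric(0),
                      magnitude = character(0), stringsAsFactors = FALSE)
  prof <- pgc_profile(series)
  if (nrow(prof) == 0L) {
    warning("series ", series$tree_id, " too short for release detection")
    return(empty)
  }
  hot <- prof$pgc >= moderate
  if (!any(hot)) return(empty)
  run_id <- cumsum(c(hot[1], diff(hot) == 1))  # increments at run starts
  events <- lapply(split(which(hot), run_id[hot]), function(ix) {
    peak <- ix[which.max(prof$pgc[ix])]        # earliest max on ties
    data.frame(tree_id = series$tree_id, species = series$species,
               year = prof$year[peak], pgc = prof$pgc[peak],
               magnitude = if (prof$pgc[peak] >= major) "major" else
                 "moderate",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Release chronology over calendar bins
#'
#' Bins are aligned to the calendar in blocks of `bin` years ending on
#' multiples of `bin` (with the default 5: 1916-1920, 1921-1925, ...). The
#' numerator is the number of trees with at least one release event in the
#' bin; the denominator (sample depth) is the number of trees with an
#' evaluable percent growth change in at least one year of the bin.
#'
#' @param events row-bound output of [detect_releases()] over all trees.
#' @param series_set list of [ring_series()] (defines sample depth).
#' @param bin bin width in years.
#' @param min_depth report only bins with at least this sample depth (a
#'   common interpretive floor is 50 sampled trees).
#' @return data.frame: `bin_start`, `bin_end`, `n_released`, `depth`,
#'   `pct_released`.
#' @export
release_chronology <- function(events, series_set, bin = 5L,
                               min_depth = 0L) {
  if (length(series_set) == 0L) stop("empty series set")
  bin_of <- function(y) (ceiling(y / bin) - 1L) * bin + 1L  # bin start year
  ## evaluable years per tree
  depth_tab <- new.env()
  for (s in series_set) {
    prof <- pgc_profile(s)
    if (nrow(prof) == 0L) next
    for (b in unique(bin_of(prof$year))) {
      key <- as.character(b)
      depth_tab[[key]] <- union(if (is.null(depth_tab[[key]])) character(0)
                                else depth_tab[[key]], s$tree_id)
    }
  }
  bins <- sort(as.integer(ls(depth_tab)))
  out <- lapply(bins, function(b) {
    trees <- depth_tab[[as.character(b)]]
    rel <- if (nrow(events)) unique(events$tree_id[
      bin_of(events$year) == b & events$tree_id %in% trees]) else character(0)
    data.frame(bin_start = b, bin_end = b + bin - 1L,
               n_released = length(rel), depth = length(trees),
               pct_released = 100 * length(rel) / length(trees))
  })
  out <- do.call(rbind, out)
  out[out$depth >= min_depth, , drop = FALSE]
}
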