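## End-to-end driver: demography -> matrix model -> spatial association ->
## competition -> ring release -> trait synthesis, with all outputs written
## as CSV plus a reproducibility manifest.

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.csv(df, con, row.names = FALSE, eol = "\n")
  path
}

#' Run the full stand-dynamics pipeline
#'
#' Executes every analysis stage on one census table (and, optionally, a set
#' of ring-width series), writes each stage's output as CSV under `out_dir`,
#' and finishes with a manifest recording the seed, package version,
#' parameters and an md5 per output file. A stage failure is recorded in the
#' manifest and stages needing its output are skipped with a notice; given
#' the same inputs and seed the manifest hashes are identical across runs.
#'
#' @param census a [census_table()] or path to a census CSV (then
#'   `plot_config` must be supplied via `config`).
#' @param rings optional list of [ring_series()] or path to a ring CSV;
#'   `NULL` skips the release stage.
#' @param config list of options: `seed` (default 1), `periods`, `B`
#'   (bootstrap replicates, default 1000), `n_sim` (envelope simulations,
#'   default 1000), `r_grid`, `spatial_year`, `plot_config`.
#' @param out_dir output directory (created if needed).
#' @return list with each stage's result (`NULL` where skipped), invisibly;
#'   side effect: CSVs and `manifest.csv` under `out_dir`.
#' @export
run_pipeline <- function(census, rings = NULL, config = list(),
                         out_dir = tempfile("standdyn_run_")) {
  cfg <- utils::modifyList(
    list(seed = 1L, B = 1000L, n_sim = 1000L, r_grid = 1:10,
         periods = NULL, spatial_year = NULL, plot_config = NULL),
    config)
  if (is.character(census))
    census <- read_census(census, cfg$plot_config)
  if (is.character(rings)) rings <- read_rings(rings)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cy <- census$census_years
  whole <- c(cy[1], cy[length(cy)])
  if (is.null(cfg$spatial_year)) cfg$spatial_year <- cy[1]
  results <- list()
  status <- list()
  run_stage <- function(name, expr) {
    r <- tryCatch(expr, error = function(e)
      structure(conditionMessage(e), class = "stage_error"))
    if (inherits(r, "stage_error")) {
      status[[name]] <<- paste("FAILED:", r)
      results[[name]] <<- NULL
    } else {
      status[[name]] <<- "ok"
      results[[name]] <<- r
    }
  }
  run_stage("demography", {
    rates <- species_rates(census, whole, "species", bootstrap = TRUE,
                           B = cfg$B, seed = cfg$seed)
    write_stage_csv(as.data.frame(rates), out_dir, "species_rates")
    scm <- size_class_mortality(census, periods = cfg$periods,
                                by = "growth_form")
    write_stage_csv(scm, out_dir, "size_class_mortality")
    sdf <- standing_dead_fraction(census, span = whole, by = "growth_form")
    write_stage_csv(sdf, out_dir, "standing_dead_fraction")
    rates
  })
  run_stage("matrix", {
    grt <- growth_rate_table(census, periods = cfg$periods)
    write_stage_csv(grt, out_dir, "population_growth")
    grt
  })
  run_stage("spatial", {
    la <- layer_association(census, cfg$spatial_year, r_grid = cfg$r_grid,
                            n_sim = cfg$n_sim, seed = cfg$seed)
    rows <- list()
    for (f1 in names(la)) for (f2 in names(la[[f1]])) {
      cell <- la[[f1]][[f2]]
      rows[[paste(f1, f2)]] <- if (is.character(cell))
        data.frame(under = f1, over = f2, r = NA, L12 = NA, env_low = NA,
                   env_high = NA, classification = cell)
      else
        data.frame(under = f1, over = f2, as.data.frame(cell))
    }
    write_stage_csv(do.call(rbind, rows), out_dir, "spatial_association")
    la
  })
  run_stage("competition", {
    des <- build_design(census, periods = cfg$periods)
    write_stage_csv(as.data.frame(des), out_dir, "growth_design")
    sel <- lapply(split(des, des$growth_form), function(d)
      if (length(unique(d$tree_id)) >= 10) select_model(d) else NULL)
    for (f in names(sel))
      if (!is.null(sel[[f]]))
        write_stage_csv(as.data.frame(sel[[f]]), out_dir,
                        paste0("model_selection_", f))
    sel
  })
  run_stage("release", {
    if (is.null(rings)) stop("no ring series supplied")
    events <- do.call(rbind, lapply(rings, detect_releases))
    chron <- release_chronology(events, rings)
    write_stage_csv(events, out_dir, "release_events")
    write_stage_csv(chron, out_dir, "release_chronology")
    list(events = events, chronology = chron)
  })
  run_stage("traits", {
    if (is.null(results$demography)) stop("needs demography output")
    sm <- summarize_species(census, cy[1])
    tt <- trait_table(results$demography, results$matrix, sm)
    write_stage_csv(as.data.frame(tt), out_dir, "species_traits")
    ok <- sum(!tt$excluded & stats::complete.cases(
      tt[, c("max_dbh", "mortality", "recruitment", "ingrowth", "r")]))
    if (ok >= 3) {
      pc <- pca(tt[stats::complete.cases(
        tt[, c("max_dbh", "mortality", "recruitment", "ingrowth", "r")]), ])
      write_stage_csv(as.data.frame(pc$loadings), out_dir, "pca_loadings")
      write_stage_csv(as.data.frame(pc$scores), out_dir, "pca_scores")
      list(traits = tt, pca = pc)
    } else list(traits = tt, pca = NULL)
  })
  files <- sort(list.files(out_dir, pattern = "\\.csv$", full.names = TRUE))
  files <- files[basename(files) != "manifest.csv"]
  manifest <- data.frame(
    file = basename(files),
    md5 = as.character(tools::md5sum(files)),
    stringsAsFactors = FALSE)
  meta <- data.frame(
    file = c("_seed", "_B", "_n_sim", "_package_version",
             paste0("_stage_", names(status))),
    md5 = c(cfg$seed, cfg$B, cfg$n_sim,
            as.character(utils::packageVersion("standdyn")),
            unlist(status)),
    stringsAsFactors = FALSE)
  write_stage_csv(rbind(meta, manifest), out_dir, "manifest")
  invisible(c(results, list(out_dir = out_dir, manifest = manifest,
                            status = status)))
}
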