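# Hand-built and simulated fixtures shared across tests.

# one row of a long-format census table
tr_row <- function(id, sp, gf, x, y, year, dbh, status, parent = NA) {
  data.frame(tree_id = id, species = sp, growth_form = gf, x = x, y = y,
             census_year = year, dbh = dbh, status = status,
             sprout_parent_id = parent, stringsAsFactors = FALSE)
}

# five-tree table over censuses 2002/2007/2012 exercising survival, death,
# and recruits (one of which dies before the final census but was tagged)
toy_table <- function() {
  rows <- rbind(
    tr_row("A", "sp1", "EC", 1, 1, 2002, 10.0, "alive"),
    tr_row("A", "sp1", "EC", 1, 1, 2007, 11.0, "alive"),
    tr_row("A", "sp1", "EC", 1, 1, 2012, 12.0, "alive"),
    tr_row("B", "sp1", "EC", 2, 2, 2002, 5.0, "alive"),
    tr_row("B", "sp1", "EC", 2, 2, 2007, 5.0, "standing_dead"),
    tr_row("C", "sp1", "EC", 3, 3, 2007, 2.2, "alive"),
    tr_row("C", "sp1", "EC", 3, 3, 2012, 2.4, "stem_broken"),
    tr_row("D", "sp1", "EC", 4, 4, 2012, 2.1, "alive"),
    tr_row("E", "sp1", "EC", 5, 5, 2002, 20.0, "alive"),
    tr_row("E", "sp1", "EC", 5, 5, 2007, 21.0, "alive"),
    tr_row("E", "sp1", "EC", 5, 5, 2012, 22.0, "alive"))
  census_table(rows, plot_width = 50, plot_height = 100,
               census_years = c(2002, 2007, 2012))
}

# single-species config with exactly known annual death probability and no
# recruitment: the binomial survival oracle applies exactly
oracle_config <- function(seed, n_per_ha = 1000, p_death = 0.02,
                          years = c(2002L, 2015L)) {
  sim_config(seed = seed, census_years = years,
             species = list(species_spec(
               "sp1", "EC", density = n_per_ha, dbh_scale = 5,
               mort_baseline = p_death, mort_size_slope = 0,
               recruit_rate = 0, tree_sd = 0, resid_sd = 0.02)))
}

# small three-species stand used where realism does not matter but speed does
small_stand <- function(seed = 1) {
  simulate_stand(sim_config(seed = seed, species = list(
    species_spec("ec1", "EC", density = 120, dbh_scale = 10, max_dbh = 80,
                 mort_baseline = 0.015, recruit_rate = 1.5),
    species_spec("dh1", "DH", density = 300, dbh_scale = 5, max_dbh = 50,
                 mort_baseline = 0.035, recruit_rate = 4),
    species_spec("eh1", "EH", density = 400, dbh_scale = 2.5, max_dbh = 25,
                 mort_baseline = 0.02, recruit_rate = 8))))
}

# brute-force K12 with translation correction: the stated estimator oracle
k12_brute <- function(p1, p2, r_grid) {
  W <- p1$width; H <- p1$height
  K <- numeric(length(r_grid))
  for (a in seq_len(p1$n)) for (b in seq_len(p2$n)) {
    dx <- p1$x[a] - p2$x[b]; dy <- p1$y[a] - p2$y[b]
    d <- sqrt(dx^2 + dy^2)
    if (d == 0) next
    w <- (W * H) / ((W - abs(dx)) * (H - abs(dy)))
    K <- K + w * (d <= r_grid)
  }
  K * W * H / (p1$n * p2$n)
}

# toroidal pairwise distances of a pattern, sorted
torus_dists <- function(p) {
  n <- p$n
  out <- numeric(0)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    dx <- abs(p$x[a] - p$x[b]); dx <- min(dx, p$width - dx)
    dy <- abs(p$y[a] - p$y[b]); dy <- min(dy, p$height - dy)
    out <- c(out, sqrt(dx^2 + dy^2))
  }
  sort(out)
}

# random Poisson point pattern
rpoisson_pattern <- function(n, W = 50, H = 100) {
  point_pattern(runif(n, 0, W), runif(n, 0, H), W, H)
}
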