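# Parameters and scenarios for the annual-step individual-based eco-genetic
# salmon model.

#' Exponentially declining locus-effect weights
#'
#' Effect weights for the 21 loci of one stage set:
#' `raw_i = exp(-lambda * (i - 1)) - exp(-lambda * 20)` for `i = 1..21`, so
#' the 21st locus has exactly zero effect (a neutral marker), normalised to
#' sum to 1. Weights are strictly decreasing over the first 20 loci.
#'
#' @param lambda Positive decay rate (default 1).
#' @param n_loci Loci per set (default 21).
#' @return List of class `locus_effects` with components `embryo`,
#'   `juvenile`, `adult` (identical weight vectors) and `lambda`.
#' @export
locus_effect_weights <- function(lambda = 1, n_loci = 21) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0) {
    stop("lambda must be a single positive number")
  }
  i <- seq_len(n_loci)
  raw <- exp(-lambda * (i - 1)) - exp(-lambda * (n_loci - 1))
  w <- raw / sum(raw)
  structure(list(embryo = w, juvenile = w, adult = w, lambda = lambda),
            class = "locus_effects")
}

#' Demographic and genetic parameters of the eco-genetic model
#'
#' Defaults describe a small, grilse-dominated Atlantic salmon river: parr
#' annual survivals 0.55 / 0.65 / 0.75 (ages 0, 1, 2), smolting at age 3,
#' one sea-winter with smolt-to-return survival 0.2, fecundity 1500 eggs per
#' kg of female weight, mean female return weight 2.5 kg, post-spawn (kelt)
#' survival 0.1, and Beverton-Holt egg-to-parr0 recruitment
#' `s_egg * E / (1 + E / K)` with capacity scale `K`. `s_egg` and `s_marine`
#' are the two knobs adjusted by [calibrate_stationarity()]. Escapee
#' spawners get spawning-success multipliers of 0.3 (females) and 0.05
#' (males); precocious parr1 males mature with probability 0.2 and enter the
#' siring lottery (weights proportional to `length^beta_length`) with a 0.05
#' discount. Genotype acts on survival at the parr0 and parr1 stages with
#' the scenario-specific relative survival (`rs` set per [scenario()]), and
#' at the marine stage through the adult locus set with the fixed,
#' scenario-independent `rs_marine = 0.26`: survival is genotype-influenced
#' at each life stage, and relative survival at sea is what ultimately
#' drives selection on the adult gene set. `rs_parr2` and `rs_embryo`
#' default to 1 (neutral).
#'
#' Growth is genotype-dependent as well as survival: domestication selects
#' for fast growth, so size at return scales linearly from the wild
#' phenotype up to `1 + growth_farm_advantage` (default 0.25) for the pure
#' farm genotype. Larger farm-ancestry spawners deposit more eggs and win
#' more sirings, so introgression feeds back on reproduction while survival
#' selects against it.
#'
#' Density regulates survival at more than one freshwater stage: besides the
#' egg-stage Beverton-Holt, parr survival is adjusted for territorial
#' crowding. The adjustment factor `(1 + theta) / (1 + theta * B / B_ref)`
#' (with `theta = parr_dd_strength`, `B` the cohort's expected
#' genotype-survivors and `B_ref` its calibrated equilibrium value) equals 1
#' at equilibrium, releases survivors when cohort-mates die young, and
#' compresses survival in crowded years; `parr_dd_strength = 0` disables it.
#'
#' @param ... Named overrides of any default.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(...) {
  p <- list(
    s_egg = 0.142, K = 60000,
    s_parr0 = 0.55, s_parr1 = 0.65, s_parr2 = 0.75,
    s_marine = 0.2, post_spawn_surv = 0.1,
    smolt_age = 3,
    fecundity = 1500,
    adult_length_mean = 55, adult_length_sd = 5,     # cm
    adult_weight_mean = 2.5, adult_weight_sd = 0.3,  # kg
    repeat_length_gain = 4, repeat_weight_gain = 0.5,
    parr_length = c(parr0 = 5.5, parr1 = 9, parr2 = 12.5, marine = 15),
    growth_farm_advantage = 0.25,
    esc_female_discount = 0.3, esc_male_discount = 0.05,
    p_precocious = 0.2, precocious_discount = 0.05,
    beta_length = 2, sex_ratio = 0.5,
    rs_embryo = 1, rs_parr2 = 1, rs_marine = 0.26,
    parr_dd_strength = 4,
    lambda = 1)
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  probs <- c("s_egg", "s_parr0", "s_parr1", "s_parr2", "s_marine",
             "post_spawn_surv", "p_precocious", "sex_ratio")
  for (nm in probs) {
    if (p[[nm]] < 0 || p[[nm]] > 1) stop(nm, " must lie in [0, 1]")
  }
  if (p$K <= 0) stop("K must be > 0")
  p$effects <- locus_effect_weights(p$lambda)
  structure(p, class = "sim_params")
}

#' The three relative-survival settings
#'
#' Relative survival of the pure farm genotype at the parr0 and parr1
#' stages: `low` = 0.075/0.13, `calculated` = 0.15/0.26 (the field
#' estimates), `high` = 0.3/0.52 (double).
#'
#' @return Named list of length-2 numeric vectors `c(parr0, parr1)`.
#' @export
rs_levels <- function() {
  list(low = c(0.075, 0.13), calculated = c(0.15, 0.26), high = c(0.3, 0.52))
}

#' Invasion scenario
#'
#' @param invasion_years Length of the invasion window in years (10, 50 or
#'   100 in the standard grid; 0 for a pure baseline).
#' @param invaders_per_year Escapee adults entering at spawning time in each
#'   invasion year (0 disables invasion).
#' @param rs Length-2 relative survival of the pure farm genotype at
#'   parr0/parr1 (see [rs_levels()]).
#' @param burn_in Years simulated before the invasion window (default 100).
#' @param post_invasion Years simulated after the window closes (default 100).
#' @return Object of class `sim_scenario`. The invasion window is years
#'   `burn_in + 1` to `burn_in + invasion_years`; total run length is
#'   `burn_in + invasion_years + post_invasion`.
#' @export
scenario <- function(invasion_years = 10, invaders_per_year = 500,
                     rs = rs_levels()$calculated, burn_in = 100,
                     post_invasion = 100) {
  if (invasion_years < 0 || invaders_per_year < 0) {
    stop("invasion_years and invaders_per_year must be >= 0")
  }
  if (length(rs) != 2 || any(rs <= 0)) {
    stop("rs must be two positive values (parr0, parr1)")
  }
  structure(list(invasion_years = as.integer(invasion_years),
                 invaders_per_year = as.integer(invaders_per_year),
                 rs = as.numeric(rs),
                 burn_in = as.integer(burn_in),
                 post_invasion = as.integer(post_invasion)),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "sim_scenario: %d invaders/yr for %d yr (burn-in %d, post %d), RS %.3g/%.3g\n",
    x$invaders_per_year, x$invasion_years, x$burn_in, x$post_invasion,
    x$rs[1], x$rs[2]))
  invisible(x)
}

#' The 27-cell scenario grid
#'
#' Three temporal scenarios (10, 50, 100 invasion years) crossed with three
#' invasion magnitudes (zero, intermediate, high; annual counts chosen so the
#' total number of invaders matches across temporal scenarios: 500x10 =
#' 100x50 = 50x100) and the three relative-survival settings.
#'
#' @return Data frame with one row per cell: `duration`, `magnitude`,
#'   `rs_level`, `invaders_per_year`, `rs0`, `rs1`.
#' @export
grid_cells <- function() {
  inv <- list(`10` = c(zero = 0, intermediate = 500, high = 1000),
              `50` = c(zero = 0, intermediate = 100, high = 200),
              `100` = c(zero = 0, intermediate = 50, high = 100))
  rs <- rs_levels()
  rows <- list()
  for (dur in names(inv)) {
    for (mag in names(inv[[dur]])) {
      for (lv in names(rs)) {
        rows[[length(rows) + 1]] <- data.frame(
          duration = as.integer(dur), magnitude = mag, rs_level = lv,
          invaders_per_year = unname(inv[[dur]][mag]),
          rs0 = rs[[lv]][1], rs1 = rs[[lv]][2], stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$cell <- sprintf("y%s_%s_%s", out$duration, out$magnitude, out$rs_level)
  out
}

#' Write / read a scenario as YAML
#'
#' @param scen A [scenario()].
#' @param path File path.
#' @return `write_scenario_yaml` returns `path` invisibly;
#'   `read_scenario_yaml` returns a [scenario()].
#' @export
write_scenario_yaml <- function(scen, path) {
  stopifnot(inherits(scen, "sim_scenario"))
  yaml::write_yaml(unclass(scen), path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  scenario(invasion_years = x$invasion_years,
           invaders_per_year = x$invaders_per_year,
           rs = unlist(x$rs), burn_in = x$burn_in,
           post_invasion = x$post_invasion)
}
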