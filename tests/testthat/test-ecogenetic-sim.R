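# Individual-based eco-genetic model: locus effects, genotypic values,
# survival, reproduction, recruitment, invasion, annual dynamics.

test_that("locus-effect weights decline exponentially with a neutral marker", {
  for (lam in c(0.25, 1, 3)) {
    w <- locus_effect_weights(lam)$adult
    expect_length(w, 21)
    expect_equal(w[21], 0)
    expect_equal(sum(w), 1)
    expect_true(all(diff(w) < 0))
  }
  # lambda -> 0+ limit of raw_i = exp(-l(i-1)) - exp(-20 l) is
  # proportional to (21 - i): the triangular profile
  w0 <- locus_effect_weights(1e-6)$adult
  tri <- (21 - 1:21) / sum(21 - 1:21)
  expect_equal(w0, tri, tolerance = 1e-4)
  expect_error(locus_effect_weights(0), "positive")
  expect_error(locus_effect_weights(-1), "positive")
})

test_that("genotypic value is the weighted wild-allele dose", {
  eff <- locus_effect_weights(1)
  expect_equal(genotypic_value(rep(2L, 63), "adult", eff), 1)
  expect_equal(genotypic_value(rep(0L, 63), "juvenile", eff), 0)
  expect_equal(genotypic_value(rep(1L, 63), "embryo", eff), 0.5)
  # linearity: a mixed genotype scores between the endpoints
  g <- rep(2L, 63)
  g[43] <- 0L  # strongest adult-set locus to farm/farm
  expect_equal(genotypic_value(g, "adult", eff), 1 - eff$adult[1])
})

test_that("stage survival interpolates between farm and wild endpoints", {
  p <- sim_params()
  rs <- c(0.15, 0.26)
  expect_equal(stage_survival_prob(1, "parr0", p, rs), p$s_parr0)
  expect_equal(stage_survival_prob(0, "parr0", p, rs), 0.15 * p$s_parr0)
  expect_equal(stage_survival_prob(0.5, "parr0", p, rs), 0.575 * p$s_parr0)
  expect_equal(stage_survival_prob(0.5, "parr1", p, rs),
               p$s_parr1 * (0.26 + 0.5 * 0.74))
  # parr2 neutral by default
  expect_equal(stage_survival_prob(0, "parr2", p, rs), p$s_parr2)
})

test_that("recruitment obeys the Beverton-Holt limits", {
  p <- sim_params()
  expect_equal(density_dependent_recruitment(0, p), 0L)
  expect_error(density_dependent_recruitment(-1, p), ">= 0")
  set.seed(2)
  # small-density limit: expectation ~ s_egg * eggs
  small <- mean(replicate(400, density_dependent_recruitment(1000, p)))
  mu_small <- p$s_egg * 1000 / (1 + 1000 / p$K)
  expect_lt(abs(small - mu_small), 3 * sqrt(mu_small / 400))
  # saturation: expectation -> s_egg * K
  big <- mean(replicate(50, density_dependent_recruitment(1e9, p)))
  expect_lt(abs(big - p$s_egg * p$K) / (p$s_egg * p$K), 0.01)
})

test_that("reproduction is Mendelian with sex-specific lotteries", {
  p <- sim_params()
  # wild x wild, all-wild: every offspring fixed wild
  sp <- data.frame(sex = c("F", "M"), origin = "wildborn", weight = 2.5,
                   length = 55, stringsAsFactors = FALSE)
  g2 <- matrix(2L, 2, 63)
  set.seed(1)
  off <- reproduce(sp, g2, p, n_recruits = 50)
  expect_true(all(off$genotypes == 2L))
  # all-wild dam x all-farm escapee sire: obligate heterozygotes, g = 0.5
  sp2 <- data.frame(sex = c("F", "M"), origin = c("wildborn", "escapee"),
                    weight = 2.5, length = 55, stringsAsFactors = FALSE)
  gmix <- rbind(matrix(2L, 1, 63), matrix(0L, 1, 63))
  off2 <- reproduce(sp2, gmix, p, n_recruits = 50)
  expect_true(all(off2$genotypes == 1L))
  expect_equal(genotypic_value(off2$genotypes, "adult", p$effects),
               rep(0.5, 50))
  # no eligible male -> zero offspring
  sp3 <- sp[1, , drop = FALSE]
  off3 <- reproduce(sp3, g2[1, , drop = FALSE], p)
  expect_equal(nrow(off3$genotypes), 0)
})

test_that("escapee females deposit eggs at the configured discount", {
  p <- sim_params()
  sp <- data.frame(sex = c("F", "F", "M"),
                   origin = c("wildborn", "escapee", "wildborn"),
                   weight = 2.5, length = 55, stringsAsFactors = FALSE)
  g <- rbind(matrix(2L, 1, 63), matrix(0L, 1, 63), matrix(2L, 1, 63))
  set.seed(31)
  off <- reproduce(sp, g, p, n_recruits = 6000)
  expect_equal(off$esc_egg_share, 0.3 / 1.3, tolerance = 1e-12)
  p_esc <- mean(off$mother == 2)
  se <- sqrt(p_esc * (1 - p_esc) / 6000)
  expect_lt(abs(p_esc - 0.3 / 1.3), 3 * se + 1e-3)
})

test_that("with selection and discounts off, offspring admixture matches gamete shares", {
  p <- sim_params(esc_female_discount = 1, esc_male_discount = 1,
                  rs_embryo = 1)
  n_w <- 60
  n_e <- 40
  sp <- data.frame(
    sex = rep(c("F", "M"), times = c(n_w + n_e, n_w + n_e)),
    origin = rep(rep(c("wildborn", "escapee"), c(n_w, n_e)), 2),
    weight = 2.5, length = 55, stringsAsFactors = FALSE)
  g <- matrix(2L, nrow(sp), 63)
  g[sp$origin == "escapee", ] <- 0L
  set.seed(77)
  off <- reproduce(sp, g, p, n_recruits = 5000)
  # selection-free oracle: expected farm-allele fraction is the mean of the
  # escapee egg share and the escapee sire share
  expected <- (off$esc_egg_share + off$esc_sire_share) / 2
  expect_equal(expected, 0.4, tolerance = 1e-12)
  observed <- mean(2L - off$genotypes) / 2
  expect_lt(abs(observed - expected), 0.02)
})

test_that("invasion adds escapee adults with balanced sexes inside the window", {
  p <- small_sim_params()
  set.seed(5)
  st <- new_sim_state(p)
  n0 <- sum(st$alive)
  invade(st, 500, p)
  expect_equal(sum(st$alive), n0 + 500)
  esc <- which(st$origin == 2L & st$alive)
  expect_length(esc, 500)
  expect_equal(sum(st$sex[esc] == 1L), 250)
  expect_true(all(st$geno[, esc] == 0L))
  expect_true(all(st$stage[esc] == 5L))
  scen <- scenario(10, 500, rs_levels()$calculated, burn_in = 100)
  expect_error(invade(st, 10, p, year = 50, scen = scen), "window")
  expect_error(invade(st, 10, p, year = 111, scen = scen), "window")
  invisible(invade(st, 10, p, year = 105, scen = scen))
  expect_equal(sum(st$alive), n0 + 510)
})

test_that("identical seeds give identical trajectories", {
  p <- small_sim_params()
  scen <- scenario(5, 100, rs_levels()$calculated, burn_in = 15,
                   post_invasion = 15)
  a <- run_scenario(p, scen, n_replicates = 2, seed = 9)
  b <- run_scenario(p, scen, n_replicates = 2, seed = 9)
  expect_identical(a$yearly, b$yearly)
})

test_that("every head-count change is a logged birth, invasion or death", {
  p <- small_sim_params()
  scen <- scenario(5, 200, rs_levels()$high, burn_in = 20, post_invasion = 20)
  out <- run_scenario(p, scen, n_replicates = 2, seed = 3)
  expect_true(audit_conservation(out))
  # also through the embryo-selection branch
  p2 <- small_sim_params(rs_embryo = 0.8)
  out2 <- run_scenario(p2, scenario(3, 100, rs_levels()$calculated,
                                    burn_in = 10, post_invasion = 10),
                       n_replicates = 1, seed = 4)
  expect_true(audit_conservation(out2))
})

test_that("allele frequencies stay in bounds and fixed-wild stays fixed", {
  p <- small_sim_params()
  out <- run_scenario(p, scenario(0, 0, burn_in = 300, post_invasion = 0),
                      n_replicates = 3, seed = 6)
  f <- out$yearly$mean_allele_freq
  expect_true(all(f >= 0 & f <= 1))
  # no farm alleles ever enter under zero invasion: frequency is exactly 1
  expect_true(all(f == 1))
  inv <- run_scenario(p, scenario(5, 300, rs_levels()$high, burn_in = 20,
                                  post_invasion = 30), 1, seed = 6)
  fi <- inv$yearly$mean_allele_freq
  expect_true(all(fi >= 0 & fi <= 1))
  expect_lt(min(fi), 1)
})

test_that("zero survival drives the population extinct within a life span", {
  p <- small_sim_params()
  pz <- small_sim_params(s_egg = 0, s_parr0 = 0, s_parr1 = 0, s_parr2 = 0,
                         s_marine = 0, post_spawn_surv = 0)
  set.seed(2)
  st <- new_sim_state(p)
  expect_gt(sum(st$alive), 0)
  scen <- scenario(0, 0, burn_in = 6, post_invasion = 0)
  rec <- annual_step(st, pz, scen, 1)
  expect_equal(rec$n_alive, 0)
})

test_that("minimum abundance decreases with invasion pressure", {
  p <- small_sim_params()
  min_ab <- function(rs, invaders) {
    out <- run_scenario(p, scenario(8, invaders, rs, burn_in = 40,
                                    post_invasion = 60), 3, seed = 12)
    mean(vapply(1:3, function(r) {
      y <- out$yearly[out$yearly$replicate == r, ]
      min(y$adults_total[y$year > 40])
    }, numeric(1)))
  }
  none <- min_ab(rs_levels()$high, 0)
  mid <- min_ab(rs_levels()$high, 200)
  high <- min_ab(rs_levels()$high, 400)
  expect_gte(none, mid)
  expect_gte(mid, high)
})

test_that("recovery-time criterion behaves on synthetic step series", {
  mk_out <- function(x, burn_in = 20, invasion_years = 5) {
    structure(list(
      yearly = data.frame(replicate = 1L, year = seq_along(x),
                          adults_total = x, mean_allele_freq = 1,
                          mean_genetic_value = 1),
      scenario = scenario(invasion_years, 100, burn_in = burn_in,
                          post_invasion = length(x) - burn_in - invasion_years),
      seeds = 1L, n_init = 100), class = "sim_output")
  }
  base <- mk_out(rep(100, 80))
  expect_equal(recovery_time(mk_out(rep(100, 80)), base)$recovery_years, 0)
  # permanently depressed: never recovers
  expect_true(is.na(recovery_time(mk_out(rep(60, 80)), base)$recovery_years))
  # step from 60 to 100 at year k: trailing-10 mean crosses 95 once 9 of the
  # 10 window years sit at 100, i.e. at year k + 8
  k <- 40
  x <- c(rep(60, k - 1), rep(100, 80 - k + 1))
  rec <- recovery_time(mk_out(x), base)$recovery_years
  expect_equal(rec, (k + 8) - 25)
})

test_that("calibration rejects unreachable targets quickly", {
  p <- small_sim_params()
  expect_error(calibrate_stationarity(p, target = 1e9), "not reachable")
})

test_that("scenario YAML round-trips", {
  scen <- scenario(50, 200, rs_levels()$high, burn_in = 80)
  path <- tempfile(fileext = ".yaml")
  write_scenario_yaml(scen, path)
  back <- read_scenario_yaml(path)
  expect_equal(back, scen)
  expect_error(scenario(-1, 5), ">= 0")
  expect_error(sim_params(bogus = 1), "unknown parameter")
})
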