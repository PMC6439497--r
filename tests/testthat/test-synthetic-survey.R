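# Baseline panel generation, genotype simulation, survey structure,
# duplicate-genotyping discordance.

test_that("gen_baseline_panel draws divergences in spec and is seed-deterministic", {
  p <- gen_baseline_panel(95, seed = 1)
  d <- abs(p$wild_freq - p$farm_freq)
  expect_length(p$locus_ids, 95)
  expect_true(all(d >= 0.3 - 1e-12 & d <= 0.7 + 1e-12))
  expect_true(all(p$wild_freq >= 0.02 & p$wild_freq <= 0.98))
  p1 <- gen_baseline_panel(10, seed = 7)
  p2 <- gen_baseline_panel(10, seed = 7)
  expect_identical(p1, p2)
  expect_error(gen_baseline_panel(0), "n_loci")
})

test_that("a point-mass divergence of 1 yields fully diagnostic loci", {
  p <- gen_baseline_panel(1, divergence = 1, seed = 0, freq_bounds = c(0, 1))
  expect_true((p$wild_freq == 1 && p$farm_freq == 0) ||
                (p$wild_freq == 0 && p$farm_freq == 1))
})

test_that("simulated genotypes honour class structure on diagnostic panels", {
  pan <- diagnostic_panel(25)
  g_f1 <- simulate_individual("F1", pan, 0, 0, seed = 3)
  expect_true(all(g_f1 == 1L))
  g_w <- simulate_individual("WILD", pan, 0, 0, seed = 3)
  expect_true(all(g_w == 2L))
  g_fer <- simulate_individual("FERAL", pan, 0, 0, seed = 3)
  expect_true(all(g_fer == 0L))
})

test_that("F2 genotype frequencies converge to the Mendelian enumeration oracle", {
  pan <- diagnostic_panel(1)
  set.seed(42)
  g <- simulate_genotypes(rep("F2", 10000), pan, 0, 0)
  obs <- tabulate(g + 1L, nbins = 3) / 10000
  expected <- vapply(0:2, function(k) {
    enum_genotype_prob(class_phi("F2")[1, ], 1, 0, k)
  }, numeric(1))
  expect_equal(expected, c(0.25, 0.5, 0.25))
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_true(all(abs(obs - expected) < 3 * se + 1e-9))
})

test_that("Monte-Carlo genotype frequencies match class probabilities for every class", {
  pan <- baseline_panel("L1", 0.85, 0.25)
  set.seed(7)
  for (cls in GENETIC_CLASSES) {
    g <- simulate_genotypes(rep(cls, 10000), pan, 0, 0)
    obs <- tabulate(g + 1L, nbins = 3) / 10000
    expected <- genotype_class_probability(cls, 0:2, 0.85, 0.25)
    se <- sqrt(expected * (1 - expected) / 10000)
    expect_true(all(abs(obs - expected) < 3 * se + 1e-3),
                label = paste("class", cls))
  }
})

test_that("survey mixtures propagate by class-specific survival", {
  pan <- diagnostic_panel(5)
  rv <- river_config("A", 10, samples_per_age = 400)
  # absorbing zero: feral removed from older age classes
  w0 <- c(WILD = 1, FERAL = 0, F1 = 1, F2 = 1, BCW = 1, BCF = 1)
  sv <- simulate_survey(list(rv), w0, 2014:2016, pan, 0, 0, seed = 5)
  older <- sv$individuals[sv$individuals$length_mm > 70, ]
  expect_true(all(older$true_class != "FERAL"))
  expect_true(any(sv$individuals$true_class == "FERAL"))  # present in YoY
  # determinism
  sv2 <- simulate_survey(list(rv), w0, 2014:2016, pan, 0, 0, seed = 5)
  expect_identical(sv$genotypes, sv2$genotypes)
  # degenerate mixture errors
  wz <- stats::setNames(rep(0, 6), GENETIC_CLASSES)
  expect_error(simulate_survey(list(rv), wz, 2014:2016, pan, 0, 0, seed = 1),
               "degenerated")
})

test_that("neutral survival leaves age-class mixtures within multinomial noise", {
  pan <- diagnostic_panel(2)
  rv <- river_config("A", 10, samples_per_age = 300)
  w1 <- stats::setNames(rep(1, 6), GENETIC_CLASSES)
  mix <- rv$initial_class_mix
  # collapse rare hybrid classes so chi-square expectations stay healthy
  collapse <- function(cls) {
    ifelse(cls %in% c("WILD", "FERAL", "F1"), cls, "OTHER")
  }
  probs <- c(mix[c("WILD", "FERAL", "F1")], OTHER = sum(mix[4:6]))
  pass <- 0L
  n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    sv <- simulate_survey(list(rv), w1, 2014, pan, 0, 0, seed = 1000 + s)
    ok <- TRUE
    for (ac in unique(age_class_from_length(sv$individuals$length_mm))) {
      sub <- sv$individuals[age_class_from_length(sv$individuals$length_mm) == ac, ]
      counts <- table(factor(collapse(sub$true_class),
                             levels = c("WILD", "FERAL", "F1", "OTHER")))
      p <- suppressWarnings(stats::chisq.test(counts, p = probs)$p.value)
      if (p < 0.01) ok <- FALSE
    }
    if (ok) pass <- pass + 1L
  }
  expect_gte(pass / n_seeds, 0.95)
})

test_that("discordance rate follows its definition and the collision oracle", {
  g <- c(0L, 1L, 2L, NA, 2L)
  expect_equal(as.numeric(estimate_discordance(list(list(g, g)))), 0)
  a <- rep(0L, 1000)
  b <- a
  b[1] <- 1L
  expect_equal(as.numeric(estimate_discordance(list(list(a, b)))), 0.001)
  expect_error(estimate_discordance(list(list(NA_integer_, 1L))), "comparable")
  expect_error(estimate_discordance(list()), "pair")
  # analytic collision probability: each replicate call is replaced with a
  # uniform draw from {0,1,2} with probability e, independently
  e <- 0.0017
  q <- 1 - 2 * e / 3
  p_disc <- 1 - q^2 - 2 * (e / 3)^2
  set.seed(11)
  pan <- diagnostic_panel(95)
  n_pairs <- 2000
  pairs <- lapply(seq_len(n_pairs), function(i) {
    truth <- simulate_genotypes("WILD", pan, 0, 0)
    jitter <- function(x) {
      err <- stats::runif(length(x)) < e
      x[err] <- sample(0:2, sum(err), replace = TRUE)
      x
    }
    list(jitter(as.integer(truth)), jitter(as.integer(truth)))
  })
  rate <- as.numeric(estimate_discordance(pairs))
  n_comp <- n_pairs * 95
  se <- sqrt(p_disc * (1 - p_disc) / n_comp)
  expect_lt(abs(rate - p_disc), 3 * se + 1e-6)
})
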