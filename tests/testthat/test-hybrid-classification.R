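# Genotype-frequency-class likelihoods and the Bayes classifier.

test_that("genotype probabilities sum to 1 over a frequency grid, all classes", {
  grid <- expand.grid(p_w = seq(0, 1, 0.1), p_f = seq(0, 1, 0.1))
  for (cls in GENETIC_CLASSES) {
    tot <- genotype_class_probability(cls, 0, grid$p_w, grid$p_f) +
      genotype_class_probability(cls, 1, grid$p_w, grid$p_f) +
      genotype_class_probability(cls, 2, grid$p_w, grid$p_f)
    expect_true(all(abs(tot - 1) < 1e-12), label = cls)
  }
  expect_error(genotype_class_probability("F1", 3, 0.5, 0.5), "g must")
})

test_that("class probabilities match enumeration and hand values", {
  expect_equal(genotype_class_probability("F1", 1, 1, 0), 1)
  expect_equal(genotype_class_probability("F2", 0:2, 1, 0), c(0.25, 0.5, 0.25))
  expect_equal(genotype_class_probability("BCW", 1, 0.9, 0.1), 0.5)
  expect_equal(genotype_class_probability("BCW", 2, 0.9, 0.1), 0.45)
  expect_equal(genotype_class_probability("BCW", 0, 0.9, 0.1), 0.05)
  # random-frequency agreement with the exhaustive enumeration oracle
  set.seed(5)
  for (i in 1:20) {
    pw <- runif(1)
    pf <- runif(1)
    cls <- sample(GENETIC_CLASSES, 1)
    g <- sample(0:2, 1)
    expect_equal(genotype_class_probability(cls, g, pw, pf),
                 enum_genotype_prob(class_phi(cls)[1, ], pw, pf, g),
                 tolerance = 1e-12)
  }
})

test_that("phi values are Mendelian-consistent with gamete enumeration", {
  # F1 gametes carry wild ancestry with probability 1/2; wild gametes always
  expect_equal(unname(class_phi("F2")[1, ]), unname(phi_from_cross(0.5, 0.5)))
  expect_equal(unname(class_phi("BCW")[1, ]), unname(phi_from_cross(0.5, 1)))
  expect_equal(unname(class_phi("BCF")[1, ]), unname(phi_from_cross(0.5, 0)))
  expect_equal(unname(class_phi("F1")[1, ]), unname(phi_from_cross(1, 0)))
  expect_true(all(abs(rowSums(class_phi()) - 1) < 1e-12))
})

test_that("log-likelihood floors impossible genotypes and matches brute force", {
  pan <- diagnostic_panel(10)
  het <- rep(1L, 10)
  expect_equal(class_loglikelihood(het, pan, "F1"), 0)
  expect_equal(class_loglikelihood(het, pan, "WILD"), 10 * log(1e-9))
  expect_error(class_loglikelihood(rep(NA_integer_, 10), pan, "F2"),
               "missing")
  # enumeration oracle on a random 3-locus panel
  set.seed(9)
  pan3 <- gen_baseline_panel(3, seed = 9)
  g <- sample(0:2, 3, TRUE)
  manual <- sum(log(vapply(1:3, function(j) {
    enum_genotype_prob(class_phi("F2")[1, ], pan3$wild_freq[j],
                       pan3$farm_freq[j], g[j])
  }, numeric(1))))
  expect_equal(class_loglikelihood(g, pan3, "F2"), manual, tolerance = 1e-12)
})

test_that("classify resolves diagnostic genotypes and respects the threshold", {
  pan <- diagnostic_panel(20)
  cp <- classify(rep(1L, 20), pan)
  expect_equal(cp$assigned, "F1")
  expect_gt(cp$probs[["F1"]], 0.999)
  expect_equal(sum(cp$probs), 1, tolerance = 1e-9)
  # closed-form posterior for an all-homozygous-reference fish:
  # only WILD (1), BCW (0.5^L) and F2 (0.25^L) have nonzero likelihood
  # before flooring
  L <- 20
  floor_l <- 1e-9^L
  post_wild <- 1 / (1 + 0.5^L + 0.25^L + 3 * floor_l)
  cp2 <- classify(rep(2L, L), pan)
  expect_equal(cp2$assigned, "WILD")
  expect_equal(unname(cp2$probs["WILD"]), post_wild, tolerance = 1e-12)
  # zero information: posterior equals the prior, unassigned at 0.8
  cp3 <- classify(rep(1L, 10), flat_panel(10))
  expect_equal(unname(cp3$probs), rep(1 / 6, 6), tolerance = 1e-12)
  expect_equal(cp3$assigned, "UNASSIGNED")
})

test_that("posterior is invariant to locus order and uninformative loci", {
  set.seed(21)
  pan <- gen_baseline_panel(12, seed = 21)
  g <- simulate_individual("BCW", pan, 0, 0, seed = 3)
  base <- classify(g, pan)$probs
  perm <- sample(12)
  pan_p <- baseline_panel(pan$locus_ids[perm], pan$wild_freq[perm],
                          pan$farm_freq[perm])
  expect_equal(classify(g[perm], pan_p)$probs, base, tolerance = 1e-12)
  # appending loci with p_w == p_f changes nothing
  pan_aug <- baseline_panel(c(pan$locus_ids, "flat"),
                            c(pan$wild_freq, 0.4), c(pan$farm_freq, 0.4))
  expect_equal(classify(c(g, 1L), pan_aug)$probs, base, tolerance = 1e-12)
})

test_that("assign_dataset retains correctly and is monotone in threshold", {
  pan <- diagnostic_panel(15)
  meta <- data.frame(id = as.character(1:100), river = "A", year = 2014L,
                     length_mm = 50L, true_class = "WILD",
                     stringsAsFactors = FALSE)
  g <- simulate_genotypes(meta$true_class, pan, 0, 0)
  ds <- survey_dataset(pan, meta, g,
                       data.frame(river = "A", axial_length = 1))
  a <- assign_dataset(ds)
  expect_equal(attr(a, "n_retained"), 100L)
  expect_true(all(a$assigned == "WILD"))
  # empty dataset
  ds0 <- survey_dataset(pan, meta[0, ], g[0, , drop = FALSE],
                        data.frame(river = "A", axial_length = 1))
  expect_equal(nrow(assign_dataset(ds0)), 0)
  # noisy data: higher threshold can only retain fewer
  pan2 <- gen_baseline_panel(12, seed = 3)
  set.seed(3)
  cls <- sample(GENETIC_CLASSES, 300, TRUE)
  meta2 <- data.frame(id = as.character(1:300), river = "A", year = 2014L,
                      length_mm = 50L, true_class = cls,
                      stringsAsFactors = FALSE)
  ds2 <- survey_dataset(pan2, meta2, simulate_genotypes(cls, pan2),
                        data.frame(river = "A", axial_length = 1))
  r08 <- attr(assign_dataset(ds2, threshold = 0.8), "n_retained")
  r10 <- attr(assign_dataset(ds2, threshold = 1.0), "n_retained")
  expect_lte(r10, r08)
})

test_that("accuracy approaches 1 as diagnostic locus count grows", {
  set.seed(14)
  cls <- rep(GENETIC_CLASSES, each = 60)
  acc <- vapply(c(6, 40), function(L) {
    pan <- diagnostic_panel(L)
    g <- simulate_genotypes(cls, pan, 0, 0)
    ds <- survey_dataset(pan,
                         data.frame(id = seq_along(cls), river = "A",
                                    year = 2014L, length_mm = 50L,
                                    true_class = cls,
                                    stringsAsFactors = FALSE),
                         g, data.frame(river = "A", axial_length = 1))
    a <- assign_dataset(ds)
    ret <- a[a$retained, ]
    mean(ret$assigned == ret$true_class)
  }, numeric(1))
  expect_gt(acc[2], 0.99)
  expect_gte(acc[2], acc[1])
})
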