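# Annual-step individual-based eco-genetic salmon model.
#
# Life cycle: parr0 -> parr1 -> parr2 -> marine (smolt at age 3, one
# sea-winter) -> adult spawner, with post-spawn (kelt) survival allowing
# repeat spawning. Each fish carries three independent sets of 21 unlinked
# diploid loci (embryo / juvenile / adult stage sets); alleles are wild (1)
# or farm (0) and genotypes are stored as per-locus wild-allele counts.
# The genotypic value g in [0, 1] (weighted mean of wild alleles) linearly
# interpolates stage survival between the farm and wild endpoints.
#
# State is a preallocated pool held in an environment: death flips a flag,
# birth fills a free slot, so the genotype matrix is never copied during a
# run; offspring genotypes are drawn by the C++ Mendelian kernel.

.EMB <- 1:21
.JUV <- 22:42
.AD <- 43:63
.N_GLOCI <- 63L
# stage codes
.PARR0 <- 1L; .PARR1 <- 2L; .PARR2 <- 3L; .MARINE <- 4L; .ADULT <- 5L
# sex / origin codes
.FEMALE <- 1L; .MALE <- 2L; .WILDBORN <- 1L; .ESCAPEE <- 2L

.state_new <- function(capacity) {
  e <- new.env(parent = emptyenv())
  e$capacity <- as.integer(capacity)
  e$alive <- logical(capacity)
  e$stage <- integer(capacity)
  e$age <- integer(capacity)
  e$sex <- integer(capacity)
  e$origin <- integer(capacity)
  e$len <- numeric(capacity)
  e$wt <- numeric(capacity)
  e$prec <- logical(capacity)
  # locus x individual: each fish's genotype is one contiguous column
  e$geno <- matrix(0L, .N_GLOCI, capacity)
  e$free <- seq_len(capacity)
  class(e) <- "sim_state"
  e
}

.state_grow <- function(e) {
  add <- e$capacity
  e$alive <- c(e$alive, logical(add))
  e$stage <- c(e$stage, integer(add))
  e$age <- c(e$age, integer(add))
  e$sex <- c(e$sex, integer(add))
  e$origin <- c(e$origin, integer(add))
  e$len <- c(e$len, numeric(add))
  e$wt <- c(e$wt, numeric(add))
  e$prec <- c(e$prec, logical(add))
  e$geno <- cbind(e$geno, matrix(0L, .N_GLOCI, add))
  e$free <- c(e$free, e$capacity + seq_len(add))
  e$capacity <- e$capacity + add
  invisible(e)
}

.state_insert <- function(e, n, stage, age, sex, origin, len, wt,
                          geno_fill = NA_integer_) {
  if (n == 0L) return(integer(0))
  while (length(e$free) < n) .state_grow(e)
  idx <- e$free[seq_len(n)]
  e$free <- e$free[-seq_len(n)]
  e$alive[idx] <- TRUE
  e$stage[idx] <- stage
  e$age[idx] <- age
  e$sex[idx] <- sex
  e$origin[idx] <- origin
  e$len[idx] <- len
  e$wt[idx] <- wt
  e$prec[idx] <- FALSE
  if (!is.na(geno_fill)) e$geno[, idx] <- geno_fill
  idx
}

.state_kill <- function(e, idx) {
  if (!length(idx)) return(invisible(e))
  e$alive[idx] <- FALSE
  e$free <- c(e$free, idx)
  invisible(e)
}

#' @export
print.sim_state <- function(x, ...) {
  st <- x$stage[x$alive]
  cat("sim_state:", sum(x$alive), "individuals alive",
      sprintf("(parr0 %d, parr1 %d, parr2 %d, marine %d, adults %d)\n",
              sum(st == .PARR0), sum(st == .PARR1), sum(st == .PARR2),
              sum(st == .MARINE), sum(st == .ADULT)))
  invisible(x)
}

#' Genotypic value of one stage set
#'
#' Weighted mean wild-allele dose over the 21 loci of a stage set:
#' `g = sum_i w_i * (count_i / 2)`, so an all-wild homozygote scores 1, an
#' all-farm homozygote 0 and a full heterozygote 0.5.
#'
#' @param genotype Integer vector of length 63 or matrix with 63 columns
#'   (three sets of 21 wild-allele counts: embryo, juvenile, adult).
#' @param set Which stage set to score.
#' @param effects Locus-effect weights from [locus_effect_weights()].
#' @return Numeric genotypic value(s) in `[0, 1]`.
#' @export
genotypic_value <- function(genotype, set = c("embryo", "juvenile", "adult"),
                            effects = locus_effect_weights()) {
  set <- match.arg(set)
  cols <- switch(set, embryo = .EMB, juvenile = .JUV, adult = .AD)
  w <- effects[[set]]
  if (is.matrix(genotype)) {
    as.numeric(genotype[, cols, drop = FALSE] %*% w) / 2
  } else {
    sum(genotype[cols] * w) / 2
  }
}

#' Stage-specific survival probability
#'
#' Annual survival at the freshwater and marine stages. At parr0 and parr1
#' the probability interpolates linearly between the farm endpoint
#' (`rs * s_stage`) and the wild endpoint (`s_stage`) through the juvenile
#' genotypic value: `p = s_stage * (rs + g * (1 - rs))`. parr2 and marine
#' survival are genotype-neutral unless `rs_parr2` / `rs_marine` are set
#' below 1 in the parameters. Probabilities are clipped to `[0, 1]`.
#'
#' @param g Genotypic value(s) of the relevant stage set.
#' @param stage One of `"parr0"`, `"parr1"`, `"parr2"`, `"marine"`.
#' @param params [sim_params()].
#' @param rs Length-2 relative survival of the pure farm genotype at
#'   parr0/parr1 (the scenario's setting).
#' @return Survival probability vector.
#' @export
stage_survival_prob <- function(g, stage = c("parr0", "parr1", "parr2",
                                             "marine"),
                                params = sim_params(), rs = c(1, 1)) {
  stage <- match.arg(stage)
  p <- switch(stage,
    parr0 = params$s_parr0 * (rs[1] + g * (1 - rs[1])),
    parr1 = params$s_parr1 * (rs[2] + g * (1 - rs[2])),
    parr2 = params$s_parr2 * (params$rs_parr2 + g * (1 - params$rs_parr2)),
    marine = params$s_marine * (params$rs_marine + g * (1 - params$rs_marine)))
  pmin(1, pmax(0, p))
}

#' Beverton-Holt egg-to-recruit draw
#'
#' Expected parr0 recruits from `n_eggs` deposited eggs are
#' `s_egg * n_eggs / (1 + n_eggs / K)`; the realised count is a Poisson
#' draw around that expectation.
#'
#' @param n_eggs Non-negative egg count.
#' @param params [sim_params()].
#' @return Integer recruit count.
#' @export
density_dependent_recruitment <- function(n_eggs, params = sim_params()) {
  if (n_eggs < 0) stop("n_eggs must be >= 0")
  if (n_eggs == 0) return(0L)
  mu <- params$s_egg * n_eggs / (1 + n_eggs / params$K)
  as.integer(stats::rpois(1, mu))
}

#' Sex-specific spawning with escapee discounts
#'
#' Egg deposition per female is `fecundity * weight`, multiplied by the
#' escapee female discount for escapee spawners. Each recruit's dam is drawn
#' with probability proportional to her egg deposition; its sire is drawn
#' from the eligible males (anadromous plus precocious parr) with
#' probability proportional to `length^beta_length`, with escapee males and
#' precocious parr further discounted. Offspring genotypes are Mendelian
#' draws per unlinked locus; offspring are wild-born regardless of
#' parentage. If `rs_embryo < 1`, each offspring is additionally retained
#' with probability `rs_embryo + g_embryo * (1 - rs_embryo)`.
#'
#' @param spawners Data frame with columns `sex` (`"F"`/`"M"`), `origin`
#'   (`"wildborn"`/`"escapee"`), `weight` (kg), `length` (cm) and optionally
#'   `precocious` (logical, for parr males).
#' @param geno Integer genotype matrix (63 columns), rows aligned with
#'   `spawners`.
#' @param params [sim_params()].
#' @param n_recruits Optional recruit count; by default drawn via
#'   [density_dependent_recruitment()] from the total egg deposition.
#' @return List with `genotypes` (recruits x 63), `sex`, `mother`, `father`
#'   (row indices into `spawners`), `n_eggs`, `esc_egg_share`,
#'   `esc_sire_share`. Zero recruits when either parental pool is empty.
#' @export
reproduce <- function(spawners, geno, params = sim_params(),
                      n_recruits = NULL) {
  stopifnot(nrow(spawners) == nrow(geno), ncol(geno) == .N_GLOCI)
  prec <- if (is.null(spawners$precocious)) {
    rep(FALSE, nrow(spawners))
  } else {
    spawners$precocious
  }
  fem <- which(spawners$sex == "F")
  mal <- which(spawners$sex == "M")
  empty <- list(genotypes = matrix(0L, 0, .N_GLOCI), sex = integer(0),
                mother = integer(0), father = integer(0), n_eggs = 0,
                esc_egg_share = NA_real_, esc_sire_share = NA_real_)
  if (!length(fem) || !length(mal)) return(empty)
  esc_f <- spawners$origin[fem] == "escapee"
  eggs <- params$fecundity * spawners$weight[fem] *
    ifelse(esc_f, params$esc_female_discount, 1)
  E <- sum(eggs)
  if (is.null(n_recruits)) n_recruits <- density_dependent_recruitment(E, params)
  esc_m <- spawners$origin[mal] == "escapee"
  swt <- spawners$length[mal]^params$beta_length *
    ifelse(esc_m, params$esc_male_discount, 1) *
    ifelse(prec[mal], params$precocious_discount, 1)
  shares <- list(egg = sum(eggs[esc_f]) / E,
                 sire = sum(swt[esc_m]) / sum(swt))
  if (n_recruits == 0) {
    empty$n_eggs <- E
    empty$esc_egg_share <- shares$egg
    empty$esc_sire_share <- shares$sire
    return(empty)
  }
  mothers <- fem[sample.int(length(fem), n_recruits, TRUE, prob = eggs)]
  fathers <- mal[sample.int(length(mal), n_recruits, TRUE, prob = swt)]
  off <- t(cross_genotypes(t(geno), mothers, fathers))
  if (params$rs_embryo < 1) {
    g_emb <- genotypic_value(off, "embryo", params$effects)
    keep <- stats::runif(nrow(off)) <
      params$rs_embryo + g_emb * (1 - params$rs_embryo)
    off <- off[keep, , drop = FALSE]
    mothers <- mothers[keep]
    fathers <- fathers[keep]
  }
  n <- nrow(off)
  list(genotypes = off,
       sex = ifelse(stats::runif(n) < params$sex_ratio, .FEMALE, .MALE),
       mother = mothers, father = fathers, n_eggs = E,
       esc_egg_share = shares$egg, esc_sire_share = shares$sire)
}

#' Add escapee adults to the population
#'
#' Escapees enter as adult spawners with an all-farm genotype at all three
#' stage sets, a 1:1 (rounded) sex ratio, and sizes drawn from the adult
#' size distribution.
#'
#' @param state A `sim_state`.
#' @param n_invaders Number of escapees (>= 0).
#' @param params [sim_params()].
#' @param year,scen Optional: when both are given the call errors if `year`
#'   lies outside the scenario's invasion window.
#' @return The state, invisibly (modified in place).
#' @export
invade <- function(state, n_invaders, params = sim_params(), year = NULL,
                   scen = NULL) {
  if (n_invaders < 0) stop("n_invaders must be >= 0")
  if (!is.null(year) && !is.null(scen)) {
    lo <- scen$burn_in + 1L
    hi <- scen$burn_in + scen$invasion_years
    if (year < lo || year > hi) {
      stop("invasion requested in year ", year,
           " outside the invasion window [", lo, ", ", hi, "]")
    }
  }
  if (n_invaders == 0) return(invisible(state))
  n_f <- round(n_invaders / 2)
  n_m <- n_invaders - n_f
  sex <- c(rep(.FEMALE, n_f), rep(.MALE, n_m))
  size_f <- 1 + params$growth_farm_advantage  # all-farm genotype, g = 0
  len <- pmax(30, stats::rnorm(n_invaders, params$adult_length_mean,
                               params$adult_length_sd)) * size_f
  wt <- pmax(0.5, stats::rnorm(n_invaders, params$adult_weight_mean,
                               params$adult_weight_sd)) * size_f
  .state_insert(state, n_invaders, .ADULT, 5L, sex, .ESCAPEE, len, wt,
                geno_fill = 0L)
  invisible(state)
}

.dd_reference <- function(params) {
  if (params$parr_dd_strength <= 0) return(c(1, 1))
  eq <- .expected_equilibrium(params)
  pmax(c(eq$recruits * params$s_parr0, eq$parr1 * params$s_parr1), 1e-9)
}

# Deterministic equilibrium of the expected (mean-field) dynamics; used to
# seed the initial age structure and as the calibration starting point.
.expected_equilibrium <- function(params) {
  sp <- params$s_parr0 * params$s_parr1 * params$s_parr2
  A <- 100
  for (i in 1:500) {
    E <- A * params$sex_ratio * params$adult_weight_mean * params$fecundity
    R0 <- params$s_egg * E / (1 + E / params$K)
    A_new <- R0 * sp * params$s_marine + params$post_spawn_surv * A
    if (abs(A_new - A) < 1e-8) break
    A <- A_new
  }
  E <- A * params$sex_ratio * params$adult_weight_mean * params$fecundity
  R0 <- params$s_egg * E / (1 + E / params$K)
  list(adults = A, recruits = R0,
       parr1 = R0 * params$s_parr0,
       parr2 = R0 * params$s_parr0 * params$s_parr1,
       marine = R0 * sp)
}

#' Initialise a population at the deterministic equilibrium age structure
#'
#' All founders carry the all-wild genotype; cohort sizes follow the
#' expected equilibrium of the parameter set, so a burn-in only has to
#' absorb demographic stochasticity, not a transient.
#'
#' @param params [sim_params()].
#' @param capacity Optional pool capacity (grown automatically if exceeded).
#' @return A `sim_state`.
#' @export
new_sim_state <- function(params = sim_params(), capacity = NULL) {
  eq <- .expected_equilibrium(params)
  sizes <- c(round(eq$recruits), round(eq$parr1), round(eq$parr2),
             round(eq$marine), round(eq$adults))
  if (is.null(capacity)) capacity <- max(2L * sum(sizes) + 20000L, 40000L)
  e <- .state_new(capacity)
  stages <- c(.PARR0, .PARR1, .PARR2, .MARINE, .ADULT)
  ages <- c(0L, 1L, 2L, 3L, 4L)
  pl <- params$parr_length
  lens <- c(pl[["parr0"]], pl[["parr1"]], pl[["parr2"]], pl[["marine"]], NA)
  for (k in seq_along(sizes)) {
    n <- sizes[k]
    if (n == 0) next
    sex <- ifelse(stats::runif(n) < params$sex_ratio, .FEMALE, .MALE)
    if (stages[k] == .ADULT) {
      len <- pmax(30, stats::rnorm(n, params$adult_length_mean,
                                   params$adult_length_sd))
      wt <- pmax(0.5, stats::rnorm(n, params$adult_weight_mean,
                                   params$adult_weight_sd))
    } else {
      len <- pmax(2, stats::rnorm(n, lens[k], 0.5))
      wt <- 0.05
    }
    .state_insert(e, n, stages[k], ages[k], sex, .WILDBORN, len, wt,
                  geno_fill = 2L)
  }
  e
}

#' One simulated year
#'
#' Fixed event order: (1) stage survival draws (parr0, parr1, parr2,
#' marine), with the parr draws adjusted for territorial crowding (see
#' [sim_params()]); (2) ageing and stage transitions (smolting, maturation to adult
#' after the sea winter); (3) growth; (4) invasion pulse if the year lies in
#' the scenario's invasion window; (5) precocious-maturation draws among
#' parr1 males; (6) spawning and Beverton-Holt recruitment; (7) post-spawn
#' survival of spawners; (8) output record.
#'
#' @param state A `sim_state` (modified in place).
#' @param params [sim_params()].
#' @param scen A [scenario()].
#' @param year Year index (1-based from the start of the burn-in).
#' @return Invisibly, a one-row list of the year's record: adult counts
#'   (total / wild-born / escapees), mean adult-set wild-allele frequency
#'   among adults, and the bookkeeping columns (births, deaths, invaders,
#'   eggs, escapee egg/sire shares, end-of-year head count).
#' @export
annual_step <- function(state, params, scen, year) {
  rs <- scen$rs
  juv_w <- params$effects$juvenile
  deaths <- 0L

  # territorial-crowding reference: expected equilibrium genotype-survivors
  theta <- params$parr_dd_strength
  dd_ref <- attr(params, "dd_ref")
  if (is.null(dd_ref)) dd_ref <- .dd_reference(params)

  # 1) stage survival
  alive_idx <- which(state$alive)
  st <- state$stage[alive_idx]
  for (blk in list(list(code = .PARR0, stage = "parr0"),
                   list(code = .PARR1, stage = "parr1"),
                   list(code = .PARR2, stage = "parr2"),
                   list(code = .MARINE, stage = "marine"))) {
    i <- alive_idx[st == blk$code]
    if (!length(i)) next
    needs_g <- blk$code %in% c(.PARR0, .PARR1) ||
      (blk$code == .PARR2 && params$rs_parr2 < 1) ||
      (blk$code == .MARINE && params$rs_marine < 1)
    g <- if (needs_g) {
      if (blk$code == .MARINE) {
        as.numeric(params$effects$adult %*%
                     state$geno[.AD, i, drop = FALSE]) / 2
      } else {
        as.numeric(juv_w %*% state$geno[.JUV, i, drop = FALSE]) / 2
      }
    } else {
      1
    }
    p <- stage_survival_prob(g, blk$stage, params, rs)
    if (theta > 0 && blk$code %in% c(.PARR0, .PARR1)) {
      k <- if (blk$code == .PARR0) 1L else 2L
      crowd <- (1 + theta) / (1 + theta * sum(p) / dd_ref[k])
      p <- pmin(1, p * crowd)
    }
    dead <- i[stats::runif(length(i)) >= p]
    deaths <- deaths + length(dead)
    .state_kill(state, dead)
  }

  # 2) ageing and transitions
  alive_idx <- which(state$alive)
  state$age[alive_idx] <- state$age[alive_idx] + 1L
  st <- state$stage[alive_idx]
  new_adult <- alive_idx[st == .MARINE]
  state$stage[alive_idx[st == .PARR2]] <- .MARINE
  state$stage[new_adult] <- .ADULT
  state$stage[alive_idx[st == .PARR1]] <- .PARR2
  state$stage[alive_idx[st == .PARR0]] <- .PARR1

  # 3) growth
  pl <- params$parr_length
  stg_new <- state$stage[alive_idx]
  for (tr in list(list(code = .PARR1, len = pl[["parr1"]]),
                  list(code = .PARR2, len = pl[["parr2"]]),
                  list(code = .MARINE, len = pl[["marine"]]))) {
    i <- alive_idx[stg_new == tr$code]
    if (length(i)) state$len[i] <- pmax(2, stats::rnorm(length(i), tr$len, 0.5))
  }
  if (length(new_adult)) {
    # farm genotype grows faster: size scales with 1 + adv * (1 - g_adult)
    size_f <- 1 + params$growth_farm_advantage *
      (1 - as.numeric(params$effects$adult %*%
                        state$geno[.AD, new_adult, drop = FALSE]) / 2)
    state$len[new_adult] <- pmax(30, stats::rnorm(length(new_adult),
                                                  params$adult_length_mean,
                                                  params$adult_length_sd)) *
      size_f
    state$wt[new_adult] <- pmax(0.5, stats::rnorm(length(new_adult),
                                                  params$adult_weight_mean,
                                                  params$adult_weight_sd)) *
      size_f
  }
  repeat_ad <- alive_idx[st == .ADULT]
  if (length(repeat_ad)) {
    state$len[repeat_ad] <- state$len[repeat_ad] + params$repeat_length_gain
    state$wt[repeat_ad] <- state$wt[repeat_ad] + params$repeat_weight_gain
  }

  # 4) invasion pulse
  invaders <- 0L
  if (scen$invaders_per_year > 0 && year > scen$burn_in &&
      year <= scen$burn_in + scen$invasion_years) {
    invade(state, scen$invaders_per_year, params, year = year, scen = scen)
    invaders <- scen$invaders_per_year
  }

  # 5) precocious maturation among parr1 males
  alive2 <- which(state$alive)
  stg2 <- state$stage[alive2]
  p1m <- alive2[stg2 == .PARR1 & state$sex[alive2] == .MALE]
  prec_m <- if (length(p1m) && params$p_precocious > 0) {
    p1m[stats::runif(length(p1m)) < params$p_precocious]
  } else {
    integer(0)
  }
  state$prec[prec_m] <- TRUE

  # 6) spawning
  ad <- alive2[stg2 == .ADULT]
  fem <- ad[state$sex[ad] == .FEMALE]
  mal <- ad[state$sex[ad] == .MALE]
  births <- 0L
  n_eggs <- 0
  esc_egg_share <- NA_real_
  esc_sire_share <- NA_real_
  if (length(fem) && (length(mal) + length(prec_m))) {
    esc_f <- state$origin[fem] == .ESCAPEE
    eggs <- params$fecundity * state$wt[fem] *
      ifelse(esc_f, params$esc_female_discount, 1)
    n_eggs <- sum(eggs)
    esc_egg_share <- sum(eggs[esc_f]) / n_eggs
    sires <- c(mal, prec_m)
    swt <- state$len[sires]^params$beta_length
    swt <- swt * ifelse(state$origin[sires] == .ESCAPEE,
                        params$esc_male_discount, 1)
    if (length(prec_m)) {
      swt[seq.int(length(mal) + 1L, length(sires))] <-
        swt[seq.int(length(mal) + 1L, length(sires))] *
        params$precocious_discount
    }
    esc_sire_share <- sum(swt[state$origin[sires] == .ESCAPEE]) / sum(swt)
    n_rec <- density_dependent_recruitment(n_eggs, params)
    if (n_rec > 0) {
      mothers <- fem[sample.int(length(fem), n_rec, TRUE, prob = eggs)]
      fathers <- sires[sample.int(length(sires), n_rec, TRUE, prob = swt)]
      if (params$rs_embryo < 1) {
        off <- cross_genotypes(state$geno, mothers, fathers)  # locus x kid
        g_emb <- as.numeric(params$effects$embryo %*%
                              off[.EMB, , drop = FALSE]) / 2
        keep <- stats::runif(n_rec) <
          params$rs_embryo + g_emb * (1 - params$rs_embryo)
        off <- off[, keep, drop = FALSE]
        n_rec <- ncol(off)
        if (n_rec > 0) {
          sex <- ifelse(stats::runif(n_rec) < params$sex_ratio, .FEMALE, .MALE)
          idx <- .state_insert(state, n_rec, .PARR0, 0L, sex, .WILDBORN,
                               pl[["parr0"]], 0.05)
          state$geno[, idx] <- off
          births <- n_rec
        }
      } else {
        sex <- ifelse(stats::runif(n_rec) < params$sex_ratio, .FEMALE, .MALE)
        idx <- .state_insert(state, n_rec, .PARR0, 0L, sex, .WILDBORN,
                             pl[["parr0"]], 0.05)
        cross_genotypes_into(state$geno, mothers, fathers, idx)
        births <- n_rec
      }
    }
  }

  # 8) record (adult metrics captured at spawning time)
  adults_total <- length(ad)
  escapees <- sum(state$origin[ad] == .ESCAPEE)
  if (adults_total) {
    ad_geno <- state$geno[.AD, ad, drop = FALSE]
    freq <- mean(ad_geno) / 2
    gval <- mean(as.numeric(params$effects$adult %*% ad_geno)) / 2
  } else {
    freq <- NA_real_
    gval <- NA_real_
  }

  # 7) post-spawn survival of spawners
  if (length(ad)) {
    dead <- ad[stats::runif(length(ad)) >= params$post_spawn_surv]
    deaths <- deaths + length(dead)
    .state_kill(state, dead)
  }
  state$prec[prec_m] <- FALSE  # a single freshwater spawning season

  invisible(list(year = year, adults_total = adults_total,
                 adults_wildborn = adults_total - escapees,
                 escapees = escapees, mean_allele_freq = freq,
                 mean_genetic_value = gval,
                 births = births, deaths = deaths, invaders = invaders,
                 n_eggs = n_eggs, esc_egg_share = esc_egg_share,
                 esc_sire_share = esc_sire_share,
                 n_alive = sum(state$alive)))
}

#' Run one invasion scenario
#'
#' Runs burn-in, invasion window and recovery phases for `n_replicates`
#' independent replicates and collects the yearly records.
#'
#' @param params [sim_params()].
#' @param scen A [scenario()].
#' @param n_replicates Number of replicate runs (default 1).
#' @param seed Integer seed; replicate `r` uses `seed + r - 1`, so two
#'   scenarios run with the same `seed` are replicate-paired.
#' @return Object of class `sim_output`: list with `yearly` (data frame of
#'   per-replicate, per-year records), `scenario`, `seeds` and `n_init`
#'   (named vector of initial head counts per replicate).
#' @export
run_scenario <- function(params, scen, n_replicates = 1, seed = 1) {
  total <- scen$burn_in + scen$invasion_years + scen$post_invasion
  attr(params, "dd_ref") <- .dd_reference(params)
  seeds <- seed + seq_len(n_replicates) - 1L
  out <- vector("list", n_replicates)
  n_init <- integer(n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(seeds[r])
    state <- new_sim_state(params)
    n_init[r] <- sum(state$alive)
    rows <- vector("list", total)
    for (y in seq_len(total)) {
      rows[[y]] <- annual_step(state, params, scen, y)
    }
    df <- do.call(rbind, lapply(rows, function(x) as.data.frame(x)))
    df$replicate <- r
    out[[r]] <- df
  }
  yearly <- do.call(rbind, out)
  structure(list(yearly = yearly, scenario = scen, seeds = seeds,
                 n_init = n_init),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  y <- x$yearly
  cat(sprintf(
    "sim_output: %d replicate(s) x %d years; invasion %d/yr for %d yr\n",
    length(x$seeds), max(y$year), x$scenario$invaders_per_year,
    x$scenario$invasion_years))
  last <- y[y$year > max(y$year) - 50, ]
  cat(sprintf("  mean adults over final 50 yr: %.1f; final allele freq %.3f\n",
              mean(last$adults_total), mean(last$mean_allele_freq)))
  invisible(x)
}

#' Head-count conservation audit
#'
#' Checks that every change in the yearly head count is accounted for by the
#' logged births, invaders and deaths:
#' `n_alive(t) = n_alive(t-1) + births(t) + invaders(t) - deaths(t)`.
#'
#' @param output A [run_scenario()] result.
#' @return `TRUE` if the identity holds in every replicate and year;
#'   otherwise `FALSE` with attribute `max_discrepancy`.
#' @export
audit_conservation <- function(output) {
  ok <- TRUE
  worst <- 0
  for (r in unique(output$yearly$replicate)) {
    y <- output$yearly[output$yearly$replicate == r, ]
    y <- y[order(y$year), ]
    n_prev <- c(output$n_init[r], y$n_alive[-nrow(y)])
    d <- y$n_alive - (n_prev + y$births + y$invaders - y$deaths)
    worst <- max(worst, max(abs(d)))
    if (any(d != 0)) ok <- FALSE
  }
  structure(ok, max_discrepancy = worst)
}

#' Run the full 27-cell scenario grid
#'
#' Three invasion durations x three magnitudes (including zero) x three
#' relative-survival settings; see [grid_cells()]. All cells share the same
#' replicate seeds, so cells differing only in invasion magnitude are
#' replicate-paired with their zero-invasion baseline.
#'
#' @param params Calibrated [sim_params()].
#' @param n_replicates Replicates per cell (default 5).
#' @param seed Base seed shared across cells.
#' @return Object of class `scenario_grid`: list with `cells` (the
#'   [grid_cells()] table) and `outputs` (named list of [run_scenario()]
#'   results).
#' @export
scenario_grid <- function(params, n_replicates = 5, seed = 1) {
  cells <- grid_cells()
  outputs <- vector("list", nrow(cells))
  names(outputs) <- cells$cell
  for (k in seq_len(nrow(cells))) {
    scen <- scenario(invasion_years = cells$duration[k],
                     invaders_per_year = cells$invaders_per_year[k],
                     rs = c(cells$rs0[k], cells$rs1[k]))
    outputs[[k]] <- run_scenario(params, scen, n_replicates, seed)
  }
  structure(list(cells = cells, outputs = outputs,
                 n_replicates = n_replicates, seed = seed),
            class = "scenario_grid")
}

# Trailing-mean recovery on one series. Returns years since invasion end,
# or NA if the criterion is never sustained inside the window.
.recovery_series <- function(x, years, base_mean, invasion_end, frac = 0.95,
                             window = 10L, sustain = 10L) {
  ord <- order(years)
  x <- x[ord]
  years <- years[ord]
  tm <- stats::filter(x, rep(1 / window, window), sides = 1)
  met <- !is.na(tm) & tm >= frac * base_mean
  eligible <- which(years >= invasion_end)
  for (t in eligible) {
    if (t + sustain - 1L > length(met)) break
    if (all(met[t:(t + sustain - 1L)])) return(years[t] - invasion_end)
  }
  NA_real_
}

#' Average replicate trajectories into one series
#'
#' Pools a multi-replicate [run_scenario()] output into a single
#' across-replicate mean trajectory (one pseudo-replicate), the smoothed
#' trend on which recovery is naturally read — the analogue of judging
#' recovery from a loess curve over replicate runs rather than from each
#' noisy replicate separately.
#'
#' @param output A [run_scenario()] result.
#' @return A `sim_output` with a single averaged replicate.
#' @export
pool_replicates <- function(output) {
  y <- output$yearly
  num <- c("adults_total", "adults_wildborn", "escapees", "mean_allele_freq",
           "mean_genetic_value", "births", "deaths", "invaders", "n_eggs",
           "n_alive")
  agg <- stats::aggregate(y[num], list(year = y$year), mean, na.rm = TRUE)
  agg <- agg[order(agg$year), ]
  agg$replicate <- 1L
  structure(list(yearly = agg, scenario = output$scenario,
                 seeds = output$seeds[1], n_init = mean(output$n_init)),
            class = "sim_output")
}

#' Time to recovery relative to a zero-invasion baseline
#'
#' A replicate has recovered in the first post-invasion year at which the
#' `window`-year trailing mean of the metric reaches `frac` of the paired
#' baseline replicate's long-run mean (its mean over all post-burn-in
#' years), sustained for `sustain` consecutive years. Replicates that never
#' meet the criterion within the simulated window are reported as `NA`
#' (not recovered).
#'
#' @param output [run_scenario()] result for the invasion scenario.
#' @param baseline_output Paired zero-invasion [run_scenario()] result with
#'   the same time axis and seeds.
#' @param metric `"abundance"` (total adults), `"allele_freq"` (unweighted
#'   mean adult-set wild-allele frequency) or `"genetic_value"`
#'   (effect-weighted mean adult-set genotypic value, the sum of the
#'   genetic effects).
#' @param frac Recovery fraction of the baseline mean (default 0.95).
#' @param window Trailing-mean window in years (default 10).
#' @param sustain Years the criterion must hold (default 10).
#' @return Data frame with one row per replicate: `replicate`,
#'   `recovery_years` (years since the end of invasion; `NA` = not
#'   recovered), `recovered`.
#' @export
recovery_time <- function(output, baseline_output,
                          metric = c("abundance", "allele_freq",
                                     "genetic_value"),
                          frac = 0.95, window = 10L, sustain = 10L) {
  metric <- match.arg(metric)
  col <- switch(metric, abundance = "adults_total",
                allele_freq = "mean_allele_freq",
                genetic_value = "mean_genetic_value")
  scen <- output$scenario
  invasion_end <- scen$burn_in + scen$invasion_years
  reps <- sort(unique(output$yearly$replicate))
  res <- vapply(reps, function(r) {
    y <- output$yearly[output$yearly$replicate == r, ]
    b <- baseline_output$yearly[baseline_output$yearly$replicate == r, ]
    base_mean <- mean(b[[col]][b$year > baseline_output$scenario$burn_in],
                      na.rm = TRUE)
    .recovery_series(y[[col]], y$year, base_mean, invasion_end, frac,
                     window, sustain)
  }, numeric(1))
  data.frame(replicate = reps, recovery_years = res, recovered = !is.na(res))
}

#' Calibrate wild survival for a stationary zero-invasion population
#'
#' Adjusts the two overall wild-survival knobs (`s_egg`, and if necessary
#' `s_marine`) so the mean adult abundance over the final `last` of `years`
#' zero-invasion years matches `target` within `tolerance`, averaged over
#' `n_replicates` replicates. A closed-form equilibrium solve gives the
#' starting value of `s_egg`; a short stochastic bisection then refines it.
#'
#' @param params [sim_params()] to calibrate.
#' @param target Target mean adult abundance (default 475).
#' @param tolerance Relative tolerance (default 0.1).
#' @param n_replicates Replicates per evaluation (default 5).
#' @param years,last Evaluation horizon and averaging window (200 / 50).
#' @param seed Seed for the evaluation runs.
#' @param max_iter Maximum bisection evaluations (default 6).
#' @return Calibrated [sim_params()] with an `attr(, "calibration")` data
#'   frame of the evaluations. Errors with diagnostics if the target is not
#'   reachable within the parameter bounds.
#' @export
calibrate_stationarity <- function(params, target = 475, tolerance = 0.1,
                                   n_replicates = 5, years = 200, last = 50,
                                   seed = 1, max_iter = 6) {
  if (target <= 0) stop("target must be > 0")
  sp <- params$s_parr0 * params$s_parr1 * params$s_parr2
  solve_s_egg <- function(p) {
    E <- target * p$sex_ratio * p$adult_weight_mean * p$fecundity
    R0 <- target * (1 - p$post_spawn_surv) / (sp * p$s_marine)
    R0 * (1 + E / p$K) / E
  }
  for (attempt in 1:3) {
    s_egg <- solve_s_egg(params)
    if (s_egg <= 0.95) break
    params$s_marine <- min(0.9, params$s_marine * 2)
  }
  if (s_egg > 0.95) {
    stop("target abundance ", target, " not reachable: required s_egg ",
         signif(s_egg, 3), " exceeds bounds even at s_marine = ",
         params$s_marine)
  }
  evaluate <- function(se, eval_seed) {
    p <- params
    p$s_egg <- se
    out <- run_scenario(p, scenario(invasion_years = 0,
                                    invaders_per_year = 0, burn_in = years,
                                    post_invasion = 0),
                        n_replicates, seed = eval_seed)
    mean(out$yearly$adults_total[out$yearly$year > years - last])
  }
  lo <- s_egg / 2
  hi <- min(0.95, s_egg * 2)
  cur <- s_egg
  evals <- data.frame(s_egg = numeric(0), mean_adults = numeric(0))
  best <- cur
  best_m <- NA_real_
  for (it in seq_len(max_iter)) {
    m <- evaluate(cur, seed + it)
    evals <- rbind(evals, data.frame(s_egg = cur, mean_adults = m))
    if (is.na(best_m) || abs(m - target) < abs(best_m - target)) {
      best <- cur
      best_m <- m
    }
    if (abs(m - target) <= 0.5 * tolerance * target) break
    if (m < target) lo <- cur else hi <- cur
    cur <- sqrt(lo * hi)
  }
  if (abs(best_m - target) > tolerance * target) {
    stop("calibration did not converge: best mean abundance ",
         round(best_m, 1), " for target ", target, "; evaluations:\n",
         paste(utils::capture.output(print(evals)), collapse = "\n"))
  }
  params$s_egg <- best
  attr(params, "calibration") <- evals
  params
}
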