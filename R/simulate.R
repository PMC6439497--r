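# Synthetic parr-survey generator: class mixtures that evolve across age
# steps by class-specific survival, genotypes drawn from the baseline panel
# through each class's ancestry-category proportions, genotyping error and
# missing calls.

#' Per-river survey configuration
#'
#' @param name River name.
#' @param axial_length Positive river length (used as a weight when pooling
#'   class proportions across rivers).
#' @param initial_class_mix Named 6-vector of starting class proportions
#'   (order of [GENETIC_CLASSES]); must sum to 1.
#' @param samples_per_age Expected sampled count per (year, age class):
#'   either a single number or a `years x 3` matrix (columns YoY, 1+, 2+).
#' @return Object of class `river_config`.
#' @export
river_config <- function(name, axial_length,
                         initial_class_mix = default_class_mix(),
                         samples_per_age = 30) {
  if (!is.numeric(axial_length) || axial_length <= 0) {
    stop("axial_length must be > 0")
  }
  mix <- as.numeric(initial_class_mix)
  if (length(mix) != 6 || any(mix < 0) || abs(sum(mix) - 1) > 1e-9) {
    stop("initial_class_mix must be 6 non-negative proportions summing to 1")
  }
  names(mix) <- GENETIC_CLASSES
  structure(list(name = as.character(name), axial_length = axial_length,
                 initial_class_mix = mix, samples_per_age = samples_per_age),
            class = "river_config")
}

#' Default starting class mixture
#'
#' Starting composition of a river the year after a large escape event:
#' roughly 72% wild with the remainder split over feral and hybrid classes,
#' the regime observed in invaded systems.
#'
#' @return Named 6-vector summing to 1.
#' @export
default_class_mix <- function() {
  c(WILD = 0.72, FERAL = 0.10, F1 = 0.10, F2 = 0.03, BCW = 0.03, BCF = 0.02)
}

#' Default per-age-step class survival multipliers
#'
#' The field point estimates for feral (0.15) and F1 (0.81) relative
#' survival over the first age step, extended to the remaining classes on an
#' ancestry gradient: second-generation hybrids intermediate (0.6),
#' backcross wild near-wild (0.95), backcross feral closer to feral (0.3).
#' Applied at every age step unless a step-specific matrix is supplied.
#'
#' @return Named 6-vector of survival multipliers (wild = 1).
#' @export
default_true_w <- function() {
  c(WILD = 1, FERAL = 0.15, F1 = 0.81, F2 = 0.6, BCW = 0.95, BCF = 0.3)
}

#' A set of example rivers
#'
#' Builds `n_rivers` river configurations with axial lengths spread over an
#' order of magnitude (log-uniform between 5 and 60 length units), mirroring
#' the size spread of a multi-river coastal survey region.
#'
#' @param n_rivers Number of rivers (default 19).
#' @param initial_class_mix Starting mixture shared by all rivers.
#' @param samples_per_age Passed to [river_config()].
#' @param seed Optional seed for the axial-length draw.
#' @return List of [river_config()] objects.
#' @export
example_rivers <- function(n_rivers = 19,
                           initial_class_mix = default_class_mix(),
                           samples_per_age = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- exp(stats::runif(n_rivers, log(5), log(60)))
  lapply(seq_len(n_rivers), function(i) {
    river_config(sprintf("R%02d", i), lens[i], initial_class_mix,
                 samples_per_age)
  })
}

# Length bins used both to draw synthetic lengths and to bin ages downstream.
AGE_BINS <- list("YoY" = c(30L, 70L), "1+" = c(71L, 110L), "2+" = c(111L, 150L))
AGE_CLASSES <- names(AGE_BINS)

#' Draw genotypes for a batch of individuals of known class
#'
#' Two-step per-locus rule: draw the ancestry category (both-wild /
#' one-of-each / both-farm) from the class's phi proportions, then draw each
#' allele from the corresponding baseline frequency. With probability
#' `error_rate` a call is replaced by a uniform draw from 0/1/2; with
#' probability `missing_rate` it is set missing.
#'
#' @param true_class Character vector of classes, one per individual.
#' @param panel A [baseline_panel()].
#' @param error_rate,missing_rate Per-genotype probabilities in `[0, 1)`.
#' @return Integer matrix (individuals x loci) of reference-allele counts
#'   with `NA` for missing calls.
#' @export
simulate_genotypes <- function(true_class, panel, error_rate = 0.0015,
                               missing_rate = 0.005) {
  if (error_rate < 0 || error_rate >= 1 || missing_rate < 0 || missing_rate >= 1) {
    stop("error_rate and missing_rate must lie in [0, 1)")
  }
  n <- length(true_class)
  L <- n_loci(panel)
  phi <- class_phi(true_class)          # n x 3
  u <- matrix(stats::runif(n * L), n, L)
  cat_ <- 1L + (u > phi[, 1]) + (u > phi[, 1] + phi[, 2])  # 1 WW, 2 WF, 3 FF
  pw <- matrix(panel$wild_freq, n, L, byrow = TRUE)
  pf <- matrix(panel$farm_freq, n, L, byrow = TRUE)
  pa <- pw                              # first allele's source frequency
  ff <- cat_ == 3L
  pa[ff] <- pf[ff]
  pb <- pf                              # second allele's source frequency
  ww <- cat_ == 1L
  pb[ww] <- pw[ww]
  g <- (matrix(stats::runif(n * L), n, L) < pa) +
    (matrix(stats::runif(n * L), n, L) < pb)
  if (error_rate > 0) {
    err <- matrix(stats::runif(n * L), n, L) < error_rate
    ne <- sum(err)
    if (ne) g[err] <- sample(0:2, ne, replace = TRUE)
  }
  if (missing_rate > 0) {
    mis <- matrix(stats::runif(n * L), n, L) < missing_rate
    g[mis] <- NA
  }
  storage.mode(g) <- "integer"
  colnames(g) <- panel$locus_ids
  g
}

#' Simulate a single individual's genotype
#'
#' @inheritParams simulate_genotypes
#' @param cls Genetic class of the individual.
#' @param seed Optional seed.
#' @return Integer vector of reference-allele counts (`NA` = missing).
#' @export
simulate_individual <- function(cls, panel, error_rate = 0.0015,
                                missing_rate = 0.005, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  simulate_genotypes(cls, panel, error_rate, missing_rate)[1, ]
}

#' Construct a survey dataset
#'
#' @param panel A [baseline_panel()].
#' @param individuals Data frame with columns `id`, `river`, `year`,
#'   `length_mm` and optionally `true_class`.
#' @param genotypes Integer matrix (individuals x loci).
#' @param rivers Data frame with columns `river`, `axial_length`.
#' @return Object of class `survey_dataset`.
#' @export
survey_dataset <- function(panel, individuals, genotypes, rivers) {
  stopifnot(inherits(panel, "baseline_panel"))
  if (nrow(individuals) != nrow(genotypes)) {
    stop("individuals and genotypes must have matching row counts")
  }
  if (ncol(genotypes) != n_loci(panel)) {
    stop("genotype matrix must have one column per panel locus")
  }
  if (any(individuals$length_mm <= 0, na.rm = TRUE)) {
    stop("length_mm must be positive")
  }
  if (!all(individuals$river %in% rivers$river)) {
    stop("every individual's river must appear in the river table")
  }
  structure(list(panel = panel, individuals = individuals,
                 genotypes = genotypes, rivers = rivers),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("survey_dataset:", nrow(x$individuals), "individuals,",
      n_loci(x$panel), "loci,", nrow(x$rivers), "rivers,",
      "years", paste(sort(unique(x$individuals$year)), collapse = "/"), "\n")
  invisible(x)
}

# Mixture of a cohort after `a` age steps of class-specific survival.
.mix_at_age <- function(mix0, true_w, a) {
  mix <- mix0
  if (a > 0) {
    for (s in seq_len(a)) {
      w <- if (is.matrix(true_w)) true_w[, min(s, ncol(true_w))] else true_w
      mix <- mix * w
      tot <- sum(mix)
      if (tot <= 0) stop("class mixture degenerated to all-zero at age step ", s)
      mix <- mix / tot
    }
  }
  mix
}

#' Simulate a multi-river, multi-year parr survey
#'
#' For each river the class mixture of a cohort at age step `a + 1` equals
#' its age-`a` mixture multiplied elementwise by the class survival
#' multipliers `true_w` and renormalised. Sampled counts per (year, age
#' class) follow each river's `samples_per_age` plan, classes are drawn
#' multinomially from the age-specific mixture, lengths uniformly within the
#' age bin, and genotypes via [simulate_genotypes()].
#'
#' @param rivers List of [river_config()] objects.
#' @param true_w Named 6-vector of per-age-step class survival multipliers
#'   (>= 0; `WILD` conventionally 1), or a `6 x n_steps` matrix for
#'   step-specific values.
#' @param years Consecutive sampling years (e.g. `2014:2016`).
#' @param panel A [baseline_panel()].
#' @param error_rate,missing_rate Passed to [simulate_genotypes()].
#' @param seed Optional seed; the survey is deterministic given the seed.
#' @return A [survey_dataset()] whose `individuals` carry hidden `true_class`
#'   labels.
#' @export
simulate_survey <- function(rivers, true_w, years, panel,
                            error_rate = 0.0015, missing_rate = 0.005,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(rivers, "river_config")) rivers <- list(rivers)
  if (length(years) > 1 && any(diff(sort(years)) != 1)) {
    stop("years must be consecutive")
  }
  w_chk <- if (is.matrix(true_w)) as.vector(true_w) else true_w
  if (any(w_chk < 0)) stop("true_w values must be >= 0")
  years <- sort(years)
  meta_list <- list()
  for (rv in rivers) {
    plan <- rv$samples_per_age
    for (yi in seq_along(years)) {
      for (ai in seq_along(AGE_CLASSES)) {
        n <- if (is.matrix(plan)) plan[yi, ai] else plan
        if (n <= 0) next
        mix <- .mix_at_age(rv$initial_class_mix, true_w, ai - 1L)
        counts <- as.vector(stats::rmultinom(1, n, mix))
        cls <- rep(GENETIC_CLASSES, counts)
        bin <- AGE_BINS[[ai]]
        len <- sample(bin[1]:bin[2], n, replace = TRUE)
        meta_list[[length(meta_list) + 1]] <- data.frame(
          id = sprintf("%s_%d_%s_%03d", rv$name, years[yi],
                       sub("\\+", "p", AGE_CLASSES[ai]), seq_len(n)),
          river = rv$name, year = years[yi], length_mm = len,
          true_class = cls, stringsAsFactors = FALSE)
      }
    }
  }
  meta <- do.call(rbind, meta_list)
  geno <- simulate_genotypes(meta$true_class, panel, error_rate, missing_rate)
  rownames(geno) <- meta$id
  river_tab <- data.frame(
    river = vapply(rivers, `[[`, character(1), "name"),
    axial_length = vapply(rivers, `[[`, numeric(1), "axial_length"),
    stringsAsFactors = FALSE)
  survey_dataset(panel, meta, geno, river_tab)
}
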