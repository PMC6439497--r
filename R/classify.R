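# Genotype-frequency-class likelihoods and the plug-in Bayes classifier.
#
# Under class c with ancestry-category proportions phi = (WW, WF, FF), the
# per-locus genotype distribution is the phi-mixture of the three
# category-conditional allele draws: both alleles from the wild baseline,
# one from each, or both from the farm baseline.

# Per-locus genotype probabilities for one class: L x 3 matrix, columns g=0,1,2.
.class_genotype_probs <- function(panel, cls) {
  phi <- class_phi(cls)[1, ]
  pw <- panel$wild_freq
  pf <- panel$farm_freq
  qw <- 1 - pw
  qf <- 1 - pf
  p2 <- phi["WW"] * pw^2 + phi["WF"] * pw * pf + phi["FF"] * pf^2
  p1 <- phi["WW"] * 2 * pw * qw + phi["WF"] * (pw * qf + qw * pf) +
    phi["FF"] * 2 * pf * qf
  p0 <- phi["WW"] * qw^2 + phi["WF"] * qw * qf + phi["FF"] * qf^2
  cbind(`0` = p0, `1` = p1, `2` = p2)
}

#' Per-locus genotype probability under a genetic class
#'
#' Probability of observing reference-allele count `g` at a locus with wild
#' and farm baseline frequencies `p_w`, `p_f`, for an individual of class
#' `cls`. With phi = (WW, WF, FF) the probability of `g = 2` is
#' `WW*p_w^2 + WF*p_w*p_f + FF*p_f^2`, of `g = 1` is
#' `WW*2*p_w*(1-p_w) + WF*(p_w*(1-p_f) + (1-p_w)*p_f) + FF*2*p_f*(1-p_f)`,
#' and `g = 0` follows the same pattern on the complements; the three sum to 1.
#'
#' @param cls One of [GENETIC_CLASSES].
#' @param g Reference-allele count, 0, 1 or 2 (vectorised with `p_w`, `p_f`).
#' @param p_w,p_f Baseline reference-allele frequencies in `[0, 1]`.
#' @return Numeric vector of probabilities.
#' @examples
#' genotype_class_probability("F1", 1, p_w = 1, p_f = 0)  # 1: obligate het
#' genotype_class_probability("BCW", 1, p_w = 0.9, p_f = 0.1)  # 0.5
#' @export
genotype_class_probability <- function(cls, g, p_w, p_f) {
  if (anyNA(g) || !all(g %in% 0:2)) stop("g must be 0, 1 or 2")
  if (any(p_w < 0 | p_w > 1) || any(p_f < 0 | p_f > 1)) {
    stop("p_w and p_f must lie in [0, 1]")
  }
  n <- max(length(g), length(p_w), length(p_f))
  g <- rep_len(g, n)
  panel <- baseline_panel(seq_len(n), rep_len(p_w, n), rep_len(p_f, n))
  probs <- .class_genotype_probs(panel, cls)
  probs[cbind(seq_len(n), g + 1L)]
}

#' Log-likelihood of a genotype under a genetic class
#'
#' Sum over non-missing loci of the log per-locus genotype probability, with
#' each per-locus probability floored at `floor` so that a single impossible
#' call (e.g. a genotyping error at a diagnostic locus) does not drive the
#' log-likelihood to `-Inf`.
#'
#' @param genotype Integer vector of reference-allele counts (0/1/2, `NA` for
#'   missing), one per panel locus.
#' @param panel A [baseline_panel()].
#' @param cls One of [GENETIC_CLASSES].
#' @param floor Per-locus probability floor (default `1e-9`).
#' @return Single numeric log-likelihood.
#' @export
class_loglikelihood <- function(genotype, panel, cls, floor = 1e-9) {
  if (length(genotype) != n_loci(panel)) {
    stop("genotype length must equal the panel's locus count")
  }
  ok <- !is.na(genotype)
  if (!any(ok)) stop("all loci missing: cannot compute a likelihood")
  probs <- .class_genotype_probs(panel, cls)
  p <- probs[cbind(which(ok), genotype[ok] + 1L)]
  sum(log(pmax(p, floor)))
}

# Batch log-likelihood matrix: n individuals x 6 classes, computed with three
# indicator matrix products so that surveys of tens of thousands of
# individuals classify in well under a second.
.loglik_matrix <- function(G, panel, floor = 1e-9) {
  stopifnot(ncol(G) == n_loci(panel))
  lp <- lapply(GENETIC_CLASSES, function(cls) {
    log(pmax(.class_genotype_probs(panel, cls), floor))
  })
  # L x 6 log-prob matrices for each genotype value
  lp0 <- vapply(lp, function(m) m[, 1], numeric(n_loci(panel)))
  lp1 <- vapply(lp, function(m) m[, 2], numeric(n_loci(panel)))
  lp2 <- vapply(lp, function(m) m[, 3], numeric(n_loci(panel)))
  I0 <- (G == 0L); I0[is.na(I0)] <- FALSE; storage.mode(I0) <- "double"
  I1 <- (G == 1L); I1[is.na(I1)] <- FALSE; storage.mode(I1) <- "double"
  I2 <- (G == 2L); I2[is.na(I2)] <- FALSE; storage.mode(I2) <- "double"
  ll <- I0 %*% lp0 + I1 %*% lp1 + I2 %*% lp2
  colnames(ll) <- GENETIC_CLASSES
  ll
}

.posterior_from_loglik <- function(ll, prior) {
  lpost <- sweep(ll, 2, log(prior), `+`)
  m <- apply(lpost, 1, max)
  w <- exp(lpost - m)
  w / rowSums(w)
}

#' Classify one genotype into the six genetic classes
#'
#' Plug-in Bayes classifier: the posterior over the six classes is
#' proportional to `prior * exp(log-likelihood)` with max-log stabilisation.
#' The individual is assigned to the top class only if its posterior
#' probability reaches `threshold`, otherwise it is `UNASSIGNED`.
#'
#' @inheritParams class_loglikelihood
#' @param prior Prior over the six classes (default uniform); must sum to 1.
#' @param threshold Minimum posterior probability for assignment
#'   (default 0.8).
#' @return Object of class `class_posterior`: list with `probs` (named
#'   6-vector summing to 1), `assigned` (class name or `"UNASSIGNED"`) and
#'   `threshold`.
#' @examples
#' pan <- baseline_panel(1:20, rep(1, 20), rep(0, 20))
#' classify(rep(1L, 20), pan)$assigned  # "F1"
#' @export
classify <- function(genotype, panel, prior = rep(1 / 6, 6), threshold = 0.8) {
  if (abs(sum(prior) - 1) > 1e-9 || length(prior) != 6) {
    stop("prior must be a 6-vector summing to 1")
  }
  if (length(genotype) != n_loci(panel)) {
    stop("genotype length must equal the panel's locus count")
  }
  if (all(is.na(genotype))) stop("all loci missing: cannot classify")
  G <- matrix(as.integer(genotype), nrow = 1)
  post <- .posterior_from_loglik(.loglik_matrix(G, panel), prior)[1, ]
  names(post) <- GENETIC_CLASSES
  assigned <- if (max(post) >= threshold) {
    GENETIC_CLASSES[which.max(post)]
  } else {
    "UNASSIGNED"
  }
  structure(list(probs = post, assigned = assigned, threshold = threshold),
            class = "class_posterior")
}

#' @export
print.class_posterior <- function(x, ...) {
  cat("class_posterior: assigned =", x$assigned,
      sprintf("(threshold %.2f)\n", x$threshold))
  print(round(x$probs, 4))
  invisible(x)
}

#' Classify every individual in a survey dataset
#'
#' Runs the Bayes classifier over all individuals of a [survey_dataset()] and
#' returns a per-individual assignment table. Individuals with every locus
#' missing cannot be scored and are dropped with a warning. Rivers share the
#' same global baselines; each individual is scored independently, so
#' per-river batches are equivalent to one pooled run.
#'
#' @param dataset A [survey_dataset()].
#' @param threshold Minimum posterior probability for assignment (default 0.8).
#' @param prior Prior over the six classes (default uniform).
#' @return Data frame with columns `id`, `river`, `year`, `length_mm`,
#'   `age_class`, `true_class` (if the dataset carries hidden labels), one
#'   posterior column `P_<class>` per class, `assigned` and `retained`.
#'   The number of retained (assigned) individuals is available as
#'   `attr(, "n_retained")`.
#' @export
assign_dataset <- function(dataset, threshold = 0.8, prior = rep(1 / 6, 6)) {
  stopifnot(inherits(dataset, "survey_dataset"))
  meta <- dataset$individuals
  G <- dataset$genotypes
  if (nrow(meta) == 0) {
    out <- cbind(meta[, c("id", "river", "year", "length_mm"), drop = FALSE],
                 age_class = character(0))
    attr(out, "n_retained") <- 0L
    return(out)
  }
  all_missing <- rowSums(!is.na(G)) == 0
  if (any(all_missing)) {
    warning(sum(all_missing), " individual(s) with all loci missing dropped")
    meta <- meta[!all_missing, , drop = FALSE]
    G <- G[!all_missing, , drop = FALSE]
  }
  post <- .posterior_from_loglik(.loglik_matrix(G, dataset$panel), prior)
  top <- max.col(post, ties.method = "first")
  pmax_ <- post[cbind(seq_len(nrow(post)), top)]
  assigned <- ifelse(pmax_ >= threshold, GENETIC_CLASSES[top], "UNASSIGNED")
  out <- data.frame(id = meta$id, river = meta$river, year = meta$year,
                    length_mm = meta$length_mm,
                    age_class = age_class_from_length(meta$length_mm),
                    stringsAsFactors = FALSE)
  if (!is.null(meta$true_class)) out$true_class <- meta$true_class
  colnames(post) <- paste0("P_", GENETIC_CLASSES)
  out <- cbind(out, as.data.frame(post))
  out$assigned <- assigned
  out$retained <- assigned != "UNASSIGNED"
  rownames(out) <- NULL
  attr(out, "n_retained") <- sum(out$retained)
  out
}
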