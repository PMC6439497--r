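# Baseline panel: per-locus wild and farm reference-allele frequencies.

#' Construct a baseline panel
#'
#' A baseline panel holds, for each SNP locus, the frequency of the reference
#' allele in the wild baseline and in the farm baseline. Genotypes everywhere
#' in the package are counts of the reference allele (0, 1 or 2).
#'
#' @param locus_ids Character vector of locus labels.
#' @param wild_freq Numeric vector in `[0, 1]`, reference-allele frequency in
#'   the wild baseline, one value per locus.
#' @param farm_freq Same for the farm baseline.
#' @return Object of class `baseline_panel`.
#' @export
baseline_panel <- function(locus_ids, wild_freq, farm_freq) {
  locus_ids <- as.character(locus_ids)
  wild_freq <- as.numeric(wild_freq)
  farm_freq <- as.numeric(farm_freq)
  if (length(wild_freq) != length(locus_ids) ||
      length(farm_freq) != length(locus_ids)) {
    stop("wild_freq and farm_freq must have one value per locus")
  }
  if (anyNA(wild_freq) || anyNA(farm_freq) ||
      any(wild_freq < 0 | wild_freq > 1) || any(farm_freq < 0 | farm_freq > 1)) {
    stop("allele frequencies must lie in [0, 1]")
  }
  structure(list(locus_ids = locus_ids,
                 wild_freq = wild_freq,
                 farm_freq = farm_freq),
            class = "baseline_panel")
}

#' @export
print.baseline_panel <- function(x, ...) {
  d <- abs(x$wild_freq - x$farm_freq)
  cat("baseline_panel:", length(x$locus_ids), "loci\n")
  cat(sprintf("  |wild - farm| frequency difference: mean %.3f, range [%.3f, %.3f]\n",
              mean(d), min(d), max(d)))
  invisible(x)
}

#' Number of loci in a panel
#' @param panel A [baseline_panel()].
#' @return Integer locus count.
#' @export
n_loci <- function(panel) length(panel$locus_ids)

#' Generate a synthetic farm/wild-discriminating SNP panel
#'
#' Draws per-locus baseline frequencies such that the absolute wild-farm
#' frequency difference follows a configurable divergence distribution.
#' The default, uniform on `[0.3, 0.7]`, emulates a panel pre-selected for
#' discriminating farmed from wild salmon.
#'
#' For each locus a difference `d` is drawn from `divergence`, a midpoint is
#' drawn uniformly so that both frequencies fit in `[0, 1]`, the wild/farm
#' orientation is randomised, and the two frequencies are clipped to
#' `freq_bounds`.
#'
#' @param n_loci Number of loci (>= 1); default 95.
#' @param divergence Either a numeric length-2 range for a uniform draw of
#'   `|wild - farm|`, a single number (point mass), or a `function(n)`
#'   returning `n` values in `[0, 1]`.
#' @param seed Optional integer seed; the panel is deterministic given the seed.
#' @param freq_bounds Length-2 numeric; frequencies are clipped into this
#'   interval (default `c(0.02, 0.98)`). Use `c(0, 1)` to allow fully
#'   diagnostic loci.
#' @return A [baseline_panel()].
#' @examples
#' p <- gen_baseline_panel(95, seed = 1)
#' range(abs(p$wild_freq - p$farm_freq))
#' @export
gen_baseline_panel <- function(n_loci = 95, divergence = c(0.3, 0.7),
                               seed = NULL, freq_bounds = c(0.02, 0.98)) {
  if (!is.numeric(n_loci) || length(n_loci) != 1 || n_loci < 1) {
    stop("n_loci must be a single integer >= 1")
  }
  n_loci <- as.integer(n_loci)
  if (!is.null(seed)) set.seed(seed)
  d <- if (is.function(divergence)) {
    divergence(n_loci)
  } else if (length(divergence) == 1) {
    rep(as.numeric(divergence), n_loci)
  } else {
    stats::runif(n_loci, min(divergence), max(divergence))
  }
  if (anyNA(d) || any(d < 0 | d > 1)) {
    stop("divergence spec must yield values in [0, 1]")
  }
  centre <- stats::runif(n_loci, d / 2, 1 - d / 2)
  hi <- centre + d / 2
  lo <- centre - d / 2
  flip <- stats::runif(n_loci) < 0.5
  wild <- ifelse(flip, lo, hi)
  farm <- ifelse(flip, hi, lo)
  clip <- function(x) pmin(max(freq_bounds), pmax(min(freq_bounds), x))
  baseline_panel(sprintf("SNP_%03d", seq_len(n_loci)), clip(wild), clip(farm))
}
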