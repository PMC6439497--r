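# Shared fixtures and independent oracles.

# A panel where every locus is fully diagnostic (wild fixed for the
# reference allele, farm fixed for the alternate).
diagnostic_panel <- function(L = 20) {
  baseline_panel(paste0("L", seq_len(L)), rep(1, L), rep(0, L))
}

# A panel with zero information (identical baseline frequencies).
flat_panel <- function(L = 10, p = 0.5) {
  baseline_panel(paste0("L", seq_len(L)), rep(p, L), rep(p, L))
}

# Oracle: per-locus genotype probability by exhaustive enumeration of the
# ancestry category and the two allele draws (independent of the package's
# closed-form expressions).
enum_genotype_prob <- function(phi, p_w, p_f, g) {
  total <- 0
  freqs <- list(c(p_w, p_w), c(p_w, p_f), c(p_f, p_f))
  for (k in 1:3) {
    fr <- freqs[[k]]
    for (a1 in 0:1) {
      for (a2 in 0:1) {
        pr <- (if (a1) fr[1] else 1 - fr[1]) * (if (a2) fr[2] else 1 - fr[2])
        if (a1 + a2 == g) total <- total + phi[k] * pr
      }
    }
  }
  unname(total)
}

# Oracle: ancestry-category proportions of a cross by gamete enumeration.
# Each parent's gametes are described by the probability that a gamete
# carries wild-baseline ancestry.
phi_from_cross <- function(p_wild_gamete_a, p_wild_gamete_b) {
  pa <- p_wild_gamete_a
  pb <- p_wild_gamete_b
  c(WW = pa * pb, WF = pa * (1 - pb) + (1 - pa) * pb,
    FF = (1 - pa) * (1 - pb))
}

# Assignment-like table built from known true classes (bypasses the
# classifier; used to test the composition / survival stages in isolation).
assignments_from_truth <- function(dataset) {
  meta <- dataset$individuals
  data.frame(id = meta$id, river = meta$river, year = meta$year,
             length_mm = meta$length_mm,
             age_class = age_class_from_length(meta$length_mm),
             assigned = meta$true_class, retained = TRUE,
             stringsAsFactors = FALSE)
}

# Small, fast parameter set for structural simulator tests (same rates,
# smaller recruitment capacity so runs are an order of magnitude cheaper).
small_sim_params <- function(...) sim_params(K = 15000, ...)

# Shared expensive objects, built at most once per test session.
.test_cache <- new.env(parent = emptyenv())

calibrated_test_params <- function() {
  if (is.null(.test_cache$calibrated)) {
    .test_cache$calibrated <- calibrate_stationarity(sim_params(), seed = 101)
  }
  .test_cache$calibrated
}
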