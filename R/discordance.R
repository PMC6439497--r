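# Duplicate-genotyping QC: discordance rate between replicate genotype calls,
# the standard proxy for the per-genotype error rate.

#' Genotyping discordance rate from replicate pairs
#'
#' Proportion of discordant locus calls among all comparable calls across a
#' set of replicate genotype pairs. A locus is comparable only when it is
#' non-missing in both replicates of a pair.
#'
#' @param replicate_pairs List of pairs; each pair is a list (or 2-row
#'   matrix) of two integer genotype vectors of equal length, `NA` = missing.
#' @return Single numeric rate in `[0, 1]`, with attributes `n_discordant`
#'   and `n_compared`.
#' @examples
#' g <- c(0L, 1L, 2L, NA)
#' estimate_discordance(list(list(g, g)))  # 0
#' @export
estimate_discordance <- function(replicate_pairs) {
  if (!length(replicate_pairs)) stop("at least one replicate pair is required")
  disc <- 0L
  comp <- 0L
  for (pr in replicate_pairs) {
    if (is.matrix(pr)) pr <- list(pr[1, ], pr[2, ])
    a <- pr[[1]]
    b <- pr[[2]]
    if (length(a) != length(b)) {
      stop("replicate genotypes within a pair must have equal length")
    }
    ok <- !is.na(a) & !is.na(b)
    comp <- comp + sum(ok)
    disc <- disc + sum(a[ok] != b[ok])
  }
  if (comp == 0) stop("no comparable (jointly non-missing) calls in any pair")
  structure(disc / comp, n_discordant = disc, n_compared = comp)
}
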