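# Six genetic classes shared by the survey simulator and the classifier.
# phi gives the expected per-locus ancestry-category proportions
# (both-wild, one-of-each, both-farm) under each class.

#' The six genetic classes
#'
#' Character vector of the class labels used throughout the package:
#' pure wild (`WILD`), pure feral (`FERAL`, wild-born offspring of two
#' escapees), first- and second-generation hybrids (`F1`, `F2`) and the
#' backcrosses of F1 to wild (`BCW`) and to feral/farm (`BCF`).
#'
#' @format Character vector of length 6.
#' @export
GENETIC_CLASSES <- c("WILD", "FERAL", "F1", "F2", "BCW", "BCF")

CLASS_PHI_TABLE <- matrix(
  c(1,    0,   0,
    0,    0,   1,
    0,    1,   0,
    0.25, 0.5, 0.25,
    0.5,  0.5, 0,
    0,    0.5, 0.5),
  nrow = 6, byrow = TRUE,
  dimnames = list(GENETIC_CLASSES, c("WW", "WF", "FF")))

#' Ancestry-category proportions of a genetic class
#'
#' For each class, the expected proportion of loci at which an individual
#' carries two wild-derived alleles (`WW`), one allele from each baseline
#' (`WF`), or two farm-derived alleles (`FF`). These follow from Mendelian
#' segregation of the defining crosses: e.g. an F1 is `WF` at every locus,
#' an F2 (F1 x F1) is (1/4, 1/2, 1/4), a backcross wild (F1 x wild) is
#' (1/2, 1/2, 0).
#'
#' @param cls Character vector of class names (subset of [GENETIC_CLASSES]).
#' @return Numeric matrix with one row per requested class and columns
#'   `WW`, `WF`, `FF`; rows sum to 1.
#' @examples
#' class_phi("F2")
#' @export
class_phi <- function(cls = GENETIC_CLASSES) {
  bad <- setdiff(cls, GENETIC_CLASSES)
  if (length(bad)) {
    stop("unknown genetic class: ", paste(bad, collapse = ", "))
  }
  CLASS_PHI_TABLE[cls, , drop = FALSE]
}
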