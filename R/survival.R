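# Within-cohort relative-survival estimator: per-river proportional change of
# each class across one age step, averaged over rivers and normalised by the
# wild class's average change.

#' Per-river proportional change with exclusion rules
#'
#' `P_t1 / P_t` for one river and class across one age step, or an exclusion:
#' rivers with fewer than `min_n` retained individuals in either age class
#' are excluded (`"small-sample"`), and rivers where the starting proportion
#' is zero are excluded (`"zero-denominator"`) rather than producing an
#' infinite ratio.
#'
#' @param P_t,P_t1 Class proportions in `[0, 1]` at the earlier and later
#'   age step.
#' @param n_t,n_t1 Retained group sizes at the two steps.
#' @param min_n Minimum group size (default 10).
#' @return List with `ratio` (numeric or `NA`) and `excluded` (`NA` or the
#'   exclusion reason).
#' @examples
#' per_river_ratio(0.20, 0.05, 50, 40)$ratio  # 0.25
#' @export
per_river_ratio <- function(P_t, P_t1, n_t, n_t1, min_n = 10) {
  if (P_t < 0 || P_t > 1 || P_t1 < 0 || P_t1 > 1) {
    stop("proportions must lie in [0, 1]")
  }
  if (n_t < min_n || n_t1 < min_n) {
    return(list(ratio = NA_real_, excluded = "small-sample"))
  }
  if (P_t == 0) {
    return(list(ratio = NA_real_, excluded = "zero-denominator"))
  }
  list(ratio = P_t1 / P_t, excluded = NA_character_)
}

#' Select a cohort's slices from an assignment table
#'
#' Restricts assignments to the (year, age class) pairs of one cohort, e.g.
#' the earliest year's YoY followed as 1+ and 2+ in the next two years, and
#' returns the corresponding composition table (no small-group filter by
#' default; the survival estimator applies its own per-river sample rule).
#'
#' @param assignments Assignment table from [assign_dataset()].
#' @param cohort Data frame with columns `year`, `age_class`; ages must
#'   increment with years. Default: [default_cohort()].
#' @param min_group Minimum retained group size (default 0).
#' @return Composition table as from [class_proportions()].
#' @export
cohort_select <- function(assignments, cohort = default_cohort(assignments),
                          min_group = 0) {
  rank <- match(cohort$age_class, AGE_CLASSES) - 1L
  if (anyNA(rank) || !all(diff(rank) == diff(cohort$year))) {
    stop("cohort spec inconsistent: age class must increment with year")
  }
  class_proportions(assignments, "cohort", min_group = min_group,
                    cohort = cohort)
}

#' Relative survival of genetic classes from a cohort composition table
#'
#' For each age step (consecutive pair of cohort slices) and each class, the
#' per-river proportional change `P_t1 / P_t` is computed with the
#' [per_river_ratio()] exclusion rules, averaged over the included rivers
#' (`R_c`), and divided by the wild class's average change to give the
#' relative survival `w_c = R_c / R_WILD`; wild is exactly 1 by construction.
#' The standard error is taken across rivers: the SD over rivers of the
#' wild-normalised per-river ratios divided by the square root of the number
#' of rivers used, so the wild class itself gets a nonzero SE reflecting
#' between-river spread. `se_method = "delta"` instead propagates the ratio-
#' of-means uncertainty of `R_c / R_WILD` from the two river-level SEs.
#'
#' @param cohort_table Composition table from [cohort_select()] (or
#'   [class_proportions()] with cohort grouping).
#' @param classes Classes to estimate (default wild, F1, feral; the rarer
#'   second-generation classes are a deliberate opt-in).
#' @param min_n Minimum retained individuals per river and age class
#'   (default 10).
#' @param se_method `"rivers"` (default) or `"delta"`.
#' @return Data frame of class `survival_estimate` with columns `age_step`,
#'   `class`, `w`, `se`, `n_rivers`; one row per class and age step. Classes
#'   with no included river are absent. Errors if no river passes the
#'   filters for the wild class.
#' @export
relative_survival <- function(cohort_table,
                              classes = c("WILD", "F1", "FERAL"),
                              min_n = 10, se_method = c("rivers", "delta")) {
  se_method <- match.arg(se_method)
  bad <- setdiff(classes, GENETIC_CLASSES)
  if (length(bad)) stop("unknown class: ", paste(bad, collapse = ", "))
  steps <- unique(cohort_table[, c("year", "age_class")])
  steps <- steps[order(steps$year), , drop = FALSE]
  if (nrow(steps) < 2) stop("cohort table must span at least two age steps")
  res <- list()
  for (k in seq_len(nrow(steps) - 1)) {
    s0 <- cohort_table[cohort_table$year == steps$year[k] &
                         cohort_table$age_class == steps$age_class[k], ]
    s1 <- cohort_table[cohort_table$year == steps$year[k + 1] &
                         cohort_table$age_class == steps$age_class[k + 1], ]
    step_lab <- paste(steps$age_class[k], "to", steps$age_class[k + 1])
    both <- intersect(unique(s0$river), unique(s1$river))
    ratios <- lapply(stats::setNames(nm = c("WILD", setdiff(classes, "WILD"))),
                     function(cl) {
      r <- vapply(both, function(rv) {
        a <- s0[s0$river == rv & s0$class == cl, ]
        b <- s1[s1$river == rv & s1$class == cl, ]
        pr <- per_river_ratio(a$proportion, b$proportion,
                              a$n_group[1], b$n_group[1], min_n)
        pr$ratio
      }, numeric(1))
      r[!is.na(r)]
    })
    rw <- ratios[["WILD"]]
    if (!length(rw)) {
      stop("no river passes the sample filters for the wild class at step ",
           step_lab)
    }
    R_wild <- mean(rw)
    for (cl in classes) {
      r <- ratios[[cl]]
      if (!length(r)) next
      m <- length(r)
      w <- if (cl == "WILD") 1 else mean(r) / R_wild
      se <- if (se_method == "rivers") {
        if (m > 1) stats::sd(r / R_wild) / sqrt(m) else NA_real_
      } else {
        se_c <- if (m > 1) stats::sd(r) / sqrt(m) else NA_real_
        se_w <- if (length(rw) > 1) stats::sd(rw) / sqrt(length(rw)) else NA_real_
        if (cl == "WILD") {
          se_w / R_wild
        } else {
          abs(mean(r) / R_wild) *
            sqrt((se_c / mean(r))^2 + (se_w / R_wild)^2)
        }
      }
      res[[length(res) + 1]] <- data.frame(
        age_step = step_lab, class = cl, w = w, se = se, n_rivers = m,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("survival_estimate", "data.frame")
  out
}
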