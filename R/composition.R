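# Cohort composition: length-based age binning, per-group class proportions
# with small-sample filtering, axial-length-weighted overall proportions and
# year-over-year change factors.

#' Age class from fork length
#'
#' Bins fork length (mm) into the three freshwater age classes:
#' young-of-year (`YoY`) up to 70 mm, `1+` for 71-110 mm inclusive, `2+`
#' above 110 mm. Real-valued lengths are floored to the mm before binning.
#'
#' @param length_mm Positive length(s) in mm.
#' @return Character vector of `"YoY"`, `"1+"`, `"2+"`.
#' @examples
#' age_class_from_length(c(70, 71, 110, 111))
#' @export
age_class_from_length <- function(length_mm) {
  if (anyNA(length_mm) || any(length_mm <= 0)) {
    stop("length_mm must be positive")
  }
  l <- floor(length_mm)
  ifelse(l <= 70, "YoY", ifelse(l <= 110, "1+", "2+"))
}

.proportion_table <- function(assignments, keys, min_group) {
  a <- assignments[assignments$retained, , drop = FALSE]
  if (!nrow(a)) {
    return(data.frame(river = character(0), year = integer(0),
                      age_class = character(0), class = character(0),
                      count = integer(0), n_group = integer(0),
                      proportion = numeric(0)))
  }
  key_df <- a[, keys, drop = FALSE]
  grp <- do.call(paste, c(key_df, sep = "\r"))
  cls <- factor(a$assigned, levels = GENETIC_CLASSES)
  tab <- table(grp, cls)
  n_grp <- rowSums(tab)
  keep <- n_grp >= min_group
  tab <- tab[keep, , drop = FALSE]
  n_grp <- n_grp[keep]
  if (!nrow(tab)) {
    return(data.frame(river = character(0), year = integer(0),
                      age_class = character(0), class = character(0),
                      count = integer(0), n_group = integer(0),
                      proportion = numeric(0)))
  }
  parts <- do.call(rbind, strsplit(rownames(tab), "\r", fixed = TRUE))
  out <- data.frame(
    river = rep(parts[, match("river", keys)], times = 6),
    year = rep(as.integer(parts[, match("year", keys)]), times = 6),
    age_class = if ("age_class" %in% keys) {
      rep(parts[, match("age_class", keys)], times = 6)
    } else {
      "all"
    },
    class = rep(GENETIC_CLASSES, each = nrow(tab)),
    count = as.integer(as.vector(tab)),
    n_group = rep(as.integer(n_grp), times = 6),
    stringsAsFactors = FALSE)
  out$proportion <- out$count / out$n_group
  out <- out[order(out$river, out$year, out$age_class,
                   match(out$class, GENETIC_CLASSES)), ]
  rownames(out) <- NULL
  out
}

#' Per-river class proportions
#'
#' Builds a composition table (counts and proportions of the six classes)
#' over retained (assigned) individuals, grouped per river and year. Three
#' groupings are supported: all ages pooled (`"all"`), young-of-year only
#' (`"yoy"`), and a single cohort followed through the age bins
#' (`"cohort"`). Groups with fewer than `min_group` retained individuals are
#' dropped to avoid noisy proportions.
#'
#' @param assignments Assignment table from [assign_dataset()].
#' @param grouping One of `"all"`, `"yoy"`, `"cohort"`.
#' @param min_group Minimum retained individuals per group (default 5).
#' @param cohort For `grouping = "cohort"`: data frame with columns `year`
#'   and `age_class` describing the cohort slices; defaults to the earliest
#'   sampled year's YoY followed through `1+` and `2+`.
#' @return Data frame with columns `river`, `year`, `age_class`, `class`,
#'   `count`, `n_group`, `proportion`; within each retained group the six
#'   proportions sum to 1.
#' @export
class_proportions <- function(assignments, grouping = c("all", "yoy", "cohort"),
                              min_group = 5, cohort = NULL) {
  grouping <- match.arg(grouping)
  if (grouping == "all") {
    return(.proportion_table(assignments, c("river", "year"), min_group))
  }
  if (grouping == "yoy") {
    sub <- assignments[assignments$age_class == "YoY", , drop = FALSE]
    return(.proportion_table(sub, c("river", "year"), min_group))
  }
  if (is.null(cohort)) cohort <- default_cohort(assignments)
  sub <- assignments[paste(assignments$year, assignments$age_class) %in%
                       paste(cohort$year, cohort$age_class), , drop = FALSE]
  .proportion_table(sub, c("river", "year", "age_class"), min_group)
}

#' Default cohort specification
#'
#' The earliest sampled year's young-of-year followed through the next two
#' years as `1+` then `2+`.
#'
#' @param assignments Assignment table (only `year` is consulted).
#' @return Data frame with columns `year`, `age_class`.
#' @export
default_cohort <- function(assignments) {
  y0 <- min(assignments$year)
  data.frame(year = y0 + 0:2, age_class = c("YoY", "1+", "2+"),
             stringsAsFactors = FALSE)
}

#' Axial-length-weighted overall proportions
#'
#' Pools per-river class proportions into a regional series, weighting each
#' river by its axial length: `P(c) = sum_r L_r P_cr / sum_r L_r` over the
#' rivers retained in that (year, age grouping).
#'
#' @param table Composition table from [class_proportions()].
#' @param lengths Named numeric vector of axial lengths (names = rivers) or a
#'   data frame with columns `river`, `axial_length`.
#' @return Data frame with columns `year`, `age_class`, `class`,
#'   `proportion`; proportions sum to 1 over classes within each group.
#' @export
axial_weighted_overall <- function(table, lengths) {
  if (is.data.frame(lengths)) {
    lengths <- stats::setNames(lengths$axial_length, lengths$river)
  }
  missing_r <- setdiff(unique(table$river), names(lengths))
  if (length(missing_r)) {
    stop("no axial length for river(s): ", paste(missing_r, collapse = ", "))
  }
  L <- lengths[table$river]
  grp <- paste(table$year, table$age_class, table$class, sep = "\r")
  num <- tapply(L * table$proportion, grp, sum)
  den <- tapply(L, grp, sum)
  parts <- do.call(rbind, strsplit(names(num), "\r", fixed = TRUE))
  out <- data.frame(year = as.integer(parts[, 1]), age_class = parts[, 2],
                    class = parts[, 3],
                    proportion = as.numeric(num / den),
                    stringsAsFactors = FALSE)
  out <- out[order(out$year, out$age_class, match(out$class, GENETIC_CLASSES)), ]
  rownames(out) <- NULL
  out
}

#' Year-over-year change factors of overall class proportions
#'
#' `factor(t -> t+1) = P(t+1) / P(t)` per class within each age grouping.
#' When a class is absent (proportion 0) in the earlier year the factor is
#' undefined and reported as `NA` rather than 0/0.
#'
#' @param overall Output of [axial_weighted_overall()].
#' @return Data frame with columns `age_class`, `class`, `from_year`,
#'   `to_year`, `factor`.
#' @export
yearly_change_factor <- function(overall) {
  years <- sort(unique(overall$year))
  if (length(years) < 2) stop("at least two years are required")
  # cohort-style series carry one age class per year; pair across years then
  per_year <- tapply(overall$age_class, overall$year,
                     function(x) length(unique(x)))
  if (all(per_year == 1) && length(unique(overall$age_class)) > 1) {
    overall$age_class <- "cohort"
  }
  res <- list()
  for (ac in unique(overall$age_class)) {
    sub <- overall[overall$age_class == ac, , drop = FALSE]
    for (i in seq_len(length(years) - 1)) {
      p0 <- sub[sub$year == years[i], ]
      p1 <- sub[sub$year == years[i + 1], ]
      if (!nrow(p0) || !nrow(p1)) next
      m <- match(p0$class, p1$class)
      f <- ifelse(p0$proportion > 0, p1$proportion[m] / p0$proportion, NA_real_)
      res[[length(res) + 1]] <- data.frame(
        age_class = ac, class = p0$class, from_year = years[i],
        to_year = years[i + 1], factor = f, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
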