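# Genepop text import/export. Dialect: title line, one locus name per line,
# "Pop" separators between rivers, one individual per line as
# "<id> ,  <4-digit genotype> ...". Reference allele coded 01, alternate 02,
# missing 0000. The reader tolerates 2- and 3-digit allele codes.

#' Write a survey dataset as Genepop text
#'
#' @param dataset A [survey_dataset()].
#' @param path Optional file path; if `NULL` the lines are returned.
#' @param title First (comment) line of the file.
#' @return Character vector of file lines, invisibly when `path` is given.
#' @export
write_genepop <- function(dataset, path = NULL,
                          title = "feralsim parr survey") {
  stopifnot(inherits(dataset, "survey_dataset"))
  g <- dataset$genotypes
  code <- matrix("0000", nrow(g), ncol(g))
  code[!is.na(g) & g == 2L] <- "0101"
  code[!is.na(g) & g == 1L] <- "0102"
  code[!is.na(g) & g == 0L] <- "0202"
  lines <- c(title, dataset$panel$locus_ids)
  for (rv in unique(dataset$individuals$river)) {
    rows <- which(dataset$individuals$river == rv)
    lines <- c(lines, "Pop",
               paste(dataset$individuals$id[rows], ", ",
                     apply(code[rows, , drop = FALSE], 1, paste,
                           collapse = " ")))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

.parse_genepop_entry <- function(x, lineno) {
  nc <- nchar(x)
  if (!all(nc == nc[1]) || !(nc[1] %in% c(4L, 6L)) ||
      any(grepl("[^0-9]", x))) {
    stop("malformed genotype entry on line ", lineno)
  }
  w <- nc[1] / 2
  a1 <- substr(x, 1, w)
  a2 <- substr(x, w + 1, nc[1])
  miss <- as.integer(a1) == 0L | as.integer(a2) == 0L
  g <- (a1 == sprintf(paste0("%0", w, "d"), 1)) +
    (a2 == sprintf(paste0("%0", w, "d"), 1))
  g[miss] <- NA
  as.integer(g)
}

#' Read Genepop text into a survey dataset
#'
#' @param x Path to a Genepop file, or a character vector of its lines.
#' @param metadata Data frame with columns `id`, `river`, `year`, `length_mm`
#'   (and optionally `true_class`) matched to individuals by `id`. If `NULL`,
#'   rivers are named after the Pop blocks and year/length are `NA`.
#' @param rivers Optional data frame (`river`, `axial_length`); derived from
#'   `metadata`/pop blocks with unit lengths when absent.
#' @param wild_freq,farm_freq Optional baseline frequencies for the returned
#'   panel; default 0.5 placeholders (the file stores genotypes only).
#' @return A [survey_dataset()].
#' @export
read_genepop <- function(x, metadata = NULL, rivers = NULL,
                         wild_freq = NULL, farm_freq = NULL) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 3) stop("malformed Genepop input: fewer than 3 lines")
  is_pop <- toupper(trimws(lines)) %in% c("POP")
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3) {
    stop("malformed Genepop input: no Pop line after the locus list")
  }
  loci <- trimws(lines[2:(first_pop - 1)])
  if (length(loci) == 1 && grepl(",", loci)) {
    loci <- trimws(strsplit(loci, ",")[[1]])
  }
  L <- length(loci)
  ids <- character(0)
  pop <- integer(0)
  geno_rows <- list()
  pop_i <- 0L
  for (i in seq(first_pop, length(lines))) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (is_pop[i]) {
      pop_i <- pop_i + 1L
      next
    }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2) stop("missing ',' separator on line ", i)
    id <- trimws(parts[1])
    entries <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[ \t]+")[[1]]
    if (length(entries) != L) {
      stop("line ", i, ": ", length(entries), " genotypes but ", L,
           " loci declared in the header")
    }
    ids <- c(ids, id)
    pop <- c(pop, pop_i)
    geno_rows[[length(geno_rows) + 1]] <- .parse_genepop_entry(entries, i)
  }
  geno <- do.call(rbind, geno_rows)
  colnames(geno) <- loci
  rownames(geno) <- ids
  if (is.null(wild_freq)) wild_freq <- rep(0.5, L)
  if (is.null(farm_freq)) farm_freq <- rep(0.5, L)
  panel <- baseline_panel(loci, wild_freq, farm_freq)
  if (is.null(metadata)) {
    meta <- data.frame(id = ids, river = sprintf("pop%02d", pop),
                       year = NA_integer_, length_mm = NA_integer_,
                       stringsAsFactors = FALSE)
  } else {
    m <- match(ids, metadata$id)
    if (anyNA(m)) {
      stop("metadata is missing ", sum(is.na(m)), " sampled id(s), e.g. ",
           ids[which(is.na(m))[1]])
    }
    meta <- metadata[m, , drop = FALSE]
    rownames(meta) <- NULL
  }
  if (is.null(rivers)) {
    rivers <- data.frame(river = unique(meta$river), axial_length = 1,
                         stringsAsFactors = FALSE)
  }
  sd <- survey_dataset(panel, meta, geno, rivers)
  # length_mm may legitimately be NA when no metadata was supplied
  sd
}
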