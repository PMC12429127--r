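# Unique-peptide length distributions and missed-cleavage accounting.

LENGTH_BINS <- c("5-8", "9-12", "13-16", "17-20", ">21")

# Named-bin label for a length >= 5; ">21" is inclusive of 21 so the five
# bins partition all lengths >= 5.
length_bin <- function(len) {
  cut(len, breaks = c(5, 9, 13, 17, 21, Inf), right = FALSE,
      labels = LENGTH_BINS)
}

#' Summarize unique-peptide lengths
#'
#' Moments, order statistics and binned distribution of the lengths of a
#' set of distinct peptide sequences. The standard deviation is the sample
#' (n-1) estimator; the mode is the most frequent length with ties broken
#' to the smallest; the median of an even count is the mean of the central
#' pair. The histogram covers every observed length as a percentage of all
#' unique peptides; the five named bins cover lengths >= 5 only, with the
#' count of shorter peptides reported separately in `n_below_bins`.
#'
#' @param peptides Character vector of peptide sequences; duplicates are
#'   collapsed (with a message) so statistics are over unique sequences.
#' @return A `length_summary`: list with `n_unique`, `mean`, `sd`,
#'   `median`, `mode`, `histogram` (length -> percentage), `bins`
#'   (bin label -> percentage) and `n_below_bins`.
#' @export
#' @examples
#' length_summary(c("AGGAK", "LSTRWQA", "MAK"))
length_summary <- function(peptides) {
  stopifnot(is.character(peptides))
  uniq <- unique(peptides)
  if (length(uniq) == 0) stop("no peptides: cannot summarize lengths")
  if (length(uniq) < length(peptides)) {
    message(sprintf("collapsed %d duplicate sequence(s)",
                    length(peptides) - length(uniq)))
  }
  lens <- nchar(uniq)
  n <- length(lens)
  tab <- table(lens)
  mode_len <- as.integer(names(tab)[which.max(tab)])  # ties -> smallest

  hist <- 100 * as.numeric(tab) / n
  names(hist) <- names(tab)

  binned <- lens[lens >= 5]
  bins <- stats::setNames(numeric(length(LENGTH_BINS)), LENGTH_BINS)
  if (length(binned) > 0) {
    bt <- table(length_bin(binned))
    bins[names(bt)] <- 100 * as.numeric(bt) / n
  }
  n_below <- sum(lens < 5)
  if (n_below > 0) {
    message(sprintf("%d peptide(s) shorter than 5 residues excluded from named bins",
                    n_below))
  }
  structure(list(n_unique = n,
                 mean = mean(lens),
                 sd = if (n > 1) stats::sd(lens) else NA_real_,
                 median = stats::median(lens),
                 mode = mode_len,
                 histogram = hist,
                 bins = bins,
                 n_below_bins = n_below),
            class = "length_summary")
}

#' @export
print.length_summary <- function(x, ...) {
  cat(sprintf(
    "%d unique peptides: length %.2f +/- %.2f aa (median %s, mode %d)\n",
    x$n_unique, x$mean, x$sd, format(x$median), x$mode))
  invisible(x)
}

#' Count missed cleavages in one peptide
#'
#' A missed cleavage is an internal residue matching the protease's
#' cleavage-residue set: positions 1 .. length-1 are eligible (the final
#' residue is the realized cleavage site or the protein terminus and never
#' counts).
#'
#' @param peptide Single peptide sequence.
#' @param rule_residues Character vector of P1 cleavage residues (e.g.
#'   `c("G", "K")`).
#' @return Integer count.
#' @export
#' @examples
#' count_missed_cleavages("AGGAK", "G")       # 2
#' count_missed_cleavages("AGKAG", c("G", "K"))  # 2
count_missed_cleavages <- function(peptide, rule_residues) {
  stopifnot(is.character(peptide), length(peptide) == 1L,
            nchar(peptide) >= 1L)
  ch <- strsplit(peptide, "", fixed = TRUE)[[1]]
  sum(ch[-length(ch)] %in% rule_residues)
}

#' Missed-cleavage report over a peptide set
#'
#' Per-peptide missed-cleavage counts and the fraction of unique peptides
#' carrying at least one, under a declared cleavage-residue set.
#'
#' @param peptides Character vector of peptide sequences (collapsed to
#'   unique sequences).
#' @param rule_residues Character vector of P1 cleavage residues.
#' @return A `missed_cleavage_report`: list with `rule_residues`,
#'   `n_peptides`, `n_with_missed`, `fraction` (percentage) and
#'   `per_peptide` (named integer vector).
#' @export
#' @examples
#' missed_cleavage_report(c("AGGAK", "LLLL"), "G")
missed_cleavage_report <- function(peptides, rule_residues) {
  uniq <- unique(peptides)
  if (length(uniq) == 0) stop("no peptides")
  per <- vapply(uniq, count_missed_cleavages, integer(1),
                rule_residues = rule_residues)
  n_with <- sum(per >= 1L)
  structure(list(rule_residues = rule_residues,
                 n_peptides = length(uniq),
                 n_with_missed = n_with,
                 fraction = 100 * n_with / length(uniq),
                 per_peptide = per),
            class = "missed_cleavage_report")
}

#' @export
print.missed_cleavage_report <- function(x, ...) {
  cat(sprintf(
    "missed cleavages ({%s}): %d/%d unique peptides (%.1f%%) with >= 1\n",
    paste(x$rule_residues, collapse = ","), x$n_with_missed, x$n_peptides,
    x$fraction))
  invisible(x)
}

#' Write a length summary as JSON and its histogram as TSV
#'
#' @param summary A `length_summary`.
#' @param json_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_length_summary <- function(summary, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(summary, "length_summary"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(n_unique = summary$n_unique, mean = summary$mean,
           sd = summary$sd, median = summary$median, mode = summary$mode,
           bins = as.list(summary$bins),
           n_below_bins = summary$n_below_bins),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(
      data.frame(length = as.integer(names(summary$histogram)),
                 percentage = unname(summary$histogram)),
      tsv_path, sep = "\t", quote = FALSE, row.names = FALSE,
      fileEncoding = "UTF-8")
  }
  invisible(c(json_path, tsv_path))
}
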