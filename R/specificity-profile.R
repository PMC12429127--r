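# Residue x subsite specificity matrices: raw counts, per-subsite
# frequencies, background-normalized ratios and binomial-proportion
# Z-scores. Rows are always the 20 canonical residues in alphabetical
# order; columns are the subsites P6..P5' (or the layout carried by the
# window set).

new_specificity_matrix <- function(counts, n_defined, subsites) {
  freq <- sweep(counts, 2L, ifelse(n_defined > 0, n_defined, 1), "/")
  freq[, n_defined == 0] <- 0
  structure(list(counts = counts, frequency = freq,
                 n_defined = n_defined, subsites = subsites),
            class = "specificity_matrix")
}

#' Construct a specificity matrix from residue counts
#'
#' Builds the count and frequency layers directly from a residue-by-subsite
#' count matrix and the per-subsite number of defined (non-padded)
#' observations. This is the entry point for externally tabulated counts;
#' [build_matrix()] tallies windows into the same structure. `n_defined`
#' may exceed the column sums when only a subset of residues was tabulated.
#'
#' @param counts Numeric matrix, 20 rows named by [aa_alphabet()] (rows are
#'   reordered to the alphabet; missing residues count 0), one column per
#'   subsite.
#' @param n_defined Per-subsite totals used as frequency denominators
#'   (default: column sums of `counts`).
#' @return A `specificity_matrix` with `counts`, `frequency`, `n_defined`
#'   and `subsites` fields.
#' @export
#' @examples
#' counts <- matrix(0, 20, 11, dimnames = list(aa_alphabet(), subsite_names()))
#' counts["L", "P1"] <- 478
#' m <- specificity_matrix(counts, n_defined = rep(3231, 11))
#' m$frequency["L", "P1"]
specificity_matrix <- function(counts, n_defined = colSums(counts)) {
  if (is.null(rownames(counts))) stop("counts must have residue rownames")
  if (any(counts < 0)) stop("counts must be non-negative")
  full <- matrix(0, nrow = 20, ncol = ncol(counts),
                 dimnames = list(AA20, colnames(counts)))
  common <- intersect(rownames(counts), AA20)
  full[common, ] <- counts[common, ]
  n_defined <- as.numeric(n_defined)
  if (length(n_defined) != ncol(full)) {
    stop("n_defined must have one entry per subsite")
  }
  if (any(colSums(full) > n_defined + 1e-9)) {
    stop("column counts exceed n_defined")
  }
  subsites <- colnames(full) %||% subsite_names(6L, ncol(full) - 6L)
  new_specificity_matrix(full, n_defined, subsites)
}

#' Tally cleavage windows into a specificity matrix
#'
#' Counts, for every subsite, how many windows carry each canonical residue
#' there. Padded (`'-'`) and non-canonical slots are excluded from both the
#' counts and the per-subsite denominators, so each frequency column sums
#' to 1 over the residues actually observed at that subsite.
#'
#' @param windows Window data frame from [extract_windows()].
#' @return A `specificity_matrix` (see [specificity_matrix()]).
#' @export
build_matrix <- function(windows) {
  if (nrow(windows) == 0) stop("no cleavage sites: cannot build a matrix")
  layout <- window_layout(windows)
  chars <- window_chars(windows$window)
  counts <- vapply(seq_len(ncol(chars)), function(s) {
    tab <- table(factor(chars[, s], levels = AA20))
    as.numeric(tab)
  }, numeric(20))
  dimnames(counts) <- list(AA20, layout$subsites)
  new_specificity_matrix(counts, colSums(counts), layout$subsites)
}

#' @export
print.specificity_matrix <- function(x, ...) {
  cat(sprintf("specificity matrix: 20 residues x %d subsites (%s)\n",
              length(x$subsites), paste(range(x$n_defined), collapse = "-")),
      sprintf("layers: %s\n",
              paste(intersect(c("counts", "frequency", "ratio", "zscore"),
                              names(x)), collapse = ", ")))
  invisible(x)
}

#' One-decimal frequency percentages
#'
#' The frequency layer expressed in percent, rounded half-up to `digits`
#' decimals (the convention used for presenting subsite frequencies).
#'
#' @param matrix A `specificity_matrix`.
#' @param digits Decimal places (default 1).
#' @return Numeric matrix of percentages.
#' @export
frequency_percent <- function(matrix, digits = 1L) {
  stopifnot(inherits(matrix, "specificity_matrix"))
  round_half_up(100 * matrix$frequency, digits)
}

#' Background residue (and dipeptide) composition
#'
#' Constructs the null composition used to normalize specificity matrices:
#' per-residue frequencies and, optionally, ordered adjacent dipeptide
#' frequencies.
#'
#' @param residue_freq Named residue -> frequency vector over (a subset of)
#'   the canonical alphabet, non-negative, summing to 1.
#' @param dipeptide_freq Optional 20 x 20 matrix (rows = first residue,
#'   columns = second) of ordered-pair frequencies summing to 1.
#' @param source Provenance label (`"identified_proteins"` or
#'   `"external_table"`).
#' @param n_residues Number of residues the composition was counted from
#'   (`NA` for external tables).
#' @return A `background_composition` object.
#' @export
background_composition <- function(residue_freq, dipeptide_freq = NULL,
                                   source = "external_table",
                                   n_residues = NA_real_) {
  rf <- check_composition(residue_freq)
  if (!is.null(dipeptide_freq)) {
    stopifnot(is.matrix(dipeptide_freq),
              nrow(dipeptide_freq) == 20, ncol(dipeptide_freq) == 20)
    if (any(dipeptide_freq < 0) ||
        abs(sum(dipeptide_freq) - 1) > 1e-9) {
      stop("dipeptide frequencies must be non-negative and sum to 1")
    }
    dimnames(dipeptide_freq) <- list(AA20, AA20)
  }
  structure(list(source = source, residue_freq = rf,
                 dipeptide_freq = dipeptide_freq,
                 n_residues = n_residues),
            class = "background_composition")
}

#' Background composition from a protein set
#'
#' Pools the residues of the unique protein set (each protein counted once,
#' regardless of how many peptides identified it) into per-residue
#' frequencies, and tallies all ordered adjacent residue pairs within each
#' sequence (never across protein boundaries) into dipeptide frequencies.
#' Non-canonical residues are ignored, and pairs containing one are
#' skipped.
#'
#' @param proteins Protein collection ([Biostrings::AAStringSet], named
#'   character vector, or accession/sequence data frame).
#' @return A `background_composition` with `source = "identified_proteins"`.
#' @export
#' @examples
#' bg <- background_from_proteins(c(A = "AG", B = "GA"))
#' bg$residue_freq[c("A", "G")]
background_from_proteins <- function(proteins) {
  seqs <- as_protein_set(proteins)
  if (length(seqs) == 0) stop("empty protein set")
  chars <- strsplit(unname(seqs), "", fixed = TRUE)
  all_ch <- unlist(chars, use.names = FALSE)
  res_counts <- tabulate(match(all_ch, AA20), nbins = 20)
  names(res_counts) <- AA20
  first <- unlist(lapply(chars, function(v) v[-length(v)]), use.names = FALSE)
  second <- unlist(lapply(chars, function(v) v[-1]), use.names = FALSE)
  i <- match(first, AA20)
  j <- match(second, AA20)
  ok <- !is.na(i) & !is.na(j)
  pair_counts <- matrix(tabulate((i[ok] - 1L) * 20L + j[ok], nbins = 400),
                        nrow = 20, ncol = 20, byrow = TRUE,
                        dimnames = list(AA20, AA20))
  n_res <- sum(res_counts)
  if (n_res == 0) stop("protein set contains no canonical residues")
  n_pairs <- sum(pair_counts)
  background_composition(
    residue_freq = res_counts / n_res,
    dipeptide_freq = if (n_pairs > 0) pair_counts / n_pairs,
    source = "identified_proteins",
    n_residues = n_res)
}

#' Read or write a background composition table
#'
#' Two tab-separated columns, `residue` and `frequency`, one row per
#' canonical residue (e.g. a Swiss-Prot composition snapshot). Frequencies
#' must sum to 1 within 1e-6.
#'
#' @param path File path.
#' @param background A `background_composition` (writer).
#' @return The reader returns a `background_composition` with
#'   `source = "external_table"`.
#' @export
read_background_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "", comment.char = "")
  if (!all(c("residue", "frequency") %in% names(df))) {
    stop("background TSV needs 'residue' and 'frequency' columns")
  }
  freq <- stats::setNames(as.numeric(df$frequency), as.character(df$residue))
  if (abs(sum(freq) - 1) > 1e-6) {
    stop(sprintf("background frequencies sum to %.8f, not 1", sum(freq)))
  }
  freq <- freq / sum(freq)
  background_composition(freq, source = "external_table")
}

#' @rdname read_background_tsv
#' @export
write_background_tsv <- function(background, path) {
  stopifnot(inherits(background, "background_composition"))
  utils::write.table(
    data.frame(residue = AA20,
               frequency = unname(background$residue_freq[AA20])),
    path, sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8")
  invisible(path)
}

#' Normalize a specificity matrix against a background
#'
#' Adds the `ratio` layer: each subsite frequency divided by the background
#' frequency of that residue, so 1 means "as often as expected from
#' composition alone". A residue observed at a subsite while absent from
#' the background (frequency 0) is an error; an unobserved residue with
#' zero background yields ratio 0.
#'
#' @param matrix A `specificity_matrix` with a frequency layer.
#' @param background A `background_composition`.
#' @return The matrix with a `ratio` layer added.
#' @export
normalize_matrix <- function(matrix, background) {
  stopifnot(inherits(matrix, "specificity_matrix"),
            inherits(background, "background_composition"))
  q <- background$residue_freq[rownames(matrix$frequency)]
  bad <- q == 0 & rowSums(matrix$counts) > 0
  if (any(bad)) {
    stop("residue(s) observed but absent from background: ",
         paste(names(q)[bad], collapse = ", "))
  }
  ratio <- sweep(matrix$frequency, 1L, ifelse(q > 0, q, 1), "/")
  ratio[q == 0, ] <- 0
  matrix$ratio <- ratio
  matrix
}

#' Z-score a specificity matrix against a background
#'
#' Adds the `zscore` layer using a one-sample binomial-proportion model per
#' cell: with observed frequency f at a subsite with n defined
#' observations, and background frequency q of the residue,
#' `Z = (f - q) / sqrt(q (1 - q) / n)`. Z is the deviation of the observed
#' frequency from its background expectation in standard-deviation units.
#' Degenerate backgrounds (q of 0 or 1) give Z = 0 when f equals q and
#' signed infinity otherwise.
#'
#' @param matrix A `specificity_matrix` with a frequency layer.
#' @param background A `background_composition`.
#' @return The matrix with a `zscore` layer added.
#' @export
zscore_matrix <- function(matrix, background) {
  stopifnot(inherits(matrix, "specificity_matrix"),
            inherits(background, "background_composition"))
  q <- background$residue_freq[rownames(matrix$frequency)]
  n <- matrix$n_defined
  if (any(n < 1)) stop("every subsite needs at least one defined observation")
  f <- matrix$frequency
  se <- sqrt(outer(q * (1 - q), n, function(v, nn) v / nn))
  z <- (f - q) / se
  degenerate <- q %in% c(0, 1)
  if (any(degenerate)) {
    for (r in which(degenerate)) {
      z[r, ] <- ifelse(f[r, ] == q[r], 0, sign(f[r, ] - q[r]) * Inf)
    }
  }
  matrix$zscore <- z
  matrix
}

#' Correlate two residue compositions
#'
#' Pearson and Spearman correlation over the 20 paired residue
#' frequencies; used to check how closely an experimental composition
#' tracks a database snapshot. Zero variance in either composition makes a
#' coefficient undefined (`NA` with a warning).
#'
#' @param a,b `background_composition` objects.
#' @return List with elements `pearson` and `spearman`.
#' @export
compare_compositions <- function(a, b) {
  stopifnot(inherits(a, "background_composition"),
            inherits(b, "background_composition"))
  x <- a$residue_freq[AA20]
  y <- b$residue_freq[AA20]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(list(pearson = NA_real_, spearman = NA_real_))
  }
  list(pearson = stats::cor(x, y, method = "pearson"),
       spearman = stats::cor(x, y, method = "spearman"))
}

#' Write or read a matrix layer as TSV
#'
#' Rows are the 20 residues in alphabetical order; columns the subsites
#' P6..P5'. Values are written in full precision so a re-read reproduces
#' the layer to 1e-9.
#'
#' @param matrix A `specificity_matrix`.
#' @param layer One of `"counts"`, `"frequency"`, `"ratio"`, `"zscore"`.
#' @param path File path.
#' @return The reader returns a numeric matrix with residue rownames.
#' @export
write_matrix_tsv <- function(matrix, layer, path) {
  stopifnot(inherits(matrix, "specificity_matrix"))
  if (is.null(matrix[[layer]])) stop("layer not present: ", layer)
  m <- matrix[[layer]]
  df <- data.frame(residue = rownames(m),
                   format(m, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "", comment.char = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}
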