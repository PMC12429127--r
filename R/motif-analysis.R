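# P2-P1 pair and P3-P2-P1 triplet motif statistics, including the
# conditional P1 analysis that asks whether a residue at P2 (e.g. proline)
# restricts the residues accepted at the scissile bond.

# Indices of the P3, P2, P1 slots within a window layout.
unprimed_slot <- function(layout, k) layout$upstream - k + 1L

#' Count P2-P1 residue pairs
#'
#' Tallies, over all windows with defined (non-padded, canonical) P2 and P1
#' slots, how often each ordered residue pair occupies them.
#'
#' @param windows Window data frame from [extract_windows()].
#' @return A `pair_matrix`: list with `counts` (20 x 20, rows = P2 residue,
#'   columns = P1 residue) and `n_pairs` (total pairs counted).
#' @export
pair_counts <- function(windows) {
  layout <- window_layout(windows)
  if (layout$upstream < 2L) stop("window layout lacks a P2 subsite")
  chars <- window_chars(windows$window)
  p2 <- chars[, unprimed_slot(layout, 2L)]
  p1 <- chars[, unprimed_slot(layout, 1L)]
  i <- match(p2, AA20)
  j <- match(p1, AA20)
  ok <- !is.na(i) & !is.na(j)
  counts <- matrix(tabulate((i[ok] - 1L) * 20L + j[ok], nbins = 400),
                   nrow = 20, ncol = 20, byrow = TRUE,
                   dimnames = list(AA20, AA20))
  structure(list(counts = counts, n_pairs = sum(counts)),
            class = "pair_matrix")
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("P2-P1 pair matrix: %d pairs%s\n", x$n_pairs,
              if (!is.null(x$zscore)) " (+zscore layer)" else ""))
  invisible(x)
}

#' Z-score P2-P1 pairs against a dipeptide background
#'
#' Adds a `zscore` layer to a pair matrix using the same one-sample
#' binomial-proportion model as [zscore_matrix()]: with observed pair
#' proportion p = count / n_pairs and background ordered-dipeptide
#' frequency q, `Z = (p - q) / sqrt(q (1 - q) / n_pairs)`. A pair observed
#' with zero background frequency is an error.
#'
#' @param pairs A `pair_matrix` from [pair_counts()].
#' @param background A `background_composition` carrying `dipeptide_freq`
#'   (see [background_from_proteins()]).
#' @return The pair matrix with a `zscore` layer added.
#' @export
pair_zscores <- function(pairs, background) {
  stopifnot(inherits(pairs, "pair_matrix"),
            inherits(background, "background_composition"))
  if (is.null(background$dipeptide_freq)) {
    stop("background has no dipeptide frequencies")
  }
  q <- background$dipeptide_freq
  n <- pairs$n_pairs
  if (n < 1) stop("no pairs counted")
  bad <- q == 0 & pairs$counts > 0
  if (any(bad)) {
    pp <- which(bad, arr.ind = TRUE)
    stop("pair(s) observed but absent from background: ",
         paste(paste0(AA20[pp[, 1]], "-", AA20[pp[, 2]]), collapse = ", "))
  }
  p_hat <- pairs$counts / n
  z <- (p_hat - q) / sqrt(q * (1 - q) / n)
  z[q == 0] <- 0
  pairs$zscore <- z
  pairs
}

#' Rank pairs by a layer
#'
#' Convenience accessor: the pair matrix flattened to a data frame of
#' (P2, P1, value), sorted by decreasing value (ties by P2 then P1
#' alphabetically).
#'
#' @param pairs A `pair_matrix`.
#' @param layer `"counts"` (default) or `"zscore"`.
#' @return Data frame with columns p2, p1, value.
#' @export
top_pairs <- function(pairs, layer = c("counts", "zscore")) {
  layer <- match.arg(layer)
  m <- pairs[[layer]]
  if (is.null(m)) stop("layer not present: ", layer)
  df <- data.frame(p2 = rep(AA20, each = 20), p1 = rep(AA20, 20),
                   value = as.vector(t(m)), stringsAsFactors = FALSE)
  df[order(-df$value, df$p2, df$p1), , drop = FALSE]
}

#' Conditional P1 distribution given a P2 residue
#'
#' Splits the windows with a defined P2 slot into those carrying
#' `condition_residue` at P2 and all others, and returns the P1 residue
#' frequency vector of each partition. An empty partition yields a zero
#' vector flagged as insufficient.
#'
#' @param windows Window data frame from [extract_windows()].
#' @param condition_residue Single residue conditioned on at P2 (default
#'   `"P"`, proline).
#' @return List with `with` and `without` (each: `freq` over the 20 P1
#'   residues, `n` events, `insufficient` flag) plus `n_defined_p2`, the
#'   number of windows with a defined P2.
#' @export
conditional_p1_distribution <- function(windows, condition_residue = "P") {
  stopifnot(condition_residue %in% AA20)
  layout <- window_layout(windows)
  if (layout$upstream < 2L) stop("window layout lacks a P2 subsite")
  chars <- window_chars(windows$window)
  p2 <- chars[, unprimed_slot(layout, 2L)]
  p1 <- chars[, unprimed_slot(layout, 1L)]
  defined <- p2 %in% AA20 & p1 %in% AA20
  part <- function(sel) {
    n <- sum(sel)
    freq <- stats::setNames(numeric(20), AA20)
    if (n > 0) {
      tab <- tabulate(match(p1[sel], AA20), nbins = 20)
      freq <- stats::setNames(tab / n, AA20)
    }
    list(freq = freq, n = n, insufficient = n == 0)
  }
  list(with = part(defined & p2 == condition_residue),
       without = part(defined & p2 != condition_residue),
       n_defined_p2 = sum(defined))
}

# Parse one element of a triplet pattern: "X" (any residue), a single
# residue, or a bracketed class like "[LMP]".
parse_pattern_element <- function(el) {
  if (el == "X") return(AA20)
  if (grepl("^\\[[A-Z]+\\]$", el)) {
    return(strsplit(substr(el, 2, nchar(el) - 1), "")[[1]])
  }
  if (el %in% AA20) return(el)
  stop("invalid pattern element: ", el)
}

#' Count P3-P2-P1 triplet patterns
#'
#' Tallies the concrete residue triples occupying the P3, P2 and P1
#' subsites (windows with padding or non-canonical residues in those slots
#' are skipped), and additionally counts user-declared generalized
#' patterns written as three dash-separated elements: a residue, `X` (any
#' residue), or a bracketed residue class — e.g. `"G-X-[LMP]"` for glycine
#' at P3, anything at P2, and leucine/methionine/proline at P1. Dedupe to
#' unique peptides, when wanted, must happen upstream (one window per
#' unique peptide).
#'
#' @param windows Window data frame from [extract_windows()].
#' @param patterns Character vector of generalized pattern declarations
#'   (may be empty).
#' @return Data frame with columns `pattern`, `count` and `generalized`,
#'   sorted by decreasing count (ties alphabetically by pattern).
#' @export
#' @examples
#' w <- structure(data.frame(accession = "P1", position = 7,
#'                           p1 = "L", window = "AKLGALSTRWQ"),
#'                upstream = 6L, downstream = 5L)
#' triplet_patterns(w, patterns = "G-X-[LMP]")
triplet_patterns <- function(windows, patterns = character(0)) {
  layout <- window_layout(windows)
  if (layout$upstream < 3L) stop("window layout lacks a P3 subsite")
  chars <- window_chars(windows$window)
  p3 <- chars[, unprimed_slot(layout, 3L)]
  p2 <- chars[, unprimed_slot(layout, 2L)]
  p1 <- chars[, unprimed_slot(layout, 1L)]
  ok <- p3 %in% AA20 & p2 %in% AA20 & p1 %in% AA20
  p3 <- p3[ok]; p2 <- p2[ok]; p1 <- p1[ok]

  concrete <- if (length(p1) > 0) {
    tab <- table(paste(p3, p2, p1, sep = "-"))
    data.frame(pattern = names(tab), count = as.integer(tab),
               generalized = FALSE, stringsAsFactors = FALSE)
  } else {
    data.frame(pattern = character(0), count = integer(0),
               generalized = logical(0))
  }

  general <- lapply(patterns, function(pat) {
    els <- strsplit(pat, "-", fixed = TRUE)[[1]]
    if (length(els) != 3L) stop("pattern must have three elements: ", pat)
    sets <- lapply(els, parse_pattern_element)
    n <- sum(p3 %in% sets[[1]] & p2 %in% sets[[2]] & p1 %in% sets[[3]])
    data.frame(pattern = pat, count = as.integer(n), generalized = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- rbind(concrete, do.call(rbind, general))
  out <- out[order(-out$count, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}
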