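# From peptide termini to unique cleavage sites and fixed subsite windows.
# A peptide observed at [start, end] implies the protease cut before its
# first residue (P1 = residue start-1) and after its last (P1 = residue
# end), except at the protein termini and after a removed initiator Met.

#' Extract unique cleavage sites from identification records
#'
#' For each peptide, an N-boundary site is placed at `start - 1` unless the
#' peptide begins the protein (`start == 1`) or directly follows an
#' initiator methionine (`start == 2` with residue 1 == M, where the free
#' N-terminus more likely reflects co-translational Met removal than
#' proteolysis). A C-boundary site is placed at `end` unless the peptide
#' runs to the protein's last residue (the C-terminus is not a cleavage
#' product). Sites are deduplicated by (accession, position) — a position
#' supported by both an N- and a C-boundary counts once.
#'
#' @param records Validated identification data frame (see
#'   [validate_identifications()]).
#' @return Data frame with columns accession, position (1-based index of
#'   the P1 residue), p1 (that residue) and origin
#'   (`"n_boundary"`/`"c_boundary"`), sorted by accession then position.
#' @export
#' @examples
#' recs <- data.frame(accession = "P1", protein_sequence = "MAGKLSTRW",
#'                    peptide_sequence = "LSTR", start = 5, end = 8,
#'                    score = 30)
#' extract_sites(recs)
extract_sites <- function(records) {
  if (nrow(records) == 0) {
    return(data.frame(accession = character(0), position = integer(0),
                      p1 = character(0), origin = character(0)))
  }
  prot_len <- nchar(records$protein_sequence)
  init_met <- substring(records$protein_sequence, 1L, 1L) == "M"

  n_ok <- records$start > 1L & !(records$start == 2L & init_met)
  c_ok <- records$end < prot_len

  sites <- rbind(
    data.frame(accession = records$accession[n_ok],
               protein_sequence = records$protein_sequence[n_ok],
               position = records$start[n_ok] - 1L,
               origin = rep("n_boundary", sum(n_ok)),
               stringsAsFactors = FALSE),
    data.frame(accession = records$accession[c_ok],
               protein_sequence = records$protein_sequence[c_ok],
               position = records$end[c_ok],
               origin = rep("c_boundary", sum(c_ok)),
               stringsAsFactors = FALSE))
  sites$p1 <- substring(sites$protein_sequence, sites$position, sites$position)
  sites <- sites[order(sites$accession, sites$position, sites$origin), ,
                 drop = FALSE]
  sites <- sites[!duplicated(sites[, c("accession", "position")]), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  sites[, c("accession", "position", "p1", "origin")]
}

#' Extract fixed subsite windows around cleavage sites
#'
#' For a site with P1 at `position`, the window spans residues
#' `position - upstream + 1` .. `position + downstream` of the parent
#' protein, laid out as subsites P`upstream`..P1, P1'..P`downstream`'
#' (default P6..P5', width 11). Subsites falling outside the protein are
#' padded with `'-'`; padded slots are excluded from all downstream
#' counting denominators.
#'
#' @param sites Site data frame from [extract_sites()].
#' @param proteins Protein collection ([Biostrings::AAStringSet], named
#'   character vector, or accession/sequence data frame) resolving every
#'   site's accession.
#' @param upstream,downstream Number of unprimed / primed subsites
#'   (defaults 6 and 5).
#' @return Data frame with columns accession, position, p1, window, sorted
#'   by accession then position; the subsite layout is attached as
#'   attributes `upstream`, `downstream` and `subsites`.
#' @export
#' @examples
#' sites <- data.frame(accession = "P1", position = 4, p1 = "K",
#'                     origin = "n_boundary")
#' extract_windows(sites, c(P1 = "MAGKLSTRW"))
extract_windows <- function(sites, proteins, upstream = 6L, downstream = 5L) {
  stopifnot(upstream >= 1L, downstream >= 1L)
  seqs <- as_protein_set(proteins)
  missing_acc <- setdiff(unique(sites$accession), names(seqs))
  if (length(missing_acc) > 0) {
    stop("accession(s) not resolvable to a sequence: ",
         paste(missing_acc, collapse = ", "))
  }
  if (nrow(sites) > 0 &&
      any(sites$position < 1L |
          sites$position >= nchar(seqs[sites$accession]))) {
    stop("site position outside 1..(protein length - 1)")
  }
  padded <- paste0(strrep(PAD, upstream - 1L), seqs, strrep(PAD, downstream))
  names(padded) <- names(seqs)
  win <- substring(padded[sites$accession], sites$position,
                   sites$position + upstream + downstream - 1L)
  out <- data.frame(accession = sites$accession, position = sites$position,
                    p1 = sites$p1, window = unname(win),
                    stringsAsFactors = FALSE)
  out <- out[order(out$accession, out$position), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, upstream = as.integer(upstream),
            downstream = as.integer(downstream),
            subsites = subsite_names(upstream, downstream))
}

# Subsite layout of a window data frame, with the P6..P5' default for
# plain 11-character windows from other sources.
window_layout <- function(windows) {
  up <- attr(windows, "upstream") %||% 6L
  down <- attr(windows, "downstream") %||%
    (nchar(windows$window[1]) - up)
  list(upstream = up, downstream = down,
       subsites = attr(windows, "subsites") %||% subsite_names(up, down))
}

#' Read or write cleavage windows as TSV
#'
#' Four tab-separated columns: accession, position, p1, window.
#'
#' @param windows Window data frame from [extract_windows()].
#' @param path File path.
#' @return The reader returns the window data frame with its subsite
#'   layout attributes restored (inferred from the window width, P1 at
#'   `width - 5` for the standard 11-wide window).
#' @export
write_windows_tsv <- function(windows, path) {
  utils::write.table(windows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_windows_tsv
#' @export
read_windows_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer", "character",
                                         "character"),
                          check.names = FALSE, quote = "", comment.char = "")
  need <- c("accession", "position", "p1", "window")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("windows TSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  width <- if (nrow(df) > 0) nchar(df$window[1]) else 11L
  up <- width - 5L
  structure(df[, need], upstream = as.integer(up),
            downstream = as.integer(width - up),
            subsites = subsite_names(up, width - up))
}
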