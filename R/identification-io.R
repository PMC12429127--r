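# Reading and validating peptide identification results. Two dialects are
# supported: a Mascot XML export (protein sequences included in the hit
# output) and a plain TSV interchange used by the simulator. Both converge
# on the same validated record layout.

ID_COLUMNS <- c("accession", "protein_sequence", "peptide_sequence",
                "start", "end", "score")

# Strip modification annotations from a peptide string: parenthesized or
# bracketed groups (e.g. "M(Oxidation)") and any non-letter characters are
# removed, and the result is uppercased.
strip_modifications <- function(x) {
  x <- gsub("\\([^)]*\\)|\\[[^]]*\\]", "", x)
  toupper(gsub("[^A-Za-z]", "", x))
}

#' Validate peptide identification records
#'
#' Enforces the record contract: coordinates are 1-based inclusive and lie
#' within the protein, the stated substring of the protein equals the
#' peptide sequence, and the peptide uses only the 20 canonical residues
#' (records containing B, Z, X, U, O or other letters are excluded from
#' downstream counting). Failing records are dropped with a warning that
#' tallies each reason.
#'
#' @param records Data frame with columns accession, protein_sequence,
#'   peptide_sequence, start, end, score.
#' @return The validated subset, with integer coordinates and numeric
#'   scores; the number of drops per reason is attached as attribute
#'   `"dropped"`.
#' @export
validate_identifications <- function(records) {
  missing_cols <- setdiff(ID_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    stop("missing identification column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  records$accession <- as.character(records$accession)
  records$protein_sequence <- toupper(as.character(records$protein_sequence))
  records$peptide_sequence <- toupper(as.character(records$peptide_sequence))
  records$score <- as.numeric(records$score)

  start <- suppressWarnings(as.integer(records$start))
  end <- suppressWarnings(as.integer(records$end))
  bad_coord <- is.na(start) | is.na(end) | start < 1L | end < start |
    end > nchar(records$protein_sequence)
  records$start <- start
  records$end <- end

  sub_ok <- !bad_coord &
    substring(records$protein_sequence, pmax(start, 1L), end) ==
      records$peptide_sequence
  noncanonical <- grepl(paste0("[^", paste(AA20, collapse = ""), "]"),
                        records$peptide_sequence)
  keep <- !bad_coord & sub_ok & !noncanonical

  dropped <- c(bad_coordinates = sum(bad_coord),
               substring_mismatch = sum(!bad_coord & !sub_ok),
               noncanonical_residue = sum(!bad_coord & sub_ok & noncanonical))
  if (any(dropped > 0)) {
    warning(sprintf(
      "dropped %d record(s): %s", sum(dropped),
      paste(sprintf("%s=%d", names(dropped), dropped)[dropped > 0],
            collapse = ", ")), call. = FALSE)
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Read a Mascot XML search-result export
#'
#' Parses the XML export dialect in which each protein hit carries its full
#' sequence (`prot_seq`) and each peptide match its sequence, 1-based
#' start/end coordinates and Ion Score. Namespaces are ignored and unknown
#' elements skipped, so minor schema variations across Mascot versions are
#' tolerated. Peptide strings are stripped of modification annotations
#' before validation. Hits without a protein sequence are skipped with a
#' warning; records failing coordinate or substring consistency are dropped
#' and tallied by [validate_identifications()].
#'
#' @param path Path to the XML file.
#' @return Validated identification data frame (see
#'   [validate_identifications()]).
#' @export
read_mascot_xml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  hits <- xml2::xml_find_all(doc, ".//hit/protein")
  rows <- lapply(hits, function(prot) {
    acc <- xml2::xml_attr(prot, "accession")
    seq_node <- xml2::xml_find_first(prot, "./prot_seq")
    if (is.na(xml2::xml_text(seq_node)) ||
        !nzchar(xml2::xml_text(seq_node))) {
      warning(sprintf("protein %s has no prot_seq element; hit skipped", acc),
              call. = FALSE)
      return(NULL)
    }
    pseq <- toupper(gsub("\\s", "", xml2::xml_text(seq_node)))
    peps <- xml2::xml_find_all(prot, "./peptide")
    if (length(peps) == 0) return(NULL)
    field <- function(node, name) xml2::xml_text(xml2::xml_find_first(node, name))
    data.frame(
      accession = acc,
      protein_sequence = pseq,
      peptide_sequence = strip_modifications(
        vapply(peps, field, character(1), "./pep_seq")),
      start = vapply(peps, field, character(1), "./pep_start"),
      end = vapply(peps, field, character(1), "./pep_end"),
      score = as.numeric(vapply(peps, field, character(1), "./pep_score")),
      stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(validate_identifications(
      data.frame(accession = character(0), protein_sequence = character(0),
                 peptide_sequence = character(0), start = integer(0),
                 end = integer(0), score = numeric(0))))
  }
  validate_identifications(do.call(rbind, rows))
}

#' Write identification records as a Mascot-style XML export
#'
#' Emits the same element layout [read_mascot_xml()] consumes (hit/protein/
#' prot_seq/peptide/pep_seq/pep_start/pep_end/pep_score); used to build
#' fixtures and for interchange round-trips.
#'
#' @param records Identification data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mascot_xml <- function(records, path) {
  doc <- xml2::xml_new_root("mascot_search_results")
  hits <- xml2::xml_add_child(doc, "hits")
  for (acc in unique(records$accession)) {
    sub <- records[records$accession == acc, , drop = FALSE]
    hit <- xml2::xml_add_child(hits, "hit")
    prot <- xml2::xml_add_child(hit, "protein", accession = acc)
    xml2::xml_add_child(prot, "prot_seq", sub$protein_sequence[1])
    for (i in seq_len(nrow(sub))) {
      pep <- xml2::xml_add_child(prot, "peptide")
      xml2::xml_add_child(pep, "pep_seq", sub$peptide_sequence[i])
      xml2::xml_add_child(pep, "pep_start", as.character(sub$start[i]))
      xml2::xml_add_child(pep, "pep_end", as.character(sub$end[i]))
      xml2::xml_add_child(pep, "pep_score", format(sub$score[i], digits = 15))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read or write the TSV identification dialect
#'
#' Plain UTF-8 tab-separated interchange with header columns accession,
#' protein_sequence, peptide_sequence, start, end, score ('.' as the
#' decimal separator). Rows with non-integer coordinates are skipped with a
#' warning; a missing column is fatal.
#'
#' @param path File path.
#' @return For the reader, a validated identification data frame.
#' @export
read_identification_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  missing_cols <- setdiff(ID_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("identification TSV lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) > 0) {
    ok <- grepl("^[0-9]+$", df$start) & grepl("^[0-9]+$", df$end)
    if (any(!ok)) {
      warning(sprintf("skipped %d row(s) with non-integer coordinates",
                      sum(!ok)), call. = FALSE)
      df <- df[ok, , drop = FALSE]
    }
  }
  validate_identifications(df)
}

#' @rdname read_identification_tsv
#' @param records Identification data frame to write.
#' @export
write_identification_tsv <- function(records, path) {
  utils::write.table(records[, intersect(c(ID_COLUMNS, "is_decoy"),
                                         names(records)), drop = FALSE],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read/write FASTA protein collections
#'
#' Thin wrappers over [Biostrings::readAAStringSet()] /
#' [Biostrings::writeXStringSet()]; accessions are the first whitespace-
#' delimited token of each FASTA header.
#'
#' @param path FASTA file path.
#' @param proteins An [Biostrings::AAStringSet] or named character vector.
#' @return The reader returns an [Biostrings::AAStringSet].
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' @rdname read_fasta
#' @export
write_fasta <- function(proteins, path) {
  seqs <- as_protein_set(proteins)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Apply the confidence filter to identification records
#'
#' Retains records with score at or above the Ion Score threshold
#' (inclusive, default 20) and, when `dedupe_peptides` is set, keeps one
#' record per distinct peptide sequence — the highest-scoring occurrence
#' (first such record on ties). The operation is idempotent.
#'
#' @param records Identification data frame.
#' @param min_ion_score Inclusive score threshold (default 20).
#' @param dedupe_peptides Collapse duplicate peptide sequences (default
#'   `TRUE`).
#' @return The filtered data frame.
#' @export
#' @examples
#' recs <- data.frame(accession = "P1", protein_sequence = "MAGKLSTRW",
#'                    peptide_sequence = c("LSTR", "LSTR", "AGK"),
#'                    start = c(5, 5, 2), end = c(8, 8, 4),
#'                    score = c(25, 40, 19))
#' apply_filters(recs)
apply_filters <- function(records, min_ion_score = 20,
                          dedupe_peptides = TRUE) {
  stopifnot(min_ion_score >= 0)
  out <- records[records$score >= min_ion_score, , drop = FALSE]
  if (isTRUE(dedupe_peptides) && nrow(out) > 1) {
    ord <- order(out$peptide_sequence, -out$score)
    out <- out[ord, , drop = FALSE]
    out <- out[!duplicated(out$peptide_sequence), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
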