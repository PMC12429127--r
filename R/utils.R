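# Shared internal helpers and constants.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
PAD <- "-"

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# round() uses round-half-even; percentages are presented round-half-up.
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Coerce a protein collection (AAStringSet, named character vector, or
# data.frame with accession/sequence columns) to a named character vector.
as_protein_set <- function(proteins) {
  if (methods::is(proteins, "XStringSet")) {
    seqs <- as.character(proteins)
  } else if (is.data.frame(proteins)) {
    if (!all(c("accession", "sequence") %in% names(proteins))) {
      stop("protein data.frame needs 'accession' and 'sequence' columns")
    }
    seqs <- stats::setNames(as.character(proteins$sequence),
                            as.character(proteins$accession))
  } else if (is.character(proteins)) {
    seqs <- proteins
  } else {
    stop("unsupported protein container: ", class(proteins)[1])
  }
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    stop("every protein sequence must carry an accession (name)")
  }
  if (anyDuplicated(names(seqs))) {
    seqs <- seqs[!duplicated(names(seqs))]
  }
  seqs
}

# Validate a residue composition: expand to the full 20-letter alphabet
# (unlisted residues get 0), require non-negative entries summing to 1.
check_composition <- function(composition, tol = 1e-9) {
  if (is.null(names(composition))) {
    stop("composition must be a named residue -> frequency vector")
  }
  unknown <- setdiff(names(composition), AA20)
  if (length(unknown) > 0) {
    stop("composition names outside the 20-letter alphabet: ",
         paste(unknown, collapse = ", "))
  }
  full <- stats::setNames(numeric(20), AA20)
  full[names(composition)] <- as.numeric(composition)
  if (any(full < 0)) stop("composition frequencies must be non-negative")
  s <- sum(full)
  if (abs(s - 1) > tol) {
    stop(sprintf("composition frequencies must sum to 1 (got %.12f)", s))
  }
  full
}

# Character matrix (windows x subsites) from a window string vector.
window_chars <- function(windows) {
  stopifnot(is.character(windows))
  if (length(windows) == 0) {
    return(matrix(character(0), nrow = 0, ncol = 0))
  }
  w <- nchar(windows)
  if (length(unique(w)) != 1L) stop("windows must all have the same width")
  matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
         nrow = length(windows), byrow = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
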