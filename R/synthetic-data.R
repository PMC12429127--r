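# In-silico proteome generation and probabilistic digestion. The simulator is
# the generative inverse of the profiling pipeline: it plants a known
# P1-conditioned (optionally P2-modified) cleavage preference and emits
# post-search-style identification tables with ground truth, so parameter
# recovery can be checked end to end.

#' Protein length laws
#'
#' Constructors for the three supported protein-length distributions used by
#' [proteome_spec()]: a fixed length, a discrete uniform range, and a
#' truncated lognormal. The lognormal default (meanlog 5.8, sdlog 0.45,
#' truncated to 50-2000 residues) gives a median length of roughly 330
#' residues, typical of mammalian proteomes.
#'
#' @param length,min,max Integer residue counts; all lengths must be >= 2.
#' @param meanlog,sdlog Lognormal parameters on the log scale.
#' @return A length-law object consumed by [proteome_spec()].
#' @export
#' @examples
#' length_fixed(100)
#' length_lognormal()
length_fixed <- function(length) {
  stopifnot(length >= 2)
  structure(list(law = "fixed", length = as.integer(length)),
            class = "length_law")
}

#' @rdname length_fixed
#' @export
length_uniform <- function(min, max) {
  stopifnot(min >= 2, max >= min)
  structure(list(law = "uniform", min = as.integer(min), max = as.integer(max)),
            class = "length_law")
}

#' @rdname length_fixed
#' @export
length_lognormal <- function(meanlog = 5.8, sdlog = 0.45,
                             min = 50L, max = 2000L) {
  stopifnot(min >= 2, max >= min, sdlog >= 0)
  structure(list(law = "lognormal", meanlog = meanlog, sdlog = sdlog,
                 min = as.integer(min), max = as.integer(max)),
            class = "length_law")
}

sample_lengths <- function(law, n) {
  switch(law$law,
    fixed = rep(law$length, n),
    uniform = sample(seq(law$min, law$max), n, replace = TRUE),
    lognormal = {
      out <- integer(0)
      while (length(out) < n) {
        x <- round(stats::rlnorm(n, law$meanlog, law$sdlog))
        out <- c(out, x[x >= law$min & x <= law$max])
      }
      as.integer(out[seq_len(n)])
    },
    stop("unknown length law: ", law$law)
  )
}

#' Uniform residue composition
#'
#' Equal frequency 1/20 for each canonical amino acid.
#'
#' @return Named numeric vector over [aa_alphabet()].
#' @export
uniform_composition <- function() {
  stats::setNames(rep(1 / 20, 20), AA20)
}

#' Specify a synthetic proteome
#'
#' @param n_proteins Number of proteins to generate.
#' @param length_law A length law from [length_fixed()], [length_uniform()]
#'   or [length_lognormal()].
#' @param composition Named residue -> frequency vector over (a subset of)
#'   the 20 canonical amino acids; unlisted residues get frequency 0.
#'   Frequencies must be non-negative and sum to 1.
#' @param initiator_met If `TRUE`, residue 1 of every protein is forced to
#'   methionine, mimicking the initiator Met of translated sequences.
#' @param seed Integer seed making generation deterministic, or `NULL`.
#' @return A `proteome_spec` object for [generate_proteome()].
#' @export
#' @examples
#' sp <- proteome_spec(3, length_fixed(60), seed = 1)
#' generate_proteome(sp)
proteome_spec <- function(n_proteins,
                          length_law = length_lognormal(),
                          composition = uniform_composition(),
                          initiator_met = TRUE,
                          seed = NULL) {
  stopifnot(n_proteins >= 1)
  comp <- check_composition(composition)
  structure(list(n_proteins = as.integer(n_proteins),
                 length_law = length_law,
                 composition = comp,
                 initiator_met = isTRUE(initiator_met),
                 seed = seed),
            class = "proteome_spec")
}

#' Generate a synthetic proteome
#'
#' Draws `n_proteins` sequences over the 20-letter alphabet with i.i.d.
#' residues from the spec's composition and lengths from its length law.
#' Accessions are `SYN0001`, `SYN0002`, ... Deterministic given the spec's
#' seed.
#'
#' @param spec A [proteome_spec()].
#' @return A [Biostrings::AAStringSet] named by accession.
#' @export
generate_proteome <- function(spec) {
  stopifnot(inherits(spec, "proteome_spec"))
  with_seed(spec$seed, {
    lens <- sample_lengths(spec$length_law, spec$n_proteins)
    res <- sample(AA20, sum(lens), replace = TRUE, prob = spec$composition)
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    seqs <- vapply(seq_along(lens), function(i) {
      paste(res[starts[i]:ends[i]], collapse = "")
    }, character(1))
    if (spec$initiator_met) {
      substr(seqs, 1L, 1L) <- "M"
    }
    names(seqs) <- sprintf("SYN%04d", seq_along(seqs))
    Biostrings::AAStringSet(seqs)
  })
}

#' Define a probabilistic protease rule
#'
#' A rule gives, per P1 residue, the probability that the bond C-terminal of
#' that residue is hydrolyzed; unlisted residues are never cut. An optional
#' P2 modifier multiplies the P1 probability when a given residue occupies
#' P2 (the product is clamped to \[0, 1\]), modelling subsite cooperation
#' such as a proline preference one position upstream of the scissile bond.
#'
#' @param p1_prob Named residue -> probability vector, each in \[0, 1\].
#' @param p2_modifier Optional named residue -> multiplicative factor vector
#'   (factors >= 0); absent residues act as factor 1.
#' @param name Label for reports.
#' @return A `protease_rule` object.
#' @export
#' @examples
#' protease_rule(c(G = 0.9, K = 0.5), name = "Gly/Lys protease")
#' protease_rule(c(F = 0.2, M = 0.2, L = 0.2), p2_modifier = c(P = 5))
protease_rule <- function(p1_prob, p2_modifier = NULL, name = "synthetic") {
  if (length(p1_prob) > 0) {
    if (is.null(names(p1_prob))) stop("p1_prob must be named by residue")
    unknown <- setdiff(names(p1_prob), AA20)
    if (length(unknown) > 0) {
      stop("p1_prob residues outside the alphabet: ",
           paste(unknown, collapse = ", "))
    }
    if (any(p1_prob < 0 | p1_prob > 1)) stop("p1_prob entries must be in [0, 1]")
  }
  if (!is.null(p2_modifier)) {
    if (is.null(names(p2_modifier))) stop("p2_modifier must be named by residue")
    if (any(p2_modifier < 0)) stop("p2_modifier factors must be >= 0")
  }
  structure(list(name = name,
                 p1_prob = p1_prob,
                 p2_modifier = p2_modifier),
            class = "protease_rule")
}

# Per-bond cut probabilities for a residue vector, reading the original
# sequence: bond i (after residue i, i in 1..L-1) has probability
# p1_prob[res i] * p2_modifier[res i-1], clamped to [0, 1]. An initiator
# methionine is never a cut P1.
cut_probabilities <- function(res, rule) {
  L <- length(res)
  if (L < 2) return(numeric(0))
  p <- rule$p1_prob[res[seq_len(L - 1L)]]
  p[is.na(p)] <- 0
  p <- as.numeric(p)
  if (!is.null(rule$p2_modifier) && L > 2) {
    m <- rule$p2_modifier[res[seq_len(L - 2L)]]
    m[is.na(m)] <- 1
    p[-1L] <- p[-1L] * as.numeric(m)
  }
  p <- pmin(pmax(p, 0), 1)
  if (res[1L] == "M") p[1L] <- 0
  p
}

#' Digest one protein with a probabilistic rule
#'
#' Each internal peptide bond is cut by an independent Bernoulli draw with
#' probability `p1_prob[P1 residue] * p2_modifier[P2 residue]` (clamped to
#' \[0, 1\]; modifier 1 when absent or when the bond follows residue 1).
#' The P2 residue is read from the original sequence, not from fragments,
#' and an initiator methionine at position 1 is never a cut P1. Peptides are
#' the maximal fragments between realized cuts; their concatenation always
#' reconstructs the input.
#'
#' @param sequence Residue string of length >= 1.
#' @param rule A [protease_rule()].
#' @param seed Optional integer seed; `NULL` uses (and advances) the current
#'   RNG stream.
#' @return List with `peptides` (character), `cuts` (1-based P1 positions of
#'   realized cuts), `starts` and `ends` (peptide coordinates).
#' @export
#' @examples
#' digest_protein("MAKGLKR", protease_rule(c(K = 1)))
digest_protein <- function(sequence, rule, seed = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nchar(sequence) >= 1L, inherits(rule, "protease_rule"))
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(res)
  p <- cut_probabilities(res, rule)
  cut <- with_seed(seed, stats::runif(length(p)) < p)
  cuts <- which(cut)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, L)
  peptides <- substring(sequence, starts, ends)
  list(peptides = peptides, cuts = cuts, starts = starts, ends = ends)
}

#' Score laws for simulated identifications
#'
#' @param min,max Bounds of a uniform score distribution.
#' @param mean,sd Parameters of a normal score distribution (truncated at 0).
#' @return A score-law object for [ident_sim_config()].
#' @export
score_uniform <- function(min, max) {
  stopifnot(max >= min)
  structure(list(law = "uniform", min = min, max = max), class = "score_law")
}

#' @rdname score_uniform
#' @export
score_normal <- function(mean, sd) {
  stopifnot(sd >= 0)
  structure(list(law = "normal", mean = mean, sd = sd), class = "score_law")
}

sample_scores <- function(law, n) {
  switch(law$law,
    uniform = stats::runif(n, law$min, law$max),
    normal = pmax(stats::rnorm(n, law$mean, law$sd), 0),
    stop("unknown score law: ", law$law)
  )
}

#' Configure the identification simulator
#'
#' @param detect_len Inclusive peptide-length detectability window; fragments
#'   outside it are never emitted (default `c(5, 40)`, the usual LC-MS/MS
#'   identification range).
#' @param true_score_law,decoy_score_law Score distributions for genuine and
#'   spurious rows (defaults U\[30, 80\] and U\[0, 15\], so an Ion-Score-style
#'   threshold of 20 separates them cleanly).
#' @param decoy_fraction Fraction of emitted rows that are spurious random
#'   substrings of real proteins, in \[0, 1).
#' @param seed Integer seed or `NULL`.
#' @return An `ident_sim_config` object.
#' @export
ident_sim_config <- function(detect_len = c(5L, 40L),
                             true_score_law = score_uniform(30, 80),
                             decoy_score_law = score_uniform(0, 15),
                             decoy_fraction = 0,
                             seed = NULL) {
  stopifnot(length(detect_len) == 2L, detect_len[1] >= 1,
            detect_len[2] >= detect_len[1],
            decoy_fraction >= 0, decoy_fraction < 1)
  structure(list(detect_len = as.integer(detect_len),
                 true_score_law = true_score_law,
                 decoy_score_law = decoy_score_law,
                 decoy_fraction = decoy_fraction,
                 seed = seed),
            class = "ident_sim_config")
}

#' Simulate a post-search identification table
#'
#' Digests every protein with the rule, keeps fragments inside the
#' detectability window, attaches 1-based inclusive coordinates and scores
#' from the true-hit law, and optionally mixes in decoy rows: random
#' substrings of the real proteins (so coordinate consistency still holds)
#' carrying decoy-law scores. The ground-truth cut list records every
#' realized cleavage, whether or not its flanking fragments were emitted.
#'
#' @param proteome An [Biostrings::AAStringSet] or named character vector.
#' @param rule A [protease_rule()].
#' @param cfg An [ident_sim_config()].
#' @return List with `ids` (data.frame: accession, protein_sequence,
#'   peptide_sequence, start, end, score, is_decoy) and `truth` (data.frame:
#'   accession, position).
#' @export
simulate_identifications <- function(proteome, rule,
                                     cfg = ident_sim_config()) {
  stopifnot(inherits(rule, "protease_rule"), inherits(cfg, "ident_sim_config"))
  seqs <- as_protein_set(proteome)
  with_seed(cfg$seed, {
    per <- lapply(seq_along(seqs), function(i) {
      d <- digest_protein(seqs[[i]], rule, seed = NULL)
      keep <- nchar(d$peptides) >= cfg$detect_len[1] &
        nchar(d$peptides) <= cfg$detect_len[2]
      list(
        ids = data.frame(
          accession = rep(names(seqs)[i], sum(keep)),
          peptide_sequence = d$peptides[keep],
          start = d$starts[keep], end = d$ends[keep],
          stringsAsFactors = FALSE),
        truth = data.frame(
          accession = rep(names(seqs)[i], length(d$cuts)),
          position = d$cuts, stringsAsFactors = FALSE)
      )
    })
    ids <- do.call(rbind, lapply(per, `[[`, "ids"))
    truth <- do.call(rbind, lapply(per, `[[`, "truth"))
    ids$score <- sample_scores(cfg$true_score_law, nrow(ids))
    ids$is_decoy <- rep(FALSE, nrow(ids))

    n_decoy <- round(nrow(ids) * cfg$decoy_fraction / (1 - cfg$decoy_fraction))
    if (n_decoy > 0) {
      lens <- nchar(seqs)
      ok <- which(lens >= cfg$detect_len[1])
      pick <- sample(ok, n_decoy, replace = TRUE)
      dl <- vapply(pick, function(i) {
        sample(seq(cfg$detect_len[1], min(cfg$detect_len[2], lens[i])), 1L)
      }, integer(1))
      dstart <- vapply(seq_len(n_decoy), function(k) {
        sample(seq_len(lens[pick[k]] - dl[k] + 1L), 1L)
      }, integer(1))
      decoys <- data.frame(
        accession = names(seqs)[pick],
        peptide_sequence = substring(seqs[pick], dstart, dstart + dl - 1L),
        start = dstart, end = dstart + dl - 1L,
        score = sample_scores(cfg$decoy_score_law, n_decoy),
        is_decoy = TRUE, stringsAsFactors = FALSE)
      ids <- rbind(ids, decoys)
    }
    ids$protein_sequence <- unname(seqs[ids$accession])
    ids <- ids[, c("accession", "protein_sequence", "peptide_sequence",
                   "start", "end", "score", "is_decoy")]
    rownames(ids) <- NULL
    rownames(truth) <- NULL
    list(ids = ids, truth = truth)
  })
}
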