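# Independent brute-force oracles and shared fixtures. Every oracle here is
# written as a plain loop over the raw inputs so it shares no code path with
# the package implementation it checks.

AA <- aa_alphabet()

# Residue x subsite tally by explicit per-window, per-slot iteration.
oracle_count_matrix <- function(window_strings, n_subsites = 11L) {
  counts <- matrix(0L, nrow = 20, ncol = n_subsites,
                   dimnames = list(AA, subsite_names(n_subsites - 5L, 5L)))
  for (w in window_strings) {
    for (s in seq_len(n_subsites)) {
      ch <- substr(w, s, s)
      if (ch %in% AA) counts[ch, s] <- counts[ch, s] + 1L
    }
  }
  counts
}

# P2-P1 pair tally (slots 5 and 6 of an 11-wide window).
oracle_pair_counts <- function(window_strings) {
  counts <- matrix(0L, 20, 20, dimnames = list(AA, AA))
  for (w in window_strings) {
    a <- substr(w, 5, 5)
    b <- substr(w, 6, 6)
    if (a %in% AA && b %in% AA) counts[a, b] <- counts[a, b] + 1L
  }
  counts
}

# Residue and ordered-dipeptide frequencies by explicit iteration.
oracle_background <- function(seqs) {
  res <- setNames(numeric(20), AA)
  pair <- matrix(0, 20, 20, dimnames = list(AA, AA))
  for (s in seqs) {
    ch <- strsplit(s, "")[[1]]
    for (k in seq_along(ch)) {
      if (ch[k] %in% AA) res[ch[k]] <- res[ch[k]] + 1
      if (k > 1 && ch[k - 1] %in% AA && ch[k] %in% AA) {
        pair[ch[k - 1], ch[k]] <- pair[ch[k - 1], ch[k]] + 1
      }
    }
  }
  list(residue_freq = res / sum(res), dipeptide_freq = pair / sum(pair))
}

oracle_missed <- function(peptide, residues) {
  ch <- strsplit(peptide, "")[[1]]
  n <- 0L
  for (k in seq_len(length(ch) - 1L)) {
    if (ch[k] %in% residues) n <- n + 1L
  }
  n
}

# Score filter + max-score dedupe by explicit iteration.
oracle_filter <- function(records, min_score, dedupe) {
  keep <- records[records$score >= min_score, , drop = FALSE]
  if (!dedupe) return(keep)
  out <- keep[0, , drop = FALSE]
  for (pep in sort(unique(keep$peptide_sequence))) {
    sub <- keep[keep$peptide_sequence == pep, , drop = FALSE]
    out <- rbind(out, sub[which.max(sub$score), , drop = FALSE])
  }
  out
}

# Small simulated dataset shared across tests: proteome + digest + windows.
make_sim <- function(seed, n_proteins = 60, rule = protease_rule(c(G = 0.9, K = 0.5)),
                     cfg = ident_sim_config(seed = seed + 1000L)) {
  proteome <- generate_proteome(
    proteome_spec(n_proteins, length_lognormal(), uniform_composition(),
                  seed = seed))
  sim <- simulate_identifications(proteome, rule, cfg)
  filtered <- apply_filters(sim$ids)
  sites <- extract_sites(filtered)
  windows <- extract_windows(sites, proteome)
  list(proteome = proteome, sim = sim, filtered = filtered,
       sites = sites, windows = windows)
}

# Identification records as a plain data.frame, for handmade fixtures.
make_records <- function(protein, peptides, starts, ends, scores,
                         accession = "P1") {
  data.frame(accession = accession, protein_sequence = protein,
             peptide_sequence = peptides, start = starts, end = ends,
             score = scores, stringsAsFactors = FALSE)
}
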