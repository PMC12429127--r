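---
title: "Profiling protease cleavage-site specificity from peptide identifications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling protease cleavage-site specificity from peptide identifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleavemap)
```

## The problem

A protease's substrate specificity is usually summarized by which residues
it tolerates around the scissile bond. In shotgun-proteomics specificity
profiling, a complex protein mixture is digested with the enzyme of
interest, the resulting peptides are identified by LC-MS/MS database
search, and each confidently identified peptide terminus is read back as
evidence of a cleavage event in its parent protein. Aggregating thousands
of such events yields a position-specific picture of the enzyme's subsite
preferences.

`cleavemap` implements that aggregation path end to end: confidence
filtering of identifications, cleavage-site inference from peptide
boundaries, fixed-window extraction in Schechter–Berger coordinates,
background-normalized enrichment statistics, motif analysis, and length /
missed-cleavage summaries. Because real specificity datasets require an
instrument and a search engine, the package also ships a generative
digestion simulator whose planted specificity the pipeline must recover —
the main correctness argument for the whole chain.

## Subsite coordinates and site inference

Residues flanking a cleaved bond are labelled P6..P1 on the N-terminal
side (P1 adjacent to the scissile bond) and P1'..P5' on the C-terminal
side; the enzyme cleaves between P1 and P1'. "Cleaving after glycine"
therefore means G at P1.

From a peptide at 1-based inclusive coordinates `[start, end]` in its
parent protein, `extract_sites()` infers:

* an **N-boundary site** at `start - 1` — the residue before the peptide
  was the P1 of the cut that created the peptide's N-terminus. No site is
  inferred when the peptide begins the protein, nor when `start == 2` with
  methionine at position 1: that N-terminus more likely reflects
  co-translational initiator-Met removal than proteolysis. A methionine
  anywhere else before a peptide is a legitimate P1 — the exclusion
  targets the initiator position only, since Met specificity itself can be
  biologically real.
* a **C-boundary site** at `end`, unless the peptide runs to the
  protein's final residue (a chain terminus is not a cleavage product).

Each unique `(accession, position)` pair counts once, whichever and
however many peptide boundaries support it. `extract_windows()` then cuts
a fixed window around each site. The default layout is **six unprimed and
five primed subsites** (P6..P5', width 11): the subsite enumeration and
the heatmap axes this layout supports include a P6 column, and that
enumerated form is taken as authoritative. Out-of-range subsites are
padded with `'-'`; padding is absence of data, so padded slots never enter
any counting denominator.

## The specificity model

`build_matrix()` tallies windows into a 20 x 11 count matrix and converts
each subsite column to frequencies using that column's number of defined
(non-padded) observations as denominator, so every column sums to 1.

Raw frequencies confound enzyme preference with proteome composition —
rare residues look disfavoured merely because they are rare. Two
normalizations against a background composition `q` (either the identified
proteins themselves, via `background_from_proteins()`, or an external
table such as a Swiss-Prot composition snapshot, via
`read_background_tsv()`) address this:

* **ratio**: `f / q[r]` — 1 means "as expected from composition alone";
* **z-score**: a one-sample binomial-proportion statistic,

  $$Z_{rs} = \frac{f_{rs} - q_r}{\sqrt{q_r (1 - q_r) / n_s}},$$

  where $n_s$ is the subsite's defined-observation count. This is the
  deviation of the observed frequency from its background expectation in
  standard-deviation units under the null that residues at subsite $s$
  are drawn i.i.d. with probability $q_r$.

The binomial-proportion form was an open design choice: a z-score is
defined only relative to a null model, and several are defensible
(bootstrap over sites, per-row standardization of the ratio layer, ...).
We chose the one-sample proportion test because it uses exactly the
quantities the pipeline already defines (observed frequency, background
frequency, site count), has an explicit sampling model, and is the
standard statistic behind residue-enrichment heatmaps. Published z values
from other tools are generally not comparable across choices of null, so
cross-study comparison should be done on frequencies or ratios.
Degenerate backgrounds ($q \in \{0, 1\}$) yield Z = 0 when the
observation equals the expectation and signed infinity otherwise; a
residue *observed* at a subsite while absent from the background is an
error, since no normalization can be meaningful there.

`compare_compositions()` (Pearson + Spearman over the 20 paired residue
frequencies) quantifies how closely an experimental composition tracks a
database snapshot — the usual justification for normalizing to the
identified-protein set.

## Motif statistics

Pair analysis (`pair_counts()`, `pair_zscores()`) tallies the ordered
(P2, P1) residue pair of every window with both slots defined and scores
it against the background's *ordered adjacent dipeptide* frequencies,
counted within each unique identified protein and never across protein
boundaries. The same binomial-proportion form is used with $n$ = number
of pairs, for internal consistency with the single-residue statistic.

`conditional_p1_distribution()` splits windows by the residue at P2
(proline by default) and compares P1 frequency vectors between the two
partitions — the direct test of whether a P2 preference restricts the
residues accepted at the scissile bond.

`triplet_patterns()` counts concrete P3-P2-P1 triples and user-declared
generalized patterns such as `"G-X-[LMP]"` (`X` = any residue, brackets =
residue class). Site-level matrices deduplicate by `(accession,
position)`, whereas triplet/pair motif counting follows the
unique-peptide convention — the caller controls which window set goes in,
and the two dedupe keys are deliberately distinct.

## Length and missed-cleavage statistics

`length_summary()` works on unique peptide sequences: mean, sample (n−1)
standard deviation, median (mean of central pair for even counts), mode
(ties to the smallest length), a full per-length percentage histogram,
and the five named bins 5–8, 9–12, 13–16, 17–20, >21. The bin labelled
">21" is inclusive of 21 so that the bins partition all lengths ≥ 5;
shorter peptides stay in the histogram but are reported separately from
the named bins. The sample-SD and tie-break conventions are our choices
where the summary-statistic literature leaves them implicit.

A **missed cleavage** is an internal peptide residue matching the
declared cleavage-residue set: positions 1..len−1 are eligible, the final
residue never is (it is the realized cut or the protein terminus).
`missed_cleavage_report()` reports the per-peptide counts and the
fraction of unique peptides with at least one. Note that per-peptide
counts are monotone when the residue set grows, but the
fraction-of-peptides statistic is not — adding a residue changes the
peptide population a real digest produces.

## Logos and reports

`percent_difference_logo()` scores each cell as the percentage-point
difference between observed subsite frequency and a reference
composition, with a two-sided exact binomial test per cell and masking at
`p >= alpha` (default 0.05, no multiple-testing correction; `alpha >= 1`
disables masking). The exact test is conservative and dependency-free; we
do not claim equivalence with any specific logo web tool's internal
sampling procedure, only the percent-difference scale. Because both the
observed and reference vectors sum to 1, each subsite's differences sum
to 0 — a conservation law the tests assert.

`render_heatmap()` draws any layer (no clustering, diverging palette
centred at 0 for z-scores), `render_logo()` draws the masked differences
as stacked letters, and `run_report()` writes all artifacts plus a
`manifest.json` with MD5 checksums, so a rerun with identical inputs is
verifiable byte-for-byte on the data artifacts.

## The digestion simulator

`generate_proteome()` draws i.i.d. residues under a declared composition
with lengths from a fixed, uniform, or truncated-lognormal law. The
lognormal default (meanlog 5.8, sdlog 0.45, truncated to 50–2000) gives a
median around 330 residues, a realistic protein-length scale; the
`initiator_met` flag forces residue 1 to M, matching translated
sequences.

`digest_protein()` cuts each internal bond with an independent Bernoulli
draw at probability `p1_prob[P1] * p2_modifier[P2]` (clamped to [0, 1]),
reading P2 from the original sequence, not from fragments; the initiator
Met is never a cut P1, so the site-inference exclusion rule has a clean
ground truth. Left-to-right independent draws are the simplest generative
model consistent with per-site cut frequencies; they are a stand-in for
real protease kinetics, not a claim about any particular enzyme's
mechanism.

`simulate_identifications()` emits fragments inside a detectability
window (default 5–40 residues, the usual LC-MS/MS identification range)
with true-hit scores (default U[30, 80]) and, optionally, decoy rows with
decoy scores (default U[0, 15]) — so a score threshold of 20 separates
the populations and the confidence filter is exercised realistically.
Decoys are random substrings of real proteins rather than random strings,
so they remain coordinate-consistent and are only removable by score.

What the simulator does *not* emulate: spectrum-level effects (ionization
efficiency, missed identifications correlated with sequence), homology
between proteins, post-translational modifications, and non-independent
cut decisions. Passing the recovery tests therefore shows the *analysis
chain* is correct, not that any real enzyme satisfies the Bernoulli
model.

## Validation strategy and problem sizes

Every counting operation is checked against an independent brute-force
recount, and the pipeline is checked end to end by parameter recovery:
simulate 300 lognormal-length proteins with uniform composition, digest
with a planted rule (e.g. `{G: 0.9, K: 0.5}`), and require the top two P1
z-scores to identify the planted residues in order across a 20-seed grid;
likewise a planted P2 proline modifier must surface in the top ten pair
z-scores. These sizes give several thousand cleavage events per run —
large enough that recovery is essentially deterministic, small enough
that the whole suite runs in well under a minute.

## Worked example

```{r example}
rule <- protease_rule(c(G = 0.9, K = 0.5), name = "Gly/Lys protease")
proteome <- generate_proteome(proteome_spec(100, seed = 7))
sim <- simulate_identifications(proteome, rule,
                                ident_sim_config(seed = 8))
records <- apply_filters(sim$ids, min_ion_score = 20)
windows <- extract_windows(extract_sites(records), proteome)
bg <- background_from_proteins(proteome)
m <- zscore_matrix(normalize_matrix(build_matrix(windows), bg), bg)
round(sort(m$zscore[, "P1"], decreasing = TRUE)[1:3], 1)

peps <- unique(records$peptide_sequence)
length_summary(peps)
missed_cleavage_report(peps, c("G", "K"))
```

## Known limitations

* Peptide-to-protein ambiguity is resolved by the reported parent only;
  shared peptides are not re-assigned across proteins or isoforms.
* The z-score null treats sites as independent; overlapping windows from
  adjacent cuts violate this mildly at high cut densities.
* Heatmap/logo rendering is deterministic in content but not intended as
  a pixel-level reproduction of any external visualization tool.
* External background tables are taken at face value; database
  composition drifts between releases, so record the snapshot you used.
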