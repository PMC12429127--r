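# windows with chosen P3/P2/P1 content, built directly as 11-mers
fake_windows <- function(p3, p2, p1) {
  win <- paste0("AAA", p3, p2, p1, "AAAAA")
  structure(data.frame(accession = "P1", position = seq_along(win) + 10,
                       p1 = p1, window = win, stringsAsFactors = FALSE),
            upstream = 6L, downstream = 5L, subsites = subsite_names())
}

test_that("pair counts tally the P2/P1 slots and match a brute-force oracle", {
  w <- fake_windows("G", "P", "F")
  pc <- pair_counts(w)
  expect_equal(unname(pc$counts["P", "F"]), 1)
  expect_equal(pc$n_pairs, 1)
  expect_equal(sum(pc$counts), 1)

  # a deterministic {K} protease concentrates the P1 marginal on K
  sim_k <- make_sim(12, n_proteins = 30, rule = protease_rule(c(K = 1)))
  pck <- pair_counts(sim_k$windows)
  expect_equal(sum(pck$counts[, "K"]), pck$n_pairs)

  sim <- make_sim(13, n_proteins = 50)
  got <- pair_counts(sim$windows)
  expect_identical(unname(got$counts), unname(oracle_pair_counts(sim$windows$window)))
})

test_that("pair marginals agree with the specificity matrix P1 column", {
  sim <- make_sim(14, n_proteins = 50)
  pc <- pair_counts(sim$windows)
  m <- build_matrix(sim$windows)
  # restrict the matrix tally to windows whose P2 slot is defined
  chars <- t(vapply(strsplit(sim$windows$window, ""), identity, character(11)))
  defined_p2 <- chars[, 5] %in% aa_alphabet()
  p1_counts <- table(factor(chars[defined_p2, 6], levels = aa_alphabet()))
  expect_equal(unname(colSums(pc$counts)), as.vector(p1_counts))
  # and without the restriction the P1 column dominates the marginal
  expect_true(all(colSums(pc$counts) <= m$counts[, "P1"] + 1e-9))
})

test_that("pair z-scores follow the stated binomial form", {
  # p_hat = 0.05, q = 0.01, n = 1000 -> Z = 12.71
  counts <- matrix(0, 20, 20, dimnames = list(aa_alphabet(), aa_alphabet()))
  counts["I", "M"] <- 50
  pairs <- structure(list(counts = counts, n_pairs = 1000),
                     class = "pair_matrix")
  q <- matrix((1 - 0.01) / 399, 20, 20, dimnames = dimnames(counts))
  q["I", "M"] <- 0.01
  bg <- background_composition(uniform_composition(), dipeptide_freq = q)
  z <- pair_zscores(pairs, bg)$zscore
  expect_equal(round(unname(z["I", "M"]), 2), 12.71)

  # p_hat = q everywhere -> all Z = 0
  pairs_u <- structure(list(counts = matrix(10, 20, 20,
                                            dimnames = dimnames(counts)),
                            n_pairs = 4000), class = "pair_matrix")
  bg_u <- background_composition(
    uniform_composition(),
    dipeptide_freq = matrix(1 / 400, 20, 20, dimnames = dimnames(counts)))
  expect_true(all(abs(pair_zscores(pairs_u, bg_u)$zscore) < 1e-12))

  # observed pair with zero background frequency is fatal and names the pair
  q0 <- q
  q0["I", "M"] <- 0
  q0 <- q0 / sum(q0)
  bg0 <- background_composition(uniform_composition(), dipeptide_freq = q0)
  expect_error(pair_zscores(pairs, bg0), "I-M")
})

test_that("a P2 proline modifier surfaces in the top pair z-scores", {
  rule <- protease_rule(c(F = 0.2, M = 0.2, L = 0.2), p2_modifier = c(P = 5))
  sim <- make_sim(15, n_proteins = 150, rule = rule)
  bg <- background_from_proteins(sim$proteome)
  pz <- pair_zscores(pair_counts(sim$windows), bg)
  top10 <- head(top_pairs(pz, "zscore"), 10)
  top_keys <- paste(top10$p2, top10$p1)
  expect_true(all(c("P F", "P M", "P L") %in% top_keys))
})

test_that("conditional P1 distributions partition defined-P2 windows", {
  w <- rbind(fake_windows("G", "P", "F"), fake_windows("G", "P", "M"))
  attributes(w)[c("upstream", "downstream", "subsites")] <-
    list(6L, 5L, subsite_names())
  all_p <- conditional_p1_distribution(w, "P")
  expect_true(all_p$without$insufficient)
  expect_equal(sum(all_p$without$freq), 0)
  expect_equal(all_p$with$n, 2)

  sim <- make_sim(16, n_proteins = 50)
  cond <- conditional_p1_distribution(sim$windows, "P")
  expect_equal(cond$with$n + cond$without$n, cond$n_defined_p2)
  # brute-force recount of both partitions
  chars <- t(vapply(strsplit(sim$windows$window, ""), identity, character(11)))
  def <- chars[, 5] %in% aa_alphabet() & chars[, 6] %in% aa_alphabet()
  for (grp in list(c(TRUE, "with"), c(FALSE, "without"))) {
    sel <- def & ((chars[, 5] == "P") == as.logical(grp[1]))
    want <- table(factor(chars[sel, 6], levels = aa_alphabet())) / sum(sel)
    expect_equal(unname(cond[[grp[2]]]$freq), as.vector(want),
                 tolerance = 1e-12)
  }
})

test_that("triplet patterns count concrete and generalized motifs consistently", {
  w <- rbind(fake_windows("G", "A", "L"), fake_windows("G", "P", "M"),
             fake_windows("G", "T", "P"))
  attributes(w)[c("upstream", "downstream", "subsites")] <-
    list(6L, 5L, subsite_names())
  pats <- triplet_patterns(w, patterns = "G-X-[LMP]")
  expect_equal(pats$count[pats$pattern == "G-X-[LMP]"], 3L)
  expect_equal(pats$count[pats$pattern == "G-A-L"], 1L)

  # no matching window -> count 0
  none <- triplet_patterns(w, patterns = "W-W-W")
  expect_equal(none$count[none$pattern == "W-W-W"], 0L)

  # generalized count equals the sum of matching concrete triples,
  # and widening the class is monotone
  sim <- make_sim(17, n_proteins = 40)
  tp <- triplet_patterns(sim$windows, patterns = c("G-X-[LM]", "G-X-[LMP]"))
  concrete <- tp[!tp$generalized, ]
  expand <- function(cls) {
    sum(concrete$count[grepl(paste0("^G-[A-Z]-[", cls, "]$"),
                             concrete$pattern)])
  }
  expect_equal(tp$count[tp$pattern == "G-X-[LM]"], expand("LM"))
  expect_equal(tp$count[tp$pattern == "G-X-[LMP]"], expand("LMP"))
  expect_gte(tp$count[tp$pattern == "G-X-[LMP]"],
             tp$count[tp$pattern == "G-X-[LM]"])

  # ranking is by decreasing count with alphabetical tie-break
  expect_true(all(diff(tp$count) <= 0))
})
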