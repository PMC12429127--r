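test_that("a single window yields a one-hot P1 frequency column", {
  w <- extract_windows(
    data.frame(accession = "P1", position = 4, p1 = "K",
               origin = "n_boundary"), c(P1 = "MAGKLSTRW"))
  m <- build_matrix(w)
  expect_equal(unname(m$frequency["K", "P1"]), 1)
  expect_equal(sum(m$frequency[, "P1"]), 1)
  # two left slots are padded for a site at position 4 of a 9-mer
  expect_equal(unname(m$n_defined), c(0, 0, rep(1, 9)))
})

test_that("count and frequency layers equal a brute-force tally", {
  sim <- make_sim(7, n_proteins = 60)
  m <- build_matrix(sim$windows)
  want <- oracle_count_matrix(sim$windows$window)
  expect_identical(unname(m$counts), unname(matrix(as.numeric(want), 20, 11)))
  expect_equal(m$n_defined, colSums(want), ignore_attr = TRUE)
  expect_true(all(abs(colSums(m$frequency) - 1) < 1e-9))
})

test_that("background composition matches explicit recounts", {
  bg1 <- background_from_proteins(c(X1 = "AAAA"))
  expect_equal(unname(bg1$residue_freq["A"]), 1)
  expect_equal(unname(bg1$dipeptide_freq["A", "A"]), 1)

  bg2 <- background_from_proteins(c(X1 = "AG", X2 = "GA"))
  expect_equal(unname(bg2$residue_freq[c("A", "G")]), c(0.5, 0.5))
  expect_equal(unname(bg2$dipeptide_freq["A", "G"]), 0.5)
  expect_equal(unname(bg2$dipeptide_freq["G", "A"]), 0.5)

  pr <- generate_proteome(proteome_spec(50, length_uniform(30, 120), seed = 8))
  bg <- background_from_proteins(pr)
  want <- oracle_background(as.character(pr))
  expect_equal(bg$residue_freq, want$residue_freq, tolerance = 1e-12)
  expect_equal(bg$dipeptide_freq, want$dipeptide_freq, tolerance = 1e-12)
  expect_equal(sum(bg$residue_freq), 1, tolerance = 1e-9)
  expect_equal(sum(bg$dipeptide_freq), 1, tolerance = 1e-9)
})

test_that("normalization divides by background frequency and flags zeros", {
  counts <- matrix(0, 20, 11, dimnames = list(aa_alphabet(), subsite_names()))
  counts["G", "P1"] <- 345
  m <- specificity_matrix(counts, n_defined = rep(1000, 11))
  # direct arithmetic on a stated input pair
  bg_named <- background_composition(
    setNames(c(0.0707, rep((1 - 0.0707) / 19, 19)),
             c("G", setdiff(aa_alphabet(), "G"))))
  mm <- normalize_matrix(m, bg_named)
  expect_equal(round(unname(mm$ratio["G", "P1"]), 2), 4.88)

  # frequency identical to background -> all ratios 1 at observed residues
  n <- 2000
  counts_u <- matrix(rep(n * 0.05, 220), 20, 11,
                     dimnames = list(aa_alphabet(), subsite_names()))
  mu <- specificity_matrix(counts_u)
  bu <- background_composition(uniform_composition())
  expect_true(all(abs(normalize_matrix(mu, bu)$ratio - 1) < 1e-12))

  # observed residue with zero background frequency is fatal
  bg_zero <- background_composition(
    setNames(c(0, rep(1 / 19, 19)), c("G", setdiff(aa_alphabet(), "G"))))
  expect_error(normalize_matrix(m, bg_zero), "G")
})

test_that("z-scores follow the binomial-proportion formula", {
  # f = q everywhere -> all Z = 0
  counts_u <- matrix(rep(100 * 0.05, 220), 20, 11,
                     dimnames = list(aa_alphabet(), subsite_names()))
  mu <- specificity_matrix(counts_u)
  bu <- background_composition(uniform_composition())
  expect_true(all(abs(zscore_matrix(mu, bu)$zscore) < 1e-12))

  # f = 0.30, q = 0.20, n = 100 -> Z = 2.5
  counts <- matrix(0, 20, 11, dimnames = list(aa_alphabet(), subsite_names()))
  counts["L", "P1"] <- 30
  m <- specificity_matrix(counts, n_defined = rep(100, 11))
  bg <- background_composition(
    setNames(c(0.2, rep(0.8 / 19, 19)), c("L", setdiff(aa_alphabet(), "L"))))
  z <- zscore_matrix(m, bg)$zscore
  expect_equal(unname(z["L", "P1"]), 2.5, tolerance = 1e-12)

  # a residue-only protease puts its residue at the top of the matrix
  sim <- make_sim(9, n_proteins = 80, rule = protease_rule(c(G = 1)))
  mm <- zscore_matrix(build_matrix(sim$windows),
                      background_from_proteins(sim$proteome))
  expect_equal(which(mm$zscore == max(mm$zscore), arr.ind = TRUE)[1, ],
               c(row = which(aa_alphabet() == "G"), col = 6))
})

test_that("z-scoring and normalization are equivariant under residue relabeling", {
  sim <- make_sim(10, n_proteins = 30)
  bg <- background_from_proteins(sim$proteome)
  m <- zscore_matrix(normalize_matrix(build_matrix(sim$windows), bg), bg)

  set.seed(123)
  perm <- sample(20)
  relabel <- setNames(aa_alphabet()[perm], aa_alphabet())
  swap <- function(s) {
    paste(ifelse(strsplit(s, "")[[1]] == "-", "-",
                 relabel[strsplit(s, "")[[1]]]), collapse = "")
  }
  w2 <- sim$windows
  w2$window <- vapply(w2$window, swap, character(1), USE.NAMES = FALSE)
  w2$p1 <- unname(relabel[sim$windows$p1])
  attributes(w2)[c("upstream", "downstream", "subsites")] <-
    attributes(sim$windows)[c("upstream", "downstream", "subsites")]
  rf2 <- setNames(bg$residue_freq, relabel[names(bg$residue_freq)])
  bg2 <- background_composition(rf2[aa_alphabet()])
  bg1 <- background_composition(bg$residue_freq)
  m2 <- zscore_matrix(normalize_matrix(build_matrix(w2), bg2), bg2)
  expect_equal(m2$zscore[relabel[aa_alphabet()], ],
               zscore_matrix(build_matrix(sim$windows), bg1)$zscore,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("composition correlations behave like the textbook formulas", {
  bu <- background_composition(uniform_composition())
  set.seed(17)
  x <- runif(20)
  a <- background_composition(setNames(x / sum(x), aa_alphabet()))
  expect_equal(compare_compositions(a, a), list(pearson = 1, spearman = 1))

  # reversed ranking -> spearman -1
  xs <- sort(x)
  b_rev <- background_composition(setNames(rev(xs) / sum(xs), aa_alphabet()))
  b_fwd <- background_composition(setNames(xs / sum(xs), aa_alphabet()))
  expect_equal(compare_compositions(b_fwd, b_rev)$spearman, -1)

  # independent formula oracle on a random pair
  y <- runif(20)
  b <- background_composition(setNames(y / sum(y), aa_alphabet()))
  got <- compare_compositions(a, b)
  xf <- a$residue_freq
  yf <- b$residue_freq
  pearson_oracle <- sum((xf - mean(xf)) * (yf - mean(yf))) /
    sqrt(sum((xf - mean(xf))^2) * sum((yf - mean(yf))^2))
  rx <- rank(xf)
  ry <- rank(yf)
  spearman_oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(got$pearson, pearson_oracle, tolerance = 1e-12)
  expect_equal(got$spearman, spearman_oracle, tolerance = 1e-12)

  # zero variance -> undefined
  expect_warning(und <- compare_compositions(bu, a), "zero variance")
  expect_true(is.na(und$pearson))
})

test_that("matrix and background TSV exports round-trip to 1e-9", {
  sim <- make_sim(11, n_proteins = 20)
  bg <- background_from_proteins(sim$proteome)
  m <- zscore_matrix(build_matrix(sim$windows), bg)
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  for (layer in c("counts", "frequency", "zscore")) {
    write_matrix_tsv(m, layer, tmp)
    expect_equal(read_matrix_tsv(tmp), m[[layer]], tolerance = 1e-9)
  }
  write_background_tsv(bg, tmp)
  expect_equal(read_background_tsv(tmp)$residue_freq, bg$residue_freq,
               tolerance = 1e-9)
})
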