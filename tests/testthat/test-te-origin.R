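test_that("local_align basics: identity, strand handling, symmetry", {
  s <- "ACGTACGTACGTACGTACGTACGTACGTAC"
  al <- local_align(s, s)
  expect_equal(al$identity, 1)
  expect_equal(al$score, 2 * nchar(s))
  expect_equal(c(al$a_start, al$a_end), c(1L, nchar(s)))
  # non-palindromic sequence vs its reverse complement: chance alignment
  set.seed(14)
  a <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
             collapse = "")
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(a, "")[[1]]),
                                     collapse = ""))
  # only a chance alignment remains on the opposite strand
  expect_lt(local_align(a, rc)$score, local_align(a, a)$score)
  # score symmetry
  for (i in 1:10) {
    x <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
               collapse = "")
    y <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
               collapse = "")
    expect_equal(local_align(x, y)$score, local_align(y, x)$score)
  }
  expect_error(local_align("", "ACGT"), "nonempty")
})

test_that("local_align scores equal an independent DP oracle", {
  # Biostrings' affine-gap local aligner with identical parameters
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  set.seed(15)
  for (i in 1:50) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(5:25, 1),
                      replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(5:25, 1),
                      replace = TRUE), collapse = "")
    want <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
      substitutionMatrix = mat, gapOpening = 5, gapExtension = 2))
    expect_equal(local_align(a, b)$score, max(0, want),
                 info = paste(a, b))
  }
})

test_that("screen_te_sources recovers the simulated ancestor", {
  cfg <- sim_config(rng_seed = 77, n_species = 2, n_clusters = 2,
                    mirnas_per_cluster = 2)
  fam <- simulate_mirna_family(cfg)
  decoy <- setNames(random_rna_str(120), "decoy")
  lib <- c(ancestor = fam$ancestor_te, decoy = decoy)
  res <- screen_te_sources(lib, fam$loci)
  expect_equal(res$ranking$te[1], "ancestor")
  expect_true(res$ranking$all_species[res$ranking$te == "ancestor"])
  expect_equal(sum(res$hits$te == "decoy"), 0L)
  expect_true(all(res$hits$identity >= 0.94))
  # every descendant locus is hit at the 94% threshold (3% divergence)
  expect_equal(sort(unique(res$hits$locus)),
               sort(unlist(lapply(fam$loci, names), use.names = FALSE)))
  # perfect-identity threshold on a diverged family: no hits
  strict <- screen_te_sources(c(ancestor = fam$ancestor_te), fam$loci,
                              identity_min = 1.0)
  expect_equal(nrow(strict$hits), 0L)
  expect_error(screen_te_sources(character(), fam$loci), "empty")
})

test_that("hairpin_check flags inverted repeats and rejects homopolymers", {
  set.seed(16)
  arm <- random_rna_str(30)
  hp <- paste0(arm, "GAAA", revcomp_rna(arm))
  r <- hairpin_check(hp, window = nchar(hp))
  expect_true(r$is_hairpin)
  expect_equal(r$stem_pairs, 30L)
  expect_gte(r$loop_length, 3L)
  r2 <- hairpin_check(strrep("A", 100))
  expect_false(r2$is_hairpin)
  expect_equal(r2$stem_pairs, 0L)
  expect_error(hairpin_check("ACGU"), "too short")
})

test_that("Nussinov pair counts equal the exhaustive recursion", {
  set.seed(17)
  for (i in 1:25) {
    s <- random_rna_str(sample(10:30, 1))
    M <- mirtekit:::nussinov_matrix(strsplit(s, "")[[1]], min_loop = 3L)
    expect_equal(M[1, nchar(s)], oracle_nussinov(s, min_loop = 3L),
                 info = s)
  }
})

test_that("hairpin detection collapses on dinucleotide-shuffled hairpins", {
  set.seed(18)
  hits_true <- 0; hits_shuf <- 0
  for (i in 1:10) {
    arm <- random_rna_str(25)
    hp <- paste0(arm, "GAAA", revcomp_rna(arm))
    if (hairpin_check(hp, window = nchar(hp), min_pairs = 18)$is_hairpin)
      hits_true <- hits_true + 1
    shuf <- paste(sample(strsplit(hp, "")[[1]]), collapse = "")
    if (hairpin_check(shuf, window = nchar(shuf),
                      min_pairs = 18)$is_hairpin)
      hits_shuf <- hits_shuf + 1
  }
  expect_gt(hits_true, hits_shuf)
  expect_gte(hits_true, 9)
})

test_that("substitution_spectrum tallies against a column-wise oracle", {
  # member identical to consensus -> all-zero spectrum
  fam <- c(a = "ACGUACGU", b = "ACGUACGU", c = "ACGUACGU")
  expect_equal(sum(substitution_spectrum(fam)$counts), 0L)
  # pure U->C fixture
  fam2 <- c(a = "AUUUGG", b = "ACUUGG", c = "AUCUGG")
  sp2 <- substitution_spectrum(fam2)
  expect_equal(sp2$counts["U", "C"], 2L)
  expect_equal(sum(sp2$counts), 2L)
  # random mutation fixture vs independent counting, outgroup polarity
  set.seed(19)
  ref <- random_rna_str(60)
  mem <- vapply(1:5, function(i) {
    ch <- strsplit(ref, "")[[1]]
    idx <- sample(60, 8)
    for (p in idx) ch[p] <- sample(setdiff(c("A", "C", "G", "U"), ch[p]), 1)
    paste(ch, collapse = "")
  }, character(1))
  fam3 <- c(out = ref, setNames(mem, paste0("m", 1:5)))
  sp3 <- substitution_spectrum(fam3, "designated_outgroup", outgroup = "out")
  want <- matrix(0L, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                           c("A", "C", "G", "U")))
  rch <- strsplit(ref, "")[[1]]
  for (m in mem) {
    mch <- strsplit(m, "")[[1]]
    for (j in 1:60) {
      if (mch[j] != rch[j]) want[rch[j], mch[j]] <- want[rch[j], mch[j]] + 1L
    }
  }
  expect_equal(unname(sp3$counts), unname(want))
  expect_true(all(diag(sp3$counts) == 0))
  # unaligned input rejected
  expect_error(substitution_spectrum(c(a = "ACGU", b = "ACG")),
               "equal length")
})
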