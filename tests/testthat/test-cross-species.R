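fake_map <- function(targets, sites = NULL) {
  structure(list(sites = sites %||% data.frame(), targets = targets,
                 species = NA_character_), class = "target_map")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("shared_targets: identity orthology, identical maps -> 100%", {
  genes <- paste0("g", 1:10)
  omap <- data.frame(mouse = genes, human = genes, rat = genes,
                     stringsAsFactors = FALSE)
  tm <- fake_map(list(mir1 = genes))
  res <- shared_targets(genes, list(mouse = tm, human = tm, rat = tm),
                        omap, "mouse")
  expect_equal(res$pct_shared_all, 100)
  expect_equal(unname(res$venn["mouse&human&rat"]), 10L)
  empty <- shared_targets(character(), list(mouse = tm, human = tm),
                          omap, "mouse")
  expect_equal(empty$n_shared_all, 0L)
})

test_that("shared_targets venn equals the brute-force membership oracle", {
  set.seed(11)
  genes <- paste0("g", 1:100)
  omap <- data.frame(a = genes, b = paste0("b_", genes),
                     c = paste0("c_", genes), stringsAsFactors = FALSE)
  maps <- list(
    a = fake_map(list(m = sample(genes, 40))),
    b = fake_map(list(m = sample(omap$b, 50))),
    c = fake_map(list(m = sample(omap$c, 30))))
  res <- shared_targets(genes, maps, omap, "a")
  sets <- list(a = maps$a$targets$m,
               b = genes[omap$b %in% maps$b$targets$m],
               c = genes[omap$c %in% maps$c$targets$m])
  want <- table(factor(oracle_venn(genes, sets)))
  got <- res$venn
  expect_equal(sort(names(got)), sort(names(want)))
  expect_equal(as.integer(got[sort(names(got))]),
               as.integer(want[sort(names(got))]))
  # venn partition covers every reference gene exactly once
  expect_equal(sum(res$venn), length(genes))
})

test_that("unmapped genes are counted as unshared and reported", {
  omap <- data.frame(a = c("g1", "g2"), b = c("h1", "h2"),
                     stringsAsFactors = FALSE)
  maps <- list(a = fake_map(list(m = c("g1", "g2", "g3"))),
               b = fake_map(list(m = c("h1", "h2"))))
  res <- shared_targets(c("g1", "g2", "g3"), maps, omap, "a")
  expect_equal(res$unmapped, "g3")
  expect_false(res$membership["g3", "b"])
})

test_that("targets_per_mirna counts within the universe", {
  uni <- paste0("g", 1:50)
  tm <- fake_map(list(m1 = uni, m2 = uni, m3 = uni))
  res <- targets_per_mirna(tm, uni)
  expect_equal(res$n_targets, rep(50L, 3))
  expect_equal(attr(res, "mean"), 50)
  # absent miRNA gets a zero count, not an error
  tm2 <- fake_map(list(m1 = uni, m4 = character()))
  expect_equal(targets_per_mirna(tm2, uni)$n_targets, c(50L, 0L))
  expect_error(targets_per_mirna(tm, character()), "nonempty")
  # relabeling transcripts leaves the mean invariant
  relab <- fake_map(lapply(tm$targets, function(g) paste0("x_", g)))
  expect_equal(attr(targets_per_mirna(relab, paste0("x_", uni)), "mean"),
               attr(res, "mean"))
})

test_that("single-miRNA comparison is declined explicitly", {
  res <- compare_targets_per_mirna(c(5), c(4, 6))
  expect_equal(res$status, "insufficient groups")
  expect_true(is.na(res$p.value))
})

test_that("planted target-load difference is detected", {
  # species A miRNAs get systematically more targets than species B
  set.seed(5)
  reject <- 0
  for (rep in 1:20) {
    a <- rbinom(8, 100, 0.6)
    b <- rbinom(8, 100, 0.4)
    cmp <- compare_targets_per_mirna(a, b)
    if (!is.na(cmp$p.value) && cmp$p.value < 0.05 && cmp$mean_a > cmp$mean_b)
      reject <- reject + 1
  }
  expect_gte(reject, 18)
})

test_that("sites_per_transcript equals a brute-force tally", {
  set.seed(21)
  sites <- data.frame(
    mirna = sample(paste0("m", 1:4), 200, replace = TRUE),
    transcript = sample(paste0("t", 1:30), 200, replace = TRUE),
    start = 0L, end = 6L, site_class = "6mer", wobble_count = 0L,
    predictor_tier = "x", stringsAsFactors = FALSE)
  tm <- fake_map(list(), sites = sites)
  res <- sites_per_transcript(tm)
  for (tx in res$transcript) {
    expect_equal(res$n_sites[res$transcript == tx],
                 sum(sites$transcript == tx))
  }
  # one implanted site per target -> all counts 1
  s1 <- sites[!duplicated(sites$transcript), ]
  expect_true(all(sites_per_transcript(fake_map(list(), s1))$n_sites == 1L))
})

test_that("te_containing_transcripts matches the quadratic overlap oracle", {
  # containment and disjoint basics
  utr <- data.frame(chrom = "chr1", start = 100L, end = 300L,
                    transcript = "t1", stringsAsFactors = FALSE)
  te_in <- data.frame(chrom = "chr1", start = 150L, end = 180L,
                      name = "TEfam", stringsAsFactors = FALSE)
  expect_equal(te_containing_transcripts(utr, te_in, "TEfam")$transcripts,
               "t1")
  te_out <- data.frame(chrom = "chr1", start = 400L, end = 500L,
                       name = "TEfam", stringsAsFactors = FALSE)
  expect_equal(te_containing_transcripts(utr, te_out, "TEfam")$n, 0L)
  # random pairs against the O(n^2) oracle
  set.seed(33)
  utrs <- data.frame(chrom = sample(c("chr1", "chr2"), 200, replace = TRUE),
                     start = sample(0:5000, 200),
                     transcript = paste0("t", 1:200),
                     stringsAsFactors = FALSE)
  utrs$end <- utrs$start + sample(20:200, 200, replace = TRUE)
  tes <- data.frame(chrom = sample(c("chr1", "chr2"), 200, replace = TRUE),
                    start = sample(0:5000, 200),
                    name = "TEfam", stringsAsFactors = FALSE)
  tes$end <- tes$start + sample(20:200, 200, replace = TRUE)
  got <- te_containing_transcripts(utrs, tes, "TEfam")
  want <- utrs$transcript[oracle_overlap(utrs, tes)]
  expect_setequal(got$transcripts, want)
  # DET intersection bookkeeping
  res <- te_containing_transcripts(utrs, tes, "TEfam",
                                   det_pool = got$transcripts[1:3])
  expect_equal(res$n_in_det, 3L)
})

test_that("chromosome naming mismatch is reported", {
  utr <- data.frame(chrom = "chr1", start = 1L, end = 10L,
                    transcript = "t1", stringsAsFactors = FALSE)
  te <- data.frame(chrom = "1", start = 1L, end = 10L, name = "TEfam",
                   stringsAsFactors = FALSE)
  w <- capture_warnings(te_containing_transcripts(utr, te, "TEfam"))
  expect_true(any(grepl("chromosome", w)))
})
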