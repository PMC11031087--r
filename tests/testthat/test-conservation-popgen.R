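test_that("map_scores_to_utr follows block order and strand", {
  trk <- cons_track(data.frame(chrom = "chr1", start = 0:99, end = 1:100,
                               score = as.numeric(0:99)))
  # single-block plus strand: the genomic slice verbatim
  u <- utr_record("g1", seq = strrep("A", 10),
                  genomic_intervals = data.frame(chrom = "chr1",
                                                 start = 20L, end = 30L,
                                                 strand = "+"))
  expect_equal(map_scores_to_utr(trk, u), as.numeric(20:29))
  # minus strand: reversed slice, values unchanged
  um <- utr_record("g1", seq = strrep("A", 10),
                   genomic_intervals = data.frame(chrom = "chr1",
                                                  start = 20L, end = 30L,
                                                  strand = "-"))
  expect_equal(map_scores_to_utr(trk, um), as.numeric(29:20))
  # two blocks: manual concatenation of slices
  u2 <- utr_record("g2", seq = strrep("A", 15),
                   genomic_intervals = data.frame(
                     chrom = "chr1", start = c(10L, 50L),
                     end = c(20L, 55L), strand = "+"))
  expect_equal(map_scores_to_utr(trk, u2), as.numeric(c(10:19, 50:54)))
  # outside the track extent -> NA with warning
  u3 <- utr_record("g3", seq = strrep("A", 10),
                   genomic_intervals = data.frame(chrom = "chr1",
                                                  start = 95L, end = 105L,
                                                  strand = "+"))
  expect_warning(v <- map_scores_to_utr(trk, u3), "outside")
  expect_equal(sum(is.na(v)), 5L)
})

test_that("site_vs_nonsite_contrast on a noise-free delta fixture", {
  set.seed(2)
  utrs <- lapply(1:20, function(i) {
    utr_record(paste0("t", i), seq = random_rna_str(100))
  })
  names(utrs) <- paste0("t", 1:20)
  sites <- data.frame(transcript = paste0("t", 1:20),
                      start = 10L, end = 18L, stringsAsFactors = FALSE)
  vec <- simulate_conservation_track(utrs, sites, base_mean = 0,
                                     site_elevation_delta = 1,
                                     noise_sd = 0, rng_seed = 3)
  res <- site_vs_nonsite_contrast(vec, sites)
  expect_equal(res$per_gene$diff, rep(1, 20))
  expect_lt(res$test$p.value, 1e-12)
  # partition: site + non-site bases cover each UTR exactly once
  expect_equal(length(vec[[1]]), 100L)
  # degenerate gene (all bases are site) is excluded and logged
  vec2 <- vec
  sites2 <- rbind(sites, data.frame(transcript = "t1", start = 0L,
                                    end = 100L))
  res2 <- site_vs_nonsite_contrast(vec2, sites2)
  expect_true("t1" %in% res2$excluded)
})

test_that("feature_class_summary: constants are non-significant, KW matches the rank oracle", {
  trk <- cons_track(data.frame(chrom = "chr1", start = 0L, end = 300L,
                               score = 1.5))
  feats <- data.frame(chrom = "chr1",
                      start = seq(0L, 290L, by = 30L),
                      end = seq(10L, 299L, by = 30L),
                      class = rep(c("CDS", "IGR"), 5),
                      stringsAsFactors = FALSE)
  res <- feature_class_summary(trk, feats)
  expect_equal(unname(res$class_means), c(1.5, 1.5))
  expect_gt(res$kruskal$p.value, 0.9)
  # shifted classes: statistic equals the independent rank recomputation
  set.seed(12)
  scores <- data.frame(chrom = "chr1", start = 0:299, end = 1:300,
                       score = c(rnorm(150, 0), rnorm(150, 2)))
  trk2 <- cons_track(scores)
  feats2 <- data.frame(chrom = "chr1",
                       start = seq(0L, 290L, by = 10L),
                       end = seq(10L, 300L, by = 10L),
                       class = rep(c("lo", "hi"), each = 15),
                       stringsAsFactors = FALSE)
  res2 <- feature_class_summary(trk2, feats2)
  obs <- res2$observations
  expect_equal(res2$kruskal$statistic, oracle_kw(obs$value, obs$class),
               tolerance = 1e-10)
  expect_lt(res2$kruskal$p.value, 0.01)
  expect_equal(nrow(res2$dunn), 1L)
  # empty feature list errors
  expect_error(feature_class_summary(trk, feats[0, ]), "nonempty")
  # class with < 2 features is excluded from tests but reported
  feats3 <- rbind(feats2, data.frame(chrom = "chr1", start = 0L, end = 5L,
                                     class = "solo"))
  res3 <- feature_class_summary(trk2, feats3)
  expect_equal(res3$excluded_classes, "solo")
})

test_that("KW is invariant under monotone transformation of scores", {
  set.seed(9)
  x <- rnorm(60); g <- rep(c("a", "b", "c"), 20)
  expect_equal(oracle_kw(x, g), oracle_kw(exp(x), g))
})

test_that("mnd formula, range and symmetry", {
  expect_equal(mnd(0.5), 0.5)
  expect_equal(mnd(0), 0)
  expect_equal(mnd(1), 0)
  expect_equal(mnd(0.1), 0.18)
  expect_error(mnd(1.2), "\\[0, 1\\]")
  p <- seq(0, 1, by = 1e-3)
  v <- mnd(p)
  expect_true(all(v >= 0 & v <= 0.5))
  expect_equal(mnd(p), mnd(1 - p))
})

test_that("popgen_class_compare separates shifted DAF classes", {
  al <- simulate_population_alleles(c("piRNA", "FmiR"), 500,
                                    daf_params = list(piRNA = c(5, 5),
                                                      FmiR = c(1, 9)),
                                    rng_seed = 8)
  res <- popgen_class_compare(al)
  expect_lt(res$daf_test$p.value, 1e-6)
  expect_lt(res$mnd_test$p.value, 1e-6)
  # row-wise invariant
  expect_equal(al$mnd, 2 * al$daf * (1 - al$daf))
  # single class -> declined, not an error
  one <- popgen_class_compare(al[al$class == "FmiR", ])
  expect_match(one$daf_test$status, "declined")
  expect_error(popgen_class_compare(al, classes = "nope"), "unknown")
})
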