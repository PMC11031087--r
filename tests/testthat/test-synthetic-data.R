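test_that("sim_config validates its invariants", {
  expect_error(sim_config(utr_len_range = c(500, 200)))
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(depth = -1), "depth")
  expect_error(sim_config(substitution_bias = c("U>X" = 1)), "unknown")
  cfg <- sim_config()
  expect_s3_class(cfg, "sim_config")
  expect_equal(sum(cfg$substitution_bias == 2), 2)
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(rng_seed = 42, n_genes = 20, n_clusters = 2,
                    mirnas_per_cluster = 2)
  expect_identical(simulate_mirna_family(cfg), simulate_mirna_family(cfg))
  expect_identical(simulate_transcriptome(cfg), simulate_transcriptome(cfg))
  a1 <- simulate_population_alleles("x", 10, rng_seed = 3)
  a2 <- simulate_population_alleles("x", 10, rng_seed = 3)
  expect_identical(a1, a2)
})

test_that("degenerate substitution settings behave as stated", {
  # all weight on U>C: every recorded substitution is U>C
  cfg <- sim_config(rng_seed = 1, n_species = 1, n_clusters = 1,
                    mirnas_per_cluster = 3,
                    substitution_bias = setNames(
                      c(rep(0, 10), 1, 0),
                      c("A>C", "A>G", "A>U", "C>A", "C>G", "C>U",
                        "G>A", "G>C", "G>U", "U>A", "U>C", "U>G")))
  fam <- simulate_mirna_family(cfg, n_substitutions = 10)
  expect_true(all(fam$substitutions$from == "U"))
  expect_true(all(fam$substitutions$to == "C"))
  # substitution count 0: descendants identical to the ancestor
  cfg0 <- sim_config(rng_seed = 2, n_species = 1, n_clusters = 1,
                     mirnas_per_cluster = 2)
  fam0 <- simulate_mirna_family(cfg0, n_substitutions = 0)
  expect_true(all(fam0$mirnas$precursor_seq == fam0$ancestor_te))
  expect_error(simulate_mirna_family(sim_config(n_clusters = 0)), "family")
})

test_that("biased substitution fractions match the multinomial expectation", {
  cfg <- sim_config(rng_seed = 5, n_species = 1, n_clusters = 5,
                    mirnas_per_cluster = 10, seed_rate_factor = 1)
  fam <- simulate_mirna_family(cfg, n_substitutions = 20)
  subs <- fam$substitutions
  expect_gt(nrow(subs), 800)
  # oracle: expected P(U>C or A>G) from the ancestor's base composition
  # and the weights (positions uniform at seed_rate_factor 1; each base's
  # three outgoing types share that base's weight mass)
  anc <- table(factor(strsplit(fam$ancestor_te, "")[[1]],
                      levels = c("A", "C", "G", "U")))
  pbase <- anc / sum(anc)
  w <- cfg$substitution_bias
  p_uc <- pbase[["U"]] * w[["U>C"]] / (w[["U>A"]] + w[["U>C"]] + w[["U>G"]])
  p_ag <- pbase[["A"]] * w[["A>G"]] / (w[["A>C"]] + w[["A>G"]] + w[["A>U"]])
  expected <- p_uc + p_ag
  observed <- mean(paste0(subs$from, ">", subs$to) %in% c("U>C", "A>G"))
  se <- sqrt(expected * (1 - expected) / nrow(subs))
  expect_lt(abs(observed - expected), 4 * se + 0.02)
})

test_that("seed positions are substituted at a lower rate", {
  cfg <- sim_config(rng_seed = 6, n_species = 1, n_clusters = 5,
                    mirnas_per_cluster = 10, seed_rate_factor = 0.1)
  fam <- simulate_mirna_family(cfg, n_substitutions = 15)
  seed_pos <- 17:22  # mature positions 2-7 within the precursor
  frac_seed <- mean(fam$substitutions$pos %in% seed_pos)
  # 6 of 120 positions at weight 0.1 vs 1: expected ~ 0.6/114.6
  expect_lt(frac_seed, 6 / 120)
})

test_that("simulate_transcriptome honors the ortholog fraction", {
  cfg1 <- sim_config(rng_seed = 7, n_genes = 50, ortholog_fraction = 1)
  txp1 <- simulate_transcriptome(cfg1)
  expect_true(all(!is.na(txp1$ortholog_map$speciesB)))
  expect_equal(nrow(txp1$ortholog_map), 50L)
  cfg0 <- sim_config(rng_seed = 7, n_genes = 0)
  txp0 <- simulate_transcriptome(cfg0)
  expect_equal(length(txp0$utrs$speciesA), 0L)
  # binomial 99% interval check at fraction 0.5, n = 1000
  cfg5 <- sim_config(rng_seed = 8, n_genes = 1000, ortholog_fraction = 0.5)
  txp5 <- simulate_transcriptome(cfg5)
  shared <- sum(!is.na(txp5$ortholog_map$speciesB))
  expect_gte(shared, qbinom(0.005, 1000, 0.5))
  expect_lte(shared, qbinom(0.995, 1000, 0.5))
  # UTR lengths in range
  lens <- vapply(txp5$utrs$speciesA, function(u) nchar(u$seq), integer(1))
  expect_true(all(lens >= cfg5$utr_len_range[1] &
                    lens <= cfg5$utr_len_range[2]))
})

test_that("implant_target_sites writes recoverable truth", {
  cfg <- sim_config(rng_seed = 10, n_species = 1, n_genes = 40,
                    n_clusters = 1, mirnas_per_cluster = 2)
  fam <- simulate_mirna_family(cfg)
  utrs <- simulate_transcriptome(cfg)$utrs[[1]]
  imp <- implant_target_sites(utrs, fam$mirnas, sites_per_target = 2,
                              wobble_rate = 0, rng_seed = 11)
  # scanner recovers 100% of implanted sites at the exact coordinates
  for (r in seq_len(nrow(imp$true_sites))) {
    ts <- imp$true_sites[r, ]
    mi <- fam$mirnas[fam$mirnas$name == ts$mirna, ]
    s <- scan_utr(imp$utrs[[ts$transcript]],
                  mirna_record(mi$name, mi$mature_seq))
    hit <- s[s$start == ts$start & s$end == ts$end, ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$site_class, ts$site_class)
  }
  # sites are non-overlapping and >= 2 nt apart per transcript
  by_tx <- split(imp$true_sites, imp$true_sites$transcript)
  for (d in by_tx) {
    d <- d[order(d$start), ]
    if (nrow(d) > 1) expect_true(all(diff(d$start) >= (d$end - d$start)[1] + 2))
  }
  # sites_per_target 0 -> empty truth
  imp0 <- implant_target_sites(utrs, fam$mirnas, sites_per_target = 0,
                               rng_seed = 11)
  expect_equal(nrow(imp0$true_sites), 0L)
  # too-short UTR is skipped with a warning and recorded
  short <- list(s1 = utr_record("s1", seq = strrep("C", 12)))
  expect_warning(imps <- implant_target_sites(short, fam$mirnas,
                                              sites_per_target = 2,
                                              rng_seed = 1), "short")
  expect_equal(imps$skipped, "s1")
})

test_that("wobbled sites require wobble-tolerant scanning", {
  cfg <- sim_config(rng_seed = 12, n_species = 1, n_genes = 30,
                    n_clusters = 1, mirnas_per_cluster = 1)
  fam <- simulate_mirna_family(cfg)
  utrs <- simulate_transcriptome(cfg)$utrs[[1]]
  imp <- implant_target_sites(utrs, fam$mirnas, sites_per_target = 1,
                              wobble_rate = 1, rng_seed = 13)
  wob <- imp$true_sites[imp$true_sites$wobble_count > 0, ]
  expect_gt(nrow(wob), 0)
  mi <- mirna_record(fam$mirnas$name[1], fam$mirnas$mature_seq[1])
  hit_with <- hit_without <- 0
  for (r in seq_len(nrow(wob))) {
    u <- imp$utrs[[wob$transcript[r]]]
    s_w <- scan_utr(u, mi, allow_wobble = TRUE, max_wobble = 1)
    s_n <- scan_utr(u, mi, allow_wobble = FALSE)
    if (any(s_w$start == wob$start[r])) hit_with <- hit_with + 1
    if (any(s_n$start == wob$start[r] |
              s_n$start == wob$start[r] + 1L)) hit_without <- hit_without + 1
  }
  expect_equal(hit_with, nrow(wob))
  expect_equal(hit_without, 0)
})

test_that("simulate_counts marginals and errors", {
  cfg <- sim_config(rng_seed = 20, n_genes = 400)
  genes <- sprintf("g%03d", 1:400)
  cm <- simulate_counts(list(lines = "ko1"),
                        list(ko1 = data.frame(gene = character(),
                                              lfc = numeric())),
                        cfg, genes)
  expect_equal(dim(cm$counts), c(400L, 6L))
  libs <- colSums(cm$counts)
  # expected library size within 3 SE of depth (NB sum variance)
  expect_true(all(abs(libs - cfg$depth) / cfg$depth < 0.1))
  expect_error(simulate_counts(list(lines = "k"), list(),
                               sim_config(depth = 0), genes))
  expect_error(simulate_counts(list(lines = "k"), list(),
                               sim_config(dispersion = -1), genes))
})

test_that("population alleles and competition assay generators", {
  al <- simulate_population_alleles(c("a", "b"), c(10, 0), rng_seed = 30)
  expect_false("b" %in% al$class)
  expect_equal(al$mnd, 2 * al$daf * (1 - al$daf))
  a1 <- simulate_competition_assay(50, 1, rng_seed = 31)
  expect_equal(a1$counts, c(50L, 0L))
  big <- simulate_competition_assay(1e5, 0.5, rng_seed = 32)
  expect_lt(abs(big$counts[1] / 1e5 - 0.5), 0.01)
  expect_error(simulate_competition_assay(0, 0.5), "empty")
})
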