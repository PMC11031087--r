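# Synthetic-data generation: every pipeline input is emulated with the
# statistical structure the analysis assumes, alongside a ground-truth
# ledger for recovery tests. The generator models (a) a miRNA family
# descending from a transposon ancestor by biased substitution (U->C and
# A->G favoured, as ADAR-style editing would produce), (b) orthologous
# 3'UTR sets with implanted seed sites, (c) negative-binomial count
# matrices in which knocking out miRNA clusters perturbs implanted targets
# in either direction, (d) conservation tracks elevated at target sites,
# (e) allele-frequency tables per feature class, and (f) offspring
# paternity counts from a binomial competition model.
#
# One master RNG seed per run; each stage draws from a sub-stream derived
# from the stage name (see stage_seed), so adding a stage never perturbs
# earlier stages.

SUB_TYPES <- c("A>C", "A>G", "A>U", "C>A", "C>G", "C>U",
               "G>A", "G>C", "G>U", "U>A", "U>C", "U>G")

#' Simulation configuration
#'
#' Defaults encode the world the pipeline is validated against: 5 clusters
#' (the most severe knockout ablates five family clusters), ~3% sequence
#' divergence from the ancestor (so descendants sit above a 94% identity
#' screen), substitution bias doubled for U>C and A>G, 3 replicates per
#' RNA-seq group, library depth 1e6, NB dispersion 0.01 (biological CV 0.1,
#' the standard rule of thumb for genetically identical model organisms),
#' |log2 fold change|
#' 2 at perturbed targets, and a +0.5 conservation elevation at target
#' sites under noise SD 1. Effect-size magnitudes for target perturbation
#' are free parameters of the generator, not literature values.
#'
#' @param rng_seed master seed.
#' @param n_species number of species (>= 1).
#' @param n_genes genes per species.
#' @param utr_len_range min/max 3'UTR length (bp).
#' @param n_clusters miRNA clusters per species.
#' @param mirnas_per_cluster members per cluster.
#' @param seed_len seed length (default 6, positions 2-7).
#' @param mirna_len mature miRNA length.
#' @param divergence expected per-base substitution rate ancestor ->
#'   descendant.
#' @param seed_rate_factor relative substitution rate inside the seed
#'   (< 1: seeds evolve slower).
#' @param substitution_bias named nonnegative weights over "X>Y"
#'   substitution types.
#' @param base_composition nucleotide frequencies for simulated UTRs.
#' @param ortholog_fraction fraction of genes shared across species.
#' @param site_elevation_delta conservation-score elevation at true sites.
#' @param cons_base_mean,cons_noise_sd conservation track baseline and
#'   noise.
#' @param target_log2fc |log2 fold change| applied to true targets in KO
#'   lines (sign is per-gene).
#' @param dispersion negative-binomial dispersion (> 0).
#' @param depth expected library size.
#' @param n_replicates replicates per RNA-seq group.
#' @return a `sim_config`.
#' @export
sim_config <- function(rng_seed = 1L, n_species = 2L, n_genes = 500L,
                       utr_len_range = c(200L, 500L), n_clusters = 5L,
                       mirnas_per_cluster = 4L, seed_len = 6L,
                       mirna_len = 22L, divergence = 0.03,
                       seed_rate_factor = 0.2,
                       substitution_bias = c("U>C" = 2, "A>G" = 2),
                       base_composition = c(A = .25, C = .25, G = .25,
                                            U = .25),
                       ortholog_fraction = 0.8,
                       site_elevation_delta = 0.5, cons_base_mean = 0,
                       cons_noise_sd = 1, target_log2fc = 2,
                       dispersion = 0.01, depth = 1e6,
                       n_replicates = 3L) {
  bias <- setNames(rep(1, length(SUB_TYPES)), SUB_TYPES)
  if (length(substitution_bias)) {
    unknown <- setdiff(names(substitution_bias), SUB_TYPES)
    if (length(unknown)) stop("unknown substitution type(s): ",
                              paste(unknown, collapse = ", "))
    bias[names(substitution_bias)] <- substitution_bias
  }
  cfg <- list(rng_seed = as.integer(rng_seed), n_species = n_species,
              n_genes = n_genes, utr_len_range = utr_len_range,
              n_clusters = n_clusters,
              mirnas_per_cluster = mirnas_per_cluster, seed_len = seed_len,
              mirna_len = mirna_len, divergence = divergence,
              seed_rate_factor = seed_rate_factor, substitution_bias = bias,
              base_composition = base_composition,
              ortholog_fraction = ortholog_fraction,
              site_elevation_delta = site_elevation_delta,
              cons_base_mean = cons_base_mean, cons_noise_sd = cons_noise_sd,
              target_log2fc = target_log2fc, dispersion = dispersion,
              depth = depth, n_replicates = n_replicates)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_species >= 1, cfg$n_genes >= 0,
            length(cfg$utr_len_range) == 2,
            cfg$utr_len_range[1] <= cfg$utr_len_range[2],
            all(cfg$utr_len_range > 0), cfg$mirna_len >= 8,
            cfg$seed_len > 0)
  if (any(cfg$substitution_bias < 0) || !any(cfg$substitution_bias > 0)) {
    stop("substitution weights must be nonnegative and not all zero")
  }
  if (cfg$dispersion <= 0) stop("dispersion must be positive")
  if (cfg$depth <= 0) stop("depth must be positive")
  invisible(cfg)
}

# a transposon-like ancestor built as an inverted repeat around a loop, so
# that descendants retain hairpin capability
make_ancestor_te <- function(len, base_comp) {
  arm <- (len - 8L) %/% 2L
  left <- random_rna(1, arm, base_comp)
  loop <- random_rna(1, len - 2L * arm, base_comp)
  paste0(left, loop, revcomp_rna(left))
}

# one biased substitution at a given base; returns the new base or NA if
# no substitution from this base has positive weight
draw_substitution <- function(base, bias) {
  types <- SUB_TYPES[startsWith(SUB_TYPES, base)]
  w <- bias[types]
  if (!sum(w)) return(NA_character_)
  to <- sub(".*>", "", sample(types, 1, prob = w))
  to
}

#' Simulate a transposon-descended miRNA family
#'
#' Builds a hairpin-capable ancestral transposon consensus, then derives
#' per-species precursor loci by biased substitution: positions are chosen
#' with the seed region (mature positions 2-7) downweighted by
#' `seed_rate_factor`, the substituted base is drawn from
#' `substitution_bias`, and every recorded event enters the truth ledger.
#' The mature miRNA is a fixed 5'-arm window of the precursor.
#'
#' @param cfg a `sim_config`.
#' @param n_substitutions optional fixed substitution count per descendant
#'   (default: Binomial(locus length, divergence)).
#' @return list: ancestor_te, mirnas (data.frame: name, cluster, family,
#'   species, precursor_seq, mature_seq, seed), substitutions (data.frame:
#'   mirna, pos, from, to), loci (named list per species of precursor
#'   sequences).
#' @export
simulate_mirna_family <- function(cfg, n_substitutions = NULL) {
  validate_sim_config(cfg)
  if (cfg$n_clusters < 1) stop("empty family: n_clusters must be >= 1")
  with_seed(stage_seed(cfg$rng_seed, "mirna_family"), {
    te_len <- 120L
    mature_start <- 16L  # mature miRNA occupies the 5' stem arm
    ancestor <- make_ancestor_te(te_len, cfg$base_composition)
    anc_chars <- seq_chars(ancestor)
    seed_pos <- (mature_start + 1L):(mature_start + cfg$seed_len)  # mature 2-7
    pos_weights <- rep(1, te_len)
    pos_weights[seed_pos] <- cfg$seed_rate_factor

    species <- paste0("species", LETTERS[seq_len(cfg$n_species)])
    mi_rows <- list(); sub_rows <- list(); loci <- list()
    for (sp in species) {
      loci[[sp]] <- character()
      for (cl in seq_len(cfg$n_clusters)) {
        for (k in seq_len(cfg$mirnas_per_cluster)) {
          name <- sprintf("%s-mir-c%02d-%02d", sp, cl, k)
          nsub <- if (is.null(n_substitutions)) {
            rbinom(1, te_len, cfg$divergence)
          } else n_substitutions
          chars <- anc_chars
          if (nsub > 0) {
            pos <- sample.int(te_len, min(nsub, te_len), prob = pos_weights)
            for (p in pos) {
              to <- draw_substitution(chars[p], cfg$substitution_bias)
              if (is.na(to)) next
              sub_rows[[length(sub_rows) + 1L]] <- data.frame(
                mirna = name, pos = p, from = chars[p], to = to,
                stringsAsFactors = FALSE)
              chars[p] <- to
            }
          }
          prec <- paste(chars, collapse = "")
          mat <- substr(prec, mature_start, mature_start + cfg$mirna_len - 1L)
          mi_rows[[length(mi_rows) + 1L]] <- data.frame(
            name = name, cluster = sprintf("%s-cluster%02d", sp, cl),
            family = "simfam", species = sp, precursor_seq = prec,
            mature_seq = mat, seed = substr(mat, 2, 7),
            stringsAsFactors = FALSE)
          loci[[sp]][[name]] <- prec
        }
      }
    }
    list(ancestor_te = ancestor,
         mirnas = do.call(rbind, mi_rows),
         substitutions = if (length(sub_rows)) do.call(rbind, sub_rows)
           else data.frame(mirna = character(), pos = integer(),
                           from = character(), to = character(),
                           stringsAsFactors = FALSE),
         loci = loci)
  })
}

#' Simulate per-species 3'UTR sets with an ortholog map
#'
#' `ortholog_fraction` of ortholog groups are shared by every species (the
#' remainder are species-specific); UTR lengths are uniform over
#' `utr_len_range` and base composition follows the configuration.
#'
#' @param cfg a `sim_config`.
#' @return list: utrs (named list per species of `utr_record` lists),
#'   ortholog_map (data.frame, one column per species, NA where absent).
#' @export
simulate_transcriptome <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(stage_seed(cfg$rng_seed, "transcriptome"), {
    species <- paste0("species", LETTERS[seq_len(cfg$n_species)])
    n <- cfg$n_genes
    if (n == 0) {
      omap <- as.data.frame(setNames(rep(list(character(0)), length(species)),
                                     species))
      return(list(utrs = setNames(rep(list(list()), length(species)),
                                  species),
                  ortholog_map = omap))
    }
    shared <- runif(n) < cfg$ortholog_fraction
    omap <- as.data.frame(setNames(lapply(species, function(sp) {
      ifelse(shared | sp == species[1],
             sprintf("%s_g%04d", sp, seq_len(n)), NA_character_)
    }), species), stringsAsFactors = FALSE)
    utrs <- setNames(lapply(species, function(sp) {
      present <- which(!is.na(omap[[sp]]))
      lens <- sample(cfg$utr_len_range[1]:cfg$utr_len_range[2],
                     length(present), replace = TRUE)
      seqs <- random_rna(length(present), lens, cfg$base_composition)
      out <- lapply(seq_along(present), function(i) {
        utr_record(gene = omap[[sp]][present[i]], seq = seqs[i],
                   species = sp)
      })
      names(out) <- omap[[sp]][present]
      out
    }), species)
    list(utrs = utrs, ortholog_map = omap)
  })
}

#' Implant seed-match target sites into 3'UTRs
#'
#' Writes exact reverse-complement 8mer elements (seed + m8 match + A1
#' adenine) for an assigned miRNA at non-overlapping positions at least
#' 2 nt apart; with probability `wobble_rate` one core position is flipped
#' to its G:U wobble partner (where the miRNA seed base permits one) and
#' the wobble count recorded. UTRs too short for the requested sites are
#' skipped with a warning and appear in the truth ledger as skipped.
#'
#' @param utrs named list of `utr_record`s.
#' @param mirnas data.frame from [simulate_mirna_family()] (or a list of
#'   `mirna_record`s); each UTR is assigned one miRNA round-robin.
#' @param sites_per_target sites implanted per UTR.
#' @param wobble_rate per-site probability of one wobble substitution.
#' @param rng_seed seed for placement and wobble draws.
#' @return list: utrs (modified), true_sites (data.frame: mirna,
#'   transcript, start, end, site_class, wobble_count), skipped (character).
#' @export
implant_target_sites <- function(utrs, mirnas, sites_per_target = 1L,
                                 wobble_rate = 0, rng_seed = 1L) {
  if (is.data.frame(mirnas)) {
    mi_names <- mirnas$name; mi_seqs <- mirnas$mature_seq
  } else {
    mi_names <- vapply(mirnas, `[[`, character(1), "name")
    mi_seqs <- vapply(mirnas, `[[`, character(1), "mature_seq")
  }
  truth <- list(); skipped <- character()
  with_seed(rng_seed, {
    for (i in seq_along(utrs)) {
      if (sites_per_target < 1) break
      ut <- utrs[[i]]
      mi <- ((i - 1L) %% length(mi_names)) + 1L
      mat <- seq_chars(normalize_rna(mi_seqs[mi]))
      # 8mer element on the UTR: comp(m8) + revcomp(seed) + A
      core <- revcomp_rna(paste(mat[2:7], collapse = ""))
      elem <- paste0(WC_COMP[mat[8]], core, "A")
      elen <- nchar(elem)
      n <- nchar(ut$seq)
      need <- sites_per_target * (elen + 2L)
      if (n < need) {
        warning("UTR too short for requested sites, skipped: ",
                ut$transcript)
        skipped <- c(skipped, ut$transcript)
        next
      }
      # non-overlapping starts >= 2 nt apart, drawn by rejection
      starts <- integer()
      cand <- sample.int(n - elen + 1L)
      for (s in cand) {
        if (length(starts) >= sites_per_target) break
        if (all(abs(s - starts) >= elen + 2L)) starts <- c(starts, s)
      }
      starts <- sort(starts)
      chars <- seq_chars(ut$seq)
      for (s in starts) {
        echars <- seq_chars(elem)
        wcount <- 0L
        if (runif(1) < wobble_rate) {
          # core positions where the miRNA seed base is G or U admit wobble
          wob_ok <- which(!is.na(WOBBLE_PARTNER[rev(mat[2:7])]))
          if (length(wob_ok)) {
            p <- if (length(wob_ok) == 1) wob_ok else sample(wob_ok, 1)
            echars[1L + p] <- WOBBLE_PARTNER[rev(mat[2:7])[p]]
            wcount <- 1L
          }
        }
        chars[s:(s + elen - 1L)] <- echars
        truth[[length(truth) + 1L]] <- data.frame(
          mirna = mi_names[mi], transcript = ut$transcript,
          start = s - 1L, end = s + elen - 1L, site_class = "8mer",
          wobble_count = wcount, stringsAsFactors = FALSE)
      }
      utrs[[i]] <- utr_record(ut$gene, ut$transcript,
                              paste(chars, collapse = ""),
                              species = ut$species,
                              genomic_intervals = ut$genomic_intervals)
    }
  })
  list(utrs = utrs,
       true_sites = if (length(truth)) do.call(rbind, truth) else
         data.frame(mirna = character(), transcript = character(),
                    start = integer(), end = integer(),
                    site_class = character(), wobble_count = integer(),
                    stringsAsFactors = FALSE),
       skipped = skipped)
}

#' Simulate a knockout-design count matrix
#'
#' Negative-binomial counts with log-normal baseline means scaled to the
#' configured library depth; in each knockout line the genes of that line's
#' true differential set have their mean multiplied by 2^(signed log2 fold
#' change).
#'
#' @param design list: `lines` (character vector of KO line names) and
#'   optionally `n_replicates` (default from cfg).
#' @param truth named list: line -> data.frame(gene, lfc) of signed
#'   effects.
#' @param cfg a `sim_config`.
#' @param genes character vector of gene ids.
#' @return a `count_matrix` with a WT group and one group per KO line.
#' @export
simulate_counts <- function(design, truth, cfg, genes) {
  validate_sim_config(cfg)
  nrep <- design$n_replicates %||% cfg$n_replicates
  lines <- design$lines
  with_seed(stage_seed(cfg$rng_seed, "counts"), {
    ng <- length(genes)
    base <- exp(rnorm(ng, 0, 1.5))
    base <- base / sum(base) * cfg$depth
    groups <- c("WT", lines)
    mats <- lapply(groups, function(gp) {
      mu <- base
      if (gp != "WT" && !is.null(truth[[gp]]) && nrow(truth[[gp]])) {
        idx <- match(truth[[gp]]$gene, genes)
        ok <- !is.na(idx)
        mu[idx[ok]] <- mu[idx[ok]] * 2^truth[[gp]]$lfc[ok]
      }
      matrix(rnbinom(ng * nrep, mu = rep(mu, nrep),
                     size = 1 / cfg$dispersion),
             nrow = ng,
             dimnames = list(genes, paste0(gp, "_", seq_len(nrep))))
    })
    counts <- do.call(cbind, mats)
    count_matrix(counts, line = rep(groups, each = nrep))
  })
}

#' Simulate a conservation track over 3'UTRs
#'
#' Per-base scores ~ Normal(base_mean, noise_sd), with
#' `site_elevation_delta` added inside true target sites.
#'
#' @param utrs named list of `utr_record`s.
#' @param true_sites data.frame of true sites (transcript, start, end).
#' @param base_mean,site_elevation_delta,noise_sd track parameters.
#' @param rng_seed seed.
#' @return named list: transcript -> per-base score vector.
#' @export
simulate_conservation_track <- function(utrs, true_sites, base_mean = 0,
                                        site_elevation_delta = 0.5,
                                        noise_sd = 1, rng_seed = 1L) {
  with_seed(rng_seed, {
    out <- lapply(utrs, function(ut) {
      v <- rnorm(nchar(ut$seq), base_mean, noise_sd)
      s <- true_sites[true_sites$transcript == ut$transcript, ,
                      drop = FALSE]
      for (i in seq_len(nrow(s))) {
        v[(s$start[i] + 1L):s$end[i]] <-
          v[(s$start[i] + 1L):s$end[i]] + site_elevation_delta
      }
      v
    })
    names(out) <- vapply(utrs, `[[`, character(1), "transcript")
    out
  })
}

#' Simulate population allele tables per feature class
#'
#' Draws derived allele frequencies per class from Beta distributions and
#' attaches the class label; classes with zero requested variants are
#' absent from the output.
#'
#' @param feature_classes character vector of class labels.
#' @param n_variants_per_class integer vector (recycled).
#' @param daf_params named list: class -> c(shape1, shape2) of the Beta
#'   DAF distribution (default Beta(1, 3)).
#' @param rng_seed seed.
#' @return data.frame: variant, class, daf, mnd.
#' @export
simulate_population_alleles <- function(feature_classes,
                                        n_variants_per_class,
                                        daf_params = NULL, rng_seed = 1L) {
  n_variants_per_class <- rep_len(n_variants_per_class,
                                  length(feature_classes))
  with_seed(rng_seed, {
    rows <- lapply(seq_along(feature_classes), function(i) {
      cl <- feature_classes[i]; nv <- n_variants_per_class[i]
      if (nv < 1) return(NULL)
      sh <- daf_params[[cl]] %||% c(1, 3)
      daf <- rbeta(nv, sh[1], sh[2])
      data.frame(variant = sprintf("%s_v%05d", cl, seq_len(nv)),
                 class = cl, daf = daf, mnd = 2 * daf * (1 - daf),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate a sperm-competition assay
#'
#' Binomial(n_offspring, true_fraction) offspring sired by genotype A.
#'
#' @param n_offspring total offspring (> 0).
#' @param true_fraction success probability for genotype A.
#' @param rng_seed seed.
#' @param ratio expected mix ratio recorded on the assay.
#' @param type assay type.
#' @return a `competition_assay`.
#' @export
simulate_competition_assay <- function(n_offspring, true_fraction,
                                       rng_seed = 1L, ratio = c(1, 1),
                                       type = "mixed_IVF") {
  if (n_offspring < 1) stop("empty assay: n_offspring must be positive")
  with_seed(rng_seed, {
    a <- rbinom(1, n_offspring, true_fraction)
    competition_assay(c(a, n_offspring - a), ratio = ratio, type = type)
  })
}
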