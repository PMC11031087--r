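# End-to-end orchestration over synthetic (or user-supplied) data. Stages
# run in a fixed canonical order; every stage writes a manifest (inputs,
# parameters, output checksums) and the final report aggregates headline
# statistics. Reports carry no timestamps, so a fixed seed reproduces a
# byte-identical report.

PIPELINE_STAGES <- c("simulate", "scan", "de", "det", "cross_species",
                     "conserve", "popgen", "teorigin", "compete")

log_stage <- function(stage, msg, level = "info", min_level = "info") {
  ranks <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (ranks[level] >= ranks[min_level]) {
    message(sprintf("[%s] %s", stage, msg))
  }
}

#' Default pipeline configuration
#'
#' @param seed master RNG seed.
#' @param outdir output directory.
#' @param ... overrides for top-level entries (`sim` takes a list of
#'   [sim_config()] overrides).
#' @return a nested configuration list.
#' @export
default_run_config <- function(seed = 1L, outdir = tempfile("mirtekit_run"),
                               ...) {
  cfg <- list(
    seed = as.integer(seed),
    outdir = outdir,
    log_level = "info",
    sim = list(n_genes = 300L, n_clusters = 5L, mirnas_per_cluster = 2L,
               utr_len_range = c(150L, 300L)),
    n_target_genes = 60L,
    sites_per_target = 2L,
    wobble_rate = 0,
    ko_lines = 5L,
    lines_with_effect = 3L,
    assay = list(n_offspring = 179L, true_fraction = 0.73,
                 ratio = c(1, 1)))
  mods <- list(...)
  cfg[names(mods)] <- mods
  cfg
}

write_manifest <- function(outdir, stage, params, outputs) {
  man <- list(stage = stage, parameters = params,
              outputs = lapply(outputs, function(f) {
                list(file = basename(f),
                     md5 = unname(tools::md5sum(f)))
              }))
  path <- file.path(outdir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the full synthetic-data pipeline
#'
#' Executes the canonical stage order (simulate, scan, de, det,
#' cross_species, conserve, popgen, teorigin, compete) up to and including
#' the last requested stage; earlier stages always run because later ones
#' consume their outputs. With a fixed seed two invocations produce
#' byte-identical reports.
#'
#' @param config a configuration list (see [default_run_config()]) or a
#'   path to a JSON file holding one.
#' @param stages subset of stages to target (default: all).
#' @return list: report (headline statistics), report_path, report_hash,
#'   state (in-memory objects per stage).
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = PIPELINE_STAGES) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown)) stop("unknown stage(s): ",
                            paste(unknown, collapse = ", "))
  for (req in c("seed", "outdir")) {
    if (is.null(config[[req]])) stop("config lacks required entry: ", req)
  }
  lvl <- config$log_level %||% "info"
  last <- max(match(stages, PIPELINE_STAGES))
  todo <- PIPELINE_STAGES[seq_len(last)]
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  st <- new.env(parent = emptyenv())
  report <- list(seed = config$seed)

  for (stage in todo) {
    log_stage(stage, "running", min_level = lvl)
    switch(stage,
      simulate = {
        st$cfg <- do.call(sim_config,
                          c(list(rng_seed = config$seed),
                            config$sim %||% list()))
        st$fam <- simulate_mirna_family(st$cfg)
        st$txp <- simulate_transcriptome(st$cfg)
        ngt <- min(config$n_target_genes %||% 60L, st$cfg$n_genes)
        st$target_groups <- seq_len(ngt)
        # implant sites for each species' own miRNAs into the UTRs of the
        # shared target ortholog groups present in that species
        st$true_sites <- list()
        for (sp in names(st$txp$utrs)) {
          genes <- st$txp$ortholog_map[[sp]][st$target_groups]
          genes <- genes[!is.na(genes)]
          genes <- intersect(genes, names(st$txp$utrs[[sp]]))
          mi <- st$fam$mirnas[st$fam$mirnas$species == sp, , drop = FALSE]
          imp <- implant_target_sites(
            st$txp$utrs[[sp]][genes], mi,
            sites_per_target = config$sites_per_target %||% 2L,
            wobble_rate = config$wobble_rate %||% 0,
            rng_seed = stage_seed(config$seed, paste0("implant_", sp)))
          st$txp$utrs[[sp]][genes] <- imp$utrs
          st$true_sites[[sp]] <- imp$true_sites
        }
        fa_mirna <- file.path(outdir, "mirnas.fa")
        write_fasta(setNames(st$fam$mirnas$mature_seq, st$fam$mirnas$name),
                    fa_mirna)
        fa_te <- file.path(outdir, "ancestor_te.fa")
        write_fasta(c(ancestor_te = st$fam$ancestor_te), fa_te)
        fa_utr <- vapply(names(st$txp$utrs), function(sp) {
          f <- file.path(outdir, paste0("utrs_", sp, ".fa"))
          write_fasta(vapply(st$txp$utrs[[sp]], `[[`, character(1), "seq"),
                      f)
          f
        }, character(1))
        bed_truth <- file.path(outdir, "true_sites.bed")
        ts <- do.call(rbind, st$true_sites)
        write_bed(data.frame(chrom = ts$transcript, start = ts$start,
                             end = ts$end,
                             name = paste(ts$mirna, ts$site_class,
                                          sep = "|"),
                             score = ts$wobble_count, strand = "+"),
                  bed_truth)
        truth_json <- file.path(outdir, "truth.json")
        jsonlite::write_json(list(target_groups = st$target_groups,
                                  ancestor_te = st$fam$ancestor_te),
                             truth_json, auto_unbox = TRUE, digits = NA)
        write_manifest(outdir, stage,
                       list(seed = config$seed,
                            n_genes = st$cfg$n_genes,
                            n_target_genes = ngt),
                       c(fa_mirna, fa_te, fa_utr, bed_truth, truth_json))
      },
      scan = {
        st$maps <- lapply(setNames(nm = names(st$txp$utrs)), function(sp) {
          mi <- st$fam$mirnas[st$fam$mirnas$species == sp, , drop = FALSE]
          mirnas <- lapply(seq_len(nrow(mi)), function(i) {
            mirna_record(mi$name[i], mi$mature_seq[i],
                         cluster = mi$cluster[i], family = mi$family[i],
                         species = sp)
          })
          predict_targets(mirnas, st$txp$utrs[[sp]])
        })
        outs <- vapply(names(st$maps), function(sp) {
          f <- file.path(outdir, paste0("sites_", sp, ".tsv"))
          write.table(st$maps[[sp]]$sites, f, sep = "\t", quote = FALSE,
                      row.names = FALSE)
          f
        }, character(1))
        report$n_predicted_sites <- vapply(st$maps,
                                           function(m) nrow(m$sites),
                                           integer(1))
        write_manifest(outdir, stage, list(tiers = "default"), outs)
      },
      de = {
        ref_sp <- names(st$txp$utrs)[1]
        genes <- names(st$txp$utrs[[ref_sp]])
        nlines <- config$ko_lines %||% 5L
        neff <- config$lines_with_effect %||% 3L
        lines <- paste0("ko", seq_len(nlines))
        tg <- st$txp$ortholog_map[[ref_sp]][st$target_groups]
        tg <- intersect(tg[!is.na(tg)], genes)
        sign <- with_seed(stage_seed(config$seed, "effect_signs"),
                          sample(c(-1, 1), length(tg), replace = TRUE))
        eff <- data.frame(gene = tg,
                          lfc = sign * st$cfg$target_log2fc,
                          stringsAsFactors = FALSE)
        st$de_truth <- setNames(lapply(seq_len(nlines), function(i) {
          if (i <= neff) eff else eff[0, ]
        }), lines)
        st$counts <- simulate_counts(list(lines = lines), st$de_truth,
                                     st$cfg, genes)
        write_counts_tsv(st$counts, file.path(outdir, "counts.tsv"))
        st$de <- lapply(setNames(nm = lines), function(ln) {
          differential_expression(st$counts, ln)
        })
        st$degs <- lapply(st$de, select_degs)
        report$n_degs <- vapply(st$degs, length, integer(1))
        write_manifest(outdir, stage,
                       list(lines = lines, lines_with_effect = neff),
                       file.path(outdir, "counts.tsv"))
      },
      det = {
        ref_sp <- names(st$maps)[1]
        st$dets <- select_dets(st$degs, st$maps[[ref_sp]], min_lines = 2L)
        f <- file.path(outdir, "det_pool.tsv")
        write.table(st$dets$pooled, f, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        report$n_det_pool <- nrow(st$dets$pooled)
        report$n_det_all_lines <- length(st$dets$all_lines)
        write_manifest(outdir, stage, st$dets$params, f)
      },
      cross_species = {
        ref_sp <- names(st$maps)[1]
        shared <- shared_targets(st$dets$pooled$gene, st$maps,
                                 st$txp$ortholog_map, ref_sp)
        st$shared <- shared
        universe <- lapply(names(st$maps), function(sp) {
          st$txp$ortholog_map[[sp]][st$target_groups]
        })
        tpm <- lapply(seq_along(st$maps), function(i) {
          u <- universe[[i]][!is.na(universe[[i]])]
          targets_per_mirna(st$maps[[i]], u)
        })
        names(tpm) <- names(st$maps)
        cmp <- if (length(tpm) >= 2) {
          compare_targets_per_mirna(tpm[[1]], tpm[[2]])
        } else list(status = "single species")
        report$pct_shared_all <- shared$pct_shared_all
        report$venn <- as.list(shared$venn)
        report$targets_per_mirna_mean <- vapply(tpm, function(d)
          attr(d, "mean"), numeric(1))
        report$targets_per_mirna_p <- cmp$p.value %||% NA_real_
        f <- file.path(outdir, "venn.json")
        jsonlite::write_json(report$venn, f, auto_unbox = TRUE, digits = NA)
        write_manifest(outdir, stage, list(reference = ref_sp), f)
      },
      conserve = {
        ref_sp <- names(st$txp$utrs)[1]
        ts <- st$true_sites[[ref_sp]]
        tx_with_sites <- unique(ts$transcript)
        vec <- simulate_conservation_track(
          st$txp$utrs[[ref_sp]][tx_with_sites], ts,
          base_mean = st$cfg$cons_base_mean,
          site_elevation_delta = st$cfg$site_elevation_delta,
          noise_sd = st$cfg$cons_noise_sd,
          rng_seed = stage_seed(config$seed, "cons_track"))
        st$contrast <- site_vs_nonsite_contrast(vec, ts)
        report$site_contrast_estimate <- st$contrast$test$estimate
        report$site_contrast_p <- st$contrast$test$p.value
        f <- file.path(outdir, "site_contrast.tsv")
        write.table(st$contrast$per_gene, f, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        write_manifest(outdir, stage,
                       list(delta = st$cfg$site_elevation_delta), f)
      },
      popgen = {
        alleles <- simulate_population_alleles(
          c("piRNA", "FmiR", "SmiR", "all_miRNA"),
          c(300L, 120L, 120L, 300L),
          daf_params = list(piRNA = c(5, 5), FmiR = c(1, 9),
                            SmiR = c(2, 8), all_miRNA = c(3, 7)),
          rng_seed = stage_seed(config$seed, "popgen"))
        st$popgen <- popgen_class_compare(alleles)
        report$popgen_daf_p <- st$popgen$daf_test$p.value
        report$popgen_mnd_p <- st$popgen$mnd_test$p.value
        f <- file.path(outdir, "alleles.tsv")
        write.table(alleles, f, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        write_manifest(outdir, stage, list(), f)
      },
      teorigin = {
        decoys <- with_seed(stage_seed(config$seed, "te_decoys"),
                            setNames(random_rna(2, c(120L, 120L)),
                                     c("decoy_te1", "decoy_te2")))
        lib <- c(ancestor_te = st$fam$ancestor_te, decoys)
        # screen against the first cluster's precursor loci per species
        loci <- lapply(st$fam$loci, function(lv) lv[seq_len(
          min(length(lv), st$cfg$mirnas_per_cluster))])
        st$screen <- screen_te_sources(lib, loci)
        st$hairpin <- hairpin_check(st$fam$ancestor_te)
        fam_aln <- c(ancestor = st$fam$ancestor_te,
                     setNames(st$fam$mirnas$precursor_seq,
                              st$fam$mirnas$name))
        st$spectrum <- substitution_spectrum(
          fam_aln, reference_policy = "designated_outgroup",
          outgroup = "ancestor")
        report$te_top_candidate <-
          if (nrow(st$screen$ranking)) st$screen$ranking$te[1] else NA
        report$te_candidate_loci_hit <-
          if (nrow(st$screen$ranking)) st$screen$ranking$n_loci[1] else 0L
        report$ancestor_is_hairpin <- st$hairpin$is_hairpin
        cm <- st$spectrum$counts
        report$ucag_substitution_fraction <-
          (cm["U", "C"] + cm["A", "G"]) / max(1, sum(cm))
        f <- file.path(outdir, "te_candidates.tsv")
        write.table(st$screen$hits, f, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        write_manifest(outdir, stage,
                       list(identity_min = 0.94, min_span = 50), f)
      },
      compete = {
        ac <- config$assay %||% list()
        assay <- simulate_competition_assay(
          ac$n_offspring %||% 179L, ac$true_fraction %||% 0.73,
          rng_seed = stage_seed(config$seed, "compete"),
          ratio = ac$ratio %||% c(1, 1))
        st$gof <- paternity_gof(assay)
        ci <- paternity_fraction_ci(assay)
        report$competition_chisq <- st$gof$statistic
        report$competition_p <- st$gof$p.value
        report$competition_fraction <- ci$fraction
        f <- file.path(outdir, "competition.tsv")
        write.table(data.frame(genotype = c("A", "B"),
                               count = assay$counts,
                               expected = st$gof$expected),
                    f, sep = "\t", quote = FALSE, row.names = FALSE)
        write_manifest(outdir, stage, ac, f)
      })
  }

  report_path <- file.path(outdir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  list(report = report, report_path = report_path,
       report_hash = unname(tools::md5sum(report_path)),
       state = as.list(st))
}

#' Command-line entry point
#'
#' Subcommands: `run-all` plus each stage name (`simulate`, `scan`, `de`,
#' `det`, `cross-species`, `conserve`, `popgen`, `teorigin`, `compete`;
#' running a stage runs the canonical prefix it depends on). Global flags:
#' `--seed`, `--config` (JSON), `--outdir`, `--log-level`.
#'
#' @param args character vector (default: the process command line).
#' @return invisibly, the [run_pipeline()] result.
#' @export
mirtekit_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: mirtekit <run-all|", paste(gsub("_", "-",
            PIPELINE_STAGES), collapse = "|"),
            "> [--seed N] [--config F] [--outdir D] [--log-level L]")
    return(invisible(NULL))
  }
  cmd <- args[1]
  rest <- args[-1]
  getopt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (length(i) && i[1] < length(rest)) rest[i[1] + 1] else default
  }
  config <- if (!is.null(cf <- getopt("--config"))) {
    jsonlite::read_json(cf, simplifyVector = TRUE)
  } else {
    default_run_config()
  }
  if (!is.null(s <- getopt("--seed"))) config$seed <- as.integer(s)
  if (!is.null(o <- getopt("--outdir"))) config$outdir <- o
  if (!is.null(l <- getopt("--log-level"))) config$log_level <- l
  stages <- if (cmd == "run-all") PIPELINE_STAGES else gsub("-", "_", cmd)
  res <- run_pipeline(config, stages = stages)
  message("report: ", res$report_path, " (md5 ", res$report_hash, ")")
  invisible(res)
}
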