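# Cross-species target sharing and target-load statistics: how many of a
# reference target-gene set are shared across species through orthology,
# how many targets each family miRNA has within a gene universe, and how
# many family sites each transcript carries.

#' Cross-species target sharing of a reference gene set
#'
#' Maps each reference gene through an explicit ortholog table and asks, per
#' species, whether any family miRNA of that species targets the ortholog.
#' Returns per-combination venn counts and pairwise overlaps with
#' percentages of the reference set. Genes missing from the ortholog table
#' are counted as unshared and reported.
#'
#' @param reference_set character vector of genes in the reference species'
#'   naming.
#' @param target_maps named list: species -> `target_map`.
#' @param ortholog_map data.frame with one column per species (same names as
#'   `target_maps` plus the reference species), one row per ortholog group,
#'   NA where a species lacks the gene.
#' @param reference_species column of `ortholog_map` holding the reference
#'   naming.
#' @return list: membership (logical matrix genes x species), venn (named
#'   counts per species combination), pairwise (data.frame), shared_all
#'   (genes shared with every non-reference species), unmapped (genes absent
#'   from the ortholog table).
#' @export
shared_targets <- function(reference_set, target_maps, ortholog_map,
                           reference_species) {
  reference_set <- unique(reference_set)
  species <- names(target_maps)
  if (is.null(species)) stop("target_maps must be a named list")
  stopifnot(reference_species %in% names(ortholog_map))
  idx <- match(reference_set, ortholog_map[[reference_species]])
  unmapped <- reference_set[is.na(idx)]

  membership <- matrix(FALSE, nrow = length(reference_set),
                       ncol = length(species),
                       dimnames = list(reference_set, species))
  for (sp in species) {
    targeted <- unique(unlist(target_maps[[sp]]$targets, use.names = FALSE))
    if (sp == reference_species) {
      ortho <- reference_set
    } else {
      if (!sp %in% names(ortholog_map)) {
        stop("ortholog_map lacks a column for species: ", sp)
      }
      ortho <- ortholog_map[[sp]][idx]
    }
    membership[, sp] <- !is.na(ortho) & ortho %in% targeted
  }

  combo <- apply(membership, 1, function(r) {
    if (!any(r)) "none" else paste(species[r], collapse = "&")
  })
  venn <- table(factor(combo))
  others <- setdiff(species, reference_species)
  shared_all <- reference_set[rowSums(membership[, others, drop = FALSE]) ==
                                length(others)]
  pairwise <- do.call(rbind, lapply(others, function(sp) {
    n <- sum(membership[, sp])
    data.frame(species = sp, shared = n,
               pct_of_reference = 100 * n / length(reference_set),
               stringsAsFactors = FALSE)
  }))
  list(membership = membership, venn = c(venn),
       pairwise = pairwise, shared_all = shared_all,
       n_shared_all = length(shared_all),
       pct_shared_all = 100 * length(shared_all) / max(1, length(reference_set)),
       unmapped = unmapped)
}

#' Unique-target counts per miRNA within a gene universe
#'
#' @param target_map a `target_map`.
#' @param universe character vector of transcripts to count within.
#' @return data.frame (mirna, n_targets) plus the arithmetic mean as
#'   attribute `"mean"`.
#' @export
targets_per_mirna <- function(target_map, universe) {
  if (!length(universe)) stop("universe must be nonempty")
  counts <- vapply(names(target_map$targets), function(mn) {
    length(intersect(target_map$targets[[mn]], universe))
  }, integer(1))
  out <- data.frame(mirna = names(counts), n_targets = as.integer(counts),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "mean") <- mean(counts)
  out
}

#' Compare per-miRNA target counts between two species
#'
#' Two-sample Welch test on the per-miRNA unique-target count vectors.
#'
#' @param counts_a,counts_b outputs of [targets_per_mirna()] (or numeric
#'   vectors).
#' @return list: mean_a, mean_b, statistic, p.value, status ("ok" or
#'   "insufficient groups" when either species has fewer than 2 miRNAs).
#' @export
compare_targets_per_mirna <- function(counts_a, counts_b) {
  xa <- if (is.data.frame(counts_a)) counts_a$n_targets else counts_a
  xb <- if (is.data.frame(counts_b)) counts_b$n_targets else counts_b
  if (length(xa) < 2 || length(xb) < 2) {
    return(list(mean_a = mean(xa), mean_b = mean(xb), statistic = NA_real_,
                p.value = NA_real_, status = "insufficient groups"))
  }
  tt <- tryCatch(t.test(xa, xb), error = function(e) NULL)
  if (is.null(tt)) {
    return(list(mean_a = mean(xa), mean_b = mean(xb), statistic = NA_real_,
                p.value = NA_real_, status = "degenerate: zero variance"))
  }
  list(mean_a = mean(xa), mean_b = mean(xb),
       statistic = unname(tt$statistic), p.value = tt$p.value, status = "ok")
}

#' Family site counts per transcript
#'
#' Tallies every target-site record per transcript across all family
#' miRNAs, restricted to a universe.
#'
#' @param target_map a `target_map`.
#' @param universe transcripts to include (default: all with sites).
#' @return data.frame (transcript, n_sites).
#' @export
sites_per_transcript <- function(target_map, universe = NULL) {
  sites <- target_map$sites
  if (!is.null(universe)) sites <- sites[sites$transcript %in% universe, ,
                                         drop = FALSE]
  tab <- table(sites$transcript)
  out <- data.frame(transcript = names(tab), n_sites = as.integer(tab),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(universe)) {
    missing <- setdiff(universe, out$transcript)
    if (length(missing)) {
      out <- rbind(out, data.frame(transcript = missing, n_sites = 0L,
                                   stringsAsFactors = FALSE))
    }
  }
  out[order(out$transcript), , drop = FALSE]
}

#' Compare per-transcript site-count distributions between two species
#'
#' @param sites_a,sites_b outputs of [sites_per_transcript()].
#' @return list with Welch test results and the two ECDF step tables.
#' @export
compare_sites_per_transcript <- function(sites_a, sites_b) {
  xa <- sites_a$n_sites; xb <- sites_b$n_sites
  if (length(xa) < 2 || length(xb) < 2) {
    return(list(statistic = NA_real_, p.value = NA_real_,
                status = "insufficient groups"))
  }
  tt <- tryCatch(t.test(xa, xb), error = function(e) NULL)
  if (is.null(tt)) {
    return(list(statistic = NA_real_, p.value = NA_real_,
                status = "degenerate: zero variance"))
  }
  list(mean_a = mean(xa), mean_b = mean(xb),
       statistic = unname(tt$statistic), p.value = tt$p.value,
       ecdf_a = ecdf_table(xa), ecdf_b = ecdf_table(xb), status = "ok")
}

ecdf_table <- function(x) {
  xs <- sort(unique(x))
  data.frame(value = xs, cum_fraction = ecdf(x)(xs))
}

#' Transcripts whose 3'UTR overlaps a transposon family
#'
#' Interval-overlap join between UTR annotations and transposon
#' annotations, both 0-based half-open on the same genome. "Containing"
#' means an overlap of at least 1 bp; `max_distance` relaxes this towards
#' closest-feature semantics.
#'
#' @param utr_annotations data.frame: chrom, start, end, transcript.
#' @param te_annotations data.frame: chrom, start, end, name (TE family).
#' @param te_family TE family name to screen for.
#' @param det_pool optional `det_pool` or character vector; the overlap with
#'   the pooled DET genes is reported.
#' @param max_distance maximum gap (bp) still counted (default 0 =
#'   overlap required).
#' @return list: transcripts (character), n, in_det (character), n_in_det.
#' @export
te_containing_transcripts <- function(utr_annotations, te_annotations,
                                      te_family, det_pool = NULL,
                                      max_distance = 0L) {
  te <- te_annotations[te_annotations$name == te_family, , drop = FALSE]
  if (!length(intersect(unique(utr_annotations$chrom), unique(te$chrom))) &&
      nrow(te) && nrow(utr_annotations)) {
    warning("no shared chromosome names between UTR and TE annotations; ",
            "check naming conventions")
  }
  gr_utr <- GenomicRanges::GRanges(
    utr_annotations$chrom,
    IRanges::IRanges(utr_annotations$start + 1L, utr_annotations$end))
  gr_te <- GenomicRanges::GRanges(
    te$chrom, IRanges::IRanges(te$start + 1L, te$end))
  hits <- GenomicRanges::findOverlaps(gr_utr, gr_te,
                                      maxgap = if (max_distance > 0)
                                        max_distance else -1L)
  transcripts <- sort(unique(
    utr_annotations$transcript[S4Vectors::queryHits(hits)]))
  det_genes <- if (inherits(det_pool, "det_pool")) det_pool$pooled$gene
    else as.character(det_pool)
  in_det <- intersect(transcripts, det_genes)
  list(transcripts = transcripts, n = length(transcripts),
       in_det = sort(in_det), n_in_det = length(in_det))
}
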