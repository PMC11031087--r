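# Per-base conservation mapping and statistics: mapping genomic
# conservation scores (PhyloP-like signed, or PhastCons-like in [0,1]) into
# 3'UTR coordinates, contrasting target-site bases against the rest of the
# UTR, summarizing conservation by feature class, and derived-allele-
# frequency / nucleotide-diversity comparisons.

#' Build a per-chromosome conservation track from interval scores
#'
#' @param intervals data.frame: chrom, start, end (0-based half-open),
#'   score. Overlapping intervals are rejected.
#' @param semantics "phylop" (signed) or "phastcons" (must lie in [0,1]).
#' @return a `cons_track`: per-chromosome list(offset, scores) with NA for
#'   uncovered positions.
#' @export
cons_track <- function(intervals, semantics = c("phylop", "phastcons")) {
  semantics <- match.arg(semantics)
  if (semantics == "phastcons" &&
      any(intervals$score < 0 | intervals$score > 1)) {
    stop("phastcons-like scores must lie in [0, 1]")
  }
  by_chrom <- split(intervals, intervals$chrom)
  chroms <- lapply(by_chrom, function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (any(d$start[-1] < d$end[-nrow(d)])) {
      stop("overlapping intervals in conservation track on ", d$chrom[1])
    }
    off <- min(d$start)
    v <- rep(NA_real_, max(d$end) - off)
    for (i in seq_len(nrow(d))) {
      v[(d$start[i] - off + 1L):(d$end[i] - off)] <- d$score[i]
    }
    list(offset = off, scores = v)
  })
  structure(list(chroms = chroms, semantics = semantics),
            class = "cons_track")
}

track_slice <- function(track, chrom, start, end) {
  ch <- track$chroms[[chrom]]
  out <- rep(NA_real_, end - start)
  if (is.null(ch)) return(out)
  pos <- start:(end - 1L)                 # 0-based genomic positions
  idx <- pos - ch$offset + 1L
  ok <- idx >= 1L & idx <= length(ch$scores)
  out[ok] <- ch$scores[idx[ok]]
  out
}

#' Map conservation scores into 3'UTR coordinates
#'
#' Concatenates per-base scores over the UTR's genomic blocks in transcript
#' order; on the minus strand each block is reversed so that index 1 is the
#' UTR 5' end (score values are unchanged: conservation is strandless).
#' Positions outside the track become NA with a warning.
#'
#' @param track a `cons_track`.
#' @param utr a `utr_record` with `genomic_intervals`.
#' @return numeric vector, one score per UTR base, 5'->3'.
#' @export
map_scores_to_utr <- function(track, utr) {
  gi <- utr$genomic_intervals
  if (is.null(gi)) stop("UTR has no genomic_intervals: ", utr$transcript)
  pieces <- lapply(seq_len(nrow(gi)), function(i) {
    v <- track_slice(track, gi$chrom[i], gi$start[i], gi$end[i])
    if (gi$strand[i] == "-") rev(v) else v
  })
  out <- unlist(pieces, use.names = FALSE)
  if (anyNA(out)) {
    warning(sum(is.na(out)), " UTR position(s) outside track extent for ",
            utr$transcript)
  }
  out
}

#' Target-site versus non-site conservation contrast
#'
#' Per gene: mean score over the union of target-site bases versus the mean
#' over the remaining UTR bases; then a paired test over genes (t-test by
#' default, Wilcoxon signed-rank behind `method = "wilcoxon"`). Genes
#' without at least one non-missing site base and one non-missing non-site
#' base are excluded and reported. Missing scores are excluded pairwise,
#' never imputed. A pooled-bases variant of the test is also reported.
#'
#' @param score_vectors named list: transcript -> per-base score vector
#'   (UTR coordinates).
#' @param sites data.frame of target sites (`transcript`, `start`, `end`,
#'   0-based half-open).
#' @param method "t" (default) or "wilcoxon".
#' @return list: per_gene (data.frame gene, site_mean, nonsite_mean, diff),
#'   test (paired over genes), pooled_test, ecdf_site, ecdf_nonsite,
#'   excluded.
#' @export
site_vs_nonsite_contrast <- function(score_vectors, sites,
                                     method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  rows <- list(); excluded <- character()
  pooled_site <- list(); pooled_non <- list()
  for (tx in names(score_vectors)) {
    v <- score_vectors[[tx]]
    s <- sites[sites$transcript == tx, , drop = FALSE]
    mask <- rep(FALSE, length(v))
    for (i in seq_len(nrow(s))) {
      lo <- max(0L, s$start[i]); hi <- min(length(v), s$end[i])
      if (hi > lo) mask[(lo + 1L):hi] <- TRUE
    }
    sv <- v[mask]; nv <- v[!mask]
    if (!sum(!is.na(sv)) || !sum(!is.na(nv))) {
      excluded <- c(excluded, tx)
      next
    }
    rows[[tx]] <- data.frame(gene = tx,
                             site_mean = mean(sv, na.rm = TRUE),
                             nonsite_mean = mean(nv, na.rm = TRUE),
                             stringsAsFactors = FALSE)
    pooled_site[[tx]] <- sv[!is.na(sv)]
    pooled_non[[tx]] <- nv[!is.na(nv)]
  }
  per_gene <- do.call(rbind, rows)
  if (is.null(per_gene) || nrow(per_gene) < 2) {
    stop("fewer than 2 usable genes for the paired contrast")
  }
  rownames(per_gene) <- NULL
  per_gene$diff <- per_gene$site_mean - per_gene$nonsite_mean
  test <- if (method == "t") {
    if (sd(per_gene$diff) < 1e-12 * max(1, abs(mean(per_gene$diff)))) {
      # noise-free fixtures: constant difference, p below machine floor
      m <- mean(per_gene$diff)
      list(method = "paired t (degenerate: constant differences)",
           estimate = m, statistic = if (m == 0) 0 else sign(m) * Inf,
           p.value = if (m == 0) 1 else 0)
    } else {
      tt <- t.test(per_gene$diff)
      list(method = "paired t", estimate = mean(per_gene$diff),
           statistic = unname(tt$statistic), p.value = tt$p.value)
    }
  } else {
    wt <- suppressWarnings(wilcox.test(per_gene$diff))
    list(method = "wilcoxon signed-rank", estimate = median(per_gene$diff),
         statistic = unname(wt$statistic), p.value = wt$p.value)
  }
  all_site <- unlist(pooled_site, use.names = FALSE)
  all_non <- unlist(pooled_non, use.names = FALSE)
  pooled <- tryCatch(t.test(all_site, all_non), error = function(e) NULL)
  pooled_res <- if (is.null(pooled)) {
    m <- mean(all_site) - mean(all_non)
    list(method = "welch on pooled bases (degenerate: constant data)",
         estimate = m, statistic = if (m == 0) 0 else sign(m) * Inf,
         p.value = if (m == 0) 1 else 0)
  } else {
    list(method = "welch on pooled bases",
         estimate = mean(all_site) - mean(all_non),
         statistic = unname(pooled$statistic), p.value = pooled$p.value)
  }
  list(per_gene = per_gene, test = test,
       pooled_test = pooled_res,
       ecdf_site = ecdf_table(all_site), ecdf_nonsite = ecdf_table(all_non),
       excluded = excluded)
}

#' Dunn's pairwise post-hoc test after Kruskal-Wallis
#'
#' Rank-sum z statistics with the standard tie correction; p-values
#' adjusted by Holm.
#'
#' @param x numeric observations.
#' @param g group factor.
#' @return data.frame: group1, group2, z, p.value, p.adjusted.
#' @export
dunn_posthoc <- function(x, g) {
  g <- factor(g)
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- droplevels(g[ok])
  n <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_r <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  res <- apply(pairs, 2, function(p) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / n_g[p[1]] + 1 / n_g[p[2]]))
    z <- (mean_r[p[1]] - mean_r[p[2]]) / se
    c(z = unname(z), p.value = 2 * pnorm(-abs(unname(z))))
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = res["z", ], p.value = res["p.value", ],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$p.adjusted <- p.adjust(out$p.value, method = "holm")
  out
}

#' Conservation summary by feature class
#'
#' Each feature contributes one observation (its mean score over its bases)
#' unless `unit = "base"`, in which case every base is an observation.
#' Kruskal-Wallis omnibus over classes, then Dunn pairwise post hoc with
#' Holm adjustment. Classes with fewer than 2 observations are excluded
#' from testing and reported.
#'
#' @param track a `cons_track`.
#' @param features data.frame: chrom, start, end (0-based half-open),
#'   class.
#' @param unit "feature" (default; one mean per feature, avoiding
#'   pseudoreplication) or "base".
#' @return list: observations (data.frame), class_means, kruskal, dunn,
#'   excluded_classes.
#' @export
feature_class_summary <- function(track, features, unit = c("feature", "base")) {
  unit <- match.arg(unit)
  if (!nrow(features)) stop("feature list must be nonempty")
  obs <- list()
  for (i in seq_len(nrow(features))) {
    v <- track_slice(track, features$chrom[i], features$start[i],
                     features$end[i])
    v <- v[!is.na(v)]
    if (!length(v)) next
    obs[[i]] <- if (unit == "feature") {
      data.frame(class = features$class[i], value = mean(v),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(class = features$class[i], value = v,
                 stringsAsFactors = FALSE)
    }
  }
  obs <- do.call(rbind, obs)
  if (is.null(obs)) stop("no feature overlapped the track")
  counts <- table(obs$class)
  excluded <- names(counts)[counts < 2]
  keep <- obs[!obs$class %in% excluded, , drop = FALSE]
  class_means <- c(tapply(obs$value, obs$class, mean))
  kw <- if (length(unique(keep$class)) < 2) {
    list(statistic = NA_real_, df = NA_real_, p.value = NA_real_,
         status = "insufficient classes")
  } else if (length(unique(keep$value)) < 2) {
    # all observations tied: no evidence against equality
    list(statistic = 0, df = length(unique(keep$class)) - 1L, p.value = 1,
         status = "ok (all values tied)")
  } else {
    k <- kruskal.test(keep$value, factor(keep$class))
    list(statistic = unname(k$statistic), df = unname(k$parameter),
         p.value = k$p.value, status = "ok")
  }
  dunn <- if (identical(kw$status, "ok")) {
    dunn_posthoc(keep$value, keep$class)
  } else NULL
  list(observations = obs, class_means = class_means, kruskal = kw,
       dunn = dunn, excluded_classes = excluded)
}

#' Mean nucleotide diversity from derived allele frequency
#'
#' MND = 2 * DAF * (1 - DAF): the expected heterozygosity contribution of a
#' biallelic site, maximal (0.5) at DAF 0.5 and symmetric about it.
#'
#' @param daf numeric vector in [0, 1].
#' @return numeric vector in [0, 0.5].
#' @export
mnd <- function(daf) {
  if (any(is.na(daf)) || any(daf < 0 | daf > 1)) {
    stop("DAF values must lie in [0, 1]")
  }
  2 * daf * (1 - daf)
}

#' Compare DAF and MND distributions across feature classes
#'
#' Groups variants by class; Kruskal-Wallis omnibus and Dunn post hoc are
#' run separately for DAF and MND. A single class yields a declined status
#' rather than an error.
#'
#' @param alleles data.frame with columns `class` and `daf` (an `mnd`
#'   column is recomputed and verified if present).
#' @param classes optional subset of classes to compare.
#' @return list: summary (per-class n/means), daf_test, mnd_test, with
#'   Dunn tables when applicable.
#' @export
popgen_class_compare <- function(alleles, classes = NULL) {
  if (!is.null(classes)) {
    unknown <- setdiff(classes, unique(alleles$class))
    if (length(unknown)) stop("unknown class label(s): ",
                              paste(unknown, collapse = ", "))
    alleles <- alleles[alleles$class %in% classes, , drop = FALSE]
  }
  alleles$mnd <- mnd(alleles$daf)
  smry <- do.call(rbind, lapply(split(alleles, alleles$class), function(d) {
    data.frame(class = d$class[1], n = nrow(d), mean_daf = mean(d$daf),
               mean_mnd = mean(d$mnd), stringsAsFactors = FALSE)
  }))
  rownames(smry) <- NULL
  one_test <- function(value) {
    if (length(unique(alleles$class)) < 2) {
      return(list(statistic = NA_real_, p.value = NA_real_,
                  status = "single class; omnibus declined", dunn = NULL))
    }
    k <- kruskal.test(value, factor(alleles$class))
    list(statistic = unname(k$statistic), df = unname(k$parameter),
         p.value = k$p.value, status = "ok",
         dunn = dunn_posthoc(value, alleles$class))
  }
  list(summary = smry, daf_test = one_test(alleles$daf),
       mnd_test = one_test(alleles$mnd))
}
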