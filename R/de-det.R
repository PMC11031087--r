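# Lightweight differential expression and differentially-expressed-target
# (DET) selection/pooling across knockout lines.
#
# The DE engine is deliberately simple (median-of-ratios normalization +
# per-gene Welch test on log2 normalized counts + Benjamini-Hochberg); the
# scientific content of this module is the DEG threshold (|fold change| >= 2
# and FDR < 0.05), the intersection of DEGs with predicted targets, and the
# pooling rule (a gene enters the DET pool when supported by at least two
# knockout lines). An ingestion path for externally computed DE tables
# preserves fidelity for users with full RNA-seq pipelines.

#' Assemble a count matrix with sample metadata
#'
#' @param counts integer matrix, genes x samples.
#' @param line character vector of group labels per sample (e.g. "WT",
#'   "ko1").
#' @param replicate optional replicate ids.
#' @return a `count_matrix` list.
#' @export
count_matrix <- function(counts, line, replicate = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (length(line) != ncol(counts)) stop("one line label per sample required")
  if (is.null(replicate)) replicate <- stats::ave(seq_along(line), line,
                                                  FUN = seq_along)
  structure(list(counts = counts,
                 samples = data.frame(sample = colnames(counts) %||%
                                        paste0("s", seq_along(line)),
                                      line = line, replicate = replicate,
                                      stringsAsFactors = FALSE)),
            class = "count_matrix")
}

#' Median-of-ratios size factors
#'
#' DESeq-style: per-gene geometric means over the supplied samples, then the
#' per-sample median of count/geomean over genes with positive geometric
#' mean.
#'
#' @param counts genes x samples matrix.
#' @return numeric size factors, one per sample.
#' @export
size_factors_mor <- function(counts) {
  lg <- log(counts)
  lg[!is.finite(lg)] <- NA
  geo <- exp(rowMeans(lg))
  keep <- is.finite(geo) & geo > 0
  if (!any(keep)) stop("no gene with all-positive counts; cannot normalize")
  apply(counts[keep, , drop = FALSE], 2, function(cn) median(cn / geo[keep]))
}

# vectorized two-sample Welch test over matrix rows
row_welch <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(t), df)
  p[se2 == 0 & ma == mb] <- 1
  list(t = t, df = df, p = p)
}

#' Differential expression of one knockout line against wild type
#'
#' log2 fold change is computed from mean normalized counts (median-of-
#' ratios size factors over the compared samples); a pseudocount of 0.5 is
#' used when a group mean is zero. The p-value is a two-sample Welch test on
#' log2(normalized count + 0.5); FDR by Benjamini-Hochberg.
#'
#' @param counts a `count_matrix`.
#' @param ko_line knockout group label.
#' @param wt_line reference group label (default "WT").
#' @return data.frame of `DeRecord`s: gene, ko_line, log2fc, pvalue, fdr.
#' @export
differential_expression <- function(counts, ko_line, wt_line = "WT") {
  stopifnot(inherits(counts, "count_matrix"))
  sel_ko <- counts$samples$line == ko_line
  sel_wt <- counts$samples$line == wt_line
  if (sum(sel_ko) < 2 || sum(sel_wt) < 2) {
    stop("at least 2 replicates per compared group required")
  }
  sub <- counts$counts[, sel_ko | sel_wt, drop = FALSE]
  if (any(colSums(sub) == 0)) stop("degenerate all-zero library in comparison")
  sf <- size_factors_mor(sub)
  norm <- sweep(sub, 2, sf, "/")
  ko <- norm[, counts$samples$line[sel_ko | sel_wt] == ko_line, drop = FALSE]
  wt <- norm[, counts$samples$line[sel_ko | sel_wt] == wt_line, drop = FALSE]
  mko <- rowMeans(ko); mwt <- rowMeans(wt)
  lfc <- log2(ifelse(mko > 0, mko, 0.5) / ifelse(mwt > 0, mwt, 0.5))
  lfc[mko == 0 & mwt == 0] <- 0
  w <- row_welch(log2(ko + 0.5), log2(wt + 0.5))
  data.frame(gene = rownames(sub) %||% paste0("g", seq_len(nrow(sub))),
             ko_line = ko_line, log2fc = lfc, pvalue = w$p,
             fdr = benjamini_hochberg(w$p), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param pvalues numeric vector in [0, 1] (NA allowed, propagated).
#' @return adjusted values, monotone nondecreasing in p-rank.
#' @export
benjamini_hochberg <- function(pvalues) {
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  out <- rep(NA_real_, length(pvalues))
  if (n) {
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    adj <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
    out[ok] <- adj
  }
  out
}

#' Read an externally computed differential-expression table
#'
#' TSV schema: gene, log2fc, pvalue, fdr, line. Preserves fidelity when a
#' full DESeq2/edgeR pipeline was run upstream.
#'
#' @param path TSV file path.
#' @return data.frame of DeRecords.
#' @export
read_de_table <- function(path) {
  de <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "pvalue", "fdr", "line")
  if (!all(need %in% names(de))) {
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  }
  names(de)[names(de) == "line"] <- "ko_line"
  de[c("gene", "ko_line", "log2fc", "pvalue", "fdr")]
}

#' Select differentially expressed genes
#'
#' DEG rule: absolute fold change at least `fc_min` (either direction) AND
#' FDR strictly below `fdr_max`.
#'
#' @param de data.frame of DeRecords.
#' @param fc_min minimum fold change on the linear scale (default 2).
#' @param fdr_max FDR threshold, strict (default 0.05).
#' @return character vector of gene ids.
#' @export
select_degs <- function(de, fc_min = 2, fdr_max = 0.05) {
  if (fc_min < 1) stop("fc_min must be >= 1")
  if (!nrow(de)) return(character())
  sel <- abs(de$log2fc) >= log2(fc_min) & !is.na(de$fdr) & de$fdr < fdr_max
  unique(de$gene[sel])
}

#' Select and pool differentially expressed targets across knockout lines
#'
#' Per line, DET = DEGs intersected with the genes predicted as targets of
#' ANY family miRNA. The pooled DET set contains genes supported by at least
#' `min_lines` lines; the all-lines intersection is also reported. Pooling
#' is by gene identity only; per-line fold-change signs are reported but not
#' required to agree.
#'
#' @param deg_sets named list: knockout line -> character vector of DEGs.
#' @param target_map a `target_map` (or character vector of target genes).
#' @param min_lines minimum line support for the pool (default 2).
#' @return a `det_pool` list: per_line (list), pooled (data.frame gene,
#'   support), all_lines (character), params.
#' @export
select_dets <- function(deg_sets, target_map, min_lines = 2L) {
  if (min_lines > length(deg_sets)) {
    stop("min_lines exceeds the number of knockout lines supplied")
  }
  targeted <- if (inherits(target_map, "target_map")) {
    unique(unlist(target_map$targets, use.names = FALSE))
  } else as.character(target_map)
  per_line <- lapply(deg_sets, function(g) intersect(g, targeted))
  support <- table(unlist(per_line, use.names = FALSE))
  pooled <- data.frame(gene = as.character(names(support) %||% character()),
                       support = as.integer(support),
                       stringsAsFactors = FALSE)
  pooled <- pooled[pooled$support >= min_lines, , drop = FALSE]
  pooled <- pooled[order(pooled$gene), , drop = FALSE]
  rownames(pooled) <- NULL
  all_lines <- Reduce(intersect, per_line)
  structure(list(per_line = per_line, pooled = pooled,
                 all_lines = sort(all_lines),
                 params = list(min_lines = min_lines)),
            class = "det_pool")
}
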