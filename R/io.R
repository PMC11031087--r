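# Format I/O. All intervals are 0-based half-open internally; 1-based
# conventions appear only at the VCF boundary. Malformed lines raise
# errors with file/line diagnostics — never a silent skip.

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings that move between files and named
#' character vectors.
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read / write BED6
#'
#' BED is 0-based half-open. Columns beyond the sixth are ignored on read.
#'
#' @param path file path.
#' @return data.frame: chrom, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(rows, length, integer(1)) < 3)
  if (length(bad)) {
    stop("malformed BED line ", bad[1], " in ", path, ": fewer than 3 fields")
  }
  df <- data.frame(
    chrom = vapply(rows, `[`, character(1), 1),
    start = as.integer(vapply(rows, `[`, character(1), 2)),
    end = as.integer(vapply(rows, `[`, character(1), 3)),
    name = vapply(rows, function(r) if (length(r) >= 4) r[4] else ".",
                  character(1)),
    score = vapply(rows, function(r) if (length(r) >= 5) r[5] else "0",
                   character(1)),
    strand = vapply(rows, function(r) if (length(r) >= 6) r[6] else "+",
                    character(1)),
    stringsAsFactors = FALSE)
  if (anyNA(df$start) || anyNA(df$end) || any(df$start < 0) ||
      any(df$end <= df$start)) {
    bad <- which(is.na(df$start) | is.na(df$end) | df$start < 0 |
                   df$end <= df$start)[1]
    stop("malformed BED interval at line ", bad, " in ", path)
  }
  df
}

#' @rdname read_bed
#' @param bed data.frame with chrom, start, end and optionally name, score,
#'   strand.
#' @export
write_bed <- function(bed, path) {
  out <- data.frame(bed$chrom, bed$start, bed$end,
                    bed$name %||% ".", bed$score %||% 0,
                    bed$strand %||% "+")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph conservation track
#'
#' Intervals are 0-based half-open; overlapping intervals within a
#' chromosome are rejected with a diagnostic.
#'
#' @param path file path.
#' @param semantics "phylop" or "phastcons".
#' @return a `cons_track`.
#' @export
read_bedgraph <- function(path, semantics = "phylop") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  rows <- strsplit(lines, "[ \t]+")
  bad <- which(vapply(rows, length, integer(1)) != 4)
  if (length(bad)) {
    stop("malformed bedGraph line ", bad[1], " in ", path,
         ": expected 4 fields")
  }
  df <- data.frame(chrom = vapply(rows, `[`, character(1), 1),
                   start = as.integer(vapply(rows, `[`, character(1), 2)),
                   end = as.integer(vapply(rows, `[`, character(1), 3)),
                   score = as.numeric(vapply(rows, `[`, character(1), 4)),
                   stringsAsFactors = FALSE)
  if (anyNA(df)) stop("non-numeric field in bedGraph ", path)
  cons_track(df, semantics = semantics)
}

#' Minimal VCF reader
#'
#' Extracts chromosome, 1-based position (converted to 0-based), id,
#' alleles, and a derived-allele-frequency source field (INFO key `DAF=`;
#' falls back to `AF=`). Everything else is ignored. Intended for small
#' variant tables; use a full VCF stack for production data.
#'
#' @param path file path.
#' @return data.frame: chrom, pos0, id, ref, alt, daf.
#' @export
read_vcf_minimal <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(rows, length, integer(1)) < 8)
  if (length(bad)) {
    stop("malformed VCF record at data line ", bad[1], " in ", path)
  }
  info <- vapply(rows, `[`, character(1), 8)
  daf <- suppressWarnings(as.numeric(vapply(info, function(x) {
    kv <- strsplit(x, ";", fixed = TRUE)[[1]]
    v <- kv[startsWith(kv, "DAF=")]
    if (!length(v)) v <- kv[startsWith(kv, "AF=")]
    if (!length(v)) NA_character_ else sub("^[A-Z]+=", "", v[1])
  }, character(1), USE.NAMES = FALSE)))
  data.frame(chrom = vapply(rows, `[`, character(1), 1),
             pos0 = as.integer(vapply(rows, `[`, character(1), 2)) - 1L,
             id = vapply(rows, `[`, character(1), 3),
             ref = vapply(rows, `[`, character(1), 4),
             alt = vapply(rows, `[`, character(1), 5),
             daf = daf, stringsAsFactors = FALSE)
}

#' Read / write a count matrix TSV
#'
#' Genes in rows; sample columns named `<line>_<replicate>` (e.g. WT_1,
#' ko1_2), from which group labels are parsed.
#'
#' @param path file path.
#' @return a `count_matrix`.
#' @export
read_counts_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                   check.names = FALSE)
  m <- as.matrix(df)
  line <- sub("_[^_]+$", "", colnames(m))
  count_matrix(m, line = line)
}

#' @rdname read_counts_tsv
#' @param counts a `count_matrix`.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene = rownames(counts$counts), counts$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Lift target sites from UTR to genomic coordinates
#'
#' Inverse of [map_scores_to_utr()]: splits each site across the UTR's
#' genomic blocks; on the minus strand coordinates are mirrored so genomic
#' start < end always. BED output convention (0-based half-open).
#'
#' @param sites data.frame of target sites in UTR coordinates.
#' @param utr a `utr_record` with `genomic_intervals`.
#' @return data.frame: chrom, start, end, name, score, strand (one or more
#'   rows per site; lengths per site sum to the site length).
#' @export
lift_sites_to_genome <- function(sites, utr) {
  gi <- utr$genomic_intervals
  if (is.null(gi)) stop("UTR has no genomic_intervals: ", utr$transcript)
  blen <- gi$end - gi$start
  ulen <- sum(blen)
  offs <- cumsum(c(0L, blen))  # UTR offset at which each block starts
  out <- list()
  for (r in seq_len(nrow(sites))) {
    s <- sites$start[r]; e <- sites$end[r]
    if (s < 0 || e > ulen) {
      stop("site [", s, ",", e, ") beyond UTR length ", ulen, " for ",
           utr$transcript)
    }
    for (b in seq_len(nrow(gi))) {
      lo <- max(s, offs[b]); hi <- min(e, offs[b + 1L])
      if (hi <= lo) next
      if (gi$strand[b] == "+") {
        g_lo <- gi$start[b] + (lo - offs[b])
        g_hi <- gi$start[b] + (hi - offs[b])
      } else {
        g_hi <- gi$end[b] - (lo - offs[b])
        g_lo <- gi$end[b] - (hi - offs[b])
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = gi$chrom[b], start = g_lo, end = g_hi,
        name = paste(sites$mirna[r], sites$site_class[r],
                     sites$predictor_tier[r] %||% ".", sep = "|"),
        score = 0L, strand = gi$strand[b], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
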