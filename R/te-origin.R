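# Transposon-origin screen: local alignment of transposon consensus
# sequences to miRNA loci with an identity threshold, a base-pair-
# maximization hairpin heuristic (standing in for thermodynamic folding:
# miRNA biogenesis needs hairpin capability, not free energies), and the
# directional substitution spectrum of an aligned family.

#' Smith-Waterman local alignment with affine gaps
#'
#' Gotoh dynamic programming; a gap of length L costs
#' `gap_open + L * gap_extend` (both negative). Identity is matches divided
#' by aligned columns, gaps counting as columns. Defaults sit near BLASTN
#' scoring.
#'
#' @param a,b sequences (DNA or RNA; alignment runs in the normalized
#'   alphabet of the inputs).
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return list: score, identity, a_start/a_end and b_start/b_end (1-based
#'   inclusive spans), gaps, n_columns, aligned_a, aligned_b.
#' @export
local_align <- function(a, b, match = 2, mismatch = -3,
                        gap_open = -5, gap_extend = -2) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be nonempty")
  x <- seq_chars(toupper(a)); y <- seq_chars(toupper(b))
  n <- length(x); m <- length(y)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap in a (consuming b)
  F <- matrix(NEG, n + 1, m + 1)  # gap in b (consuming a)
  ptr <- matrix(0L, n + 1, m + 1) # 1 diag, 2 up (F), 3 left (E)
  best <- 0; bi <- 0L; bj <- 0L
  for (i in 2:(n + 1)) {
    Hi1 <- H[i - 1, ]
    Fi <- pmax(Hi1 + gap_open + gap_extend, F[i - 1, ] + gap_extend)
    F[i, ] <- Fi
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] + gap_open + gap_extend,
                     E[i, j - 1] + gap_extend)
      s <- Hi1[j - 1] + if (x[i - 1] == y[j - 1]) match else mismatch
      h <- max(0, s, Fi[j], E[i, j])
      H[i, j] <- h
      ptr[i, j] <- if (h == 0) 0L else if (h == s) 1L else
        if (h == Fi[j]) 2L else 3L
      if (h > best) { best <- h; bi <- i; bj <- j }
    }
  }
  if (best <= 0) {
    return(list(score = 0, identity = 0, a_start = NA, a_end = NA,
                b_start = NA, b_end = NA, gaps = 0L, n_columns = 0L,
                aligned_a = "", aligned_b = ""))
  }
  # traceback (re-deriving gap runs greedily from the stored state)
  i <- bi; j <- bj
  al_a <- character(); al_b <- character()
  while (i > 1 && j > 1 && H[i, j] > 0) {
    p <- ptr[i, j]
    if (p == 1L) {
      al_a <- c(x[i - 1], al_a); al_b <- c(y[j - 1], al_b)
      i <- i - 1; j <- j - 1
    } else if (p == 2L) {        # gap in b: consume a
      repeat {
        al_a <- c(x[i - 1], al_a); al_b <- c("-", al_b)
        stop_here <- abs(F[i, j] - (H[i - 1, j] + gap_open + gap_extend)) <
          1e-9
        i <- i - 1
        if (stop_here || i <= 1) break
      }
    } else if (p == 3L) {        # gap in a: consume b
      repeat {
        al_a <- c("-", al_a); al_b <- c(y[j - 1], al_b)
        stop_here <- abs(E[i, j] - (H[i, j - 1] + gap_open + gap_extend)) <
          1e-9
        j <- j - 1
        if (stop_here || j <= 1) break
      }
    } else break
  }
  ncol_aln <- length(al_a)
  matches <- sum(al_a == al_b & al_a != "-")
  gaps <- sum(al_a == "-") + sum(al_b == "-")
  list(score = best, identity = matches / ncol_aln,
       a_start = i, a_end = bi - 1L, b_start = j, b_end = bj - 1L,
       gaps = gaps, n_columns = ncol_aln,
       aligned_a = paste(al_a, collapse = ""),
       aligned_b = paste(al_b, collapse = ""))
}

#' Screen a transposon library for miRNA-locus sources
#'
#' Aligns every transposon consensus against every miRNA locus on both
#' strands and keeps pairs with identity at least `identity_min` over at
#' least `min_span` aligned columns. Transposons are ranked by the number
#' of loci hit; when loci are supplied per species, transposons hitting at
#' least one locus in every species are flagged.
#'
#' @param te_library named character vector of transposon consensus
#'   sequences.
#' @param mirna_loci named character vector of locus sequences, or a named
#'   list of such vectors (one per species).
#' @param identity_min identity threshold in (0, 1] (default 0.94).
#' @param min_span minimum aligned columns (default 50).
#' @param ... scoring parameters passed to [local_align()].
#' @return list: hits (data.frame te, locus, species, strand, identity,
#'   span, score), ranking (data.frame te, n_loci, all_species).
#' @export
screen_te_sources <- function(te_library, mirna_loci, identity_min = 0.94,
                              min_span = 50L, ...) {
  if (!length(te_library)) stop("transposon library is empty")
  if (identity_min <= 0 || identity_min > 1) {
    stop("identity_min must lie in (0, 1]")
  }
  if (min_span <= 0) stop("min_span must be positive")
  loci_by_sp <- if (is.list(mirna_loci)) mirna_loci else
    list(all = mirna_loci)
  rows <- list()
  for (sp in names(loci_by_sp)) {
    loci <- loci_by_sp[[sp]]
    for (te in names(te_library)) {
      for (lc in names(loci)) {
        for (strand in c("+", "-")) {
          subj <- if (strand == "+") loci[[lc]] else
            revcomp_dna(loci[[lc]])
          al <- local_align(te_library[[te]], subj, ...)
          if (al$n_columns >= min_span && al$identity >= identity_min) {
            rows[[length(rows) + 1L]] <- data.frame(
              te = te, locus = lc, species = sp, strand = strand,
              identity = al$identity, span = al$n_columns,
              score = al$score, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(te = character(), locus = character(), species = character(),
               strand = character(), identity = numeric(), span = integer(),
               score = numeric(), stringsAsFactors = FALSE)
  # best hit per (te, locus, species)
  if (nrow(hits)) {
    key <- paste(hits$te, hits$locus, hits$species, sep = "\r")
    hits <- do.call(rbind, lapply(split(hits, key), function(d) {
      d[which.max(d$score), , drop = FALSE]
    }))
    rownames(hits) <- NULL
  }
  n_species <- length(loci_by_sp)
  ranking <- do.call(rbind, lapply(names(te_library), function(te) {
    h <- hits[hits$te == te, , drop = FALSE]
    data.frame(te = te, n_loci = nrow(h),
               all_species = length(unique(h$species)) == n_species &
                 nrow(h) > 0,
               stringsAsFactors = FALSE)
  }))
  ranking <- ranking[order(-ranking$n_loci), , drop = FALSE]
  rownames(ranking) <- NULL
  list(hits = hits, ranking = ranking)
}

revcomp_dna <- function(x) {
  vapply(x, function(s) {
    paste(rev(seq_chars(chartr("ACGTUacgtu", "TGCAAtgcaa", s))),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Nussinov maximum base pairing (Watson-Crick + G:U, minimum loop length)
# returning the DP matrix; O(n^2) memory, O(n^3) time with a vectorized
# inner maximization.
nussinov_matrix <- function(bases, min_loop = 3L) {
  n <- length(bases)
  can_pair <- function(a, b) {
    (a == "A" && b == "U") || (a == "U" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G") ||
      (a == "G" && b == "U") || (a == "U" && b == "G")
  }
  M <- matrix(0L, n, n)
  if (n - 1L < min_loop + 1L) return(M)
  for (span in (min_loop + 1L):(n - 1L)) {
    for (i in 1:(n - span)) {
      j <- i + span
      best <- M[i, j - 1L]
      # j pairs with some k in [i, j - min_loop - 1]
      ks <- i:(j - min_loop - 1L)
      pairable <- vapply(ks, function(k) can_pair(bases[k], bases[j]),
                         logical(1))
      ks <- ks[pairable]
      if (length(ks)) {
        left <- ifelse(ks > i, M[cbind(pmax(i, 1L), pmax(ks - 1L, 1L))], 0L)
        left[ks == i] <- 0L
        inner <- M[cbind(pmin(ks + 1L, n), max(j - 1L, 1L))]
        inner[ks + 1L > j - 1L] <- 0L
        best <- max(best, max(1L + left + inner))
      }
      M[i, j] <- best
    }
  }
  M
}

nussinov_traceback <- function(M, bases, min_loop = 3L) {
  can_pair <- function(a, b) {
    (a == "A" && b == "U") || (a == "U" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G") ||
      (a == "G" && b == "U") || (a == "U" && b == "G")
  }
  pairs <- list()
  stack <- list(c(1L, length(bases)))
  while (length(stack)) {
    ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (j - i <= min_loop) next
    if (M[i, j] == M[i, j - 1L]) {
      stack[[length(stack) + 1L]] <- c(i, j - 1L)
      next
    }
    for (k in i:(j - min_loop - 1L)) {
      if (!can_pair(bases[k], bases[j])) next
      left <- if (k > i) M[i, k - 1L] else 0L
      inner <- if (k + 1L <= j - 1L) M[k + 1L, j - 1L] else 0L
      if (M[i, j] == 1L + left + inner) {
        pairs[[length(pairs) + 1L]] <- c(k, j)
        if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
        if (k + 1L <= j - 1L) stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
        break
      }
    }
  }
  if (!length(pairs)) return(matrix(integer(), 0, 2))
  do.call(rbind, pairs)
}

# a structure is a single stem-loop if no pair directly encloses >= 2
# child pairs (no multiloop)
is_single_stemloop <- function(pairs, n) {
  if (!nrow(pairs)) return(FALSE)
  parent_children <- function(lo, hi) {
    inside <- pairs[pairs[, 1] > lo & pairs[, 2] < hi, , drop = FALSE]
    if (!nrow(inside)) return(0L)
    # top-level pairs within (lo, hi)
    inside <- inside[order(inside[, 1]), , drop = FALSE]
    count <- 0L; pos <- lo
    for (r in seq_len(nrow(inside))) {
      if (inside[r, 1] > pos) {
        count <- count + 1L
        pos <- inside[r, 2]
      }
    }
    count
  }
  if (parent_children(0L, n + 1L) > 1L) return(FALSE)
  for (r in seq_len(nrow(pairs))) {
    if (parent_children(pairs[r, 1], pairs[r, 2]) > 1L) return(FALSE)
  }
  TRUE
}

#' Hairpin-capability check by base-pair maximization
#'
#' Slides a window over the sequence, maximizes Watson-Crick + G:U base
#' pairs (Nussinov recursion, minimum loop `min_loop`) in each window, and
#' reports the best window. The sequence is called hairpin-capable when the
#' best structure has at least `min_pairs` pairs, pairs at least
#' `min_paired_fraction` of the window, and forms a single dominant
#' stem-loop (no multiloop in the traceback). DNA input is transcribed
#' (T -> U) first.
#'
#' @param seq nucleotide sequence.
#' @param window window length (default 100; capped at the sequence
#'   length).
#' @param step window step (default 10).
#' @param min_loop minimum hairpin loop length (default 3).
#' @param min_pairs minimum base pairs (default 18).
#' @param min_paired_fraction minimum fraction of window bases paired
#'   (default 0.3).
#' @return a `hairpin_report` list: id, stem_pairs, loop_length,
#'   paired_fraction, is_hairpin, window (1-based start/end), dotbracket.
#' @export
hairpin_check <- function(seq, window = 100L, step = 10L, min_loop = 3L,
                          min_pairs = 18L, min_paired_fraction = 0.3) {
  s <- normalize_rna(seq)
  n <- nchar(s)
  if (n < 2 * min_pairs + min_loop) {
    stop("sequence too short for the requested hairpin geometry")
  }
  window <- min(window, n)
  starts <- unique(c(seq(1L, max(1L, n - window + 1L), by = step),
                     n - window + 1L))
  bases_all <- seq_chars(s)
  best <- NULL
  for (st in starts) {
    bases <- bases_all[st:(st + window - 1L)]
    M <- nussinov_matrix(bases, min_loop)
    np <- M[1, length(bases)]
    if (is.null(best) || np > best$np) {
      best <- list(st = st, np = np, bases = bases, M = M)
    }
  }
  pairs <- nussinov_traceback(best$M, best$bases, min_loop)
  single <- is_single_stemloop(pairs, length(best$bases))
  paired_fraction <- 2 * best$np / length(best$bases)
  loop_len <- if (nrow(pairs)) {
    inner <- pairs[which.max(pairs[, 1]), ]
    inner[2] - inner[1] - 1L
  } else NA_integer_
  db <- rep(".", length(best$bases))
  if (nrow(pairs)) { db[pairs[, 1]] <- "("; db[pairs[, 2]] <- ")" }
  structure(list(
    id = names(seq) %||% NA_character_,
    stem_pairs = best$np, loop_length = loop_len,
    paired_fraction = paired_fraction,
    is_hairpin = best$np >= min_pairs &&
      paired_fraction >= min_paired_fraction && single,
    window = c(start = best$st, end = best$st + length(best$bases) - 1L),
    dotbracket = paste(db, collapse = "")),
    class = "hairpin_report")
}

#' Directional substitution spectrum of an aligned family
#'
#' Per alignment column, derives a reference base (majority consensus, ties
#' broken in A < C < G < U order, or a designated outgroup row) and tallies
#' reference -> member substitutions into a 4 x 4 matrix over the RNA
#' alphabet. Columns where the reference (or the member, per cell) is a gap
#' are skipped.
#'
#' @param family named character vector of pre-aligned sequences (equal
#'   lengths; "-" for gaps; T is normalized to U).
#' @param reference_policy "consensus" or "designated_outgroup".
#' @param outgroup name of the outgroup sequence (required for the
#'   outgroup policy; the outgroup row is excluded from the tally).
#' @return a `substitution_spectrum`: list(counts = 4x4 matrix from -> to,
#'   reference_policy).
#' @export
substitution_spectrum <- function(family,
                                  reference_policy = c("consensus",
                                                       "designated_outgroup"),
                                  outgroup = NULL) {
  reference_policy <- match.arg(reference_policy)
  family <- vapply(family, function(s) chartr("tT", "uU", s), character(1))
  family <- toupper(family)
  lens <- nchar(family)
  if (length(unique(lens)) != 1) {
    stop("sequences must be pre-aligned (equal lengths)")
  }
  mat <- do.call(rbind, strsplit(family, ""))
  rownames(mat) <- names(family)
  if (reference_policy == "designated_outgroup") {
    if (is.null(outgroup) || !outgroup %in% rownames(mat)) {
      stop("outgroup must name one of the aligned sequences")
    }
    ref <- mat[outgroup, ]
    members <- mat[rownames(mat) != outgroup, , drop = FALSE]
  } else {
    ref <- apply(mat, 2, function(col) {
      col <- col[col %in% RNA_BASES]
      if (!length(col)) return("-")
      tab <- table(factor(col, levels = RNA_BASES))
      RNA_BASES[which.max(tab)]
    })
    members <- mat
  }
  counts <- matrix(0L, 4, 4, dimnames = list(from = RNA_BASES,
                                             to = RNA_BASES))
  for (j in seq_along(ref)) {
    if (!ref[j] %in% RNA_BASES) next
    col <- members[, j]
    col <- col[col %in% RNA_BASES & col != ref[j]]
    for (b in col) counts[ref[j], b] <- counts[ref[j], b] + 1L
  }
  structure(list(counts = counts, reference_policy = reference_policy),
            class = "substitution_spectrum")
}
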