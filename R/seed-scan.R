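# Seed-match target prediction over 3'UTRs.
#
# A mature miRNA binds a 3'UTR through its seed (nucleotides 2-7). The UTR
# sense strand carries the reverse complement of the seed; canonical site
# classes extend the 6-nt core with a match to miRNA position 8 (7mer-m8),
# an adenine opposite miRNA position 1 (7mer-A1), or both (8mer).

SITE_CLASSES <- c("6mer", "7mer-A1", "7mer-m8", "8mer")

site_class_rank <- function(x) match(x, SITE_CLASSES)

#' Construct a mature miRNA record
#'
#' @param name miRNA identifier.
#' @param mature_seq mature sequence 5'->3' (DNA or RNA; normalized to RNA).
#' @param cluster,family,species optional grouping identifiers.
#' @return a `mirna_record` (named list) with the seed (positions 2-7)
#'   extracted.
#' @export
mirna_record <- function(name, mature_seq, cluster = NA_character_,
                         family = NA_character_, species = NA_character_) {
  mature_seq <- normalize_rna(mature_seq)
  if (nchar(mature_seq) < 8) {
    stop("mature miRNA sequence must be at least 8 nt: ", name)
  }
  structure(list(name = name, cluster = cluster, family = family,
                 species = species, mature_seq = mature_seq,
                 seed = substr(mature_seq, 2, 7)),
            class = "mirna_record")
}

#' Extract the seed sequence (positions 2-7) of a mature miRNA
#'
#' @param mirna a `mirna_record`, or a character sequence (normalized first).
#' @return 6-nt seed string.
#' @export
extract_seed <- function(mirna) {
  if (inherits(mirna, "mirna_record")) return(mirna$seed)
  s <- normalize_rna(mirna)
  if (nchar(s) < 8) stop("mature miRNA sequence must be at least 8 nt")
  substr(s, 2, 7)
}

#' Construct a 3'UTR record
#'
#' @param gene,transcript identifiers.
#' @param seq sense-strand sequence 5'->3' (normalized to RNA).
#' @param species optional species label.
#' @param genomic_intervals optional data.frame (chrom, start, end, strand),
#'   0-based half-open, listed in transcript 5'->3' order; interval lengths
#'   must sum to the sequence length.
#' @return a `utr_record`.
#' @export
utr_record <- function(gene, transcript = gene, seq, species = NA_character_,
                       genomic_intervals = NULL) {
  seq <- normalize_rna(seq)
  if (!nzchar(seq)) stop("UTR sequence must be nonempty: ", gene)
  if (!is.null(genomic_intervals)) {
    stopifnot(all(c("chrom", "start", "end", "strand") %in%
                    names(genomic_intervals)))
    if (sum(genomic_intervals$end - genomic_intervals$start) != nchar(seq)) {
      stop("genomic interval lengths must sum to UTR length: ", transcript)
    }
  }
  structure(list(gene = gene, transcript = transcript, species = species,
                 seq = seq, genomic_intervals = genomic_intervals),
            class = "utr_record")
}

empty_sites <- function() {
  data.frame(mirna = character(), transcript = character(),
             start = integer(), end = integer(),
             site_class = character(), wobble_count = integer(),
             predictor_tier = character(), stringsAsFactors = FALSE)
}

#' Scan one 3'UTR for seed-match sites of one miRNA
#'
#' Finds every position where the UTR sense strand (5'->3') pairs
#' antiparallel with the miRNA seed (positions 2-7), classifies each locus
#' as 6mer, 7mer-A1, 7mer-m8 or 8mer, and optionally tolerates up to
#' `max_wobble` G:U pairs within the seed duplex (positions 2-7 only; the
#' m8 match must be Watson-Crick, the A1 position must be a literal A on the
#' UTR). Overlapping site classes at one seed locus are collapsed to the
#' highest class. Coordinates are 0-based half-open in UTR space and span
#' the full matched element (6-8 nt depending on class). Ambiguity codes
#' never match.
#'
#' @param utr a `utr_record` or plain sequence.
#' @param mirna a `mirna_record` or plain mature sequence.
#' @param allow_wobble allow G:U pairs in the seed duplex?
#' @param max_wobble maximum number of wobble pairs per site.
#' @param tier label stored in `predictor_tier`.
#' @return data.frame of target sites (possibly 0-row).
#' @export
scan_utr <- function(utr, mirna, allow_wobble = FALSE, max_wobble = 1L,
                     tier = "default") {
  if (!inherits(utr, "utr_record")) utr <- utr_record("utr", seq = utr)
  if (!inherits(mirna, "mirna_record")) mirna <- mirna_record("mirna", mirna)
  u <- seq_chars(utr$seq)
  n <- length(u)
  if (n < 6) return(empty_sites())
  m <- seq_chars(mirna$mature_seq)
  if (!allow_wobble) max_wobble <- 0L

  # core window starting at i (1-based) covers UTR[i..i+5]; UTR position
  # i+j (j = 0..5) pairs with miRNA position 7-j
  starts <- seq_len(n - 5L)
  ok <- rep(TRUE, length(starts))
  wob <- integer(length(starts))
  for (j in 0:5) {
    mb <- m[7 - j]
    ub <- u[starts + j]
    wc <- !is.na(WC_COMP[mb]) & ub == WC_COMP[mb]
    wp <- WOBBLE_PARTNER[mb]
    wo <- if (is.na(wp)) rep(FALSE, length(ub)) else ub == wp
    wo <- wo & !wc
    ok <- ok & (wc | wo)
    wob <- wob + as.integer(wo)
  }
  hit <- which(ok & wob <= max_wobble)
  if (!length(hit)) return(empty_sites())

  res <- lapply(hit, function(i) {
    has_m8 <- length(m) >= 8 && i > 1L && !is.na(WC_COMP[m[8]]) &&
      u[i - 1L] == WC_COMP[m[8]]
    has_a1 <- (i + 6L) <= n && u[i + 6L] == "A"
    cls <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
      else if (has_a1) "7mer-A1" else "6mer"
    s0 <- i - 1L - as.integer(has_m8)      # 0-based start
    e0 <- i + 5L + as.integer(has_a1)      # 0-based end (half-open)
    data.frame(mirna = mirna$name, transcript = utr$transcript,
               start = s0, end = e0, site_class = cls,
               wobble_count = wob[i], predictor_tier = tier,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Define a scanning stringency tier
#'
#' Tiers emulate target-prediction databases of different stringency. The
#' two defaults are a stringent tier (site class at least 7mer, no wobble)
#' and a permissive tier (6mer allowed, one G:U wobble).
#'
#' @param name tier label.
#' @param allow_wobble,max_wobble wobble policy.
#' @param min_class minimum site class retained
#'   (one of "6mer", "7mer-A1", "7mer-m8", "8mer"; classes rank in that
#'   order).
#' @return a `scan_tier` list.
#' @export
scan_tier <- function(name, allow_wobble = FALSE, max_wobble = 1L,
                      min_class = "6mer") {
  if (!min_class %in% SITE_CLASSES) stop("unknown site class: ", min_class)
  structure(list(name = name, allow_wobble = allow_wobble,
                 max_wobble = max_wobble, min_class = min_class),
            class = "scan_tier")
}

#' @rdname scan_tier
#' @export
default_tiers <- function() {
  list(scan_tier("stringent", allow_wobble = FALSE, min_class = "7mer-A1"),
       scan_tier("permissive", allow_wobble = TRUE, max_wobble = 1L,
                 min_class = "6mer"))
}

#' Predict targets of a miRNA set over a 3'UTR set
#'
#' Runs `scan_utr` once per tier; a transcript is a predicted target of a
#' miRNA if ANY tier yields at least one site (union semantics). Sites carry
#' their tier label.
#'
#' @param mirnas list of `mirna_record`s.
#' @param utrs list of `utr_record`s.
#' @param tiers nonempty list of `scan_tier`s (default `default_tiers()`).
#' @return a `target_map`: list with `sites` (data.frame of all sites),
#'   `targets` (named list miRNA -> character vector of target transcripts)
#'   and `species`.
#' @export
predict_targets <- function(mirnas, utrs, tiers = default_tiers()) {
  if (!length(tiers)) stop("tiers must be nonempty")
  for (t in tiers) if (!inherits(t, "scan_tier")) stop("unknown tier object")
  all_sites <- list()
  for (tier in tiers) {
    for (mi in mirnas) {
      for (ut in utrs) {
        s <- scan_utr(ut, mi, allow_wobble = tier$allow_wobble,
                      max_wobble = tier$max_wobble, tier = tier$name)
        if (nrow(s)) {
          s <- s[site_class_rank(s$site_class) >=
                   site_class_rank(tier$min_class), , drop = FALSE]
          if (nrow(s)) all_sites[[length(all_sites) + 1L]] <- s
        }
      }
    }
  }
  sites <- if (length(all_sites)) do.call(rbind, all_sites) else empty_sites()
  sites <- unique(sites)
  rownames(sites) <- NULL
  mirna_names <- vapply(mirnas, function(m) m$name, character(1))
  targets <- lapply(setNames(mirna_names, mirna_names), function(mn) {
    sort(unique(sites$transcript[sites$mirna == mn]))
  })
  sp <- unique(na.omit(vapply(mirnas, function(m) m$species, character(1))))
  structure(list(sites = sites, targets = targets,
                 species = if (length(sp) == 1) sp else NA_character_),
            class = "target_map")
}
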