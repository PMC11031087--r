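# Independent oracles used across the suite. These deliberately re-derive
# results with naive algorithms (exhaustive enumeration, brute-force
# tallies) and share no code with the implementation paths they check.

# --- seed-match scanning oracle: naive per-window pairing check ----------

oracle_scan <- function(utr_seq, mature_seq, allow_wobble = FALSE,
                        max_wobble = 1L) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  u <- strsplit(utr_seq, "")[[1]]
  m <- strsplit(mature_seq, "")[[1]]
  n <- length(u)
  out <- list()
  if (n < 6) return(out)
  for (i in 1:(n - 5)) {
    wob <- 0L; ok <- TRUE
    for (j in 0:5) {
      mb <- m[7 - j]; ub <- u[i + j]
      if (!mb %in% names(comp) || !ub %in% names(comp)) { ok <- FALSE; break }
      if (ub == comp[[mb]]) next
      if (allow_wobble &&
          ((mb == "G" && ub == "U") || (mb == "U" && ub == "G"))) {
        wob <- wob + 1L
        next
      }
      ok <- FALSE; break
    }
    if (!ok || wob > (if (allow_wobble) max_wobble else 0L)) next
    has_m8 <- length(m) >= 8 && i > 1 && m[8] %in% names(comp) &&
      u[i - 1] == comp[[m[8]]]
    has_a1 <- (i + 6) <= n && u[i + 6] == "A"
    cls <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8" else
      if (has_a1) "7mer-A1" else "6mer"
    out[[length(out) + 1L]] <- list(
      start = i - 1L - as.integer(has_m8),
      end = i + 5L + as.integer(has_a1),
      site_class = cls, wobble_count = wob)
  }
  out
}

oracle_scan_df <- function(utr_seq, mature_seq, ...) {
  o <- oracle_scan(utr_seq, mature_seq, ...)
  if (!length(o)) {
    return(data.frame(start = integer(), end = integer(),
                      site_class = character(), wobble_count = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(o, as.data.frame, stringsAsFactors = FALSE))
}

random_rna_str <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# --- Nussinov oracle: memoized top-down recursion ------------------------

oracle_nussinov <- function(seq, min_loop = 3L) {
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  pairs_ok <- function(x, y) {
    paste0(x, y) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i, j - 1L)
    for (k in i:(j - min_loop - 1L)) {
      if (pairs_ok(b[k], b[j])) {
        left <- if (k > i) rec(i, k - 1L) else 0L
        inner <- if (k + 1L <= j - 1L) rec(k + 1L, j - 1L) else 0L
        cand <- 1L + left + inner
        if (cand > best) best <- cand
      }
    }
    memo[[key]] <- best
    best
  }
  if (n < 2) return(0L)
  rec(1L, n)
}

# --- quadratic interval-overlap oracle -----------------------------------

oracle_overlap <- function(a, b, max_gap = 0L) {
  hits <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      if (a$start[i] < b$end[j] + max_gap && b$start[j] < a$end[i] + max_gap) {
        hits[i] <- TRUE
        break
      }
    }
  }
  hits
}

# --- brute-force venn membership oracle ----------------------------------

oracle_venn <- function(reference, sets) {
  vapply(reference, function(g) {
    members <- names(sets)[vapply(sets, function(s) g %in% s, logical(1))]
    if (!length(members)) "none" else paste(members, collapse = "&")
  }, character(1))
}

# --- Kruskal-Wallis statistic recomputed from the rank formula -----------

oracle_kw <- function(x, g) {
  g <- factor(g)
  n <- length(x)
  r <- rank(x)
  ss <- tapply(r, g, function(v) sum(v)^2 / length(v))
  h <- 12 / (n * (n + 1)) * sum(ss) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}
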