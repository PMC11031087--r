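#' @importFrom stats rnorm rbinom rnbinom rbeta runif median p.adjust pt
#'   pchisq pnorm qnorm kruskal.test t.test wilcox.test lm coef ecdf sd var
#'   setNames ave na.omit
#' @importFrom utils read.table write.table combn
NULL

RNA_BASES <- c("A", "C", "G", "U")

# Watson-Crick complement in RNA space
WC_COMP <- c(A = "U", C = "G", G = "C", U = "A")
# wobble partner on the opposite strand: G pairs U, U pairs G
WOBBLE_PARTNER <- c(A = NA, C = NA, G = "U", U = "G")

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U. Ambiguity codes are left in place; they
#' never participate in seed matching.
#'
#' @param x character vector of sequences.
#' @return character vector in RNA alphabet.
#' @export
normalize_rna <- function(x) {
  chartr("tT", "uU", toupper(chartr("acgu", "ACGU", x)))
}

#' Reverse complement in RNA space
#'
#' @param x character vector of RNA sequences (A/C/G/U).
#' @return reverse complements, 5'->3'.
#' @export
revcomp_rna <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Derive a reproducible sub-stream seed for a pipeline stage
#'
#' One master seed per run; each stage draws from a sub-stream whose seed is
#' a deterministic function of the master seed and the stage name, so adding
#' a stage never perturbs the draws of earlier stages.
#'
#' @param master_seed integer master seed.
#' @param stage stage name (character scalar).
#' @return integer seed below 2^31.
#' @export
stage_seed <- function(master_seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 2147480009
  as.integer((as.numeric(master_seed) %% 2147480009 + h) %% 2147480009) + 1L
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

random_rna <- function(n, len, base_comp = c(A = .25, C = .25, G = .25, U = .25)) {
  vapply(seq_len(n), function(i) {
    paste(sample(names(base_comp), len[min(i, length(len))],
                 replace = TRUE, prob = base_comp), collapse = "")
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
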