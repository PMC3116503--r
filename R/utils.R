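#' Reverse complement of nucleotide strings
#'
#' Vectorised reverse complement over `{A,C,G,T,N}` strings.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random nucleotide sequence
#'
#' Draws bases i.i.d. uniform over `{A,C,G,T}`. Uses the current RNG state;
#' wrap in [withr::with_seed()] for reproducibility.
#'
#' @param n Length in bases.
#' @return A single character string.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Normalise a sequence to {A,C,G,T,N}; anything else (IUPAC ambiguity codes
# etc.) becomes N, with a warning count. With preserve_case, lower-case
# (soft-masked) bases are kept for mask-aware consumers.
normalize_bases <- function(x, what = "sequence", preserve_case = FALSE) {
  if (!preserve_case) x <- toupper(x)
  pat <- if (preserve_case) "[^ACGTNacgtn]" else "[^ACGTN]"
  bad <- vapply(gregexpr(pat, x), function(m) sum(m > 0L), integer(1))
  n_bad <- sum(bad)
  if (n_bad > 0) {
    x <- gsub(pat, "N", x)
    warn(sprintf("%d non-ACGTN character(s) in %s mapped to N", n_bad, what))
  }
  x
}

# Split equal-length strings into a raw byte matrix (nchar x n). Fast path for
# per-base operations on fixed-length read pools.
str_to_raw_matrix <- function(x, width) {
  if (length(x) == 0) return(matrix(raw(0), nrow = width, ncol = 0))
  matrix(charToRaw(paste(x, collapse = "")), nrow = width)
}

raw_matrix_to_str <- function(m) {
  if (ncol(m) == 0) return(character(0))
  all <- rawToChar(as.raw(m))
  width <- nrow(m)
  substring(all, seq(1, nchar(all), by = width), seq(width, nchar(all), by = width))
}

# Smallest rotation of a repeat motif (class bookkeeping for SSRs).
canonical_rotation <- function(motif) {
  vapply(motif, function(m) {
    n <- nchar(m)
    rots <- vapply(seq_len(n), function(i) {
      paste0(substr(m, i, n), substr(m, 1, i - 1))
    }, character(1))
    min(rots)
  }, character(1), USE.NAMES = FALSE)
}

# TRUE if the motif is not a whole-number repetition of a shorter unit.
is_primitive_motif <- function(motif) {
  vapply(motif, function(m) {
    n <- nchar(m)
    for (d in seq_len(n - 1)) {
      if (n %% d == 0) {
        unit <- substr(m, 1, d)
        if (paste(rep(unit, n / d), collapse = "") == m) return(FALSE)
      }
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

# Validate a read/sequence tibble (id, seq, optional qual list column).
check_seq_tbl <- function(x, need_qual = FALSE, arg = "reads") {
  if (!is.data.frame(x) || !all(c("id", "seq") %in% names(x))) {
    abort(sprintf("`%s` must be a data frame with columns `id` and `seq`", arg))
  }
  if (need_qual && (!("qual" %in% names(x)) || all(vapply(x$qual, is.null, logical(1))))) {
    abort(sprintf("`%s` must carry per-base qualities in a `qual` list column for this step", arg))
  }
  invisible(x)
}
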