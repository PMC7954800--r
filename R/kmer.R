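# Canonical k-mer machinery.  k-mers are encoded as base-4 digits packed into
# doubles (exact up to 2^53, i.e. k <= 26), which keeps canonicalization and
# Hamming-1 masking locale-independent and fast without compiled code.

# byte -> base-4 digit lookup (A=0, C=1, G=2, T=3); other symbols -> NA
.BASE_LUT <- local({
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("C")] <- 1L
  lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("T")] <- 3L
  lut
})

# N x k integer matrix of base-4 digits; NA for non-ACGT
.kmer_digits <- function(kmers, k) {
  if (length(kmers) == 0) return(matrix(integer(0), ncol = k))
  x <- utf8ToInt(paste(kmers, collapse = ""))
  matrix(.BASE_LUT[x], ncol = k, byrow = TRUE)
}

.digits_code <- function(D, k) {
  pw <- 4^((k - 1L):0L)
  as.numeric(D %*% pw)
}

# all length-k windows of one sequence
.kmer_windows <- function(sequence, k) {
  n <- nchar(sequence)
  if (n < k) return(character(0))
  substring(sequence, seq_len(n - k + 1L), k:n)
}

# canonical form (lexicographic min of k-mer and reverse complement, decided
# on the numeric codes) for a vector of k-mers; non-ACGT k-mers -> NA
.canonicalize <- function(kmers, k) {
  if (length(kmers) == 0) {
    return(list(canonical = character(0), code = numeric(0)))
  }
  D <- matrix(.kmer_digits(kmers, k), ncol = k)
  bad <- rowSums(is.na(D)) > 0L
  cf <- .digits_code(D, k)
  # reverse-complement code without a second digit matrix:
  # rc digits are 3 - digits reversed, so rc code = (4^k - 1) - D %*% rev(pw)
  cr <- (4^k - 1) - .digits_code(D[, k:1, drop = FALSE], k)
  use_rc <- !bad & cr < cf
  canonical <- kmers
  if (any(use_rc)) canonical[use_rc] <- revcomp(kmers[use_rc])
  canonical[bad] <- NA_character_
  list(canonical = canonical, code = pmin(cf, cr))
}

# canonical codes of all valid windows of one sequence, skipping windows
# with non-ACGT symbols; digitizes the sequence once and indexes windows
.canonical_codes <- function(sequence, k) {
  d <- .BASE_LUT[utf8ToInt(toupper(sequence))]
  L <- length(d)
  if (L < k) return(numeric(0))
  n <- L - k + 1L
  idx <- rep(seq_len(n), k) + rep(0L:(k - 1L), each = n)
  D <- matrix(d[idx], nrow = n)
  cf <- .digits_code(D, k)
  cr <- (4^k - 1) - .digits_code(D[, k:1, drop = FALSE], k)
  code <- pmin(cf, cr)
  code[!is.na(code)]
}

# decode canonical numeric codes back to k-mer strings
.decode_codes <- function(codes, k) {
  if (length(codes) == 0) return(character(0))
  cols <- vector("list", k)
  rem <- codes
  for (i in k:1) {
    digit <- rem %% 4
    cols[[i]] <- DNA_BASES[digit + 1]
    rem <- (rem - digit) / 4
  }
  do.call(paste0, cols)
}

# counts of a sorted-able numeric vector via one radix sort + run lengths;
# returns list(code, n)
.code_counts <- function(codes) {
  if (length(codes) == 0) return(list(code = numeric(0), n = integer(0)))
  s <- sort(codes, method = "radix")
  new_run <- c(TRUE, s[-1L] != s[-length(s)])
  list(code = s[new_run], n = diff(c(which(new_run), length(s) + 1L)))
}

new_kmer_count_table <- function(k, counts, ci = 1L, cs = 10000L) {
  keep <- counts >= ci & counts <= cs
  structure(list(k = as.integer(k), counts = counts[keep],
                 ci = as.integer(ci), cs = as.integer(cs)),
            class = "kmer_count_table")
}

#' Count canonical k-mers in sequences
#'
#' Every length-k window free of non-ACGT symbols contributes one count to
#' its canonical form (the lexicographic minimum of the k-mer and its reverse
#' complement).  Counts outside `[ci, cs]` are then discarded, mirroring the
#' retention bounds of k-mer counters such as KMC.
#'
#' @param sequences character vector of sequences (case-insensitive).
#' @param k odd k-mer length between 11 and 31 (default 21).  Odd k rules out
#'   self-reverse-complement palindromes.
#' @param ci,cs minimum / maximum retained count (defaults 1 and 10000).
#' @return object of class `kmer_count_table`: list with `k`, `counts`
#'   (named integer vector, names are canonical k-mers), `ci`, `cs`.
#' @examples
#' count_canonical_kmers("AAAAA", k = 11)  # too short: empty table
#' @export
count_canonical_kmers <- function(sequences, k = 21L, ci = 1L, cs = 10000L) {
  k <- as.integer(k)
  if (k %% 2L == 0L) {
    stop_input("k must be odd (even k admits self-reverse-complement ",
               "palindromes)")
  }
  if (k < 3L || k > 31L) stop_input("k must be in 3..31")
  if (k > 26L) stop_input("k must be <= 26 for exact numeric encoding")
  codes <- unlist(lapply(sequences, .canonical_codes, k = k))
  cc <- .code_counts(codes)
  new_kmer_count_table(k, stats::setNames(as.integer(cc$n),
                                          .decode_codes(cc$code, k)),
                       ci, cs)
}

#' @export
print.kmer_count_table <- function(x, ...) {
  cat("canonical k-mer count table: k =", x$k, ",", length(x$counts),
      "k-mers, counts in [", x$ci, ",", x$cs, "]\n")
  invisible(x)
}

#' Read / write a two-column k-mer count TSV
#'
#' The plain-text interchange format is `kmer<TAB>count` with no header.
#'
#' @param path file path.
#' @param k k-mer length (checked against the file).
#' @param ci,cs retention bounds, as in [count_canonical_kmers()].
#' @return a `kmer_count_table`.
#' @export
read_kmer_table <- function(path, k = 21L, ci = 1L, cs = 10000L) {
  df <- read.delim(path, header = FALSE, col.names = c("kmer", "count"),
                   colClasses = c("character", "integer"))
  if (nrow(df) && any(nchar(df$kmer) != k)) {
    stop_input("k-mer length in ", path, " does not match k = ", k)
  }
  canon <- .canonicalize(df$kmer, as.integer(k))$canonical
  if (anyNA(canon)) stop_input("non-ACGT k-mer in ", path)
  new_kmer_count_table(k, stats::setNames(df$count, canon), ci, cs)
}

#' @rdname read_kmer_table
#' @param table a `kmer_count_table`.
#' @export
write_kmer_table <- function(table, path) {
  stopifnot(inherits(table, "kmer_count_table"))
  write.table(data.frame(kmer = names(table$counts),
                         count = unname(table$counts)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
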