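# Contig-bin decontamination rules and incremental read rescue for
# assemblies of non-axenic cultures.

#' Summarize the taxonomic composition of one contig bin
#'
#' @param contigs data.frame with at least columns `bin_id` and `taxon_label`
#'   (`"eukaryotic"`, `"prokaryotic"` or `"unclassified"`).  All rows must
#'   share one `bin_id`.
#' @return list with `bin_id`, `n_euk`, `n_prok`, `n_unclass`.
#' @export
summarize_bin <- function(contigs) {
  if (nrow(contigs) == 0) {
    return(list(bin_id = NA_character_, n_euk = 0L, n_prok = 0L,
                n_unclass = 0L))
  }
  bins <- unique(contigs$bin_id)
  if (length(bins) != 1L) {
    stop_input("summarize_bin expects a single bin, got: ",
               paste(bins, collapse = ", "))
  }
  tl <- contigs$taxon_label
  bad <- setdiff(unique(tl), c("eukaryotic", "prokaryotic", "unclassified"))
  if (length(bad)) stop_input("unknown taxon_label: ", paste(bad, collapse = ", "))
  list(bin_id = bins,
       n_euk = sum(tl == "eukaryotic"),
       n_prok = sum(tl == "prokaryotic"),
       n_unclass = sum(tl == "unclassified"))
}

#' Resolve the fate of a bin's unclassified contigs
#'
#' Two rules, evaluated on the bin's composition, both with inclusive
#' boundaries; if either fires, unclassified contigs are treated as
#' eukaryotic, otherwise as prokaryotic:
#'
#' 1. the number of eukaryotic contigs is at least half the number of
#'    prokaryotic contigs (`n_euk >= n_prok / 2`), or
#' 2. the number of unclassified contigs is at least twice the number of
#'    prokaryotic contigs (`n_unclass >= 2 * n_prok`).
#'
#' The rules are deliberately permissive towards eukaryotes because
#' reference databases contain far more bacteria than protists, biasing
#' taxonomic classifiers against the target organism.  With `n_prok = 0`
#' rule 1 fires trivially.
#'
#' @param summary list from [summarize_bin()], or the three counts.
#' @param n_prok,n_unclass counts when `summary` is given as `n_euk`.
#' @return `"eukaryotic"` or `"prokaryotic"`.
#' @examples
#' resolve_unclassified(10, 20, 3)  # rule 1 boundary -> eukaryotic
#' resolve_unclassified(0, 4, 8)    # rule 2 boundary -> eukaryotic
#' resolve_unclassified(1, 10, 5)   # neither rule    -> prokaryotic
#' @export
resolve_unclassified <- function(summary, n_prok = NULL, n_unclass = NULL) {
  if (is.list(summary)) {
    n_euk <- summary$n_euk; n_prok <- summary$n_prok
    n_unclass <- summary$n_unclass
  } else {
    n_euk <- summary
  }
  if (n_euk >= n_prok / 2 || n_unclass >= 2 * n_prok) {
    "eukaryotic"
  } else {
    "prokaryotic"
  }
}

#' Apply bin resolution across a classified assembly
#'
#' Relabels every unclassified contig by its bin's [resolve_unclassified()]
#' verdict, per bin.
#'
#' @param contigs data.frame with columns `bin_id`, `taxon_label`.
#' @return the data.frame with `taxon_label` resolved (no `"unclassified"`
#'   left) and a new column `resolved` flagging relabelled contigs.
#' @export
apply_bin_resolution <- function(contigs) {
  contigs$resolved <- FALSE
  for (b in unique(contigs$bin_id)) {
    idx <- contigs$bin_id == b
    verdict <- resolve_unclassified(summarize_bin(contigs[idx, , drop = FALSE]))
    un <- idx & contigs$taxon_label == "unclassified"
    contigs$taxon_label[un] <- verdict
    contigs$resolved[un] <- TRUE
  }
  contigs
}

# exact-match 31-mer dictionary over a set of contigs (both strands)
.seed_index <- function(contig_seqs, seed_len) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (s in contig_seqs) {
    s <- toupper(s)
    for (x in c(s, revcomp(s))) {
      if (nchar(x) < seed_len) next
      for (w in .kmer_windows(x, seed_len)) assign(w, TRUE, envir = env)
    }
  }
  env
}

#' Exact-seed read-to-contig hit test
#'
#' A naive stand-in for a read aligner: a read hits the contig set when at
#' least `min_seeds` of its exact length-`seed_len` substrings (read or its
#' reverse complement) occur in any contig.
#'
#' @param read read sequence (single string).
#' @param contigs character vector of contig sequences, or a prebuilt index
#'   from the internal seed dictionary.
#' @param seed_len exact-match seed length (default 31).
#' @param min_seeds minimum number of matching seeds (default 1).
#' @return logical.
#' @export
naive_seed_hit <- function(read, contigs, seed_len = 31L, min_seeds = 1L) {
  if (nchar(read) < seed_len) stop_input("seed_len exceeds read length")
  idx <- if (is.environment(contigs)) contigs else .seed_index(contigs, seed_len)
  hits <- 0L
  for (w in .kmer_windows(toupper(read), seed_len)) {
    if (exists(w, envir = idx, inherits = FALSE)) {
      hits <- hits + 1L
      if (hits >= min_seeds) return(TRUE)
    }
  }
  FALSE
}

# vectorized aligner built on the seed dictionary; the default `aligner`
# contract for incremental_read_rescue: function(reads_df, contig_seqs) ->
# logical vector of hits
seed_aligner <- function(seed_len = 31L, min_seeds = 1L) {
  function(reads, contig_seqs) {
    if (length(contig_seqs) == 0) return(rep(FALSE, nrow(reads)))
    idx <- .seed_index(contig_seqs, seed_len)
    vapply(reads$sequence, function(r) {
      naive_seed_hit(r, idx, seed_len = seed_len, min_seeds = min_seeds)
    }, logical(1), USE.NAMES = FALSE)
  }
}

#' Incremental read rescue against prokaryotic and eukaryotic contigs
#'
#' Reads are first aligned against the prokaryotic contig set; of those hits,
#' reads that also align to the eukaryotic set are kept (they may derive from
#' shared or ambiguous sequence), while prokaryote-only hits are marked
#' bacterial and excluded.  Reads hitting neither set are retained for the
#' eukaryotic assembly.  Formally, with `S1` the prokaryote hits and `S1e`
#' its eukaryote-hitting subset: `excluded = S1 \ S1e`,
#' `retained = (reads \ S1) u S1e`.
#'
#' @param reads data.frame with columns `read_id`, `sequence`.
#' @param prok_contigs,euk_contigs character vectors of contig sequences
#'   (either may be empty).
#' @param aligner function `(reads_df, contig_seqs) -> logical`; defaults to
#'   the exact-seed aligner with `seed_len`.
#' @param seed_len seed length for the default aligner.
#' @return list of class `read_partition` with `retained` and `excluded`
#'   (read-id character vectors, disjoint, jointly covering the input) and
#'   `log` (data.frame `read_id`, `hit_prok`, `hit_euk`, `fate`).
#' @export
incremental_read_rescue <- function(reads, prok_contigs, euk_contigs,
                                    aligner = NULL, seed_len = 31L) {
  if (is.null(aligner)) aligner <- seed_aligner(seed_len = seed_len)
  hit_prok <- if (length(prok_contigs)) aligner(reads, prok_contigs) else
    rep(FALSE, nrow(reads))
  hit_euk <- rep(NA, nrow(reads))
  s1 <- which(hit_prok)
  if (length(s1) && length(euk_contigs)) {
    hit_euk[s1] <- aligner(reads[s1, , drop = FALSE], euk_contigs)
  } else if (length(s1)) {
    hit_euk[s1] <- FALSE
  }
  excluded <- hit_prok & !hit_euk
  excluded[is.na(excluded)] <- FALSE
  fate <- ifelse(excluded, "excluded", "retained")
  structure(list(
    retained = reads$read_id[!excluded],
    excluded = reads$read_id[excluded],
    log = data.frame(read_id = reads$read_id, hit_prok = hit_prok,
                     hit_euk = hit_euk, fate = fate,
                     stringsAsFactors = FALSE)
  ), class = "read_partition")
}

#' Drop contigs below a minimum length
#'
#' Contigs shorter than `min_len` are discarded; contigs of exactly
#' `min_len` bp are kept.  Order is preserved.
#'
#' @param contigs data.frame with a `length` column (or a numeric vector of
#'   lengths).
#' @param min_len minimum retained length in bp (default 500).
#' @return the surviving rows (or lengths).
#' @export
filter_short_contigs <- function(contigs, min_len = 500L) {
  if (is.data.frame(contigs)) {
    contigs[contigs$length >= min_len, , drop = FALSE]
  } else {
    contigs[contigs >= min_len]
  }
}

#' Naive composition-based contig classifier
#'
#' Labels each contig by its nearest labelled reference under a composition
#' distance (absolute GC difference plus Euclidean distance between 4-mer
#' frequency profiles).  A lightweight stand-in for a taxonomic classifier,
#' intended for end-to-end tests on synthetic data; any function
#' `contigs -> labels` can replace it.
#'
#' @param contigs data.frame with columns `id`, `sequence`.
#' @param references data.frame with columns `sequence`, `label`.
#' @return character vector of labels, one per contig.
#' @export
classify_contigs_naive <- function(contigs, references) {
  profile <- function(s) {
    tab <- count_canonical_kmers(s, k = 5L)  # odd k keeps canonical simple
    p <- tab$counts / max(1L, sum(tab$counts))
    list(gc = gc_fraction(s), p = p)
  }
  refp <- lapply(references$sequence, profile)
  vapply(contigs$sequence, function(s) {
    q <- profile(s)
    d <- vapply(refp, function(r) {
      shared <- union(names(r$p), names(q$p))
      a <- stats::setNames(rep(0, length(shared)), shared)
      b <- a
      a[names(r$p)] <- r$p; b[names(q$p)] <- q$p
      gr <- if (is.na(r$gc)) 50 else r$gc
      gq <- if (is.na(q$gc)) 50 else q$gc
      abs(gr - gq) / 100 + sqrt(sum((a - b)^2))
    }, numeric(1))
    references$label[which.min(d)]
  }, character(1), USE.NAMES = FALSE)
}
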