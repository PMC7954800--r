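# Assembly and gene-model statistics: N50, partitioned GC, gene density.

#' N50 of a set of contig lengths
#'
#' The length at which the cumulative sum of lengths, sorted descending,
#' first reaches at least half the total.
#'
#' @param lengths positive contig lengths in bp.
#' @return N50 in bp.
#' @examples
#' compute_n50(c(60, 10, 10, 10, 10))  # 60
#' compute_n50(c(50, 50))              # 50
#' @export
compute_n50 <- function(lengths) {
  if (length(lengths) == 0) stop_input("compute_n50 needs at least one length")
  if (any(lengths <= 0)) stop_input("lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' GC content of a sequence, in percent
#'
#' `100 * (G + C) / (A + C + G + T)`; symbols outside ACGT (including N and
#' soft-masked lowercase is first uppercased, so masking does not change the
#' value) are excluded from both numerator and denominator.  A sequence with
#' no ACGT bases yields `NA` rather than zero.
#'
#' @param sequence character vector of sequences; GC is computed over the
#'   pool of all of them.
#' @return percentage in `[0, 100]`, or `NA_real_` if undefined.
#' @examples
#' gc_fraction("ATGC")    # 50
#' gc_fraction("ATGCNN")  # 50: N excluded
#' @export
gc_fraction <- function(sequence) {
  x <- Biostrings::BStringSet(toupper(sequence))
  f <- Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"))
  tot <- sum(f)
  if (tot == 0) return(NA_real_)
  100 * sum(f[, c("C", "G")]) / tot
}

# validate a gene-model list (shape produced by plant_genes / read_gff3)
.check_model <- function(m, contig_lengths) {
  len <- contig_lengths[[m$contig_id]]
  if (is.null(len)) stop_input("model ", m$gene_id, " references unknown contig ",
                               m$contig_id)
  iv <- rbind(m$exons[, c("start", "end")], m$cds[, c("start", "end")])
  if (any(iv$start < 1) || any(iv$end > len)) {
    stop_input("model ", m$gene_id, " extends outside contig ", m$contig_id)
  }
  if (any(iv$end < iv$start)) stop_input("model ", m$gene_id, " has an empty interval")
  invisible(TRUE)
}

#' Partition contigs into coding, intron and intergenic regions
#'
#' Coding is the union of CDS intervals; introns are the gaps between
#' consecutive exons of a transcript; intergenic is everything outside gene
#' spans.  Overlapping annotations are classified once with precedence
#' coding > intron > intergenic, so the three classes partition every contig
#' base exactly.
#'
#' @param gene_models list of gene models (see [read_gff3()]).
#' @param contig_lengths named numeric vector of contig lengths.
#' @return named list of data.frames (`coding`, `intron`, `intergenic`),
#'   each with columns `contig_id`, `start`, `end` (1-based inclusive).
#' @export
derive_regions <- function(gene_models, contig_lengths) {
  for (m in gene_models) .check_model(m, as.list(contig_lengths))
  out <- list(coding = NULL, intron = NULL, intergenic = NULL)
  res <- lapply(names(contig_lengths), function(ctg) {
    len <- contig_lengths[[ctg]]
    models <- Filter(function(m) m$contig_id == ctg, gene_models)
    whole <- IRanges::IRanges(1L, as.integer(len))
    to_ir <- function(df) IRanges::IRanges(df$start, df$end)
    coding <- IRanges::reduce(do.call(c, c(
      list(IRanges::IRanges()),
      lapply(models, function(m) to_ir(m$cds)))))
    introns <- IRanges::reduce(do.call(c, c(
      list(IRanges::IRanges()),
      lapply(models, function(m) {
        IRanges::setdiff(range(to_ir(m$exons)), to_ir(m$exons))
      }))))
    spans <- IRanges::reduce(do.call(c, c(
      list(IRanges::IRanges()),
      lapply(models, function(m) range(to_ir(m$exons))))))
    intron <- IRanges::setdiff(introns, coding)     # coding wins overlaps
    intergenic <- IRanges::setdiff(whole, spans)
    # bases inside spans but neither coding nor intron (e.g. exon bases
    # outside CDS) fall to intergenic-like non-coding; keep the partition
    # exact by assigning the remainder of spans to intergenic
    leftover <- IRanges::setdiff(IRanges::setdiff(spans, coding), intron)
    intergenic <- IRanges::reduce(c(intergenic, leftover))
    as_df <- function(ir) {
      if (length(ir) == 0) {
        return(data.frame(contig_id = character(0), start = integer(0),
                          end = integer(0)))
      }
      data.frame(contig_id = ctg, start = IRanges::start(ir),
                 end = IRanges::end(ir), stringsAsFactors = FALSE)
    }
    list(coding = as_df(coding), intron = as_df(intron),
         intergenic = as_df(intergenic))
  })
  for (cls in names(out)) {
    out[[cls]] <- do.call(rbind, lapply(res, `[[`, cls))
  }
  out
}

# pooled GC over a set of intervals
.region_gc <- function(intervals, sequences) {
  if (nrow(intervals) == 0) return(NA_real_)
  segs <- vapply(seq_len(nrow(intervals)), function(i) {
    substring(sequences[[intervals$contig_id[i]]], intervals$start[i],
              intervals$end[i])
  }, character(1))
  gc_fraction(segs)
}

#' GC content at third codon positions (GC3)
#'
#' Per transcript, CDS segments are concatenated in transcript order
#' (reverse-complemented for minus-strand genes), leading bases are dropped
#' according to the first segment's phase, any incomplete trailing codon is
#' dropped, and every third base is taken.  The GC percentage of the pool
#' over all transcripts is returned.  Transcripts shorter than one codon
#' after trimming are skipped with a warning.
#'
#' @param gene_models list of gene models (see [read_gff3()]).
#' @param sequences named character vector of contig sequences.
#' @return GC3 percentage.
#' @export
gc3 <- function(gene_models, sequences) {
  thirds <- character(0)
  for (m in gene_models) {
    seq <- sequences[[m$contig_id]]
    if (is.null(seq)) stop_input("model ", m$gene_id, " references unknown contig")
    cds <- m$cds[order(m$cds$start), , drop = FALSE]
    segs <- substring(seq, cds$start, cds$end)
    if (m$strand == "-") {
      segs <- rev(vapply(segs, function(s) revcomp(s), character(1),
                         USE.NAMES = FALSE))
      phase1 <- cds$phase[nrow(cds)]
    } else {
      phase1 <- cds$phase[1]
    }
    tx <- toupper(paste(segs, collapse = ""))
    if (phase1 > 0) tx <- substring(tx, phase1 + 1L)
    n <- nchar(tx) - nchar(tx) %% 3L
    if (n < 3L) {
      warning("CDS of ", m$gene_id, " shorter than one codon after trimming; skipped")
      next
    }
    tx <- substring(tx, 1L, n)
    idx <- seq(3L, n, by = 3L)
    thirds <- c(thirds, vapply(idx, function(i) substr(tx, i, i), character(1)))
  }
  if (!length(thirds)) return(NA_real_)
  100 * mean(thirds %in% c("G", "C"))
}

#' Gene density in genes per megabase
#'
#' `d = n / sum(lengths of contigs >= min_len) * 1e6`: the denominator is the
#' assembly span over contigs passing the short-contig filter, so a 400 bp
#' contig contributes nothing.
#'
#' @param n_genes number of genes.
#' @param contig_lengths contig lengths in bp.
#' @param min_len length filter matching [filter_short_contigs()]
#'   (default 500; the boundary contig of exactly `min_len` bp is included).
#' @return genes per Mb.
#' @examples
#' gene_density(1000, c(600000, 400000))  # 1000
#' gene_density(100, c(100000, 400))      # 1000: short contig excluded
#' @export
gene_density <- function(n_genes, contig_lengths, min_len = 500L) {
  kept <- contig_lengths[contig_lengths >= min_len]
  denom <- sum(kept)
  if (denom == 0) stop_input("no contig passes the ", min_len, " bp filter")
  n_genes / denom * 1e6
}

#' Full per-assembly statistics record
#'
#' Combines the assembly statistics (contig count, filtered span, N50),
#' the GC partition (total, coding, GC3, intron, intergenic) and gene count
#' and density into one record.
#'
#' @param sequences named character vector of contig sequences.
#' @param gene_models list of gene models (may be empty).
#' @param min_len contig length filter in bp (default 500).
#' @return list of class `genome_stats` with fields `n_contigs`,
#'   `total_bp_ge_min`, `n50`, `gc_total`, `gc_coding`, `gc3`, `gc_intron`,
#'   `gc_intergenic`, `n_genes`, `gene_density`.
#' @export
genome_stats <- function(sequences, gene_models = list(), min_len = 500L) {
  lens <- nchar(sequences)
  kept <- lens >= min_len
  regions <- derive_regions(gene_models, lens)
  structure(list(
    n_contigs = length(sequences),
    total_bp_ge_min = sum(lens[kept]),
    n50 = compute_n50(lens),
    gc_total = gc_fraction(sequences),
    gc_coding = .region_gc(regions$coding, sequences),
    gc3 = if (length(gene_models)) gc3(gene_models, sequences) else NA_real_,
    gc_intron = .region_gc(regions$intron, sequences),
    gc_intergenic = .region_gc(regions$intergenic, sequences),
    n_genes = length(gene_models),
    gene_density = gene_density(length(gene_models), lens, min_len)
  ), class = "genome_stats")
}

#' @export
print.genome_stats <- function(x, ...) {
  cat(sprintf(
    paste0("assembly: %d contigs, %d bp (>= filter), N50 %d\n",
           "GC%%: total %.1f | coding %.1f | GC3 %.1f | intron %.1f | ",
           "intergenic %.1f\ngenes: %d (density %.0f per Mb)\n"),
    x$n_contigs, x$total_bp_ge_min, x$n50, x$gc_total, x$gc_coding, x$gc3,
    x$gc_intron, x$gc_intergenic, x$n_genes, x$gene_density))
  invisible(x)
}
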