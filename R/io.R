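# Readers and writers: FASTA (case-preserving, for soft-masked input), GFF3
# gene models, pipeline configuration and the JSON run report.

#' Read / write FASTA sequences
#'
#' Reading preserves case (soft-masked lowercase runs survive a round trip)
#' and rejects duplicate ids and empty records; writing wraps sequence lines
#' at 80 columns.
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop_input("duplicate FASTA id(s) in ", path, ": ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(Biostrings::width(x) == 0)) {
    stop_input("empty FASTA record(s) in ", path, ": ",
               paste(ids[Biostrings::width(x) == 0], collapse = ", "))
  }
  stats::setNames(as.character(x), ids)
}

#' @rdname read_fasta
#' @param sequences named character vector.
#' @param width line-wrap width (default 80).
#' @export
write_fasta <- function(sequences, path, width = 80L) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop_input("write_fasta needs named sequences")
  }
  x <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read / write gene models as GFF3
#'
#' Gene models use gene/mRNA/exon/CDS features with 1-based inclusive
#' coordinates and phase on CDS rows.  Reading goes through
#' `rtracklayer::import` and assembles one model per mRNA; unknown feature
#' types are ignored with a warning.  A gene model is a list with fields
#' `gene_id`, `contig_id`, `strand`, `exons` (data.frame `start`, `end`,
#' sorted by start) and `cds` (data.frame `start`, `end`, `phase`).
#'
#' @param path file path.
#' @return list of gene models.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  known <- c("gene", "mRNA", "exon", "CDS")
  if (length(setdiff(unique(type), known))) {
    warning("ignoring feature type(s): ",
            paste(setdiff(unique(type), known), collapse = ", "))
  }
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)), type = type,
    id = as.character(gr$ID %||% NA),
    parent = vapply(as.list(gr$Parent %||% rep(list(character(0)), length(gr))),
                    function(p) if (length(p)) p[[1]] else NA_character_,
                    character(1)),
    phase = as.integer(gr$phase %||% rep(NA_integer_, length(gr))),
    stringsAsFactors = FALSE)
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  lapply(seq_len(nrow(mrnas)), function(i) {
    m <- mrnas[i, ]
    ex <- df[df$type == "exon" & df$parent == m$id, , drop = FALSE]
    cds <- df[df$type == "CDS" & df$parent == m$id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    cds <- cds[order(cds$start), , drop = FALSE]
    if (nrow(cds)) {
      if (any(cds$start < m$start | cds$end > m$end)) {
        stop_input("CDS outside mRNA span for model ", m$id, " in ", path)
      }
      if (anyNA(cds$phase) || any(!cds$phase %in% 0:2)) {
        stop_input("missing or invalid CDS phase for model ", m$id, " in ",
                   path)
      }
    }
    list(gene_id = m$id, contig_id = m$contig, strand = m$strand,
         exons = data.frame(start = ex$start, end = ex$end),
         cds = data.frame(start = cds$start, end = cds$end,
                          phase = cds$phase))
  })
}

#' @rdname read_gff3
#' @param models list of gene models.
#' @param source source tag for column 2 (default `"chrysopan"`).
#' @export
write_gff3 <- function(models, path, source = "chrysopan") {
  lines <- "##gff-version 3"
  for (m in models) {
    span <- range(c(m$exons$start, m$exons$end))
    gid <- m$gene_id
    row <- function(type, start, end, phase, id = NULL, parent = NULL) {
      attrs <- c(if (!is.null(id)) paste0("ID=", id),
                 if (!is.null(parent)) paste0("Parent=", parent))
      paste(m$contig_id, source, type, start, end, ".", m$strand,
            if (is.null(phase)) "." else phase,
            paste(attrs, collapse = ";"), sep = "\t")
    }
    lines <- c(lines,
      row("gene", span[1], span[2], NULL, id = paste0(gid, ".g")),
      row("mRNA", span[1], span[2], NULL, id = gid,
          parent = paste0(gid, ".g")),
      unlist(lapply(seq_len(nrow(m$exons)), function(e) {
        row("exon", m$exons$start[e], m$exons$end[e], NULL,
            parent = gid)
      })),
      unlist(lapply(seq_len(nrow(m$cds)), function(e) {
        row("CDS", m$cds$start[e], m$cds$end[e], m$cds$phase[e],
            parent = gid)
      })))
  }
  writeLines(lines, path)
  invisible(path)
}

PIPELINE_DEFAULTS <- list(
  k = 21L, ci = 1L, cs = 10000L, min_pair_cov = 4L,
  min_contig_len = 500L, seed_len = 31L,
  q_max = 8L, ratio_tol = 0.03, cov_tol = 0.25,
  parsimony_margin = 0.05, ambiguity_margin = 0.05,
  seed = 1L
)

#' Pipeline configuration with validated defaults
#'
#' Defaults encode the pipeline's standing parameters: k-mer counting with
#' `k = 21`, count retention bounds `ci = 1`, `cs = 10000`, the 500 bp
#' contig filter, the 31 bp aligner seed, and the ploidy-caller margins.
#' Unknown keys are rejected.
#'
#' @param ... overrides of the default keys.
#' @return list of class `pipeline_config`.
#' @examples
#' pipeline_config(k = 17, min_pair_cov = 6)
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(PIPELINE_DEFAULTS))
  if (length(unknown)) {
    stop_input("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, over)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration file
#'
#' The on-disk format is `key = value` lines; `#` starts a comment.
#'
#' @param path file path.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop_input("malformed config line(s) in ", path, ": ",
                           paste(which(bad), collapse = ", "))
  vals <- lapply(kv, function(p) {
    v <- utils::type.convert(p[2], as.is = TRUE)
    if (is.numeric(v) && p[1] %in% c("k", "ci", "cs", "min_pair_cov",
                                     "min_contig_len", "seed_len", "q_max",
                                     "seed")) v <- as.integer(v)
    v
  })
  do.call(pipeline_config, stats::setNames(vals, vapply(kv, `[[`, "", 1)))
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  writeLines(paste(names(config), unlist(config), sep = " = "), path)
  invisible(path)
}

#' Assemble and serialize a run report
#'
#' Collects the results of a pipeline run into one JSON-serializable
#' structure with the configuration echoed alongside, so a report reproduces
#' its run.  The timestamp is isolated in a single field.
#'
#' @param config the `pipeline_config` used.
#' @param ... named result sections (e.g. `genome_stats`, `ploidy`,
#'   `binning_log`, `pan_core`, `statistics`).
#' @return list of class `run_report`.
#' @export
run_report <- function(config, ...) {
  structure(list(
    software = paste0("chrysopan ",
                      as.character(utils::packageVersion("chrysopan"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    results = list(...)
  ), class = "run_report")
}

#' @rdname run_report
#' @param report a `run_report`.
#' @param path output JSON path.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
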