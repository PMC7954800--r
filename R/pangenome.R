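# Orthogroup tables, majority-rule KO annotation, pan/core set algebra over
# trophic-mode groups, KEGG-category composition and pathway completeness.

#' Read / write an OrthoFinder-dialect orthogroup table
#'
#' The format is a TSV whose header row is `Orthogroup` followed by strain
#' names; each cell holds the comma+space-separated gene ids of that strain
#' in that orthogroup, with an empty cell meaning absence.  Reading and
#' writing round-trip byte-stably.
#'
#' @param path file path.
#' @return data.frame of class `orthogroup_table`: column `Orthogroup` plus
#'   one character column per strain.
#' @export
read_orthogroups <- function(path) {
  nf <- count.fields(path, sep = "\t", quote = "", blank.lines.skip = FALSE)
  header_n <- nf[1]
  # trailing empty cells are legal (absent in the last strains); ragged rows
  # wider than the header are not
  if (any(nf > header_n)) {
    stop_input("ragged orthogroup table ", path, ": line(s) ",
               paste(which(nf > header_n), collapse = ", "),
               " have more fields than the header")
  }
  tab <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, colClasses = "character",
                    blank.lines.skip = FALSE)
  if (names(tab)[1] != "Orthogroup") {
    stop_input("first header field of ", path, " must be 'Orthogroup'")
  }
  dup <- tab$Orthogroup[duplicated(tab$Orthogroup)]
  if (length(dup)) {
    stop_input("duplicate orthogroup id(s) in ", path, ": ",
               paste(unique(dup), collapse = ", "))
  }
  tab[is.na(tab)] <- ""
  class(tab) <- c("orthogroup_table", "data.frame")
  tab
}

#' @rdname read_orthogroups
#' @param table an `orthogroup_table`.
#' @export
write_orthogroups <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Presence/absence matrix of an orthogroup table
#'
#' @param table an `orthogroup_table` from [read_orthogroups()] or
#'   [make_og_table()].
#' @return logical matrix, orthogroups x strains; `TRUE` where the strain
#'   has at least one gene in the orthogroup.
#' @export
og_presence <- function(table) {
  strains <- setdiff(names(table), "Orthogroup")
  m <- vapply(strains, function(s) nzchar(table[[s]]), logical(nrow(table)))
  m <- matrix(m, nrow = nrow(table),
              dimnames = list(table$Orthogroup, strains))
  m
}

# split an orthogroup cell into gene ids
.cell_genes <- function(cell) {
  if (!nzchar(cell)) return(character(0))
  strsplit(cell, ",[ ]?")[[1]]
}

#' Majority-rule annotation of one orthogroup
#'
#' The orthogroup's annotation is the plurality KO among its annotated
#' member genes, pooled over all strains; genes without a KO do not vote.
#' Ties break to the lexicographically smallest KO id; an orthogroup with no
#' annotated gene is unannotated (`NA`).
#'
#' @param gene_ids character vector of the orthogroup's gene ids (all
#'   strains pooled).
#' @param gene_to_ko named character vector mapping gene id to KO id
#'   (partial).
#' @return single KO id, or `NA_character_`.
#' @examples
#' majority_annotate(c("g1", "g2", "g3"),
#'                   c(g1 = "K00001", g2 = "K00001", g3 = "K00002"))
#' @export
majority_annotate <- function(gene_ids, gene_to_ko) {
  kos <- gene_to_ko[gene_ids]
  kos <- kos[!is.na(kos)]
  if (!length(kos)) return(NA_character_)
  tab <- table(kos)
  winners <- names(tab)[tab == max(tab)]
  sort(winners)[1]
}

#' Annotate every orthogroup of a table by majority rule
#'
#' @param table an `orthogroup_table`.
#' @param gene_to_ko named character vector, gene id -> KO id.
#' @return named character vector, orthogroup id -> KO id (`NA` where
#'   unannotated).
#' @export
annotate_orthogroups <- function(table, gene_to_ko) {
  strains <- setdiff(names(table), "Orthogroup")
  out <- vapply(seq_len(nrow(table)), function(i) {
    genes <- unlist(lapply(strains, function(s) .cell_genes(table[[s]][i])))
    majority_annotate(genes, gene_to_ko)
  }, character(1))
  stats::setNames(out, table$Orthogroup)
}

#' Pan and core genome of a strain group
#'
#' The pan genome of a group is every orthogroup present in at least one
#' member strain; the core genome is every orthogroup present in all member
#' strains.
#'
#' @param table an `orthogroup_table`.
#' @param strains non-empty character vector of member strain names.
#' @return character vector of orthogroup ids.
#' @export
pan_genome <- function(table, strains) {
  m <- .group_presence(table, strains)
  rownames(m)[rowSums(m) >= 1L]
}

#' @rdname pan_genome
#' @export
core_genome <- function(table, strains) {
  m <- .group_presence(table, strains)
  rownames(m)[rowSums(m) == ncol(m)]
}

.group_presence <- function(table, strains) {
  if (length(strains) == 0) stop_input("strain group must be non-empty")
  m <- og_presence(table)
  unknown <- setdiff(strains, colnames(m))
  if (length(unknown)) {
    stop_input("unknown strain(s): ", paste(unknown, collapse = ", "))
  }
  m[, strains, drop = FALSE]
}

#' Pan/core summaries for every trophic-mode combination
#'
#' For each of the seven non-empty combinations of phototrophs (P),
#' mixotrophs (M) and heterotrophs (H) that the strain set realizes, computes
#' the pan- and core-genome sizes, the composition of the pan set by
#' top-level KEGG category under majority-rule annotation, and the annotated
#' percentage.
#'
#' @param table an `orthogroup_table`.
#' @param annotation list with `gene_to_ko` (named character vector) and
#'   `ko_hierarchy` (data.frame with columns `ko`, `category`; a
#'   `subcategory` column is carried along if present).
#' @param modes named character vector, strain -> trophic mode; every strain
#'   of the table must be assigned.
#' @return data.frame with one row per combination: `combo`, `members`,
#'   `n_strains`, `pan_size`, `core_size`, `annotated_pct`, plus a
#'   list-column `composition` (named OG counts per top-level category,
#'   including `"unannotated"`, summing to `pan_size`).
#' @export
group_summaries <- function(table, annotation, modes) {
  strains <- setdiff(names(table), "Orthogroup")
  missing <- setdiff(strains, names(modes))
  if (length(missing)) {
    stop_input("strain(s) without a trophic mode: ",
               paste(missing, collapse = ", "))
  }
  og_ko <- annotate_orthogroups(table, annotation$gene_to_ko)
  hier <- annotation$ko_hierarchy
  ko_cat <- stats::setNames(hier$category, hier$ko)
  rows <- lapply(names(MODE_COMBOS), function(cn) {
    members <- strains[modes[strains] %in% MODE_COMBOS[[cn]]]
    if (length(members) == 0) return(NULL)
    pan <- pan_genome(table, members)
    core <- core_genome(table, members)
    kos <- og_ko[pan]
    cat <- ifelse(is.na(kos), "unannotated",
                  ifelse(is.na(ko_cat[kos]), "unannotated", ko_cat[kos]))
    comp <- base::table(cat)
    data.frame(combo = cn, members = paste(members, collapse = ","),
               n_strains = length(members), pan_size = length(pan),
               core_size = length(core),
               annotated_pct = 100 * mean(!is.na(kos)),
               composition = I(list(stats::setNames(as.integer(comp),
                                                    names(comp)))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' Pathway-completeness matrix from genomic and transcriptomic evidence
#'
#' For each pathway KO and strain, records whether the KO was observed in
#' the strain's genome-derived KO set, its transcriptome-derived set, both,
#' or neither.  Completeness of a pathway in a strain is the fraction of its
#' KOs with any evidence.
#'
#' @param genome_kos named list, strain -> character vector of KO ids with
#'   genomic evidence.
#' @param transcriptome_kos named list, strain -> KO ids with transcriptomic
#'   evidence (may be empty or omit strains).
#' @param pathway_definitions named list, pathway -> character vector of the
#'   KO ids composing it.
#' @return list with `cells` (data.frame `pathway`, `ko`, `strain`,
#'   `evidence` in `{"genome", "transcriptome", "both", "absent"}`) and
#'   `completeness` (data.frame `pathway`, `strain`, `completeness` in
#'   `[0, 1]`).
#' @export
pathway_completeness <- function(genome_kos, transcriptome_kos = list(),
                                 pathway_definitions = list()) {
  strains <- union(names(genome_kos), names(transcriptome_kos))
  cells <- do.call(rbind, lapply(names(pathway_definitions), function(pw) {
    kos <- pathway_definitions[[pw]]
    do.call(rbind, lapply(strains, function(s) {
      in_g <- kos %in% (genome_kos[[s]] %||% character(0))
      in_t <- kos %in% (transcriptome_kos[[s]] %||% character(0))
      ev <- ifelse(in_g & in_t, "both",
                   ifelse(in_g, "genome",
                          ifelse(in_t, "transcriptome", "absent")))
      data.frame(pathway = pw, ko = kos, strain = s, evidence = ev,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(cells)) {
    cells <- data.frame(pathway = character(0), ko = character(0),
                        strain = character(0), evidence = character(0))
  }
  comp <- if (nrow(cells)) {
    agg <- stats::aggregate(evidence ~ pathway + strain, data = cells,
                            FUN = function(e) mean(e != "absent"))
    names(agg)[names(agg) == "evidence"] <- "completeness"
    agg
  } else {
    data.frame(pathway = character(0), strain = character(0),
               completeness = numeric(0))
  }
  list(cells = cells, completeness = comp)
}

#' Write a pathway-completeness matrix as TSV
#'
#' Rows are (pathway, KO); columns are strains; cells hold the evidence
#' class.
#'
#' @param pc result of [pathway_completeness()].
#' @param path file path.
#' @export
write_pathway_matrix <- function(pc, path) {
  cells <- pc$cells
  if (nrow(cells) == 0) {
    writeLines("pathway\tko", path)
    return(invisible(path))
  }
  wide <- stats::reshape(cells, idvar = c("pathway", "ko"),
                         timevar = "strain", direction = "wide")
  names(wide) <- sub("^evidence\\.", "", names(wide))
  write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
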