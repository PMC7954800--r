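# Synthetic polyploid genomes, gene models, contaminants, reads, k-mer
# coverage and orthogroup tables with exact ground truth.

#' Specify a synthetic polyploid genome
#'
#' A genome is `ploidy` homologous copies of one reference sequence carrying
#' planted heterozygous single-nucleotide sites.  Each site is assigned a
#' genotype pattern: a string of length `ploidy` over `{A, B}` where `A`
#' denotes the reference allele and `B` the alternative, so `"AAB"` is a
#' triploid site with the alternative allele on one of three copies and
#' `"AABB"` a tetraploid site with a balanced 2:2 allele split.  The mix of
#' patterns controls where heterozygous k-mer pairs fall in the smudge plane.
#'
#' @param length reference length in bp.
#' @param ploidy integer number of genome copies, 1-8.
#' @param het_rate expected heterozygous sites per bp.
#' @param genotype_mix named numeric vector of pattern proportions summing
#'   to 1; names are A/B patterns of length `ploidy`.  Defaults: `AB` for 2n,
#'   `AAB` for 3n, `AAAB`/`AABB` at 0.5/0.5 for 4n, and the single minimal
#'   pattern (one `B`) otherwise.
#' @param min_site_spacing minimum distance in bp between adjacent variant
#'   sites; defaults to 21 so that each site yields clean k-mer pairs at the
#'   default k.
#' @param base_gc GC fraction of the i.i.d. background sequence.
#' @param seed integer RNG seed.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(length, ploidy = 2L, het_rate = 0.01,
                        genotype_mix = NULL, min_site_spacing = 21L,
                        base_gc = 0.5, seed = 1L) {
  ploidy <- as.integer(ploidy)
  if (ploidy < 1L || ploidy > 8L) stop_input("ploidy must be in 1..8")
  if (length < 1) stop_input("length must be positive")
  if (het_rate < 0) stop_input("het_rate must be >= 0")
  if (base_gc < 0 || base_gc > 1) stop_input("base_gc must be in [0,1]")
  if (is.null(genotype_mix)) {
    genotype_mix <- switch(as.character(ploidy),
      "2" = c(AB = 1),
      "3" = c(AAB = 1),
      "4" = c(AAAB = 0.5, AABB = 0.5),
      structure(1, names = paste(c(rep("A", ploidy - 1L), "B"), collapse = ""))
    )
  }
  pats <- names(genotype_mix)
  if (is.null(pats) || any(nchar(pats) != ploidy)) {
    stop_input("every genotype pattern must have length equal to ploidy (",
               ploidy, ")")
  }
  if (any(!grepl("^[AB]+$", pats)) || any(!grepl("B", pats))) {
    stop_input("genotype patterns must be strings over {A,B} containing ",
               "at least one B")
  }
  if (abs(sum(genotype_mix) - 1) > 1e-8) {
    stop_input("genotype_mix proportions must sum to 1")
  }
  structure(list(length = as.integer(length), ploidy = ploidy,
                 het_rate = het_rate, genotype_mix = genotype_mix,
                 min_site_spacing = as.integer(min_site_spacing),
                 base_gc = base_gc, seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate polyploid haplotypes with a variant-site truth table
#'
#' Draws an i.i.d. reference sequence, plants `Poisson(length * het_rate)`
#' heterozygous single-nucleotide sites with pairwise spacing of at least
#' `min_site_spacing`, assigns each site a genotype pattern from the spec's
#' mix, and materializes the `ploidy` haplotype copies.  Copy `j` carries the
#' alternative allele at a site exactly when character `j` of the site's
#' pattern is `B`.
#'
#' @param spec a [genome_spec()].
#' @return list with elements `haplotypes` (character vector of length
#'   `ploidy`, named `hap1..hapP`) and `truth` (data.frame with columns
#'   `pos`, `ref`, `alt`, `pattern`).
#' @export
make_haplotypes <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    L <- spec$length
    s <- spec$min_site_spacing
    ref <- random_bases(L, spec$base_gc)
    n_sites <- if (spec$het_rate > 0) rpois(1, L * spec$het_rate) else 0L
    if (n_sites * s > L) {
      stop_input("cannot place ", n_sites, " variant sites with spacing >= ",
                 s, " in ", L, " bp: spacing infeasible")
    }
    if (n_sites > 0) {
      # n points with minimum gap s: draw in the shrunken interval, then
      # re-inflate by the cumulative spacing
      slack <- L - (n_sites - 1L) * s
      u <- sort(sample.int(slack, n_sites, replace = FALSE))
      pos <- u + (seq_len(n_sites) - 1L) * s
    } else {
      pos <- integer(0)
    }
    pat <- if (n_sites > 0) {
      sample(names(spec$genotype_mix), n_sites, replace = TRUE,
             prob = spec$genotype_mix)
    } else character(0)
    ref_allele <- ref[pos]
    alt_allele <- vapply(ref_allele, function(b) {
      sample(setdiff(DNA_BASES, b), 1L)
    }, character(1), USE.NAMES = FALSE)
    haps <- vector("list", spec$ploidy)
    for (j in seq_len(spec$ploidy)) {
      h <- ref
      carries <- substr(pat, j, j) == "B"
      h[pos[carries]] <- alt_allele[carries]
      haps[[j]] <- paste(h, collapse = "")
    }
    names(haps) <- paste0("hap", seq_len(spec$ploidy))
    list(
      haplotypes = unlist(haps),
      truth = data.frame(pos = pos, ref = ref_allele, alt = alt_allele,
                         pattern = pat, stringsAsFactors = FALSE)
    )
  })
}

#' Specify synthetic gene structures with region-specific GC
#'
#' @param n_genes number of genes to plant.
#' @param exons_per_gene,exon_len,intron_len,intergenic_len [dist_spec()]s for
#'   counts and lengths in bp.
#' @param gc_coding12 target GC fraction at codon positions 1-2.
#' @param gc3_target target GC fraction at codon position 3.
#' @param gc_intron,gc_intergenic target GC fractions of introns and
#'   intergenic sequence.
#' @param seed integer RNG seed.
#' @return an object of class `gene_structure_spec`.
#' @export
gene_structure_spec <- function(n_genes = 20L,
                                exons_per_gene = dist_spec("uniform", min = 1, max = 5),
                                exon_len = dist_spec("uniform", min = 90, max = 450),
                                intron_len = dist_spec("uniform", min = 60, max = 300),
                                intergenic_len = dist_spec("uniform", min = 200, max = 800),
                                gc_coding12 = 0.55, gc3_target = 0.53,
                                gc_intron = 0.41, gc_intergenic = 0.36,
                                seed = 1L) {
  fr <- c(gc_coding12, gc3_target, gc_intron, gc_intergenic)
  if (any(fr < 0 | fr > 1)) stop_input("GC fractions must be in [0,1]")
  if (n_genes < 0) stop_input("n_genes must be >= 0")
  structure(list(n_genes = as.integer(n_genes),
                 exons_per_gene = exons_per_gene, exon_len = exon_len,
                 intron_len = intron_len, intergenic_len = intergenic_len,
                 gc_coding12 = gc_coding12, gc3_target = gc3_target,
                 gc_intron = gc_intron, gc_intergenic = gc_intergenic,
                 seed = as.integer(seed)),
            class = "gene_structure_spec")
}

# draw one coding sequence of length n (multiple of 3) with codon-position
# specific GC, in transcript orientation
.coding_bases <- function(n, gc12, gc3) {
  if (n == 0L) return(character(0))
  cp <- ((seq_len(n) - 1L) %% 3L) + 1L
  gc <- ifelse(cp == 3L, gc3, gc12)
  is_gc <- runif(n) < gc
  strong <- sample(c("G", "C"), n, replace = TRUE)
  weak <- sample(c("A", "T"), n, replace = TRUE)
  ifelse(is_gc, strong, weak)
}

#' Plant gene models on a synthetic contig
#'
#' Lays out `n_genes` genes left to right, each preceded by an intergenic
#' spacer and built from exons separated by introns; exons are fully coding
#' (exon == CDS) and the total coding length of each gene is forced to a
#' multiple of 3.  Strands alternate.  Coding bases are drawn with separate
#' GC targets for codon positions 1-2 and position 3 (in transcript
#' orientation; minus-strand genes are reverse-complemented into the contig),
#' introns and intergenic bases with their own targets.  The realized GC of
#' every region class is recorded exactly.
#'
#' @param sequence_length contig length in bp.
#' @param spec a [gene_structure_spec()].
#' @return list with `sequence` (the contig), `models` (list of gene models,
#'   see [read_gff3()] for the shape), `regions` (data.frame `start`, `end`,
#'   `class` covering the contig) and `truth` (realized GC percentages:
#'   `gc_coding`, `gc3`, `gc_intron`, `gc_intergenic`, plus `gc_total`).
#' @export
plant_genes <- function(sequence_length, spec) {
  stopifnot(inherits(spec, "gene_structure_spec"))
  with_seed(spec$seed, {
    L <- as.integer(sequence_length)
    parts <- character(0)       # sequence chunks in contig order
    regions <- list()
    models <- list()
    third_pos_bases <- character(0)  # codon position 3, transcript orientation
    cursor <- 1L                # next free contig position
    add_region <- function(start, end, class) {
      regions[[length(regions) + 1L]] <<- data.frame(
        start = start, end = end, class = class, stringsAsFactors = FALSE)
    }
    for (g in seq_len(spec$n_genes)) {
      gap <- as.integer(draw_dist(spec$intergenic_len, 1))
      n_ex <- as.integer(draw_dist(spec$exons_per_gene, 1))
      ex_len <- as.integer(draw_dist(spec$exon_len, n_ex))
      tot <- sum(ex_len)
      ex_len[n_ex] <- ex_len[n_ex] + (3L - tot %% 3L) %% 3L  # CDS multiple of 3
      in_len <- if (n_ex > 1) as.integer(draw_dist(spec$intron_len, n_ex - 1L)) else integer(0)
      gene_len <- sum(ex_len) + sum(in_len)
      if (cursor + gap + gene_len - 1L > L) {
        stop_input("gene ", g, " does not fit: need ", cursor + gap + gene_len - 1L,
                   " bp but contig is ", L, " bp")
      }
      if (gap > 0) {
        parts <- c(parts, random_dna(gap, spec$gc_intergenic))
        add_region(cursor, cursor + gap - 1L, "intergenic")
      }
      gstart <- cursor + gap
      strand <- if (g %% 2L == 1L) "+" else "-"
      cds_tx <- .coding_bases(sum(ex_len), spec$gc_coding12, spec$gc3_target)
      third_pos_bases <- c(third_pos_bases, cds_tx[seq_along(cds_tx) %% 3L == 0L])
      # split transcript CDS into per-exon chunks (transcript order)
      chunk_id <- rep(seq_len(n_ex), ex_len)
      chunks <- split(cds_tx, chunk_id)
      # genomic order of exons: for '-', transcript order is reversed
      genomic_chunks <- if (strand == "+") chunks else {
        lapply(rev(chunks), function(ch) {
          strsplit(revcomp(paste(ch, collapse = "")), "")[[1]]
        })
      }
      genomic_ex_len <- if (strand == "+") ex_len else rev(ex_len)
      # interleave exon/intron chunks along the contig
      pos <- gstart
      exon_iv <- matrix(0L, nrow = n_ex, ncol = 2)
      for (e in seq_len(n_ex)) {
        elen <- genomic_ex_len[e]
        parts <- c(parts, paste(genomic_chunks[[e]], collapse = ""))
        exon_iv[e, ] <- c(pos, pos + elen - 1L)
        add_region(pos, pos + elen - 1L, "coding")
        pos <- pos + elen
        if (e < n_ex) {
          ilen <- in_len[e]
          parts <- c(parts, random_dna(ilen, spec$gc_intron))
          add_region(pos, pos + ilen - 1L, "intron")
          pos <- pos + ilen
        }
      }
      # GFF3 phase: bases to skip to reach the next codon start, in
      # transcript order of the CDS segments
      tx_len <- ex_len
      phase_tx <- c(0L, cumsum(tx_len)[-n_ex]) %% 3L
      phase_tx <- (3L - phase_tx) %% 3L
      # map phases back onto genomic order
      phase_genomic <- if (strand == "+") phase_tx else rev(phase_tx)
      cds <- data.frame(start = exon_iv[, 1], end = exon_iv[, 2],
                        phase = phase_genomic)
      models[[g]] <- list(
        gene_id = sprintf("gene%04d", g), contig_id = "synth1",
        strand = strand,
        exons = data.frame(start = exon_iv[, 1], end = exon_iv[, 2]),
        cds = cds
      )
      cursor <- gstart + gene_len
    }
    if (cursor <= L) {
      parts <- c(parts, random_dna(L - cursor + 1L, spec$gc_intergenic))
      add_region(cursor, L, "intergenic")
    }
    sequence <- paste(parts, collapse = "")
    regions <- do.call(rbind, regions) %||%
      data.frame(start = integer(0), end = integer(0), class = character(0))
    gc_of <- function(class) {
      iv <- regions[regions$class == class, , drop = FALSE]
      if (nrow(iv) == 0) return(NA_real_)
      bases <- unlist(lapply(seq_len(nrow(iv)), function(i) {
        substring(sequence, iv$start[i], iv$end[i])
      }))
      gc_fraction(paste(bases, collapse = ""))
    }
    truth <- list(
      gc_coding = gc_of("coding"),
      gc3 = if (length(third_pos_bases)) {
        100 * mean(third_pos_bases %in% c("G", "C"))
      } else NA_real_,
      gc_intron = gc_of("intron"),
      gc_intergenic = gc_of("intergenic"),
      gc_total = gc_fraction(sequence)
    )
    list(sequence = sequence, models = models, regions = regions,
         truth = truth)
  })
}

#' Specify bacterial contamination of a synthetic assembly
#'
#' @param n_bact_contigs number of bacterial contaminant contigs.
#' @param bact_gc GC fraction of the contaminants.
#' @param bact_len [dist_spec()] for contaminant lengths (bp).
#' @param euk_fragmentation [dist_spec()] for eukaryotic fragment lengths.
#' @param seed integer RNG seed.
#' @return object of class `contamination_spec`.
#' @export
contamination_spec <- function(n_bact_contigs = 10L, bact_gc = 0.62,
                               bact_len = dist_spec("lognormal", meanlog = 8, sdlog = 0.5),
                               euk_fragmentation = dist_spec("lognormal", meanlog = 8.5, sdlog = 0.7),
                               seed = 1L) {
  if (n_bact_contigs < 0) stop_input("n_bact_contigs must be >= 0")
  if (bact_gc < 0 || bact_gc > 1) stop_input("bact_gc must be in [0,1]")
  structure(list(n_bact_contigs = as.integer(n_bact_contigs),
                 bact_gc = bact_gc, bact_len = bact_len,
                 euk_fragmentation = euk_fragmentation,
                 seed = as.integer(seed)),
            class = "contamination_spec")
}

#' Fragment a eukaryotic sequence and add bacterial contaminant contigs
#'
#' Emulates the assembly of a non-axenic culture: the eukaryotic genome is
#' cut into fragments and mixed with compositionally distinct bacterial
#' contigs.  Truth labels are retained per contig.
#'
#' @param sequence eukaryotic genome sequence (single string).
#' @param spec a [contamination_spec()].
#' @return data.frame with columns `id`, `sequence`, `length`, `truth_label`
#'   (`"eukaryotic"` or `"prokaryotic"`).
#' @export
make_contaminated_assembly <- function(sequence, spec) {
  stopifnot(inherits(spec, "contamination_spec"))
  with_seed(spec$seed, {
    L <- nchar(sequence)
    frags <- list()
    pos <- 1L
    while (pos <= L) {
      len <- as.integer(draw_dist(spec$euk_fragmentation, 1))
      frags[[length(frags) + 1L]] <- substring(sequence, pos,
                                               min(L, pos + len - 1L))
      pos <- pos + len
    }
    euk <- data.frame(
      id = sprintf("euk_ctg%04d", seq_along(frags)),
      sequence = unlist(frags), stringsAsFactors = FALSE)
    bact_lens <- as.integer(draw_dist(spec$bact_len, spec$n_bact_contigs))
    bact <- data.frame(
      id = sprintf("bact_ctg%04d", seq_len(spec$n_bact_contigs)),
      sequence = vapply(bact_lens, random_dna, character(1), gc = spec$bact_gc),
      stringsAsFactors = FALSE)
    out <- rbind(
      cbind(euk, truth_label = "eukaryotic", stringsAsFactors = FALSE),
      cbind(bact, truth_label = "prokaryotic", stringsAsFactors = FALSE))
    out$length <- nchar(out$sequence)
    out[, c("id", "sequence", "length", "truth_label")]
  })
}

#' Specify sequencing coverage for k-mer and read simulation
#'
#' @param haploid_coverage mean per-copy depth c.
#' @param k k-mer length (odd, >= 11).
#' @param noise `"poisson"` or `"negative_binomial"`.
#' @param dispersion size parameter for the negative binomial (ignored for
#'   Poisson).
#' @param read_len read length in bp.
#' @param error_rate per-base substitution rate in `[0, 0.1]`.
#' @param seed integer RNG seed.
#' @return object of class `coverage_spec`.
#' @export
coverage_spec <- function(haploid_coverage = 25, k = 21L,
                          noise = c("poisson", "negative_binomial"),
                          dispersion = 10, read_len = 150L,
                          error_rate = 0, seed = 1L) {
  noise <- match.arg(noise)
  if (haploid_coverage <= 0) stop_input("haploid_coverage must be > 0")
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 11L) stop_input("k must be odd and >= 11")
  if (error_rate < 0 || error_rate > 0.1) {
    stop_input("error_rate must be in [0, 0.1]")
  }
  structure(list(haploid_coverage = haploid_coverage, k = k, noise = noise,
                 dispersion = dispersion, read_len = as.integer(read_len),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "coverage_spec")
}

#' Simulate a k-mer count table from haplotypes
#'
#' Every distinct canonical k-mer present in the haplotypes receives a count
#' drawn from the noise model with mean `c * m`, where `m` is the number of
#' haplotype copies containing it.  This substitutes for sequencing followed
#' by k-mer counting, without read-level error k-mers.
#'
#' @param haplotypes character vector of haplotype sequences.
#' @param cov a [coverage_spec()].
#' @return a `kmer_count_table` (see [count_canonical_kmers()]).
#' @export
simulate_kmer_coverage <- function(haplotypes, cov) {
  stopifnot(inherits(cov, "coverage_spec"))
  if (length(haplotypes) == 0) stop_input("haplotypes must be non-empty")
  with_seed(cov$seed, {
    per_copy <- lapply(haplotypes, function(h) {
      unique(.canonical_codes(h, cov$k))
    })
    cc <- .code_counts(unlist(per_copy, use.names = FALSE))
    mu <- cov$haploid_coverage * cc$n     # copies containing the k-mer
    counts <- switch(cov$noise,
      poisson = rpois(length(mu), mu),
      negative_binomial = rnbinom(length(mu), size = cov$dispersion, mu = mu))
    keep <- counts >= 1L
    new_kmer_count_table(k = cov$k,
                         counts = stats::setNames(as.integer(counts[keep]),
                                                  .decode_codes(cc$code[keep],
                                                                cov$k)),
                         ci = 1L, cs = 10000L)
  })
}

#' Simulate error-bearing short reads with truth labels
#'
#' Reads start uniformly along each source sequence; the per-copy read count
#' is `round(c * L / read_len)`.  Substitution errors are applied per base at
#' `error_rate`; the truth label is the source sequence name.
#'
#' @param sources named character vector of source sequences (haplotypes
#'   and/or contaminant contigs).
#' @param cov a [coverage_spec()].
#' @return data.frame with columns `read_id`, `sequence`, `source`.
#' @export
simulate_reads <- function(sources, cov) {
  stopifnot(inherits(cov, "coverage_spec"))
  if (is.null(names(sources)) || any(!nzchar(names(sources)))) {
    stop_input("sources must be a named character vector")
  }
  with_seed(cov$seed, {
    out <- lapply(names(sources), function(nm) {
      s <- sources[[nm]]
      L <- nchar(s)
      if (cov$read_len > L) stop_input("read_len exceeds length of ", nm)
      n <- round(cov$haploid_coverage * L / cov$read_len)
      if (n == 0) return(NULL)
      starts <- sample.int(L - cov$read_len + 1L, n, replace = TRUE)
      reads <- substring(s, starts, starts + cov$read_len - 1L)
      if (cov$error_rate > 0) {
        reads <- vapply(reads, function(r) {
          b <- strsplit(r, "")[[1]]
          hit <- which(runif(length(b)) < cov$error_rate)
          if (length(hit)) {
            b[hit] <- vapply(b[hit], function(x) sample(setdiff(DNA_BASES, x), 1L),
                             character(1))
          }
          paste(b, collapse = "")
        }, character(1), USE.NAMES = FALSE)
      }
      data.frame(sequence = reads, source = nm, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, Filter(Negate(is.null), out))
    out$read_id <- sprintf("read%06d", seq_len(nrow(out)))
    out[, c("read_id", "sequence", "source")]
  })
}

#' Specify a synthetic orthogroup table with known pan/core structure
#'
#' @param strains named character vector: names are strain ids, values their
#'   trophic mode (`"phototroph"`, `"mixotroph"`, `"heterotroph"`).
#' @param core_all number of orthogroups present in every strain.
#' @param per_mode_shared named numeric: mode -> number of orthogroups present
#'   in exactly the strains of that mode.
#' @param per_strain_private named numeric: strain -> number of orthogroups
#'   private to that strain.
#' @param annotated_fraction fraction of orthogroups that receive a KO id.
#' @param ko_universe data.frame with columns `ko`, `category`, `subcategory`
#'   (a miniature KEGG hierarchy); defaults to a small built-in universe.
#' @param seed integer RNG seed.
#' @return object of class `og_table_spec`.
#' @export
og_table_spec <- function(strains, core_all = 50L, per_mode_shared = NULL,
                          per_strain_private = NULL, annotated_fraction = 0.2,
                          ko_universe = NULL, seed = 1L) {
  modes <- c("phototroph", "mixotroph", "heterotroph")
  if (is.null(names(strains)) || !all(strains %in% modes)) {
    stop_input("strains must be a named vector with modes in {",
               paste(modes, collapse = ", "), "}")
  }
  if (annotated_fraction < 0 || annotated_fraction > 1) {
    stop_input("annotated_fraction must be in [0,1]")
  }
  per_mode_shared <- per_mode_shared %||% stats::setNames(numeric(0), character(0))
  per_strain_private <- per_strain_private %||% stats::setNames(numeric(0), character(0))
  if (any(!names(per_mode_shared) %in% modes)) {
    stop_input("per_mode_shared names must be trophic modes")
  }
  if (any(!names(per_strain_private) %in% names(strains))) {
    stop_input("per_strain_private names must be strain ids")
  }
  if (core_all < 0 || any(per_mode_shared < 0) || any(per_strain_private < 0)) {
    stop_input("orthogroup class counts must be >= 0")
  }
  if (is.null(ko_universe)) {
    ko_universe <- data.frame(
      ko = sprintf("K%05d", 1:40),
      category = rep(c("Metabolism", "Genetic Information Processing",
                       "Environmental Information Processing",
                       "Cellular Processes"), each = 10),
      subcategory = rep(c("Carbohydrate metabolism", "Translation",
                          "Membrane transport", "Transport and catabolism"),
                        each = 10),
      stringsAsFactors = FALSE)
  }
  structure(list(strains = strains, core_all = as.integer(core_all),
                 per_mode_shared = per_mode_shared,
                 per_strain_private = per_strain_private,
                 annotated_fraction = annotated_fraction,
                 ko_universe = ko_universe, seed = as.integer(seed)),
            class = "og_table_spec")
}

# the 7 non-empty combinations of the three trophic modes, in reporting order
MODE_COMBOS <- list(
  P = "phototroph", M = "mixotroph", H = "heterotroph",
  `P+M` = c("phototroph", "mixotroph"),
  `M+H` = c("mixotroph", "heterotroph"),
  `P+H` = c("phototroph", "heterotroph"),
  `P+M+H` = c("phototroph", "mixotroph", "heterotroph")
)

#' Build a synthetic orthogroup table with analytic pan/core truth
#'
#' Orthogroups come in three classes: core (present in all strains), mode
#' shared (present in exactly the strains of one trophic mode) and strain
#' private.  Pan and core sizes of every mode combination then follow
#' analytically: the pan genome of a combination counts the core class, the
#' shared classes of its member modes and the private classes of its member
#' strains; the core genome counts the core class, plus a mode's shared class
#' only when the combination is exactly that one mode, plus a private class
#' only when the combination reduces to a single strain.
#'
#' @param spec an [og_table_spec()].
#' @return list with `table` (OrthoFinder-dialect data.frame, see
#'   [read_orthogroups()]), `annotation` (list with `gene_to_ko`,
#'   `ko_hierarchy`), `modes` (named vector strain -> mode), and `truth`
#'   (data.frame `combo`, `pan`, `core`).
#' @export
make_og_table <- function(spec) {
  stopifnot(inherits(spec, "og_table_spec"))
  with_seed(spec$seed, {
    strains <- names(spec$strains)
    classes <- list()
    add_class <- function(n, members, tag) {
      if (n <= 0) return()
      classes[[length(classes) + 1L]] <<- list(n = n, members = members,
                                               tag = tag)
    }
    add_class(spec$core_all, strains, "core")
    for (m in names(spec$per_mode_shared)) {
      add_class(spec$per_mode_shared[[m]],
                strains[spec$strains == m], paste0("mode_", m))
    }
    for (s in names(spec$per_strain_private)) {
      add_class(spec$per_strain_private[[s]], s, paste0("priv_", s))
    }
    n_og <- sum(vapply(classes, `[[`, numeric(1), "n"))
    og_ids <- sprintf("OG%07d", seq_len(n_og))
    cells <- matrix("", nrow = n_og, ncol = length(strains),
                    dimnames = list(og_ids, strains))
    gene_counter <- stats::setNames(rep(0L, length(strains)), strains)
    gene_to_ko <- character(0)
    row <- 1L
    annotated <- runif(n_og) < spec$annotated_fraction
    ko_pick <- sample(spec$ko_universe$ko, n_og, replace = TRUE)
    for (cl in classes) {
      for (i in seq_len(cl$n)) {
        og <- og_ids[row]
        n_genes_per <- sample(1:3, length(cl$members), replace = TRUE)
        for (j in seq_along(cl$members)) {
          s <- cl$members[j]
          ids <- sprintf("%s_g%05d", s,
                         gene_counter[[s]] + seq_len(n_genes_per[j]))
          gene_counter[[s]] <- gene_counter[[s]] + n_genes_per[j]
          cells[og, s] <- paste(ids, collapse = ", ")
          if (annotated[row]) {
            gene_to_ko[ids] <- ko_pick[row]
          }
        }
        row <- row + 1L
      }
    }
    tab <- data.frame(Orthogroup = og_ids, cells, check.names = FALSE,
                      stringsAsFactors = FALSE, row.names = NULL)
    class(tab) <- c("orthogroup_table", "data.frame")
    present_modes <- unique(unname(spec$strains))
    truth <- do.call(rbind, lapply(names(MODE_COMBOS), function(cn) {
      combo <- MODE_COMBOS[[cn]]
      members <- strains[spec$strains %in% combo]
      if (length(members) == 0) return(NULL)
      pan <- spec$core_all +
        sum(spec$per_mode_shared[names(spec$per_mode_shared) %in% combo]) +
        sum(spec$per_strain_private[names(spec$per_strain_private) %in% members])
      core <- spec$core_all
      for (m in names(spec$per_mode_shared)) {
        if (identical(sort(members),
                      sort(strains[spec$strains == m]))) {
          core <- core + spec$per_mode_shared[[m]]
        }
      }
      for (s in names(spec$per_strain_private)) {
        if (identical(members, s)) core <- core + spec$per_strain_private[[s]]
      }
      data.frame(combo = cn, pan = as.integer(pan), core = as.integer(core),
                 stringsAsFactors = FALSE)
    }))
    hier <- spec$ko_universe
    list(table = tab,
         annotation = list(gene_to_ko = gene_to_ko, ko_hierarchy = hier),
         modes = spec$strains,
         truth = truth)
  })
}
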