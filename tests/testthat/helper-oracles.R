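# Independent oracles used by the unit and acceptance tests.  Each is a
# deliberately different algorithm from the implementation it checks.

# All-pairs Hamming-1 scan via digit-indicator matrix algebra: the pairwise
# mismatch-count matrix is k minus the sum over the four bases of the
# indicator cross-products, minimized over relative orientation.
oracle_het_pairs <- function(counts, k, min_pair_cov = 4L) {
  counts <- counts[counts >= min_pair_cov]
  kms <- names(counts)
  n <- length(kms)
  empty <- data.frame(kmer_a = character(0), kmer_b = character(0),
                      cov_major = integer(0), cov_minor = integer(0),
                      ratio = numeric(0), total = integer(0))
  if (n < 2L) return(empty)
  D <- matrix(match(unlist(strsplit(kms, "")), c("A", "C", "G", "T")) - 1L,
              nrow = n, byrow = TRUE)
  Dr <- 3L - D[, k:1, drop = FALSE]
  Mff <- matrix(k, n, n)
  Mfr <- matrix(k, n, n)
  for (v in 0:3) {
    Ff <- (D == v) * 1
    Fr <- (Dr == v) * 1
    Mff <- Mff - tcrossprod(Ff)
    Mfr <- Mfr - tcrossprod(Ff, Fr)
  }
  dist <- pmin(Mff, Mfr)   # Hamming preserved under joint revcomp => symmetric
  adj <- dist == 1L
  diag(adj) <- FALSE       # a k-mer adjacent to its own revcomp is not a pair
  deg <- rowSums(adj)
  hits <- which(adj & upper.tri(adj), arr.ind = TRUE)
  keep <- deg[hits[, 1]] == 1L & deg[hits[, 2]] == 1L
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  ca <- unname(counts[hits[, 1]])
  cb <- unname(counts[hits[, 2]])
  res <- data.frame(
    kmer_a = kms[hits[, 1]], kmer_b = kms[hits[, 2]],
    cov_major = pmax(ca, cb), cov_minor = pmin(ca, cb),
    ratio = pmin(ca, cb) / (ca + cb), total = ca + cb,
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res[order(res$kmer_a), , drop = FALSE]
}

# random k-mer count table with planted Hamming-1 neighbors and planted
# ambiguous (multi-partner) clusters
random_kmer_table <- function(n, k, seed, p_neighbor = 0.3, p_triple = 0.05) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  rand_kmer <- function() paste(sample(bases, k, replace = TRUE),
                                collapse = "")
  mutate1 <- function(km) {
    i <- sample.int(k, 1)
    b <- sample(setdiff(bases, substr(km, i, i)), 1)
    paste0(substr(km, 1, i - 1), b, substr(km, i + 1, k))
  }
  kms <- character(0)
  while (length(kms) < n) {
    base_km <- rand_kmer()
    kms <- c(kms, base_km)
    u <- runif(1)
    if (u < p_triple && length(kms) + 2 <= n) {
      kms <- c(kms, mutate1(base_km), mutate1(base_km))
    } else if (u < p_triple + p_neighbor && length(kms) + 1 <= n) {
      kms <- c(kms, mutate1(base_km))
    }
  }
  # canonicalize and deduplicate so the table is a valid count table
  canon <- vapply(kms, function(x) {
    rc <- chrysopan::revcomp(x)
    if (x <= rc) x else rc
  }, character(1), USE.NAMES = FALSE)
  canon <- unique(canon)
  counts <- sample(1:60, length(canon), replace = TRUE)
  structure(list(k = as.integer(k),
                 counts = stats::setNames(as.integer(counts), canon),
                 ci = 1L, cs = 10000L),
            class = "kmer_count_table")
}

# N50 straight from the definition, scanning with an explicit loop
oracle_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(s) / 2
  acc <- 0
  for (x in s) {
    acc <- acc + x
    if (acc >= half) return(x)
  }
}

# pan/core by explicit per-orthogroup membership scan on the raw cells
oracle_pan_core <- function(table, strains) {
  pan <- character(0)
  core <- character(0)
  for (i in seq_len(nrow(table))) {
    present <- vapply(strains, function(s) nzchar(table[[s]][i]), logical(1))
    if (any(present)) pan <- c(pan, table$Orthogroup[i])
    if (all(present)) core <- c(core, table$Orthogroup[i])
  }
  list(pan = pan, core = core)
}

# per-base region classification: coding > intron > intergenic
oracle_region_classes <- function(models, contig_len) {
  cls <- rep("intergenic", contig_len)
  in_span <- rep(FALSE, contig_len)
  is_coding <- rep(FALSE, contig_len)
  is_intron <- rep(FALSE, contig_len)
  for (m in models) {
    span <- range(c(m$exons$start, m$exons$end))
    in_span[span[1]:span[2]] <- TRUE
    for (r in seq_len(nrow(m$cds))) {
      is_coding[m$cds$start[r]:m$cds$end[r]] <- TRUE
    }
    ex <- m$exons[order(m$exons$start), ]
    if (nrow(ex) > 1) {
      for (r in seq_len(nrow(ex) - 1)) {
        if (ex$end[r] + 1 <= ex$start[r + 1] - 1) {
          is_intron[(ex$end[r] + 1):(ex$start[r + 1] - 1)] <- TRUE
        }
      }
    }
  }
  cls[is_intron] <- "intron"
  cls[is_coding] <- "coding"
  cls
}

# expand a derive_regions interval set for one contig to per-base labels
regions_to_classes <- function(regions, contig_id, contig_len) {
  cls <- rep(NA_character_, contig_len)
  for (class in names(regions)) {
    df <- regions[[class]]
    df <- df[df$contig_id == contig_id, , drop = FALSE]
    for (i in seq_len(nrow(df))) {
      stopifnot(all(is.na(cls[df$start[i]:df$end[i]])))  # no double cover
      cls[df$start[i]:df$end[i]] <- class
    }
  }
  cls
}

# tiny deterministic orthogroup table built by hand
toy_og_table <- function() {
  tab <- data.frame(
    Orthogroup = c("OG1", "OG2", "OG3", "OG4"),
    A = c("A_g1, A_g2", "A_g3", "", ""),
    B = c("B_g1", "B_g2", "B_g3", ""),
    C = c("C_g1", "", "", "C_g2"),
    check.names = FALSE, stringsAsFactors = FALSE)
  class(tab) <- c("orthogroup_table", "data.frame")
  tab
}

# deterministic random DNA for fixtures
random_fixture_dna <- function(n, seed, gc = 0.5) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
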