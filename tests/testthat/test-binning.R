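test_that("bin summaries tally taxon labels", {
  ctg <- data.frame(bin_id = "b1",
                    taxon_label = c("eukaryotic", "eukaryotic",
                                    "unclassified"))
  s <- summarize_bin(ctg)
  expect_equal(unlist(s[c("n_euk", "n_prok", "n_unclass")]),
               c(n_euk = 2, n_prok = 0, n_unclass = 1))
  empty <- summarize_bin(ctg[0, , drop = FALSE])
  expect_equal(empty$n_euk + empty$n_prok + empty$n_unclass, 0)
  set.seed(4)
  labels <- sample(c("eukaryotic", "prokaryotic", "unclassified"), 100,
                   replace = TRUE)
  s2 <- summarize_bin(data.frame(bin_id = "x", taxon_label = labels))
  expect_equal(s2$n_euk, sum(labels == "eukaryotic"))
  expect_equal(s2$n_prok, sum(labels == "prokaryotic"))
  expect_equal(s2$n_unclass, sum(labels == "unclassified"))
  expect_error(summarize_bin(data.frame(bin_id = c("a", "b"),
                                        taxon_label = "eukaryotic")),
               "single bin")
})

test_that("resolution rules fire at their inclusive boundaries", {
  expect_equal(resolve_unclassified(10, 20, 3), "eukaryotic")   # 10 >= 20/2
  expect_equal(resolve_unclassified(0, 4, 8), "eukaryotic")     # 8 >= 2*4
  expect_equal(resolve_unclassified(1, 10, 5), "prokaryotic")
  expect_equal(resolve_unclassified(0, 0, 0), "eukaryotic")     # n_prok = 0
})

test_that("resolution matches the two-rule predicate over all small counts", {
  for (ne in 0:6) for (np in 0:6) for (nu in 0:6) {
    want <- if (ne >= np / 2 || nu >= 2 * np) "eukaryotic" else "prokaryotic"
    expect_identical(resolve_unclassified(ne, np, nu), want,
                     info = sprintf("euk=%d prok=%d unclass=%d", ne, np, nu))
  }
})

test_that("bin resolution relabels only unclassified contigs, per bin", {
  ctg <- data.frame(
    id = paste0("c", 1:6),
    bin_id = c("b1", "b1", "b1", "b2", "b2", "b2"),
    taxon_label = c("eukaryotic", "prokaryotic", "unclassified",
                    "prokaryotic", "prokaryotic", "unclassified"))
  out <- apply_bin_resolution(ctg)
  # b1: 1 >= 2/2 -> eukaryotic; b2: 0 < 2/2 and 1 < 4 -> prokaryotic
  expect_equal(out$taxon_label[3], "eukaryotic")
  expect_equal(out$taxon_label[6], "prokaryotic")
  expect_equal(out$taxon_label[c(1, 2, 4, 5)], ctg$taxon_label[c(1, 2, 4, 5)])
  expect_equal(out$resolved, c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))
})

test_that("exact-seed hits behave on planted and impossible reads", {
  contig <- random_fixture_dna(5000, seed = 9)
  read <- substr(contig, 100, 250)
  expect_true(naive_seed_hit(read, contig))
  expect_true(naive_seed_hit(revcomp(read), contig))
  expect_false(naive_seed_hit(strrep("A", 100), strrep("G", 2000)))
  expect_error(naive_seed_hit("ACGT", contig, seed_len = 31), "read length")
})

test_that("seed aligner recovers error-bearing reads from their source", {
  h <- make_haplotypes(genome_spec(50000, ploidy = 1, het_rate = 0,
                                   seed = 14))
  reads <- simulate_reads(c(src = h$haplotypes[[1]]),
                          coverage_spec(haploid_coverage = 3, read_len = 150,
                                        error_rate = 0.01, seed = 6))
  expect_gte(nrow(reads), 1000)
  idx <- chrysopan:::.seed_index(h$haplotypes[[1]], 31L)  # build index once
  hits <- vapply(reads$sequence, naive_seed_hit, logical(1),
                 contigs = idx, USE.NAMES = FALSE)
  expect_gte(mean(hits), 0.95)
})

test_that("incremental rescue implements the S1 set algebra", {
  euk <- random_fixture_dna(3000, seed = 21, gc = 0.40)
  prok <- random_fixture_dna(3000, seed = 22, gc = 0.65)
  shared <- substr(euk, 1000, 1199)
  prok_with_shared <- paste0(prok, shared)
  reads <- data.frame(
    read_id = c("euk_only", "both", "prok_only", "neither"),
    sequence = c(substr(euk, 1, 150), substr(shared, 1, 150),
                 substr(prok, 1, 150), random_fixture_dna(150, seed = 23)))
  part <- incremental_read_rescue(reads, prok_with_shared, euk)
  expect_setequal(part$retained, c("euk_only", "both", "neither"))
  expect_setequal(part$excluded, "prok_only")
  # partition invariant
  expect_length(intersect(part$retained, part$excluded), 0)
  expect_setequal(c(part$retained, part$excluded), reads$read_id)
})

test_that("rescue with empty contig sets retains everything", {
  reads <- data.frame(read_id = c("r1", "r2"),
                      sequence = c(random_fixture_dna(100, 1),
                                   random_fixture_dna(100, 2)))
  part <- incremental_read_rescue(reads, character(0), character(0))
  expect_setequal(part$retained, c("r1", "r2"))
  expect_length(part$excluded, 0)
})

test_that("adding eukaryotic contigs never shrinks the retained set", {
  euk1 <- random_fixture_dna(2000, seed = 31, gc = 0.4)
  euk2 <- random_fixture_dna(2000, seed = 32, gc = 0.4)
  prok <- paste0(random_fixture_dna(2000, seed = 33, gc = 0.65),
                 substr(euk2, 1, 300))
  reads <- simulate_reads(c(e1 = euk1, e2 = euk2, p = prok),
                          coverage_spec(haploid_coverage = 2, read_len = 120,
                                        seed = 8))
  p_small <- incremental_read_rescue(reads, prok, euk1)
  p_big <- incremental_read_rescue(reads, prok, c(euk1, euk2))
  expect_true(all(p_small$retained %in% p_big$retained))
})

test_that("rescue on truth-labeled error-free mixtures is exact", {
  h <- make_haplotypes(genome_spec(30000, ploidy = 2, het_rate = 0.01,
                                   seed = 41))
  bact <- random_fixture_dna(15000, seed = 42, gc = 0.65)
  reads <- simulate_reads(c(hap1 = h$haplotypes[[1]],
                            hap2 = h$haplotypes[[2]], bact = bact),
                          coverage_spec(haploid_coverage = 2, read_len = 150,
                                        error_rate = 0, seed = 43))
  part <- incremental_read_rescue(reads, bact, unname(h$haplotypes))
  euk_ids <- reads$read_id[reads$source != "bact"]
  bact_ids <- reads$read_id[reads$source == "bact"]
  expect_true(all(euk_ids %in% part$retained))
  expect_true(all(bact_ids %in% part$excluded))
})

test_that("short-contig filter keeps the 500 bp boundary", {
  ctg <- data.frame(id = paste0("c", 1:4),
                    length = c(100, 500, 501, 499))
  out <- filter_short_contigs(ctg)
  expect_equal(out$id, c("c2", "c3"))
  expect_equal(filter_short_contigs(c(499, 500)), 500)
})

test_that("naive composition classifier separates synthetic euk from bact", {
  h <- make_haplotypes(genome_spec(20000, ploidy = 1, het_rate = 0,
                                   base_gc = 0.40, seed = 51))
  ctg <- make_contaminated_assembly(
    h$haplotypes[[1]],
    contamination_spec(n_bact_contigs = 5, bact_gc = 0.65, seed = 52))
  refs <- data.frame(
    sequence = c(random_fixture_dna(5000, seed = 53, gc = 0.40),
                 random_fixture_dna(5000, seed = 54, gc = 0.65)),
    label = c("eukaryotic", "prokaryotic"))
  got <- classify_contigs_naive(ctg, refs)
  big <- ctg$length >= 300   # tiny trailing fragments are genuinely ambiguous
  expect_gte(mean(got[big] == ctg$truth_label[big]), 0.9)
})
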