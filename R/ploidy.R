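# Smudgeplot-style ploidy estimation: heterozygous Hamming-1 k-mer pairs and
# the characteristic minor-coverage ratio law (1/2 diploid, 1/3 triploid, ...).

#' Find heterozygous k-mer pairs (Hamming distance 1)
#'
#' Scans a canonical k-mer count table for unordered pairs of k-mers whose
#' Hamming distance, minimized over the two relative orientations (as-is and
#' reverse complement), is exactly 1.  Such pairs arise from the two alleles
#' of a heterozygous site.  K-mers with two or more candidate partners are
#' dropped entirely rather than paired greedily, which keeps the result
#' order-independent.
#'
#' The scan is linear in table size: for each of the k positions, k-mers (in
#' both orientations) are grouped by their sequence with that position masked
#' out; co-grouped k-mers differ exactly there.
#'
#' @param table a `kmer_count_table` from [count_canonical_kmers()].
#' @param min_pair_cov minimum count for a k-mer to participate (default 4;
#'   filters low-coverage sequencing-error k-mers).
#' @return data.frame with columns `kmer_a`, `kmer_b`, `cov_major`,
#'   `cov_minor`, `ratio` (`cov_minor / (cov_major + cov_minor)`, in
#'   `(0, 0.5]`) and `total`.
#' @export
find_het_pairs <- function(table, min_pair_cov = 4L) {
  stopifnot(inherits(table, "kmer_count_table"))
  k <- table$k
  counts <- table$counts[table$counts >= min_pair_cov]
  kmers <- names(counts)
  n <- length(kmers)
  empty <- data.frame(kmer_a = character(0), kmer_b = character(0),
                      cov_major = integer(0), cov_minor = integer(0),
                      ratio = numeric(0), total = integer(0))
  if (n < 2L) return(empty)
  D <- matrix(.kmer_digits(kmers, k), ncol = k)
  Dr <- 3L - D[, k:1, drop = FALSE]
  pw <- 4^((k - 1L):0L)
  code_f <- .digits_code(D, k)
  code_r <- .digits_code(Dr, k)
  # both orientations of every k-mer, tagged with its table index
  ids <- c(seq_len(n), seq_len(n))
  codes <- c(code_f, code_r)
  digits <- rbind(D, Dr)
  # composite group key per masked position: (code with digit i zeroed)
  # disambiguated by i; codes < 4^k and 4^k * k < 2^53 keeps this exact
  gkeys <- vector("list", k)
  for (i in seq_len(k)) {
    gkeys[[i]] <- (codes - digits[, i] * pw[i]) * k + (i - 1)
  }
  gv <- unlist(gkeys, use.names = FALSE)
  idv <- rep.int(ids, k)
  o <- order(gv, method = "radix")
  gs <- gv[o]
  iv <- idv[o]
  new_run <- c(TRUE, gs[-1L] != gs[-length(gs)])
  starts <- which(new_run)
  lens <- diff(c(starts, length(gs) + 1L))
  # runs of two entries give a candidate pair directly; larger runs are
  # resolved on their *distinct* k-mers — both orientations of a pair's
  # members can co-occur in one group (Hamming-1 in both orientations at
  # the same position), which is still a single pair, whereas three or
  # more distinct k-mers mean every member has >= 2 partners (ambiguity
  # rule: drop them all)
  s2 <- starts[lens == 2L]
  ia <- pmin(iv[s2], iv[s2 + 1L])
  ib <- pmax(iv[s2], iv[s2 + 1L])
  dropped_flag <- rep(FALSE, n)
  for (r in which(lens >= 3L)) {
    rid <- unique(iv[seq.int(starts[r], starts[r] + lens[r] - 1L)])
    if (length(rid) == 2L) {
      ia <- c(ia, min(rid))
      ib <- c(ib, max(rid))
    } else if (length(rid) >= 3L) {
      dropped_flag[rid] <- TRUE
    }
  }
  # a run of the two orientations of one k-mer is not a pair
  ok <- ia != ib
  ia <- ia[ok]; ib <- ib[ok]
  if (length(ia) == 0L) return(empty)
  # deduplicate pairs found at several positions/orientations, then apply
  # the global partner-multiplicity rule
  pkey <- ia * (n + 1) + ib
  first <- !duplicated(pkey)
  ia <- ia[first]; ib <- ib[first]
  partner_n <- tabulate(c(ia, ib), nbins = n)
  bad <- dropped_flag | partner_n >= 2L
  keep <- !bad[ia] & !bad[ib]
  ia <- ia[keep]; ib <- ib[keep]
  if (length(ia) == 0L) return(empty)
  ca <- unname(counts[ia])
  cb <- unname(counts[ib])
  cov_major <- pmax(ca, cb)
  cov_minor <- pmin(ca, cb)
  out <- data.frame(kmer_a = kmers[ia], kmer_b = kmers[ib],
                    cov_major = cov_major, cov_minor = cov_minor,
                    ratio = cov_minor / (cov_major + cov_minor),
                    total = cov_major + cov_minor,
                    stringsAsFactors = FALSE)
  out[order(out$kmer_a), , drop = FALSE]
}

#' Smudge-plane coordinates of heterozygous pairs
#'
#' @param pairs data.frame from [find_het_pairs()].
#' @return data.frame with columns `ratio` (minor-coverage ratio, in
#'   `(0, 0.5]`) and `total` (summed pair coverage) — one row per pair.
#' @export
smudge_coordinates <- function(pairs) {
  data.frame(ratio = pairs$cov_minor / (pairs$cov_major + pairs$cov_minor),
             total = pairs$cov_major + pairs$cov_minor)
}

#' Call ploidy from smudge coordinates
#'
#' Under ploidy `q` with haploid depth `c`, a heterozygous k-mer pair whose
#' minor allele sits on `m` of the `q` copies produces a smudge at minor
#' ratio `m/q` and total coverage `q*c` (the ratio law: 1/2 diploid, 1/3
#' triploid, and so on).  Each candidate `(q, c)` — with `c` on a
#' data-driven log grid — is scored by the mean per-pair log-likelihood of a
#' generative smudge model: the pair total is `Poisson(q*c)` and, given the
#' total, the minor count is a folded binomial at allele fraction `m/q`,
#' mixed uniformly over `m = 1..floor(q/2)`.  Density-based scoring is what
#' makes the candidates comparable: a tolerance-band count would let every
#' ploidy-`q` explanation hide inside its multiples (any noise in the minor
#' ratio is absorbed by the denser `m/q` grid of large `q`), whereas a
#' mixture must pay for every component it spreads mass on.  Scores are
#' reported as relative support `exp(mean loglik - best mean loglik)` in
#' `(0, 1]`, and the smallest `q` scoring within `parsimony_margin` of the
#' best is returned — every `q` explanation is also a `2q` explanation, so
#' near-ties resolve to the more parsimonious level.
#'
#' @param coords data.frame from [smudge_coordinates()] (>= 50 rows).
#' @param q_max largest candidate ploidy (default 8).
#' @param ratio_tol,cov_tol tolerances for the auxiliary `explained`
#'   diagnostic: the fraction of pairs within `ratio_tol` of an admissible
#'   `m/q` and within `cov_tol * q * c` of the winner's expected total
#'   (defaults 0.03 and 0.25).  They do not enter the likelihood.
#' @param parsimony_margin relative-support margin within which a smaller
#'   ploidy is preferred (default 0.05).
#' @param ambiguity_margin candidates with relative support within this
#'   margin of the winner's are reported as near-ties (default 0.05).
#' @return object of class `ploidy_call`: list with `level`,
#'   `haploid_coverage`, `scores` (relative support per candidate level),
#'   `explained` (tolerance-band fraction for the winner) and
#'   `ambiguous_with`.
#' @export
call_ploidy <- function(coords, q_max = 8L, ratio_tol = 0.03,
                        cov_tol = 0.25, parsimony_margin = 0.05,
                        ambiguity_margin = 0.05) {
  if (nrow(coords) < 50L) {
    stop_input("insufficient pairs: ploidy calling needs >= 50 smudge ",
               "coordinates, got ", nrow(coords))
  }
  total <- coords$total
  minor <- as.integer(round(coords$ratio * total))
  med <- stats::median(total)
  c_grid <- exp(seq(log(med / q_max * 0.5), log(med), length.out = 30L))
  qs <- 2:q_max
  mean_ll <- numeric(length(qs))
  c_best <- numeric(length(qs))
  floor_ll <- log(1e-12)  # robustness floor against stray coordinates
  for (j in seq_along(qs)) {
    q <- qs[j]
    ms <- seq_len(floor(q / 2))
    # minor-count mixture is independent of c: folded Binomial(total, m/q)
    mix <- rowSums(vapply(ms, function(m) {
      p <- m / q
      (stats::dbinom(minor, total, p) +
         ifelse(minor != total - minor,
                stats::dbinom(total - minor, total, p), 0)) / length(ms)
    }, numeric(length(total))))
    ll_ratio <- pmax(log(mix), floor_ll)
    ll_c <- vapply(c_grid, function(cc) {
      mean(pmax(stats::dpois(total, q * cc, log = TRUE), floor_ll) + ll_ratio)
    }, numeric(1))
    mean_ll[j] <- max(ll_c)
    c_best[j] <- c_grid[which.max(ll_c)]
  }
  scores <- exp(mean_ll - max(mean_ll))
  names(scores) <- qs
  level <- qs[which(scores >= 1 - parsimony_margin)[1]]
  win_score <- scores[as.character(level)]
  amb <- qs[scores >= win_score - ambiguity_margin & qs != level]
  cw <- c_best[match(level, qs)]
  ms <- seq_len(floor(level / 2))
  ratio_ok <- apply(vapply(ms, function(m) abs(coords$ratio - m / level),
                           numeric(length(total))), 1, min) <= ratio_tol
  explained <- mean(ratio_ok &
                      abs(total - level * cw) <= cov_tol * level * cw)
  structure(list(level = as.integer(level),
                 haploid_coverage = cw,
                 scores = scores,
                 explained = explained,
                 ambiguous_with = as.integer(amb)),
            class = "ploidy_call")
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat("ploidy call: level", x$level,
      sprintf("(haploid coverage ~ %.1f)\n", x$haploid_coverage))
  cat("scores:", paste(names(x$scores), round(x$scores, 3), sep = "=",
                       collapse = " "), "\n")
  if (length(x$ambiguous_with)) {
    cat("near-tied with:", paste(x$ambiguous_with, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Modal smudge ratio of a pair set
#'
#' Assigns every heterozygous pair to the nearest admissible smudge ratio
#' `m/q` (over `q = 2..q_max`, `m = 1..floor(q/2)`) and returns the most
#' frequent one — the empirical face of the ratio law (1/2 for a diploid,
#' 1/3 for a triploid, ...).  Ties break to the larger ratio (smaller
#' implied ploidy).
#'
#' The default grid stops at tetraploid: protist isolates are typically
#' di- to tetraploid, and a coarse grid keeps the assignment robust to the
#' per-pair ratio noise at moderate depth (at a pair total of 50 the ratio
#' standard deviation is ~0.07, comparable to the spacing of the q = 7, 8
#' ratios around 1/2).  This is a diagnostic of where pairs sit, not a
#' ploidy call — [call_ploidy()] scans further and weighs coverage too.
#'
#' @param coords data.frame from [smudge_coordinates()].
#' @param q_max largest ploidy considered for the candidate grid
#'   (default 4).
#' @return the modal candidate ratio as a numeric scalar.
#' @export
modal_smudge_ratio <- function(coords, q_max = 4L) {
  if (nrow(coords) == 0L) stop_input("coords must be non-empty")
  cand <- sort(unique(unlist(lapply(2:q_max, function(q) {
    seq_len(floor(q / 2)) / q
  }))), decreasing = TRUE)
  nearest <- apply(abs(outer(coords$ratio, cand, "-")), 1, which.min)
  hits <- tabulate(nearest, nbins = length(cand))
  cand[which.max(hits)]  # ties resolve to the larger ratio
}

#' Histogram of the smudge plane
#'
#' Diagnostic 2D histogram over minor ratio (fixed-width bins on `(0, 0.5]`)
#' and total coverage (quantile bins), the structure a smudge figure renders.
#'
#' @param coords data.frame from [smudge_coordinates()].
#' @param ratio_bin ratio bin width (default 0.01).
#' @param n_cov_bins number of coverage quantile bins (default 40).
#' @return matrix of counts (ratio bins x coverage bins); counts sum to
#'   `nrow(coords)`.
#' @export
smudge_grid <- function(coords, ratio_bin = 0.01, n_cov_bins = 40L) {
  if (nrow(coords) == 0L) stop_input("coords must be non-empty")
  rb <- seq(0, 0.5, by = ratio_bin)
  ri <- cut(coords$ratio, breaks = rb, include.lowest = FALSE,
            labels = FALSE)
  qs <- unique(stats::quantile(coords$total,
                               probs = seq(0, 1, length.out = n_cov_bins + 1L)))
  if (length(qs) < 2L) qs <- c(qs - 0.5, qs + 0.5)  # all totals identical
  ci <- cut(coords$total, breaks = qs, include.lowest = TRUE, labels = FALSE)
  m <- matrix(0L, nrow = length(rb) - 1L, ncol = length(qs) - 1L,
              dimnames = list(sprintf("(%.2f,%.2f]", rb[-length(rb)], rb[-1]),
                              NULL))
  for (i in seq_len(nrow(coords))) {
    m[ri[i], ci[i]] <- m[ri[i], ci[i]] + 1L
  }
  m
}
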