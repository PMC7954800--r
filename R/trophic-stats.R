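# Group statistics across trophic modes: means, one-way ANOVA, posthoc
# pairwise comparison, paired region-GC tests, correlation screens.

#' Bundled chrysophyte strain metadata
#'
#' Published per-strain summary values for the 16 chrysophyte strains the
#' package's analyses are modelled on: species, strain id, trophic mode,
#' whole-assembly GC percentage, BUSCO completeness percentage, N50 and the
#' reported ploidy call.  Used by the worked examples and the in-package
#' recomputations of the group statistics.
#'
#' @return data.frame with columns `species`, `strain`, `mode`,
#'   `gc_percent`, `busco_complete_pct`, `n50`, `ploidy`.
#' @export
read_strain_metadata <- function() {
  path <- system.file("extdata", "chrysophyte_strains.tsv",
                      package = "chrysopan", mustWork = TRUE)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

.check_modes <- function(modes) {
  ok <- c("phototroph", "mixotroph", "heterotroph")
  bad <- setdiff(unique(modes), ok)
  if (length(bad)) stop_input("unknown trophic mode(s): ",
                              paste(bad, collapse = ", "))
}

#' Group means of a per-strain metric
#'
#' @param values numeric vector of per-strain values (e.g. GC %).
#' @param modes trophic mode of each strain.
#' @param round_to decimal places for reporting (default 1); use `Inf` for
#'   full precision.
#' @return named numeric vector, one mean per mode present.
#' @export
group_means <- function(values, modes, round_to = 1) {
  .check_modes(modes)
  m <- tapply(values, modes, mean)
  out <- stats::setNames(as.numeric(m), names(m))
  if (is.finite(round_to)) out <- round(out, round_to)
  out
}

#' One-way fixed-effects ANOVA across trophic modes
#'
#' Classical one-way ANOVA: `F = MSB / MSW` with p from the F distribution.
#' Degenerate input with all values identical yields `F = 0`, `p = 1`.
#'
#' @param values numeric per-strain values.
#' @param modes trophic mode of each strain (>= 2 groups).
#' @return list of class `anova_result` with `f_stat`, `df_between`,
#'   `df_within`, `p_value`, `group_means`.
#' @export
one_way_anova <- function(values, modes) {
  .check_modes(modes)
  g <- factor(modes)
  if (nlevels(g) < 2) stop_input("ANOVA needs >= 2 groups")
  if (length(values) - nlevels(g) < 2) stop_input("ANOVA needs >= 2 within df")
  if (stats::var(values) == 0) {
    return(structure(list(f_stat = 0, df_between = nlevels(g) - 1L,
                          df_within = length(values) - nlevels(g),
                          p_value = 1,
                          group_means = group_means(values, modes,
                                                    round_to = Inf)),
                     class = "anova_result"))
  }
  fit <- aov(values ~ g)
  tab <- summary(fit)[[1]]
  structure(list(f_stat = tab[["F value"]][1],
                 df_between = tab[["Df"]][1],
                 df_within = tab[["Df"]][2],
                 p_value = tab[["Pr(>F)"]][1],
                 group_means = group_means(values, modes, round_to = Inf)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df_between, x$df_within, x$f_stat, x$p_value))
  cat("group means:", paste(names(x$group_means),
                            round(x$group_means, 2), sep = "=",
                            collapse = " "), "\n")
  invisible(x)
}

#' Posthoc pairwise comparison of trophic-mode groups
#'
#' Tukey's honestly-significant-difference test by default (family-wise
#' adjusted); pairwise t tests with Holm correction as an alternative.
#'
#' @param values numeric per-strain values.
#' @param modes trophic modes.
#' @param method `"tukey_hsd"` or `"pairwise_t_holm"`.
#' @return named numeric vector of adjusted p-values, one per mode pair
#'   (names like `"mixotroph-heterotroph"`).
#' @export
posthoc_pairwise <- function(values, modes,
                             method = c("tukey_hsd", "pairwise_t_holm")) {
  method <- match.arg(method)
  .check_modes(modes)
  g <- factor(modes)
  if (stats::var(values) == 0) {
    pairs <- combn(levels(g), 2)
    return(stats::setNames(rep(1, ncol(pairs)),
                           apply(pairs, 2, paste, collapse = "-")))
  }
  if (method == "tukey_hsd") {
    tk <- TukeyHSD(aov(values ~ g))$g
    stats::setNames(tk[, "p adj"], rownames(tk))
  } else {
    pt <- stats::pairwise.t.test(values, g, p.adjust.method = "holm",
                                 pool.sd = FALSE)$p.value
    out <- numeric(0)
    for (i in rownames(pt)) for (j in colnames(pt)) {
      if (!is.na(pt[i, j])) out[paste(i, j, sep = "-")] <- pt[i, j]
    }
    out
  }
}

#' Paired t-tests between region GC classes
#'
#' Compares coding, intron and intergenic GC within strains (paired by
#' strain, since the three regions belong to the same genome).  Strains
#' missing any region are dropped with a warning.  P-values are reported
#' raw, without multiple-testing correction.
#'
#' @param region_gc data.frame with columns `strain`, `coding`, `intron`,
#'   `intergenic` (GC percentages).
#' @return named numeric vector of two-sided p-values for the pairs
#'   `coding-intron`, `coding-intergenic`, `intron-intergenic`.
#' @export
region_gc_tests <- function(region_gc) {
  need <- c("coding", "intron", "intergenic")
  ok <- stats::complete.cases(region_gc[, need])
  if (any(!ok)) {
    warning("dropping ", sum(!ok), " strain(s) with missing region GC")
    region_gc <- region_gc[ok, , drop = FALSE]
  }
  if (nrow(region_gc) < 3) stop_input("region tests need >= 3 complete strains")
  pair_p <- function(a, b) {
    if (all(region_gc[[a]] == region_gc[[b]])) return(1)
    t.test(region_gc[[a]], region_gc[[b]], paired = TRUE)$p.value
  }
  c(`coding-intron` = pair_p("coding", "intron"),
    `coding-intergenic` = pair_p("coding", "intergenic"),
    `intron-intergenic` = pair_p("intron", "intergenic"))
}

#' Correlation screen between two per-strain quantities
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method correlation method, passed to [stats::cor.test()]
#'   (default `"pearson"`).
#' @return list with `r` and `p`; both `NA` (with a warning) when either
#'   input is constant.
#' @export
correlation_screen <- function(x, y, method = "pearson") {
  if (length(x) != length(y) || length(x) < 3) {
    stop_input("correlation_screen needs equal lengths >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: correlation undefined")
    return(list(r = NA_real_, p = NA_real_))
  }
  ct <- cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value)
}
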