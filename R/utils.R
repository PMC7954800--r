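DNA_BASES <- c("A", "C", "G", "T")

stop_input <- function(...) {
  stop(..., call. = FALSE)
}

#' Describe a length or count distribution
#'
#' Distribution specifications are the unit in which the synthetic-data
#' generator takes lengths and counts: a named family plus its parameters.
#' Supported families are `constant(value)`, `uniform(min, max)` and
#' `lognormal(meanlog, sdlog)`.
#'
#' @param kind one of `"constant"`, `"uniform"`, `"lognormal"`.
#' @param ... family parameters: `value` for constant; `min`, `max` for
#'   uniform; `meanlog`, `sdlog` for lognormal.
#' @return an object of class `dist_spec`.
#' @examples
#' dist_spec("uniform", min = 100, max = 300)
#' @export
dist_spec <- function(kind = c("constant", "uniform", "lognormal"), ...) {
  kind <- match.arg(kind)
  params <- list(...)
  needed <- switch(kind,
    constant = "value",
    uniform = c("min", "max"),
    lognormal = c("meanlog", "sdlog")
  )
  if (!setequal(names(params), needed)) {
    stop_input("dist_spec('", kind, "') requires parameters: ",
               paste(needed, collapse = ", "))
  }
  if (kind == "uniform" && params$min > params$max) {
    stop_input("uniform dist_spec needs min <= max")
  }
  structure(c(list(kind = kind), params), class = "dist_spec")
}

#' Draw from a distribution specification
#'
#' @param spec a [dist_spec()].
#' @param n number of draws.
#' @param integer round draws to positive integers (used for lengths/counts).
#' @return numeric vector of length `n`.
#' @export
draw_dist <- function(spec, n, integer = TRUE) {
  stopifnot(inherits(spec, "dist_spec"))
  x <- switch(spec$kind,
    constant = rep(spec$value, n),
    uniform = runif(n, spec$min, spec$max),
    lognormal = rlnorm(n, spec$meanlog, spec$sdlog)
  )
  if (integer) x <- pmax(1, round(x))
  x
}

# i.i.d. nucleotide draw: P(G)=P(C)=gc/2, P(A)=P(T)=(1-gc)/2
random_bases <- function(n, gc) {
  if (n == 0L) return(character(0))
  sample(DNA_BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

random_dna <- function(n, gc) paste(random_bases(n, gc), collapse = "")

#' Reverse complement of DNA strings
#'
#' @param x character vector of A/C/G/T sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
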