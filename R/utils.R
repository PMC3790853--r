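#' @useDynLib igcscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm pnorm qgamma pgamma setNames optim quantile rbinom sd
#' @importFrom utils combn read.table write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA <- c("A", "C", "G", "T")

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministic integer stream used to hand independent seeds to nested
#' stochastic stages (bootstraps, simulation replicates, permutations) so that
#' a single pipeline seed controls every random draw. Kept below 2^31.
#'
#' @param seed master integer seed.
#' @param index positive integer stream index.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), is.numeric(index))
  # combine affinely, then scramble through the generator itself so that
  # derived seeds are not an arithmetic progression (structured seed sets can
  # induce correlated streams)
  key <- (as.double(seed) * 48271 + as.double(index) * 16807 + 11) %% 2147483647
  with_seed(as.integer(key), sample.int(2147483646L, 1L))
}

#' Evaluate an expression under a local RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded stages do not perturb the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# string <-> residue-vector helpers
seq_to_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
chars_to_seq <- function(x) paste0(x, collapse = "")

# rows of a character matrix as strings
matrix_to_strings <- function(m) apply(m, 1L, chars_to_seq)

strings_to_matrix <- function(x) {
  stopifnot(length(unique(nchar(x))) == 1L)
  m <- do.call(rbind, strsplit(x, "", fixed = TRUE))
  rownames(m) <- names(x)
  m
}
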