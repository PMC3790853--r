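#' GTR+Gamma+I substitution model
#'
#' Container for the general time-reversible model with discrete-gamma rate
#' variation and a proportion of invariant sites — the model used both to fit
#' paralog families and to simulate the no-exchange null.
#'
#' @param rates six non-negative GTR exchangeabilities in the order
#'   AC, AG, AT, CG, CT, GT (scale-free; only ratios matter).
#' @param base_freqs stationary base frequencies `(A, C, G, T)`; must sum to 1.
#' @param gamma_shape shape `alpha` of the gamma rate distribution (> 0);
#'   smaller values mean stronger among-site rate heterogeneity.
#' @param n_rate_classes number of discrete gamma categories (category means).
#' @param p_inv proportion of invariant sites in `[0, 1)` (or exactly 1 for the
#'   degenerate all-invariant model).
#' @param log_lik optional fitted log-likelihood.
#' @return an object of class `substitution_model`.
#' @export
substitution_model <- function(rates = rep(1, 6),
                               base_freqs = rep(0.25, 4),
                               gamma_shape = 1, n_rate_classes = 4L,
                               p_inv = 0, log_lik = NA_real_) {
  rates <- as.numeric(rates); base_freqs <- as.numeric(base_freqs)
  stopifnot(length(rates) == 6L, all(rates >= 0), any(rates > 0),
            length(base_freqs) == 4L, all(base_freqs > 0),
            abs(sum(base_freqs) - 1) < 1e-6,
            gamma_shape > 0, n_rate_classes >= 1L, p_inv >= 0, p_inv <= 1)
  names(rates) <- c("AC", "AG", "AT", "CG", "CT", "GT")
  names(base_freqs) <- DNA
  structure(list(rates = rates, base_freqs = base_freqs / sum(base_freqs),
                 gamma_shape = gamma_shape,
                 n_rate_classes = as.integer(n_rate_classes),
                 p_inv = p_inv, log_lik = log_lik),
            class = "substitution_model")
}

#' Jukes-Cantor model (all rates and frequencies equal)
#' @param ... passed to [substitution_model()] (e.g. `gamma_shape`, `p_inv`).
#' @return a `substitution_model`.
#' @export
jc_model <- function(...) substitution_model(rates = rep(1, 6),
                                             base_freqs = rep(0.25, 4), ...)

#' @export
print.substitution_model <- function(x, ...) {
  cat("<substitution_model> GTR+G", x$n_rate_classes, "+I\n", sep = "")
  cat("  rates:", paste(sprintf("%s=%.3g", names(x$rates), x$rates),
                        collapse = " "), "\n")
  cat("  pi:", paste(sprintf("%s=%.3f", names(x$base_freqs), x$base_freqs),
                     collapse = " "), "\n")
  cat(sprintf("  alpha=%.3g  p_inv=%.3g\n", x$gamma_shape, x$p_inv))
  invisible(x)
}

# Normalized GTR rate matrix Q (rows A,C,G,T; mean rate 1 substitution/site).
gtr_rate_matrix <- function(model) {
  s <- model$rates; pi <- model$base_freqs
  Q <- matrix(0, 4, 4, dimnames = list(DNA, DNA))
  Q["A", "C"] <- s["AC"]; Q["A", "G"] <- s["AG"]; Q["A", "T"] <- s["AT"]
  Q["C", "G"] <- s["CG"]; Q["C", "T"] <- s["CT"]; Q["G", "T"] <- s["GT"]
  Q <- Q + t(Q)
  Q <- sweep(Q, 2L, pi, `*`)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("rate matrix is non-stochastic (zero total rate)")
  Q / mu
}

# Eigendecomposition of Q for fast P(t) = expm(Q t); reversible so we
# symmetrize with sqrt(pi) and use a symmetric eigensolver.
gtr_eigen <- function(model) {
  Q <- gtr_rate_matrix(model)
  pi <- model$base_freqs
  sq <- sqrt(pi)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(values = e$values,
       right = diag(1 / sq) %*% e$vectors,
       left = t(e$vectors) %*% diag(sq))
}

# Transition probability matrix over branch length t (subs/site) at rate r.
gtr_pmatrix <- function(eig, t, r = 1) {
  P <- eig$right %*% (exp(eig$values * t * r) * eig$left)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Discrete-gamma category rates (category means)
#'
#' @param alpha gamma shape.
#' @param k number of categories.
#' @return `k` rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k = 4L) {
  if (k == 1L) return(1)
  # mean of each equal-probability gamma(alpha, alpha) slice
  q <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  p_up <- stats::pgamma(q, shape = alpha + 1, rate = alpha)
  r <- (p_up[-1L] - p_up[-(k + 1L)]) * k
  r / mean(r)
}
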