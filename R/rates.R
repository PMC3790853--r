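#' Equilibrium per-generation IGC rate for a paralog family
#'
#' Under a steady state in which the homogenizing effect of interlocus gene
#' conversion exactly balances the diversifying effect of mutation — with each
#' paralog equally likely to be converted by any of the other `n - 1` family
#' members — the per-site, per-generation conversion rate between a pair of
#' paralogs is
#' \deqn{c = 2 \mu (n - 1) / d,}
#' where `mu` is the per-site mutation rate per generation, `d` the family's
#' mean pairwise divergence and `n` its paralog count. More divergent families
#' imply slower conversion; more paralogs dilute each pairwise rate's share of
#' the total homogenization needed to hold divergence steady.
#'
#' @param mu mutation rate, mutations/site/generation (human germline default
#'   `1.2e-8`).
#' @param d mean pairwise divergence (`1 - mean identity`), in `(0, 1)`.
#' @param n number of paralogs in the family (>= 2).
#' @return object of class `igc_rate_estimate`: `c` (conversions/site/
#'   generation) and `formula_id`.
#' @export
estimate_igc_rate <- function(mu = 1.2e-8, d, n) {
  stopifnot(mu >= 0, n >= 2)
  if (any(d <= 0)) stop("divergence-free family, rate unidentifiable (d = 0)")
  if (any(d >= 1)) stop("d must be a divergence fraction in (0, 1)")
  structure(list(c = 2 * mu * (n - 1) / d,
                 mu = mu, d = d, n = n,
                 formula_id = "equilibrium_2mu_nminus1_over_d"),
            class = "igc_rate_estimate")
}

#' @export
print.igc_rate_estimate <- function(x, ...) {
  cat(sprintf("<igc_rate_estimate> c = %.3g conversions/site/generation (mu = %.3g, d = %.3g, n = %d)\n",
              x$c, x$mu, x$d, as.integer(x$n)))
  invisible(x)
}

#' Fraction of duplicated sites involved in historical IGC
#'
#' Each conversion event relabels a block in one of the two sequences
#' involved, so the excess of observed over expected discordant-site
#' percentage double counts converted sites; halving it estimates the
#' percentage of duplicated sites that have ever been converted.
#'
#' @param observed_discordant_pct observed percentage of sites in
#'   topology-discordant blocks.
#' @param expected_discordant_pct simulation-expected percentage under no
#'   exchange.
#' @return `(observed - expected) / 2`, on the percent scale; negative values
#'   are clamped to 0 with a warning.
#' @export
converted_site_fraction <- function(observed_discordant_pct,
                                    expected_discordant_pct) {
  stopifnot(observed_discordant_pct >= 0, expected_discordant_pct >= 0)
  f <- (observed_discordant_pct - expected_discordant_pct) / 2
  if (f < 0) {
    warning("observed below expectation; converted fraction clamped to 0")
    f <- 0
  }
  f
}

#' Expected converted and mutated sites per individual per generation
#'
#' @param c_mean mean conversion rate (conversions/site/generation).
#' @param mu mutation rate (mutations/site/generation).
#' @param duplicated_bp total duplicated sequence surveyed (bp).
#' @return `list(converted, mutated)`: expected site counts per generation.
#' @export
per_generation_loads <- function(c_mean, mu, duplicated_bp) {
  stopifnot(c_mean >= 0, mu >= 0, duplicated_bp >= 0)
  list(converted = c_mean * duplicated_bp, mutated = mu * duplicated_bp)
}

#' Per-family IGC rate table
#'
#' @param families list of `aligned_family` objects.
#' @param mu mutation rate.
#' @return data frame with `family_id`, `n`, `d`, `c`; attribute
#'   `mean_rate` is the mean of per-family rates and `pooled_rate` the rate at
#'   the pooled (mean) divergence and mean paralog count.
#' @export
family_rate_table <- function(families, mu = 1.2e-8) {
  rows <- lapply(families, function(f) {
    d <- 1 - f$mean_identity
    n <- nrow(f$matrix)
    data.frame(family_id = f$family_id, n = n, d = d,
               c = estimate_igc_rate(mu, d, n)$c,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  attr(tab, "mean_rate") <- mean(tab$c)
  attr(tab, "pooled_rate") <- estimate_igc_rate(mu, mean(tab$d), mean(tab$n))$c
  tab
}
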