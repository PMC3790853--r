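TOPOLOGIES <- c("AB|CD", "AC|BD", "AD|BC")

#' Classify one quartet alignment column
#'
#' A parsimony-informative quartet column shows two bases, each carried by two
#' sequences. If the pairing matches the quartet topology induced by the family
#' tree the site is Concordant (C); if it supports one of the two alternative
#' topologies it is Reticulate (R) — the signature of interlocus exchange.
#' Columns with three or more distinct bases require multiple independent
#' mutations and are Bimutational (B). All other patterns are uninformative.
#'
#' @param column character vector of 4 bases (order `A, B, C, D`).
#' @param dominant the tree-induced topology, one of
#'   `"AB|CD"`, `"AC|BD"`, `"AD|BC"`.
#' @return `list(label, alt_topology)`: `label` in `{"C","R","B",
#'   "uninformative","skipped"}`; `alt_topology` is the supported alternative
#'   when `label == "R"`, otherwise `NA`.
#' @export
classify_quartet_site <- function(column, dominant) {
  stopifnot(length(column) == 4L, dominant %in% TOPOLOGIES)
  column <- toupper(column)
  if (!all(column %in% DNA))
    return(list(label = "skipped", alt_topology = NA_character_))
  im <- matrix(match(column, DNA), ncol = 1L)
  code <- .classify_columns(im)
  dom_i <- match(dominant, TOPOLOGIES)
  if (code == -1L) lab <- "B"
  else if (code == 0L) lab <- "uninformative"
  else if (code == dom_i) lab <- "C"
  else lab <- "R"
  list(label = lab,
       alt_topology = if (lab == "R") TOPOLOGIES[code] else NA_character_)
}

# Vectorized quartet column classifier.
# im: 4 x L integer matrix (1..4, NA = ambiguous base).
# Returns integer codes per column: 1..3 topology of an informative (2+2)
# pattern, -1 bimutational (>=3 distinct bases), 0 uninformative, NA skipped.
.classify_columns <- function(im) {
  a <- im[1L, ]; b <- im[2L, ]; c_ <- im[3L, ]; d <- im[4L, ]
  ab <- a == b; ac <- a == c_; ad <- a == d
  bc <- b == c_; bd <- b == d; cd <- c_ == d
  e <- ab + ac + ad + bc + bd + cd
  code <- integer(length(a))
  code[e <= 1L] <- -1L
  two <- which(e == 2L)
  if (length(two)) {
    t1 <- ab[two] & cd[two]
    t2 <- ac[two] & bd[two]
    t3 <- ad[two] & bc[two]
    code[two] <- 1L * t1 + 2L * t2 + 3L * t3
  }
  code[is.na(e)] <- NA_integer_
  code
}

# Enumerate the C(N,4) quartets of a family and their tree-induced topologies.
# Returns a list with integer index matrix (n_q x 4) and dominant codes.
family_quartets <- function(tree, seq_names) {
  stopifnot(all(seq_names %in% tree$tip.label))
  combs <- utils::combn(seq_along(seq_names), 4L)
  nq <- ncol(combs)
  dom <- integer(nq)
  for (q in seq_len(nq)) {
    dom[q] <- match(induced_quartet_topology(tree, seq_names[combs[, q]]),
                    TOPOLOGIES)
  }
  list(idx = t(combs), dominant = dom, leaves = seq_names)
}

# Fast whole-family scan over precomputed quartets.
# im: integer alignment matrix (1..4 / NA); qinfo from family_quartets().
# Returns union flags (R/B/informative per column) and per-quartet site codes.
.scan_core <- function(im, qinfo, keep_sites = FALSE) {
  L <- ncol(im)
  nq <- nrow(qinfo$idx)
  Rany <- Bany <- Iany <- rep(FALSE, L)
  counts <- matrix(0L, nq, 3L, dimnames = list(NULL, c("C", "R", "B")))
  sites <- if (keep_sites) vector("list", nq) else NULL
  for (q in seq_len(nq)) {
    code <- .classify_columns(im[qinfo$idx[q, ], , drop = FALSE])
    dom <- qinfo$dominant[q]
    isR <- !is.na(code) & code > 0L & code != dom
    isC <- !is.na(code) & code == dom
    isB <- !is.na(code) & code == -1L
    counts[q, ] <- c(sum(isC), sum(isR), sum(isB))
    Rany <- Rany | isR
    Bany <- Bany | isB
    Iany <- Iany | isR | isC | isB
    if (keep_sites) sites[[q]] <- code
  }
  list(counts = counts, R_union = sum(Rany), B_union = sum(Bany),
       informative_union = sum(Iany), Rany = Rany, Bany = Bany,
       sites = sites)
}

as_int_alignment <- function(mat) {
  im <- matrix(match(toupper(mat), DNA), nrow = nrow(mat))
  rownames(im) <- rownames(mat)
  im
}

#' Scan every quartet of a family for C/R/B sites
#'
#' Classifies all columns of every 4-sequence sub-alignment and aggregates the
#' family-level reticulate-site union: the number of columns reticulate in at
#' least one quartet.
#'
#' @param fam an `aligned_family` or gapless character matrix.
#' @param tree the family tree (leaf set must cover the family members).
#' @return an object of class `family_scan`: per-quartet results (`quartets`,
#'   each with ordered site columns, labels and alternative topologies),
#'   `R_union`, `B_union`, `informative_union`, and per-column union flags.
#' @export
scan_family <- function(fam, tree) {
  mat <- if (inherits(fam, "aligned_family")) fam$matrix else fam
  qinfo <- family_quartets(tree, rownames(mat))
  im <- as_int_alignment(mat)
  core <- .scan_core(im, qinfo, keep_sites = TRUE)
  quartets <- lapply(seq_len(nrow(qinfo$idx)), function(q) {
    code <- core$sites[[q]]
    dom <- qinfo$dominant[q]
    keep <- which(!is.na(code) & code != 0L)
    lab <- ifelse(code[keep] == -1L, "B",
                  ifelse(code[keep] == dom, "C", "R"))
    alt <- rep(NA_character_, length(keep))
    alt[lab == "R"] <- TOPOLOGIES[code[keep][lab == "R"]]
    structure(list(
      leaves = qinfo$leaves[qinfo$idx[q, ]],
      dominant = TOPOLOGIES[dom],
      columns = keep,
      labels = lab,
      alt = alt,
      n_C = unname(core$counts[q, "C"]), n_R = unname(core$counts[q, "R"]),
      n_B = unname(core$counts[q, "B"])
    ), class = "quartet_result")
  })
  structure(list(family_id = if (inherits(fam, "aligned_family"))
                   fam$family_id else "family",
                 quartets = quartets,
                 R_union = core$R_union, B_union = core$B_union,
                 informative_union = core$informative_union,
                 Rany = core$Rany, Bany = core$Bany,
                 alignment_length = ncol(mat)),
            class = "family_scan")
}

#' @export
print.family_scan <- function(x, ...) {
  cat(sprintf("<family_scan> %s: %d quartets, R union %d, B union %d (of %d informative columns)\n",
              x$family_id, length(x$quartets), x$R_union, x$B_union,
              x$informative_union))
  invisible(x)
}

#' Paired bootstrap-simulation test for a reticulate-site excess
#'
#' Compares the observed family-level R-site union to its expectation in the
#' absence of interlocus exchange. Uncertainty in the observed count comes from
#' 100 column bootstraps of the alignment; the null expectation comes from 100
#' alignments simulated under the fitted GTR+Gamma4+I model along the family
#' tree. After independent seeded shuffles, the i-th bootstrap draw is paired
#' with the i-th simulated count and the one-sided p-value is the fraction of
#' pairs in which the simulated count exceeds the bootstrap count (ties favor
#' the null, a conservative direction). The identical machinery is applied to
#' bimutational sites, whose non-excess bounds the parallel-mutation
#' explanation of R sites.
#'
#' @param fam an `aligned_family`.
#' @param tree family tree with branch lengths (the fitted tree attached to
#'   `model` is used when present).
#' @param model a [substitution_model()] for the simulation null.
#' @param n_boot,n_sim bootstrap and simulation replicate counts.
#' @param seed master seed.
#' @return an object of class `family_excess_test` with observed counts,
#'   bootstrap 95% CIs, simulated distributions, and p-values for R and B
#'   sites; when the family has no informative sites the test is skipped
#'   (`skipped = TRUE`, p-values `NA`).
#' @export
excess_test <- function(fam, tree, model, n_boot = 100L, n_sim = 100L,
                        seed = 1L) {
  stopifnot(inherits(model, "substitution_model"))
  mat <- if (inherits(fam, "aligned_family")) fam$matrix else fam
  fam_id <- if (inherits(fam, "aligned_family")) fam$family_id else "family"
  qinfo <- family_quartets(tree, rownames(mat))
  im <- as_int_alignment(mat)
  obs <- .scan_core(im, qinfo)
  L <- ncol(mat)

  if (obs$informative_union == 0L) {
    return(structure(list(family_id = fam_id, skipped = TRUE,
                          observed_R = 0L, observed_B = 0L,
                          p_value = NA_real_, p_value_B = NA_real_),
                     class = "family_excess_test"))
  }

  boot <- with_seed(derive_seed(seed, 1L), {
    replicate(n_boot, {
      cols <- sample.int(L, L, replace = TRUE)
      c(R = sum(obs$Rany[cols]), B = sum(obs$Bany[cols]))
    })
  })
  boot_R <- boot["R", ]; boot_B <- boot["B", ]

  sim_tree <- attr(model, "fitted_tree") %||% tree
  spec <- simulation_spec(sim_tree, model, L, n_sim, derive_seed(seed, 2L))
  sim_R <- sim_B <- integer(n_sim)
  sim_frac_R <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    sm <- as_int_alignment(simulate_alignment(spec, i))
    sc <- .scan_core(sm[rownames(im), , drop = FALSE], qinfo)
    sim_R[i] <- sc$R_union; sim_B[i] <- sc$B_union
    sim_frac_R[i] <- if (sc$informative_union > 0)
      sc$R_union / sc$informative_union else 0
  }

  # seeded shuffles document the independence of the pairing
  ord_b <- with_seed(derive_seed(seed, 3L), sample.int(n_boot))
  ord_s <- with_seed(derive_seed(seed, 4L), sample.int(n_sim))
  np <- min(n_boot, n_sim)
  p_R <- mean(sim_R[ord_s][seq_len(np)] > boot_R[ord_b][seq_len(np)])
  p_B <- mean(sim_B[ord_s][seq_len(np)] > boot_B[ord_b][seq_len(np)])

  structure(list(
    family_id = fam_id, skipped = FALSE,
    observed_R = obs$R_union, observed_B = obs$B_union,
    informative_union = obs$informative_union,
    frac_R_columns = obs$R_union / obs$informative_union,
    boot_R = boot_R, boot_B = boot_B,
    ci_R = unname(stats::quantile(boot_R, c(0.025, 0.975))),
    sim_R = sim_R, sim_B = sim_B,
    expected_R = mean(sim_R), expected_B = mean(sim_B),
    expected_frac_R = mean(sim_frac_R),
    p_value = p_R, p_value_B = p_B
  ), class = "family_excess_test")
}

#' @export
print.family_excess_test <- function(x, ...) {
  if (isTRUE(x$skipped)) {
    cat("<family_excess_test>", x$family_id, "-- skipped (no informative sites)\n")
  } else {
    cat(sprintf("<family_excess_test> %s: R observed %d (95%% CI %.0f-%.0f), expected %.1f, p = %.2f\n",
                x$family_id, x$observed_R, x$ci_R[1], x$ci_R[2],
                x$expected_R, x$p_value))
  }
  invisible(x)
}

#' Wald-Wolfowitz runs test for clustering of reticulate sites
#'
#' Reticulate sites born of gene conversion tracks cluster along the alignment,
#' producing fewer C/R runs than expected under random interleaving. For small
#' samples (`n1 + n2 <= exact_max`) the one-sided p-value is computed from the
#' exact combinatorial runs distribution; otherwise from the normal
#' approximation with continuity correction.
#'
#' @param labels ordered character vector over `{"C","R"}` (alignment order).
#' @param exact_max largest `n1 + n2` for which the exact distribution is used.
#' @return an object of class `runs_test_result` with `n1`, `n2`, `runs`, `z`,
#'   and `p_one_sided` (probability of at most the observed number of runs,
#'   i.e. of under-dispersion at least this strong).
#' @export
runs_test <- function(labels, exact_max = 20L) {
  labels <- labels[labels %in% c("C", "R")]
  n1 <- sum(labels == "C"); n2 <- sum(labels == "R")
  if (n1 == 0L || n2 == 0L) stop("degenerate: runs test needs both C and R labels")
  robs <- length(rle(labels)$lengths)
  n <- n1 + n2
  e_runs <- 1 + 2 * n1 * n2 / n
  v_runs <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  z <- if (v_runs > 0) (robs - e_runs) / sqrt(v_runs) else 0
  if (n <= exact_max) {
    p <- sum(vapply(2:robs, function(r) .runs_pmf(r, n1, n2), numeric(1)))
  } else {
    p <- stats::pnorm((robs + 0.5 - e_runs) / sqrt(v_runs))
  }
  structure(list(n1 = n1, n2 = n2, runs = robs, expected_runs = e_runs,
                 z = z, p_one_sided = min(max(p, 0), 1),
                 exact = n <= exact_max),
            class = "runs_test_result")
}

# Exact probability of observing exactly r runs in a random arrangement of
# n1 + n2 binary labels.
.runs_pmf <- function(r, n1, n2) {
  tot <- choose(n1 + n2, n1)
  if (r %% 2 == 0) {
    k <- r / 2
    2 * choose(n1 - 1, k - 1) * choose(n2 - 1, k - 1) / tot
  } else {
    k <- (r - 1) / 2
    (choose(n1 - 1, k) * choose(n2 - 1, k - 1) +
       choose(n1 - 1, k - 1) * choose(n2 - 1, k)) / tot
  }
}

#' Spacing between runs of consecutive reticulate sites
#'
#' Identifies runs of two or more consecutive R sites in a quartet's
#' informative-site series and reports the fraction of such runs whose nearest
#' neighboring R-run lies more than `min_gap` alignment bp away. Complex
#' single-event mutational mechanisms act within ~10 bp, so widely separated
#' R-runs cannot be explained that way. A qualifying run with no other R-run in
#' the quartet has no neighbor and counts as separated.
#'
#' @param columns ordered alignment positions of the informative sites, or a
#'   `quartet_result` (in which case `labels` is ignored).
#' @param labels site classes (`"C"/"R"/"B"`) matching `columns`.
#' @param min_gap separation threshold in bp.
#' @return `list(fraction, n_runs, gaps)`; `fraction` is `NA` when no run of
#'   two or more consecutive R sites exists.
#' @export
r_run_spacing <- function(columns, labels = NULL, min_gap = 10) {
  if (inherits(columns, "quartet_result")) {
    labels <- columns$labels
    columns <- columns$columns
  }
  stopifnot(length(columns) == length(labels))
  keep <- labels %in% c("C", "R")   # the C/R series; B sites are transparent
  columns <- columns[keep]; labels <- labels[keep]
  isR <- labels == "R"
  rl <- rle(isR)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  rruns <- which(rl$values)
  if (!length(rruns)) return(list(fraction = NA_real_, n_runs = 0L, gaps = numeric(0)))
  run_start_col <- columns[starts[rruns]]
  run_end_col <- columns[ends[rruns]]
  qualifying <- which(rl$lengths[rruns] >= 2L)
  if (!length(qualifying)) return(list(fraction = NA_real_, n_runs = 0L, gaps = numeric(0)))
  gaps <- vapply(qualifying, function(i) {
    others <- setdiff(seq_along(rruns), i)
    if (!length(others)) return(Inf)
    min(abs(c(run_start_col[i] - run_end_col[others],
              run_start_col[others] - run_end_col[i])))
  }, numeric(1))
  list(fraction = mean(gaps > min_gap), n_runs = length(qualifying), gaps = gaps)
}
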