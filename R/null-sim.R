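#' Specification for a no-exchange simulation run
#'
#' Bundles the tree, substitution model, alignment length and replicate count
#' for null simulations. One hundred replicates per family is the standard used
#' for reticulate-site expectations.
#'
#' @param tree an `ape` `phylo` with branch lengths in substitutions/site.
#' @param model a [substitution_model()].
#' @param length number of alignment columns to simulate.
#' @param n_replicates number of independent replicate alignments.
#' @param seed master seed; replicate `i` uses stream `derive_seed(seed, i)`.
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(tree, model, length, n_replicates = 100L, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "substitution_model"),
            length > 0, n_replicates >= 1L)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  structure(list(tree = tree, model = model, length = as.integer(length),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a gapless alignment under GTR+Gamma+I with no interlocus exchange
#'
#' Evolves sites independently along the fixed tree: each site is invariant
#' with probability `p_inv`, otherwise assigned one of the discrete gamma rate
#' categories; the root state is drawn from the stationary frequencies and
#' propagated along each branch by the GTR transition probabilities. Because
#' paralogs never exchange sequence, the output is the null for reticulate-site
#' statistics. Rates are scaled so a branch length of `d` yields `d` expected
#' substitutions per site averaged over all sites (invariant sites included),
#' matching the convention of maximum-likelihood branch length estimates.
#'
#' @param spec a [simulation_spec()].
#' @param replicate_index which replicate stream to draw (1-based); the same
#'   `(seed, replicate_index)` always reproduces the same alignment.
#' @return character matrix (rows = tree leaves) over `A,C,G,T`.
#' @export
simulate_alignment <- function(spec, replicate_index = 1L) {
  stopifnot(inherits(spec, "simulation_spec"),
            replicate_index >= 1L, replicate_index <= spec$n_replicates)
  with_seed(derive_seed(spec$seed, replicate_index),
            sim_gtr_alignment(spec$tree, spec$model, spec$length))
}

# Workhorse: evolve `L` sites along `tree` under `model` using the current RNG.
sim_gtr_alignment <- function(tree, model, L) {
  k <- model$n_rate_classes
  grates <- discrete_gamma_rates(model$gamma_shape, k)
  # Scale so the overall mean rate (over invariant + variable sites) is 1.
  if (model$p_inv < 1) grates <- grates / (1 - model$p_inv)
  inv <- runif(L) < model$p_inv
  cat_of <- integer(L)                      # 0 = invariant
  cat_of[!inv] <- sample.int(k, sum(!inv), replace = TRUE)
  eig <- gtr_eigen(model)
  pi <- model$base_freqs

  nt <- length(tree$tip.label)
  nnode <- nt + tree$Nnode
  states <- matrix(0L, nnode, L)
  root <- nt + 1L
  states[root, ] <- sample.int(4L, L, replace = TRUE, prob = pi)

  edges <- ape::reorder.phylo(tree, "postorder")$edge
  elen <- ape::reorder.phylo(tree, "postorder")$edge.length
  # walk root-ward -> tip-ward
  for (e in rev(seq_len(nrow(edges)))) {
    par <- edges[e, 1L]; chi <- edges[e, 2L]
    ps <- states[par, ]
    cs <- ps                                 # invariant sites copy through
    for (cc in seq_len(k)) {
      idx <- which(cat_of == cc)
      if (!length(idx)) next
      P <- gtr_pmatrix(eig, elen[e], grates[cc])
      for (s in 1:4) {
        here <- idx[ps[idx] == s]
        if (length(here))
          cs[here] <- sample.int(4L, length(here), replace = TRUE, prob = P[s, ])
      }
    }
    states[chi, ] <- cs
  }
  out <- matrix(DNA[states[seq_len(nt), , drop = FALSE]], nrow = nt)
  rownames(out) <- tree$tip.label
  out
}

#' Write simulation replicates as multi-FASTA files
#' @param spec a [simulation_spec()].
#' @param dir output directory (created if needed).
#' @param indices replicate indices to write (default all).
#' @return paths written, invisibly.
#' @export
write_simulated_replicates <- function(spec, dir, indices = seq_len(spec$n_replicates)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(indices, function(i) {
    p <- file.path(dir, sprintf("replicate_%03d.fa", i))
    write_alignment_fasta(simulate_alignment(spec, i), p)
    p
  }, character(1))
  invisible(paths)
}
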