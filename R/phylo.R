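#' F84 maximum-likelihood distance between two aligned sequences
#'
#' @param a,b equal-length gap-free residue vectors (or single strings).
#' @return substitutions/site under the F84 model; `Inf` (with a warning) when
#'   the sequences are saturated and the distance is undefined.
#' @export
f84_distance <- function(a, b) {
  if (is.character(a) && length(a) == 1L && nchar(a) > 1L) a <- seq_to_chars(a)
  if (is.character(b) && length(b) == 1L && nchar(b) > 1L) b <- seq_to_chars(b)
  if (length(a) != length(b)) stop("sequences have unequal lengths")
  if (length(a) == 0L) stop("zero-length sequences")
  m <- rbind(a = toupper(a), b = toupper(b))
  d <- ape::dist.dna(ape::as.DNAbin(m), model = "F84")[1]
  if (!is.finite(d)) {
    warning("F84 distance undefined (saturation); returning Inf")
    return(Inf)
  }
  max(d, 0)
}

# F84 distance matrix for a gapless character matrix; NaN -> Inf
.f84_matrix <- function(mat) {
  d <- as.matrix(ape::dist.dna(ape::as.DNAbin(mat), model = "F84"))
  d[!is.finite(d)] <- Inf
  d
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the family tree by neighbor joining on F84 distances and attaches
#' bootstrap supports: the fraction of column-resampled replicates whose NJ
#' tree reproduces each internal bipartition.
#'
#' @param fam an `aligned_family` or gapless character matrix.
#' @param n_boot number of bootstrap replicates.
#' @param seed RNG seed controlling the column resampling.
#' @return an unrooted `phylo` whose `node.label` holds support fractions in
#'   `[0, 1]` (`NA` for the basal node's trivial split).
#' @export
build_nj_tree <- function(fam, n_boot = 100L, seed = 1L) {
  mat <- if (inherits(fam, "aligned_family")) fam$matrix else fam
  stopifnot(is.matrix(mat), nrow(mat) >= 4L)
  d <- .f84_matrix(mat)
  if (any(!is.finite(d))) {
    ij <- which(!is.finite(d), arr.ind = TRUE)[1, ]
    stop("infinite F84 distance between ", rownames(mat)[ij[1]], " and ",
         rownames(mat)[ij[2]])
  }
  tree <- ape::unroot(ape::nj(stats::as.dist(d)))
  boot <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
      db <- .f84_matrix(mat[, cols, drop = FALSE])
      # saturated replicate distances are capped rather than discarded
      if (any(!is.finite(db))) db[!is.finite(db)] <- 2 * max(db[is.finite(db)], 1)
      ape::unroot(ape::nj(stats::as.dist(db)))
    })
  })
  cnt <- ape::prop.clades(tree, boot, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  sup <- cnt / n_boot
  sup[1L] <- NA_real_   # basal node: trivial bipartition
  tree$node.label <- sup
  tree
}

# support values of the non-trivial internal nodes (named by node id)
.node_supports <- function(tree) {
  s <- as.numeric(tree$node.label)
  names(s) <- length(tree$tip.label) + seq_along(s)
  s[!is.na(s)]
}

#' Iteratively remove leaves under poorly supported nodes
#'
#' While any internal node has bootstrap support below `threshold`, one leaf
#' stemming from the worst-supported node is chosen at random and dropped, and
#' the tree is rebuilt on the reduced alignment. Families reduced below four
#' sequences are rejected ("low support"), removing trees whose topology — and
#' hence whose concordant/reticulate site classification — cannot be trusted.
#'
#' @param fam an `aligned_family`.
#' @param tree tree with supports from [build_nj_tree()] (rebuilt if `NULL`).
#' @param threshold minimum acceptable support fraction.
#' @param n_boot bootstrap replicates used on each rebuild.
#' @param seed RNG seed (leaf choice and resampling).
#' @return `list(fam, tree, dropped)` on success, else a `family_rejection`.
#' @export
prune_low_support <- function(fam, tree = NULL, threshold = 0.88,
                              n_boot = 100L, seed = 1L) {
  stopifnot(inherits(fam, "aligned_family"))
  if (is.null(tree)) tree <- build_nj_tree(fam, n_boot, derive_seed(seed, 1L))
  dropped <- character(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    sup <- .node_supports(tree)
    if (!length(sup) || min(sup) >= threshold)
      return(list(fam = fam, tree = tree, dropped = dropped))
    worst <- as.integer(names(sup)[which.min(sup)])
    tips <- phangorn::Descendants(tree, worst, type = "tips")[[1]]
    victim <- with_seed(derive_seed(seed, 1000L + iter),
                        sample(tree$tip.label[tips], 1L))
    dropped <- c(dropped, victim)
    fam <- subset_family(fam, setdiff(rownames(fam$matrix), victim))
    if (nrow(fam$matrix) < 4L)
      return(.reject(fam$family_id, "low support",
                     paste("dropped:", paste(dropped, collapse = ","))))
    tree <- build_nj_tree(fam, n_boot, derive_seed(seed, iter + 1L))
  }
}

#' Restrict an aligned family to a subset of its members
#' @param fam an `aligned_family`.
#' @param keep character vector of sequence names to keep.
#' @return the reduced `aligned_family`.
#' @export
subset_family <- function(fam, keep) {
  stopifnot(inherits(fam, "aligned_family"), all(keep %in% rownames(fam$matrix)))
  fam$matrix <- fam$matrix[keep, , drop = FALSE]
  fam$col_map <- fam$col_map[keep, , drop = FALSE]
  fam$members <- fam$members[match(keep, fam$members$seq_name), , drop = FALSE]
  fam$mean_identity <- mean_family_identity(fam$matrix)
  fam
}

#' Fit GTR+Gamma4+I by maximum likelihood on a fixed topology
#'
#' Base frequencies are the empirical counts; exchangeabilities, gamma shape,
#' invariant proportion and branch lengths are optimized numerically
#' (via `phangorn::optim.pml`) holding the topology fixed.
#'
#' @param fam an `aligned_family` (or gapless character matrix).
#' @param tree the family tree (topology is kept).
#' @param k number of gamma rate classes.
#' @return a [substitution_model()] with `log_lik` set; the re-estimated tree
#'   is attached as `attr(, "fitted_tree")`.
#' @export
fit_substitution_model <- function(fam, tree, k = 4L) {
  mat <- if (inherits(fam, "aligned_family")) fam$matrix else fam
  dat <- phangorn::phyDat(mat, type = "DNA")
  bf <- as.numeric(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(matrix_to_strings(mat)), collapse = TRUE
  )[DNA])
  bf <- bf / sum(bf)
  tree2 <- ape::unroot(tree)
  if (is.null(tree2$edge.length) || any(tree2$edge.length <= 0))
    tree2$edge.length <- pmax(tree2$edge.length %||% rep(0.01, nrow(tree2$edge)),
                              1e-6)
  fit <- phangorn::pml(tree2, dat, bf = bf, k = k, inv = 0.05, shape = 1)
  fit <- tryCatch(
    phangorn::optim.pml(fit, model = "GTR", optInv = TRUE, optGamma = TRUE,
                        optEdge = TRUE, optBf = FALSE,
                        control = phangorn::pml.control(trace = 0)),
    error = function(e) stop("model optimization failed: ", conditionMessage(e))
  )
  m <- substitution_model(rates = fit$Q, base_freqs = fit$bf,
                          gamma_shape = fit$shape, n_rate_classes = k,
                          p_inv = fit$inv, log_lik = as.numeric(fit$logLik))
  attr(m, "fitted_tree") <- fit$tree
  m
}

#' Quartet topology induced by a tree on four leaves
#'
#' @param tree a `phylo` containing all four leaves.
#' @param leaves ordered character vector of 4 tip labels `(A, B, C, D)`.
#' @return one of `"AB|CD"`, `"AC|BD"`, `"AD|BC"` — the bipartition of the four
#'   leaves induced by the tree's internal edges.
#' @export
induced_quartet_topology <- function(tree, leaves) {
  stopifnot(length(leaves) == 4L)
  if (!all(leaves %in% tree$tip.label))
    stop("leaf absent from tree: ",
         paste(setdiff(leaves, tree$tip.label), collapse = ","))
  tr <- ape::unroot(ape::keep.tip(tree, leaves))
  if (tr$Nnode < 2L) stop("quartet is unresolved (multifurcation)")
  # the two tips sharing a parent node form one side of the split
  tip_ids <- match(leaves, tr$tip.label)
  parents <- tr$edge[match(tip_ids, tr$edge[, 2L]), 1L]
  partner <- which(parents == parents[1L])[-1L]
  if (length(partner) != 1L) {
    # leaf A hangs alone off an internal node: its partner is the leaf NOT in
    # the cherry formed by the other three
    tab <- table(parents[-1L])
    cherry <- as.integer(names(tab)[tab == 2L])
    partner <- which(parents != cherry)[-1L]
  }
  c("AB|CD", "AC|BD", "AD|BC")[partner - 1L]
}

#' Read a Newick tree (supports as internal node labels)
#' @param path Newick file.
#' @return a `phylo`.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write a tree as Newick, carrying supports as node labels
#' @param tree a `phylo`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
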