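#' Specification for generating a synthetic paralog family
#'
#' Defaults emulate the profile of large human segmental-duplication families:
#' 4-16 paralogs, tens of kb of aligned sequence, mean pairwise identity
#' between 88% and 99.9%, GTR substitution with a transition bias, gamma rate
#' variation over four classes and a proportion of invariant sites.
#'
#' @param n_paralogs number of family members (4-16).
#' @param length alignment length in bp.
#' @param target_identity desired mean pairwise identity; the tree height is
#'   scaled analytically so the realized value matches within about one
#'   percentage point.
#' @param tree optional `phylo` (e.g. from [read_newick()]); by default a
#'   random birth-process tree over the paralogs is drawn.
#' @param model a [substitution_model()]; the default uses mildly AT-rich base
#'   frequencies, a 4x transition bias, gamma shape 1 and 20% invariant sites.
#' @param cpg_boost optional multiplier (> 1) adding post-hoc hypermutation at
#'   CpG contexts, the dominant real-data source of coincident parallel
#'   substitutions.
#' @param seed mandatory integer seed; generation is fully deterministic.
#' @return an object of class `family_gen_spec`.
#' @export
family_gen_spec <- function(n_paralogs = 6L, length = 18800L,
                            target_identity = 0.958, tree = NULL,
                            model = NULL, cpg_boost = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory for synthetic generation")
  stopifnot(n_paralogs >= 4L, n_paralogs <= 16L, length > 0,
            target_identity > 0.5, target_identity < 1)
  if (is.null(model))
    model <- substitution_model(rates = c(1, 4, 1, 1, 4, 1),
                                base_freqs = c(0.295, 0.205, 0.205, 0.295),
                                gamma_shape = 1, n_rate_classes = 4L,
                                p_inv = 0.2)
  if (!is.null(tree)) stopifnot(inherits(tree, "phylo"),
                                length(tree$tip.label) == n_paralogs)
  structure(list(n_paralogs = as.integer(n_paralogs),
                 length = as.integer(length),
                 target_identity = target_identity, tree = tree,
                 model = model, cpg_boost = cpg_boost,
                 seed = as.integer(seed)),
            class = "family_gen_spec")
}

# Expected identity between two sequences at model distance D (subs/site):
# invariant sites always match; variable sites match per the GTR transition
# probabilities averaged over gamma classes.
.expected_identity <- function(D, model) {
  eig <- gtr_eigen(model)
  gr <- discrete_gamma_rates(model$gamma_shape, model$n_rate_classes)
  if (model$p_inv < 1) gr <- gr / (1 - model$p_inv)
  pi <- model$base_freqs
  vapply(D, function(d) {
    m <- mean(vapply(gr, function(r) sum(pi * diag(gtr_pmatrix(eig, d, r))),
                     numeric(1)))
    model$p_inv + (1 - model$p_inv) * m
  }, numeric(1))
}

# Scale a tree's branch lengths so mean pairwise identity hits the target.
.scale_tree_to_identity <- function(tree, model, target) {
  D <- ape::cophenetic.phylo(tree)
  D <- D[upper.tri(D)]
  f <- function(s) mean(.expected_identity(s * D, model)) - target
  lo <- 1e-6; hi <- 1
  while (f(hi) > 0 && hi < 1e4) hi <- hi * 4
  if (f(hi) > 0) stop("identity target unattainable: tree cannot be made divergent enough")
  if (f(lo) < 0) stop("identity target unattainable: residual divergence at zero height")
  s <- stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
  tree$edge.length <- tree$edge.length * s
  tree
}

# empty ground-truth event table
empty_truth <- function() {
  data.frame(kind = character(0), donor = character(0),
             acceptor = character(0), start = integer(0), stop = integer(0),
             generation = integer(0), stringsAsFactors = FALSE)
}

#' Generate a null paralog family (no interlocus exchange)
#'
#' Draws (or accepts) a family tree, scales its height analytically so the
#' expected mean pairwise identity equals the target, simulates the alignment
#' under the GTR+Gamma+I model, and assigns toy genomic loci (one chromosome,
#' members laid end to end with spacing). The truth set is empty by
#' construction.
#'
#' @param spec a [family_gen_spec()].
#' @param family_id identifier for the generated family.
#' @return `list(fam, tree, truth)`: an `aligned_family`, the scaled `phylo`,
#'   and an empty truth table.
#' @export
generate_null_family <- function(spec, family_id = "synth1") {
  stopifnot(inherits(spec, "family_gen_spec"))
  with_seed(derive_seed(spec$seed, 1L), {
    tree <- spec$tree
    if (is.null(tree)) tree <- ape::rtree(spec$n_paralogs,
                                          tip.label = paste0(family_id, "_p",
                                                             seq_len(spec$n_paralogs)))
    tree <- .scale_tree_to_identity(tree, spec$model, spec$target_identity)
    mat <- sim_gtr_alignment(tree, spec$model, spec$length)
    if (!is.null(spec$cpg_boost) && spec$cpg_boost > 1)
      mat <- .apply_cpg_hypermutation(mat, spec$cpg_boost, tree)
    members <- data.frame(
      family_id = family_id, seq_name = rownames(mat), chrom = "chr1",
      start = (seq_len(nrow(mat)) - 1L) * (spec$length + 10000L),
      stringsAsFactors = FALSE)
    members$end <- members$start + spec$length
    members$strand <- "+"
    fam <- new_aligned_family(family_id, mat, members)
    list(fam = fam, tree = tree, truth = empty_truth())
  })
}

# Post-hoc CpG hypermutation: each sequence independently receives extra
# C->T / G->A transitions at its CpG dinucleotides, at a probability scaled
# by (boost - 1) and the tree height. Independent hits at shared CpG contexts
# create clustered bimutational columns, which strip_cpg removes.
.apply_cpg_hypermutation <- function(mat, boost, tree) {
  height <- max(ape::cophenetic.phylo(tree)) / 2
  p_extra <- min(0.9, (boost - 1) * height)
  L <- ncol(mat)
  for (i in seq_len(nrow(mat))) {
    cg <- which(mat[i, -L] == "C" & mat[i, -1] == "G")
    if (!length(cg)) next
    hitC <- cg[runif(length(cg)) < p_extra]
    hitG <- cg[runif(length(cg)) < p_extra] + 1L
    mat[i, hitC] <- "T"
    mat[i, hitG] <- "A"
  }
  mat
}

#' Inject an interlocus gene conversion event
#'
#' Copies the donor's residues over the acceptor's on the alignment interval
#' `[start, stop]`, leaving every other position untouched, and appends the
#' event to the truth set. Operating on aligned coordinates after simulation
#' keeps the truth interval exact.
#'
#' @param fam an `aligned_family`.
#' @param donor,acceptor member names (must differ).
#' @param start,stop alignment columns (1-based inclusive).
#' @param truth an existing truth table to append to.
#' @return `list(fam, truth)` with the modified family and updated truth.
#' @export
inject_gene_conversion <- function(fam, donor, acceptor, start, stop,
                                   truth = empty_truth()) {
  stopifnot(inherits(fam, "aligned_family"), donor != acceptor,
            donor %in% rownames(fam$matrix), acceptor %in% rownames(fam$matrix))
  if (start < 1L || stop > fam$length || start > stop)
    stop("conversion interval out of alignment bounds")
  fam$matrix[acceptor, start:stop] <- fam$matrix[donor, start:stop]
  fam$mean_identity <- mean_family_identity(fam$matrix)
  truth <- rbind(truth, data.frame(kind = "igc", donor = donor,
                                   acceptor = acceptor, start = as.integer(start),
                                   stop = as.integer(stop),
                                   generation = NA_integer_,
                                   stringsAsFactors = FALSE))
  list(fam = fam, truth = truth)
}

#' Inject a non-allelic crossover
#'
#' Swaps the two sequences' suffixes from the column after `breakpoint` to the
#' end of the alignment — the single-breakpoint signature of an ectopic
#' crossover. Applying the same crossover twice restores the original family.
#'
#' @param fam an `aligned_family`.
#' @param pair character vector of two member names.
#' @param breakpoint interior column: columns `> breakpoint` are exchanged
#'   (`1 <= breakpoint < alignment length`).
#' @param truth truth table to append to.
#' @return `list(fam, truth)`.
#' @export
inject_crossover <- function(fam, pair, breakpoint, truth = empty_truth()) {
  stopifnot(inherits(fam, "aligned_family"), length(pair) == 2L,
            all(pair %in% rownames(fam$matrix)))
  if (breakpoint < 1L || breakpoint >= fam$length)
    stop("breakpoint must be interior to the alignment")
  cols <- (breakpoint + 1L):fam$length
  tmp <- fam$matrix[pair[1L], cols]
  fam$matrix[pair[1L], cols] <- fam$matrix[pair[2L], cols]
  fam$matrix[pair[2L], cols] <- tmp
  fam$mean_identity <- mean_family_identity(fam$matrix)
  truth <- rbind(truth, data.frame(kind = "crossover", donor = pair[1L],
                                   acceptor = pair[2L],
                                   start = as.integer(breakpoint),
                                   stop = as.integer(fam$length),
                                   generation = NA_integer_,
                                   stringsAsFactors = FALSE))
  list(fam = fam, truth = truth)
}

#' Evolve a family to conversion-mutation equilibrium
#'
#' Forward simulator interleaving point mutation and single-site interlocus
#' conversion across generations, used to validate the equilibrium rate
#' estimator on data generated under its own assumptions. Each site of each
#' paralog mutates with probability `mu` per generation (to a uniformly chosen
#' different base) and is overwritten by the homologous site of a uniformly
#' chosen other paralog with per-generation probability `c_rate / 2` (the
#' estimator's rate scale counts both directions of exchange between a pair;
#' see the package vignette for the balance derivation). At equilibrium the
#' mean pairwise divergence satisfies `d = 2 mu (n - 1) / c_rate`.
#'
#' @param n_paralogs family size.
#' @param length sequence length (bp).
#' @param mu per-site per-generation mutation probability (scaled up from
#'   realistic values so equilibrium is reached in a tractable number of
#'   generations; only the ratio `mu / c_rate` matters for the equilibrium).
#' @param c_rate true pairwise conversion rate on the estimator's scale.
#' @param n_generations generations to run (default: ten relaxation times).
#' @param seed RNG seed.
#' @return `list(fam, d_hat, truth)`: the final `aligned_family`, the realized
#'   mean pairwise divergence (averaged over the final quarter of the run),
#'   and a truth table whose `generation` column logs conversion events from
#'   the last generation only (the full event stream is not retained).
#' @export
evolve_family_igc <- function(n_paralogs = 4L, length = 2000L, mu = 2e-4,
                              c_rate, n_generations = NULL, seed = 1L) {
  stopifnot(n_paralogs >= 2L, c_rate > 0, mu > 0)
  g <- c_rate / 2                      # per-copy per-site acceptor probability
  relax <- (n_paralogs - 1) / (2 * g)  # pair homogenization time scale
  if (is.null(n_generations)) n_generations <- as.integer(ceiling(10 * relax))
  with_seed(seed, {
    n <- n_paralogs; L <- length
    mat <- matrix(sample.int(4L, L, replace = TRUE), n, L, byrow = TRUE)
    d_samples <- numeric(0)
    sample_from <- ceiling(0.75 * n_generations)
    for (gen in seq_len(n_generations)) {
      # point mutation
      hits <- which(runif(n * L) < mu)
      if (length(hits))
        mat[hits] <- 1L + (mat[hits] - 1L + sample.int(3L, length(hits),
                                                       replace = TRUE)) %% 4L
      # single-site conversion (synchronous, from pre-conversion state)
      cmask <- which(runif(n * L) < g)
      if (length(cmask)) {
        old <- mat
        row_i <- (cmask - 1L) %% n + 1L
        col_j <- (cmask - 1L) %/% n + 1L
        donor <- 1L + (row_i - 1L + sample.int(n - 1L, length(cmask),
                                               replace = TRUE)) %% n
        mat[cbind(row_i, col_j)] <- old[cbind(donor, col_j)]
      }
      if (gen >= sample_from && gen %% 10L == 0L) {
        dd <- 0; np <- 0L
        for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
          dd <- dd + mean(mat[i, ] != mat[j, ]); np <- np + 1L
        }
        d_samples <- c(d_samples, dd / np)
      }
    }
    cm <- matrix(DNA[mat], n, L)
    rownames(cm) <- paste0("p", seq_len(n))
    members <- data.frame(family_id = "equilibrium", seq_name = rownames(cm),
                          chrom = "chr1",
                          start = (seq_len(n) - 1L) * (L + 1000L),
                          stringsAsFactors = FALSE)
    members$end <- members$start + L
    members$strand <- "+"
    fam <- new_aligned_family("equilibrium", cm, members)
    list(fam = fam, d_hat = mean(d_samples), truth = empty_truth())
  })
}

#' Build a toy genome fixture around synthetic families
#'
#' Lays family members onto a small set of toy chromosomes (non-overlapping
#' placements, random chromosome choice), generates chromosome background
#' sequence with the member sequences written in at their loci, plants PRDM9
#' motifs at recorded positions, and emits pericentromeric/subtelomeric zones
#' plus random gene/CDS/pseudogene/repeat annotation intervals.
#'
#' @param families list of `aligned_family` objects (or `generate_null_family`
#'   outputs; the `fam` element is used).
#' @param n_chrom number of toy chromosomes.
#' @param zone_frac fraction of each chromosome inside the pericentromeric
#'   zone (centered) and, split across both ends, the subtelomeric zones.
#' @param n_motifs number of PRDM9 motif instances to plant genome-wide.
#' @param n_annotation intervals per annotation class per chromosome.
#' @param spacing_bp gap between consecutive placements on a chromosome.
#' @param seed RNG seed.
#' @return object of class `genome_fixture`: relocated `families`,
#'   `chrom_lengths`, `chrom_seqs`, `zones` (list of `GRanges`),
#'   `annotations` (list of `GRanges`), `motif_positions`, `placements`.
#' @export
build_genome_fixture <- function(families, n_chrom = 2L, zone_frac = 0.1,
                                 n_motifs = 25L, n_annotation = 8L,
                                 spacing_bp = 5000L, seed = 1L) {
  families <- lapply(families, function(f) if (inherits(f, "aligned_family")) f else f$fam)
  with_seed(seed, {
    # chromosome lengths sized to fit all members with headroom
    total_bp <- sum(vapply(families, function(f) nrow(f$matrix) * (f$length + spacing_bp),
                           numeric(1)))
    chrom_len <- as.integer(ceiling(2.5 * total_bp / n_chrom) + 50000L)
    chroms <- paste0("chr", seq_len(n_chrom))
    cursor <- stats::setNames(rep(1000L, n_chrom), chroms)

    placements <- list()
    for (fi in seq_along(families)) {
      f <- families[[fi]]
      mem <- f$members
      for (i in seq_len(nrow(mem))) {
        ch <- sample(chroms, 1L)
        start <- cursor[ch] + sample.int(spacing_bp, 1L)
        if (start + f$length > chrom_len)
          stop("layout overflow: chromosome ", ch, " cannot fit all members")
        mem$chrom[i] <- ch
        mem$start[i] <- start
        mem$end[i] <- start + f$length
        mem$strand[i] <- "+"
        cursor[ch] <- mem$end[i]
        placements[[length(placements) + 1L]] <- data.frame(
          family_id = f$family_id, seq_name = mem$seq_name[i], chrom = ch,
          start = mem$start[i], end = mem$end[i], stringsAsFactors = FALSE)
      }
      families[[fi]] <- new_aligned_family(f$family_id, f$matrix, mem)
    }
    placements <- do.call(rbind, placements)

    chrom_seqs <- stats::setNames(vapply(chroms, function(ch)
      chars_to_seq(sample(DNA, chrom_len, replace = TRUE)), character(1)), chroms)
    # write member sequences into their loci
    for (f in families) {
      for (i in seq_len(nrow(f$members))) {
        ch <- f$members$chrom[i]
        s <- f$members$start[i]
        substr(chrom_seqs[[ch]], s + 1L, s + f$length) <-
          chars_to_seq(f$matrix[i, ])
      }
    }
    # plant PRDM9 motifs at random positions (may land anywhere, including
    # inside placements; positions recorded)
    motif_rows <- list()
    for (m in seq_len(n_motifs)) {
      ch <- sample(chroms, 1L)
      pos <- sample.int(chrom_len - 13L, 1L)
      inst <- chars_to_seq(ifelse(seq_to_chars("CCnCCnTnnCCnC") == "n",
                                  sample(DNA, 13L, replace = TRUE),
                                  seq_to_chars("CCNCCNTNNCCNC")))
      substr(chrom_seqs[[ch]], pos, pos + 12L) <- inst
      motif_rows[[m]] <- data.frame(chrom = ch, start = pos - 1L,
                                    end = pos + 12L, stringsAsFactors = FALSE)
    }
    motif_positions <- do.call(rbind, motif_rows)

    half_zone <- round(zone_frac * chrom_len / 2)
    sinfo <- GenomeInfoDb::Seqinfo(seqnames = chroms,
                                   seqlengths = rep(chrom_len, n_chrom))
    zones <- list(
      pericentromeric = GenomicRanges::GRanges(chroms, IRanges::IRanges(
        round(chrom_len / 2) - half_zone, round(chrom_len / 2) + half_zone),
        seqinfo = sinfo),
      subtelomeric = GenomicRanges::GRanges(
        rep(chroms, 2),
        IRanges::IRanges(c(rep(1L, n_chrom), rep(chrom_len - half_zone, n_chrom)),
                         c(rep(half_zone, n_chrom), rep(chrom_len, n_chrom))),
        seqinfo = sinfo)
    )
    rand_iv <- function(w_min, w_max) {
      ch <- rep(chroms, each = n_annotation)
      w <- sample(w_min:w_max, length(ch), replace = TRUE)
      s <- sample.int(chrom_len - w_max, length(ch), replace = TRUE)
      GenomicRanges::GRanges(ch, IRanges::IRanges(s, s + w), seqinfo = sinfo)
    }
    annotations <- list(gene = rand_iv(2000L, 10000L),
                        cds = rand_iv(200L, 1000L),
                        pseudogene = rand_iv(1000L, 5000L),
                        SINE = rand_iv(100L, 300L),
                        LINE = rand_iv(500L, 6000L))
    structure(list(families = families, chrom_lengths =
                     stats::setNames(rep(chrom_len, n_chrom), chroms),
                   chrom_seqs = chrom_seqs, zones = zones,
                   annotations = annotations,
                   motif_positions = motif_positions,
                   placements = placements),
              class = "genome_fixture")
  })
}

#' Write a genome fixture's interval sets as BED files
#' @param fixture a `genome_fixture`.
#' @param dir output directory.
#' @return named vector of paths, invisibly.
#' @export
write_fixture_beds <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sets <- c(fixture$zones, fixture$annotations)
  paths <- vapply(names(sets), function(nm) {
    p <- file.path(dir, paste0(nm, ".bed"))
    rtracklayer::export(sets[[nm]], p, format = "BED")
    p
  }, character(1))
  invisible(paths)
}
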