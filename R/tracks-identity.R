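#' Polymorphic columns of a family alignment
#' @param mat gapless character matrix or `aligned_family`.
#' @return integer vector of columns at which members differ.
#' @export
polymorphic_columns <- function(mat) {
  if (inherits(mat, "aligned_family")) mat <- mat$matrix
  which(vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    length(unique(col)) > 1L
  }, logical(1)))
}

# faster path used internally: compare all rows to row 1
.poly_cols <- function(mat) {
  same <- rep(TRUE, ncol(mat))
  for (i in 2:nrow(mat)) same <- same & (mat[i, ] == mat[1L, ])
  which(!same)
}

#' Configuration for the identity-fragment permutation test
#'
#' @param n_perm number of random permutations of the polymorphic-column
#'   order (>= 100).
#' @param alpha significance threshold on the global or pairwise p-value.
#' @param seed RNG seed for the permutation stream.
#' @return an object of class `permutation_config`.
#' @export
permutation_config <- function(n_perm = 10000L, alpha = 0.05, seed = 1L) {
  stopifnot(n_perm >= 100L, alpha > 0, alpha < 1)
  structure(list(n_perm = as.integer(n_perm), alpha = alpha,
                 seed = as.integer(seed)),
            class = "permutation_config")
}

# all unordered pairs of row indices
.pair_index <- function(n) t(utils::combn(n, 2L))

# n_pairs x n_poly 0/1 identity matrix over the polymorphic columns
.pair_identity_matrix <- function(mat, poly) {
  pairs <- .pair_index(nrow(mat))
  B <- matrix(0L, nrow(pairs), length(poly))
  for (p in seq_len(nrow(pairs)))
    B[p, ] <- as.integer(mat[pairs[p, 1L], poly] == mat[pairs[p, 2L], poly])
  list(B = B, pairs = pairs)
}

#' Candidate perfect-identity fragments for one sequence pair
#'
#' Over the ordered polymorphic columns of the family, maximal runs at which
#' the pair is identical are candidate conversion fragments; the score of a
#' fragment is the number of polymorphic sites it spans. Monomorphic columns
#' carry no information about the pair and are ignored (the scan conditions on
#' the observed pattern of variable sites).
#'
#' @param fam an `aligned_family` or gapless character matrix.
#' @param pair character vector of two member names (or 2 row indices).
#' @return data frame with one row per fragment: `first_poly`, `last_poly`
#'   (indices into the polymorphic-site list), `start`, `stop` (alignment bp of
#'   the outermost spanned polymorphic columns), `n_poly_spanned`.
#' @export
score_pair_fragments <- function(fam, pair) {
  mat <- if (inherits(fam, "aligned_family")) fam$matrix else fam
  if (is.character(pair)) pair <- match(pair, rownames(mat))
  stopifnot(length(pair) == 2L, !anyNA(pair))
  poly <- .poly_cols(mat)
  if (length(poly) < 2L) {
    message("alignment is (nearly) monomorphic; no fragments scored")
    return(data.frame(first_poly = integer(0), last_poly = integer(0),
                      start = integer(0), stop = integer(0),
                      n_poly_spanned = integer(0)))
  }
  b <- mat[pair[1L], poly] == mat[pair[2L], poly]
  rl <- rle(b)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  keep <- which(rl$values)
  data.frame(first_poly = starts[keep], last_poly = ends[keep],
             start = poly[starts[keep]], stop = poly[ends[keep]],
             n_poly_spanned = rl$lengths[keep])
}

#' Permutation p-values for identity fragments
#'
#' The null preserves each pair's set of matches/mismatches at polymorphic
#' sites but randomizes the column order (one shared permutation per replicate
#' across all pairs). For a fragment of score `s`:
#' `p_global` is the fraction of permutations in which any pair attains a
#' maximal fragment score at least `s` (alignment-wide multiplicity);
#' `p_pairwise` is the same restricted to the fragment's own pair, Bonferroni
#' multiplied by the number of pairs. Ties count toward the null (conservative)
#' and the p-value granularity is `1/n_perm`.
#'
#' @param fam an `aligned_family` or gapless character matrix.
#' @param cfg a [permutation_config()].
#' @return object of class `identity_scan`: data frame `fragments` (all pairs,
#'   with `seq1`, `seq2`, coordinates, scores, `p_global`, `p_pairwise`) plus
#'   the permutation null summaries.
#' @export
permutation_test <- function(fam, cfg = permutation_config()) {
  mat <- if (inherits(fam, "aligned_family")) fam$matrix else fam
  fam_id <- if (inherits(fam, "aligned_family")) fam$family_id else "family"
  poly <- .poly_cols(mat)
  if (length(poly) < 2L) {
    return(structure(list(family_id = fam_id,
                          fragments = data.frame(), n_poly = length(poly),
                          n_perm = cfg$n_perm),
                     class = "identity_scan"))
  }
  pim <- .pair_identity_matrix(mat, poly)
  n_pairs <- nrow(pim$pairs)
  if (cfg$n_perm * 0.05 < 1)
    warning("n_perm too small to resolve alpha = 0.05")
  maxmat <- with_seed(cfg$seed, perm_max_runs(pim$B, cfg$n_perm))
  global_max <- apply(maxmat, 1L, max)

  # observed fragments for every pair
  frags <- lapply(seq_len(n_pairs), function(p) {
    b <- pim$B[p, ] == 1L
    rl <- rle(b)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- which(rl$values)
    if (!length(keep)) return(NULL)
    data.frame(pair = p,
               seq1 = rownames(mat)[pim$pairs[p, 1L]],
               seq2 = rownames(mat)[pim$pairs[p, 2L]],
               first_poly = starts[keep], last_poly = ends[keep],
               start = poly[starts[keep]], stop = poly[ends[keep]],
               n_poly_spanned = rl$lengths[keep],
               stringsAsFactors = FALSE)
  })
  frags <- do.call(rbind, frags)
  if (is.null(frags) || !nrow(frags)) {
    return(structure(list(family_id = fam_id, fragments = data.frame(),
                          n_poly = length(poly), n_perm = cfg$n_perm),
                     class = "identity_scan"))
  }
  # upper-tail lookup tables: P(max run >= s) over permutations
  S <- max(global_max, frags$n_poly_spanned)
  tail_global <- rev(cumsum(rev(tabulate(global_max, nbins = S)))) / cfg$n_perm
  tail_pair <- apply(maxmat, 2L, function(v)
    rev(cumsum(rev(tabulate(v, nbins = S)))) / cfg$n_perm)
  s <- frags$n_poly_spanned
  frags$p_global <- tail_global[s]
  frags$p_pairwise <- pmin(1, n_pairs * tail_pair[cbind(s, frags$pair)])
  structure(list(family_id = fam_id, fragments = frags,
                 n_poly = length(poly), n_pairs = n_pairs,
                 n_perm = cfg$n_perm, global_max = global_max),
            class = "identity_scan")
}

#' @export
print.identity_scan <- function(x, ...) {
  cat(sprintf("<identity_scan> %s: %d polymorphic sites, %d fragments (%d permutations)\n",
              x$family_id, x$n_poly,
              if (is.null(x$fragments)) 0L else nrow(x$fragments), x$n_perm))
  invisible(x)
}

#' Call significant perfect-identity conversion tracks
#'
#' Runs [permutation_test()] and retains fragments whose global or pairwise
#' p-value falls below `cfg$alpha`; retained tracks are mapped to genome
#' coordinates for both members of the pair.
#'
#' @param fam an `aligned_family`.
#' @param cfg a [permutation_config()].
#' @return data frame of class `fragment_calls`: one row per significant
#'   fragment with alignment coordinates, scores, p-values and, when the
#'   family carries locus metadata, `chrom1/gstart1/gend1` and
#'   `chrom2/gstart2/gend2` genome intervals (0-based half-open).
#' @export
call_identity_tracks <- function(fam, cfg = permutation_config()) {
  scan <- permutation_test(fam, cfg)
  fr <- scan$fragments
  empty <- structure(data.frame(), class = c("fragment_calls", "data.frame"))
  if (is.null(fr) || !nrow(fr)) return(empty)
  sig <- fr[fr$p_global < cfg$alpha | fr$p_pairwise < cfg$alpha, , drop = FALSE]
  if (!nrow(sig)) return(empty)
  sig$family_id <- scan$family_id
  if (inherits(fam, "aligned_family")) {
    g1 <- lapply(seq_len(nrow(sig)), function(i)
      map_to_genome(fam, sig$seq1[i], sig$start[i], sig$stop[i]))
    g2 <- lapply(seq_len(nrow(sig)), function(i)
      map_to_genome(fam, sig$seq2[i], sig$start[i], sig$stop[i]))
    sig$chrom1 <- vapply(g1, `[[`, character(1), "chrom")
    sig$gstart1 <- vapply(g1, `[[`, numeric(1), "start")
    sig$gend1 <- vapply(g1, `[[`, numeric(1), "end")
    sig$chrom2 <- vapply(g2, `[[`, character(1), "chrom")
    sig$gstart2 <- vapply(g2, `[[`, numeric(1), "start")
    sig$gend2 <- vapply(g2, `[[`, numeric(1), "end")
  }
  rownames(sig) <- NULL
  structure(sig, class = c("fragment_calls", "data.frame"))
}

#' Collapse overlapping track calls into unique genomic tracks
#'
#' Nested and redundant duplication families report the same conversion event
#' at the same genomic coordinates; counting those repeatedly would double
#' count any overlapping features. Both members' genome intervals of every
#' call are pooled per chromosome and merged into a set of disjoint intervals,
#' each linked back to its supporting calls.
#'
#' @param calls a `fragment_calls` data frame (possibly row-bound across
#'   families).
#' @return list with `tracks` (a `GRanges` of disjoint unique tracks, metadata
#'   column `n_support` = number of supporting call intervals) and
#'   `alignment_only` (calls lacking genome coordinates, kept separately).
#' @export
deduplicate_tracks <- function(calls) {
  if (is.null(calls) || !nrow(calls))
    return(list(tracks = GenomicRanges::GRanges(), alignment_only = calls))
  has_coords <- !is.null(calls$chrom1) && !is.null(calls$chrom2)
  if (!has_coords)
    return(list(tracks = GenomicRanges::GRanges(), alignment_only = calls))
  ok <- !is.na(calls$chrom1) & !is.na(calls$chrom2)
  iv <- rbind(
    data.frame(chrom = calls$chrom1[ok], start = calls$gstart1[ok],
               end = calls$gend1[ok], call = which(ok)),
    data.frame(chrom = calls$chrom2[ok], start = calls$gstart2[ok],
               end = calls$gend2[ok], call = which(ok))
  )
  gr <- GenomicRanges::GRanges(iv$chrom,
                               IRanges::IRanges(iv$start + 1L, iv$end))
  merged <- GenomicRanges::reduce(gr)
  hits <- GenomicRanges::findOverlaps(merged, gr)
  merged$n_support <- tabulate(S4Vectors::queryHits(hits), length(merged))
  merged$support_calls <- S4Vectors::splitAsList(
    iv$call[S4Vectors::subjectHits(hits)],
    factor(S4Vectors::queryHits(hits), levels = seq_along(merged)))
  list(tracks = merged, alignment_only = calls[!ok, , drop = FALSE])
}
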