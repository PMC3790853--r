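#' Per-quartet null expectations for site-class counts
#'
#' Simulates `n_sim` no-exchange alignments under the fitted model and returns
#' the mean C/R/B counts per quartet — the simulated B-site expectation gates
#' which quartets are clean enough for track estimation.
#'
#' @param fam an `aligned_family` (supplies members and length).
#' @param tree family tree with branch lengths.
#' @param model a [substitution_model()].
#' @param n_sim simulation replicates.
#' @param seed master seed.
#' @return numeric matrix (`n_quartets` x 3, columns C/R/B) of mean counts.
#' @export
quartet_null_expectations <- function(fam, tree, model, n_sim = 100L, seed = 1L) {
  mat <- if (inherits(fam, "aligned_family")) fam$matrix else fam
  qinfo <- family_quartets(tree, rownames(mat))
  sim_tree <- attr(model, "fitted_tree") %||% tree
  spec <- simulation_spec(sim_tree, model, ncol(mat), n_sim, seed)
  acc <- matrix(0, nrow(qinfo$idx), 3L, dimnames = list(NULL, c("C", "R", "B")))
  for (i in seq_len(n_sim)) {
    sm <- as_int_alignment(simulate_alignment(spec, i))
    acc <- acc + .scan_core(sm[rownames(mat), , drop = FALSE], qinfo)$counts
  }
  acc / n_sim
}

#' Select quartets eligible for track and breakpoint estimation
#'
#' Retains quartets in which simulations predict fewer than `max_expected_B`
#' bimutational sites while more than `min_observed_R` reticulate sites are
#' observed: with few B sites expected, parallel mutation cannot explain the
#' R sites, which can then be read as exchange tracks.
#'
#' @param scan a `family_scan` from [scan_family()].
#' @param expected_B per-quartet simulated B-site expectations (e.g. column
#'   `"B"` of [quartet_null_expectations()]).
#' @param max_expected_B strict upper bound on expected B sites.
#' @param min_observed_R strict lower bound on observed R sites.
#' @return integer indices of eligible quartets in `scan$quartets`.
#' @export
select_informative_quartets <- function(scan, expected_B, max_expected_B = 5,
                                        min_observed_R = 5) {
  stopifnot(inherits(scan, "family_scan"),
            length(expected_B) == length(scan$quartets))
  n_R <- vapply(scan$quartets, function(q) q$n_R, numeric(1))
  which(expected_B < max_expected_B & n_R > min_observed_R)
}

# C/R site series of a quartet (B sites are transparent for track geometry)
.cr_series <- function(q) {
  keep <- q$labels %in% c("C", "R")
  list(columns = q$columns[keep], labels = q$labels[keep],
       alt = q$alt[keep])
}

# maximal runs of consecutive R sites sharing one alternative topology
.r_clusters <- function(series) {
  n <- length(series$labels)
  if (!n) return(NULL)
  key <- ifelse(series$labels == "R", series$alt, "C")
  rl <- rle(key)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  keep <- which(rl$values != "C")
  if (!length(keep)) return(NULL)
  data.frame(first = starts[keep], last = ends[keep],
             alt = rl$values[keep], n_R = rl$lengths[keep],
             stringsAsFactors = FALSE)
}

#' Call gene conversion tracks from reticulate-site clusters
#'
#' Each maximal run of consecutive R sites sharing one alternative topology is
#' a putative conversion track. The most probable track boundaries are the
#' midpoints between the outermost R sites of the cluster and the flanking C
#' site on each side; clusters touching the ends of the informative-site range
#' use the alignment boundary as the flank. Alignment coordinates are 1-based.
#'
#' @param q a `quartet_result` (from [scan_family()]).
#' @param alignment_length total alignment columns (for boundary flanks).
#' @param family_id family identifier carried into the call table.
#' @return data frame of class `quartet_track_calls`: one row per track with
#'   `start`, `stop` (possibly half-integer midpoints), `length`,
#'   `n_R_support`, `alt_topology`, `kind = "conversion"`, `first_R`/`last_R`
#'   columns. Empty when the quartet has no R sites.
#' @export
call_conversion_tracks <- function(q, alignment_length, family_id = "family") {
  ser <- .cr_series(q)
  cl <- .r_clusters(ser)
  empty <- data.frame(family_id = character(0), leaves = character(0),
                      start = numeric(0), stop = numeric(0), length = numeric(0),
                      n_R_support = integer(0), alt_topology = character(0),
                      kind = character(0), first_R = numeric(0), last_R = numeric(0))
  if (is.null(cl)) return(structure(empty, class = c("quartet_track_calls", "data.frame")))
  isC <- ser$labels == "C"
  calls <- lapply(seq_len(nrow(cl)), function(i) {
    firstR <- ser$columns[cl$first[i]]
    lastR <- ser$columns[cl$last[i]]
    before <- which(isC & seq_along(isC) < cl$first[i])
    after <- which(isC & seq_along(isC) > cl$last[i])
    left <- if (length(before)) ser$columns[max(before)] else 1
    right <- if (length(after)) ser$columns[min(after)] else alignment_length
    start <- (left + firstR) / 2
    stop <- (lastR + right) / 2
    data.frame(family_id = family_id,
               leaves = paste(q$leaves, collapse = ","),
               start = start, stop = stop, length = stop - start,
               n_R_support = cl$n_R[i], alt_topology = cl$alt[i],
               kind = "conversion", first_R = firstR, last_R = lastR,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, calls),
            class = c("quartet_track_calls", "data.frame"))
}

#' Call interlocus crossover breakpoints
#'
#' A crossover between non-allelic sequences flips the topology from the
#' breakpoint to an end of the alignment. A terminal run of at least
#' `min_support` consecutive R sites of one alternative topology reaching the
#' first or last informative site is called as a crossover candidate; the
#' breakpoint is resolved to the window between the flanking C site and the
#' nearest R site of the run.
#'
#' @param q a `quartet_result`.
#' @param alignment_length total alignment columns.
#' @param min_support minimum consecutive R sites (default 5, i.e. more than
#'   four).
#' @param family_id family identifier.
#' @return data frame of class `quartet_track_calls` with `kind = "crossover"`
#'   and the breakpoint window in `start`/`stop`; empty if no terminal run
#'   qualifies.
#' @export
call_crossover_breakpoints <- function(q, alignment_length, min_support = 5L,
                                       family_id = "family") {
  ser <- .cr_series(q)
  cl <- .r_clusters(ser)
  empty <- data.frame(family_id = character(0), leaves = character(0),
                      start = numeric(0), stop = numeric(0), length = numeric(0),
                      n_R_support = integer(0), alt_topology = character(0),
                      kind = character(0), first_R = numeric(0), last_R = numeric(0))
  if (is.null(cl)) return(structure(empty, class = c("quartet_track_calls", "data.frame")))
  n <- length(ser$labels)
  out <- list()
  for (i in seq_len(nrow(cl))) {
    if (cl$n_R[i] < min_support) next
    at_start <- cl$first[i] == 1L
    at_end <- cl$last[i] == n
    if (!at_start && !at_end) next
    if (at_end) {
      firstR <- ser$columns[cl$first[i]]
      before <- which(ser$labels == "C" & seq_len(n) < cl$first[i])
      flank <- if (length(before)) ser$columns[max(before)] else 1
      win <- c(flank, firstR)
    } else {
      lastR <- ser$columns[cl$last[i]]
      after <- which(ser$labels == "C" & seq_len(n) > cl$last[i])
      flank <- if (length(after)) ser$columns[min(after)] else alignment_length
      win <- c(lastR, flank)
    }
    out[[length(out) + 1L]] <- data.frame(
      family_id = family_id, leaves = paste(q$leaves, collapse = ","),
      start = win[1], stop = win[2], length = win[2] - win[1],
      n_R_support = cl$n_R[i], alt_topology = cl$alt[i], kind = "crossover",
      first_R = ser$columns[cl$first[i]], last_R = ser$columns[cl$last[i]],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(structure(empty, class = c("quartet_track_calls", "data.frame")))
  structure(do.call(rbind, out), class = c("quartet_track_calls", "data.frame"))
}

#' Partition a quartet alignment into topology blocks
#'
#' Tiles the alignment into segments of constant supported topology: C sites
#' carry the dominant topology, R sites their alternative, B sites are
#' transparent. Segment boundaries fall at the midpoint between adjacent
#' informative sites of differing topology; the tiling covers the alignment
#' exactly.
#'
#' @param q a `quartet_result`.
#' @param alignment_length total alignment columns.
#' @return object of class `topology_block_partition`: data frame `segments`
#'   (`start`, `stop`, `topology`, `length`) and `fraction_discordant`, the
#'   fraction of alignment bp in non-dominant segments.
#' @export
partition_topology_blocks <- function(q, alignment_length) {
  ser <- .cr_series(q)
  topo <- ifelse(ser$labels == "R", ser$alt, q$dominant)
  if (!length(topo)) {
    seg <- data.frame(start = 0, stop = alignment_length,
                      topology = q$dominant, length = alignment_length,
                      stringsAsFactors = FALSE)
    return(structure(list(segments = seg, fraction_discordant = 0,
                          dominant = q$dominant),
                     class = "topology_block_partition"))
  }
  # collapse consecutive same-topology sites, cut at midpoints on changes
  change <- which(topo[-1] != topo[-length(topo)])
  cuts <- (ser$columns[change] + ser$columns[change + 1L]) / 2
  bounds <- c(0, cuts, alignment_length)
  seg_topo <- topo[c(1L, change + 1L)]
  seg <- data.frame(start = bounds[-length(bounds)], stop = bounds[-1],
                    topology = seg_topo, stringsAsFactors = FALSE)
  seg$length <- seg$stop - seg$start
  frac <- sum(seg$length[seg$topology != q$dominant]) / alignment_length
  structure(list(segments = seg, fraction_discordant = frac,
                 dominant = q$dominant),
            class = "topology_block_partition")
}

#' @export
print.topology_block_partition <- function(x, ...) {
  cat(sprintf("<topology_block_partition> %d segments, %.1f%% discordant bp (dominant %s)\n",
              nrow(x$segments), 100 * x$fraction_discordant, x$dominant))
  invisible(x)
}

#' Flag complex exchange events (clustered topology switches)
#'
#' Multiple overlapping conversions or replicative repair with serial template
#' switching (MMBIR-like) leave several abrupt topology switches in close
#' proximity. Any stretch containing at least `min_switches` switch points
#' within `window` bp is flagged; flags near the alignment edges, where
#' alignment quality is typically reduced, are annotated.
#'
#' @param q a `quartet_result`.
#' @param alignment_length total alignment columns.
#' @param window clustering window in bp.
#' @param min_switches minimum topology switches within the window.
#' @param edge_frac flags within this fraction of either alignment end are
#'   annotated `near_edge`.
#' @return data frame of flagged intervals (`start`, `stop`, `n_switches`,
#'   `near_edge`); zero rows when nothing qualifies.
#' @export
flag_complex_events <- function(q, alignment_length, window = 2000,
                                min_switches = 3L, edge_frac = 0.05) {
  part <- partition_topology_blocks(q, alignment_length)
  sw <- part$segments$start[-1]            # interior switch points
  out <- data.frame(start = numeric(0), stop = numeric(0),
                    n_switches = integer(0), near_edge = logical(0))
  if (length(sw) < min_switches) return(out)
  k <- min_switches
  hits <- which(sw[seq_len(length(sw) - k + 1L) + k - 1L] -
                  sw[seq_len(length(sw) - k + 1L)] <= window)
  if (!length(hits)) return(out)
  # merge overlapping windows of switches
  iv <- cbind(sw[hits], sw[hits + k - 1L])
  merged <- list(iv[1, ])
  if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
    last <- merged[[length(merged)]]
    if (iv[i, 1] <= last[2]) merged[[length(merged)]] <- c(last[1], max(last[2], iv[i, 2]))
    else merged[[length(merged) + 1L]] <- iv[i, ]
  }
  res <- do.call(rbind, lapply(merged, function(m) {
    data.frame(start = m[1], stop = m[2],
               n_switches = sum(sw >= m[1] & sw <= m[2]),
               near_edge = m[1] < edge_frac * alignment_length ||
                 m[2] > (1 - edge_frac) * alignment_length)
  }))
  res
}

#' Map an alignment interval of a family member to genome coordinates
#'
#' @param fam an `aligned_family`.
#' @param seq_name a member name.
#' @param start,stop alignment interval (1-based columns; fractional midpoints
#'   are snapped to the nearest covered columns).
#' @return `list(chrom, start, end, strand)` in 0-based half-open genomic
#'   coordinates.
#' @export
map_to_genome <- function(fam, seq_name, start, stop) {
  stopifnot(inherits(fam, "aligned_family"), seq_name %in% rownames(fam$matrix))
  i <- match(seq_name, rownames(fam$matrix))
  c1 <- max(1L, ceiling(start))
  c2 <- min(fam$length, floor(stop))
  if (c2 < c1) { c1 <- max(1L, floor(start)); c2 <- min(fam$length, c1) }
  g <- fam$col_map[i, c1:c2]
  list(chrom = fam$members$chrom[i], start = min(g), end = max(g) + 1L,
       strand = fam$members$strand[i])
}
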