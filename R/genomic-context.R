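#' Length-matched random re-placement of conversion tracks
#'
#' Null model for the genomic distribution of unique tracks: for each observed
#' track of length `l`, an alignment is sampled with probability proportional
#' to its length (restricted to alignments longer than `l`), two of its
#' members are chosen at random to have undergone conversion, and the track
#' start is drawn uniformly on `(1, L - l)` alignment bp. Repeating this for
#' every track yields one simulated dataset; `n_datasets` datasets form the
#' null distribution for any genomic-context statistic.
#'
#' @param track_lengths numeric vector of unique-track lengths (bp).
#' @param families list of `aligned_family` objects to place into.
#' @param n_datasets number of simulated datasets.
#' @param seed RNG seed.
#' @return data frame of placements: `dataset`, `track`, `length`,
#'   `family_id`, `seq1`, `seq2`, `start`, `stop` (alignment bp) and genome
#'   intervals `chrom1/gstart1/gend1`, `chrom2/gstart2/gend2`.
#' @export
place_random_tracks <- function(track_lengths, families, n_datasets = 1000L,
                                seed = 1L) {
  stopifnot(length(families) >= 1L, all(track_lengths > 0))
  L <- vapply(families, function(f) f$length, numeric(1))
  ids <- vapply(families, function(f) f$family_id, character(1))
  nmem <- vapply(families, function(f) nrow(f$matrix), numeric(1))
  if (any(nmem < 2L)) stop("families must have >= 2 members")
  out <- with_seed(seed, {
    rows <- vector("list", n_datasets * length(track_lengths))
    k <- 0L
    for (d in seq_len(n_datasets)) {
      for (t in seq_along(track_lengths)) {
        l <- track_lengths[t]
        ok <- which(L > l)
        if (!length(ok))
          stop("track ", t, " (length ", l,
               ") exceeds every alignment length")
        fi <- ok[sample.int(length(ok), 1L, prob = L[ok])]
        fam <- families[[fi]]
        pr <- sample.int(nrow(fam$matrix), 2L)
        start <- if (L[fi] - l <= 1) 1 else sample.int(as.integer(L[fi] - l), 1L)
        stop_ <- start + l - 1
        g1 <- map_to_genome(fam, rownames(fam$matrix)[pr[1]], start, stop_)
        g2 <- map_to_genome(fam, rownames(fam$matrix)[pr[2]], start, stop_)
        k <- k + 1L
        rows[[k]] <- data.frame(
          dataset = d, track = t, length = l, family_id = ids[fi],
          seq1 = rownames(fam$matrix)[pr[1]], seq2 = rownames(fam$matrix)[pr[2]],
          start = start, stop = stop_,
          chrom1 = g1$chrom, gstart1 = g1$start, gend1 = g1$end,
          chrom2 = g2$chrom, gstart2 = g2$start, gend2 = g2$end,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  out
}

# coerce intervals (data frame with chrom/start/end, 0-based half-open) or a
# GRanges to GRanges
as_granges <- function(x) {
  if (inherits(x, "GRanges")) return(x)
  stopifnot(is.data.frame(x))
  nm <- names(x)
  chrom <- x[[if ("chrom" %in% nm) "chrom" else "seqnames"]]
  GenomicRanges::GRanges(chrom, IRanges::IRanges(x$start + 1L, x$end))
}

#' Overlap of tracks with annotation features
#'
#' A track overlaps a feature set if it shares at least one bp with any of its
#' intervals (0-based half-open inputs; BED convention).
#'
#' @param tracks intervals: `GRanges` or data frame with `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param annotations a named list of feature interval sets (each a `GRanges`
#'   or BED-style data frame).
#' @return data frame with one row per feature: `feature`, `n_overlap`,
#'   `fraction` (of tracks overlapping).
#' @export
overlap_features <- function(tracks, annotations) {
  tr <- as_granges(tracks)
  stopifnot(is.list(annotations), !is.null(names(annotations)))
  res <- lapply(names(annotations), function(nm) {
    feat <- as_granges(annotations[[nm]])
    hit <- GenomicRanges::countOverlaps(tr, feat, minoverlap = 1L) > 0L
    data.frame(feature = nm, n_overlap = sum(hit),
               fraction = if (length(tr)) mean(hit) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Count PRDM9 binding-motif matches
#'
#' Counts occurrences of the degenerate recombinogenic 13-mer `CCnCCnTnnCCnC`
#' (n = any base) on both strands; overlapping matches are allowed.
#'
#' @param seq a nucleotide string, character residue vector, or
#'   `Biostrings::DNAString`.
#' @return integer match count (forward + reverse-complement strand).
#' @export
count_prdm9 <- function(seq) {
  if (is.character(seq) && length(seq) > 1L) seq <- chars_to_seq(seq)
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  motif <- Biostrings::DNAString("CCNCCNTNNCCNC")
  fwd <- Biostrings::countPattern(motif, seq, fixed = FALSE)
  rev <- Biostrings::countPattern(Biostrings::reverseComplement(motif), seq,
                                  fixed = FALSE)
  as.integer(fwd + rev)
}

#' Quantile-position p-value against a simulated null
#'
#' @param observed observed statistic.
#' @param null_distribution simulated values (one per simulated dataset).
#' @param direction `"enriched"` (observed high), `"depleted"` (observed low).
#' @return object of class `enrichment_result`: `observed`, `p_value` (the
#'   fraction of simulated values at least as extreme in the stated direction;
#'   reported as `1/(n+1)` with `less_than = TRUE` when the observed value is
#'   beyond every simulated one), `p_upper`, `p_lower`, `direction`, the null
#'   range, and a `degenerate` flag for constant nulls.
#' @export
enrichment_pvalue <- function(observed, null_distribution,
                              direction = c("enriched", "depleted")) {
  direction <- match.arg(direction)
  null <- null_distribution[!is.na(null_distribution)]
  stopifnot(length(null) >= 1L)
  n <- length(null)
  p_upper <- mean(null >= observed)
  p_lower <- mean(null <= observed)
  p <- if (direction == "enriched") p_upper else p_lower
  less_than <- p == 0
  if (less_than) p <- 1 / (n + 1)
  structure(list(observed = observed, p_value = p, less_than = less_than,
                 p_upper = p_upper, p_lower = p_lower, direction = direction,
                 null_range = range(null),
                 null_quantiles = stats::quantile(null, c(0.025, 0.975)),
                 degenerate = length(unique(null)) == 1L,
                 n_null = n),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> observed %.4g vs null [%.4g, %.4g]; %s p %s%.4g%s\n",
              x$observed, x$null_range[1], x$null_range[2], x$direction,
              if (x$less_than) "< " else "= ", x$p_value,
              if (x$degenerate) " (degenerate null)" else ""))
  invisible(x)
}

#' Table-style genomic-context summary of track pairs
#'
#' Computes the pairwise context categories for a set of conversion events
#' (each linking two genomic intervals): inter- vs intrachromosomal counts,
#' zone-to-zone exchanges (e.g. both partners pericentromeric or
#' subtelomeric), annotation pairings (both partners in genes, CDS, or
#' pseudogenes), per-feature overlap fractions of the track intervals, the
#' average distance between intrachromosomal track midpoints, and PRDM9 motif
#' counts within tracks when sequence is supplied. The identical code path
#' serves observed events and random placements.
#'
#' @param events data frame with `chrom1/gstart1/gend1`, `chrom2/gstart2/gend2`.
#' @param annotations optional named list of feature interval sets; names
#'   `gene`, `cds`, `pseudogene` additionally produce pair categories, and
#'   `pericentromeric`/`subtelomeric` produce zone-exchange counts.
#' @param chrom_seqs optional named character vector of chromosome sequences
#'   used to count PRDM9 motifs inside the first interval of each event.
#' @return named numeric vector of context statistics.
#' @export
context_summary <- function(events, annotations = list(), chrom_seqs = NULL) {
  stopifnot(all(c("chrom1", "gstart1", "gend1", "chrom2", "gstart2", "gend2")
                %in% names(events)))
  n <- nrow(events)
  inter <- events$chrom1 != events$chrom2
  out <- c(n_events = n, n_interchromosomal = sum(inter),
           n_intrachromosomal = sum(!inter))
  iv1 <- data.frame(chrom = events$chrom1, start = events$gstart1,
                    end = events$gend1)
  iv2 <- data.frame(chrom = events$chrom2, start = events$gstart2,
                    end = events$gend2)
  in_feature <- function(iv, feat) {
    if (!n) return(logical(0))
    GenomicRanges::countOverlaps(as_granges(iv), as_granges(feat)) > 0L
  }
  for (nm in names(annotations)) {
    h1 <- in_feature(iv1, annotations[[nm]])
    h2 <- in_feature(iv2, annotations[[nm]])
    out[paste0("frac_overlap_", nm)] <- if (n) mean(h1 | h2) else NA_real_
    if (nm %in% c("gene", "cds", "pseudogene"))
      out[paste0("n_", nm, "_", nm)] <- sum(h1 & h2)
    if (nm %in% c("pericentromeric", "subtelomeric")) {
      out[paste0("n_inter_", nm)] <- sum(h1 & h2 & inter)
    }
  }
  if (!is.null(annotations$gene) && !is.null(annotations$pseudogene)) {
    g1 <- in_feature(iv1, annotations$gene); g2 <- in_feature(iv2, annotations$gene)
    p1 <- in_feature(iv1, annotations$pseudogene); p2 <- in_feature(iv2, annotations$pseudogene)
    out["n_pseudogene_gene"] <- sum((g1 & p2) | (p1 & g2))
  }
  intra <- which(!inter)
  if (length(intra) >= 2L) {
    mid <- (events$gstart1 + events$gend1) / 2
    dists <- unlist(lapply(split(mid[intra], events$chrom1[intra]), function(m) {
      if (length(m) < 2L) return(NULL)
      as.numeric(stats::dist(m))
    }))
    out["mean_intrachrom_distance"] <- if (length(dists)) mean(dists) else NA_real_
  } else out["mean_intrachrom_distance"] <- NA_real_
  if (!is.null(chrom_seqs) && n) {
    out["n_prdm9_in_tracks"] <- sum(vapply(seq_len(n), function(i) {
      s <- chrom_seqs[[events$chrom1[i]]]
      if (is.null(s)) return(0L)
      seg <- substr(s, events$gstart1[i] + 1L, events$gend1[i])
      if (nchar(seg) < 13L) 0L else count_prdm9(seg)
    }, integer(1)))
  }
  out
}

#' Read a BED file of annotation intervals
#' @param path BED3+ file.
#' @return a `GRanges` (0-based half-open input, standard BED semantics).
#' @export
read_bed <- function(path) rtracklayer::import(path, format = "BED")
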