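#' Pipeline configuration
#'
#' Bundles the filtering, testing and replication constants for a full run:
#' 100 column bootstraps and 100 null simulations per family for the
#' reticulate-site excess test, 10,000 permutations for the identity-fragment
#' scan, 1000 simulated datasets for genomic-context enrichment, significance
#' threshold 0.05 and bootstrap-support threshold 0.88.
#'
#' @param preprocess a [preprocess_config()].
#' @param n_boot,n_sim,n_perm,n_enrich replicate counts per stage.
#' @param alpha significance threshold.
#' @param support_threshold minimum bootstrap support for tree nodes.
#' @param mu mutation rate for the rate stage.
#' @param seed global seed; every stage derives its own stream from it.
#' @param out_dir optional directory for per-stage TSV/BED artifacts.
#' @return an object of class `run_config`.
#' @export
run_config <- function(preprocess = preprocess_config(), n_boot = 100L,
                       n_sim = 100L, n_perm = 10000L, n_enrich = 1000L,
                       alpha = 0.05, support_threshold = 0.88, mu = 1.2e-8,
                       seed = 1L, out_dir = NULL) {
  stopifnot(n_boot >= 1L, n_sim >= 1L, n_perm >= 100L, n_enrich >= 1L)
  structure(list(preprocess = preprocess, n_boot = as.integer(n_boot),
                 n_sim = as.integer(n_sim), n_perm = as.integer(n_perm),
                 n_enrich = as.integer(n_enrich), alpha = alpha,
                 support_threshold = support_threshold, mu = mu,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full IGC detection pipeline on a set of families
#'
#' Stages, in order: preprocessing filters; NJ tree with bootstrap supports
#' and low-support pruning; GTR+Gamma4+I model fit; reticulate-site excess
#' tests on the full and CpG-stripped alignments; quartet conversion-track and
#' crossover calls on eligible CpG-minus quartets; identity-fragment scan and
#' significant track calls; genomic deduplication; per-family equilibrium IGC
#' rates; summary statistics. Every random draw is seeded from
#' `config$seed`, so a rerun reproduces the outputs exactly.
#'
#' @param families a list; each element either an `aligned_family`, or
#'   `list(aln = <gapped matrix or FASTA path>, members = <locus records>)` to
#'   be preprocessed, or a `generate_null_family()` result.
#' @param config a [run_config()].
#' @return object of class `igc_run`: per-stage result lists plus a `summary`
#'   list (family counts, significant-family fraction, track counts and
#'   lengths, total converted bp, per-family rates). When `config$out_dir` is
#'   set, per-stage TSV/BED artifacts are written there.
#' @export
run_pipeline <- function(families, config = run_config()) {
  t0 <- Sys.time()
  seed <- config$seed
  prep <- list(); rejected <- list()
  for (i in seq_along(families)) {
    x <- families[[i]]
    fam <- if (inherits(x, "aligned_family")) x
      else if (is.list(x) && inherits(x$fam, "aligned_family")) x$fam
      else {
        aln <- if (is.character(x$aln)) read_alignment_fasta(x$aln) else x$aln
        preprocess_alignment(aln, x$members, config$preprocess)
      }
    if (is_rejected(fam)) rejected[[length(rejected) + 1L]] <- fam
    else prep[[length(prep) + 1L]] <- fam
  }

  results <- list()
  for (k in seq_along(prep)) {
    fam <- prep[[k]]
    fseed <- derive_seed(seed, k)
    pruned <- prune_low_support(fam, threshold = config$support_threshold,
                                n_boot = config$n_boot,
                                seed = derive_seed(fseed, 1L))
    if (is_rejected(pruned)) {
      rejected[[length(rejected) + 1L]] <- pruned
      next
    }
    fam <- pruned$fam; tree <- pruned$tree
    model <- fit_substitution_model(fam, tree)
    ex_full <- excess_test(fam, tree, model, config$n_boot, config$n_sim,
                           derive_seed(fseed, 2L))
    fam_cpg <- strip_cpg(fam)
    ex_cpg <- excess_test(fam_cpg, tree, model, config$n_boot, config$n_sim,
                          derive_seed(fseed, 3L))

    # quartet tracks on the CpG-minus view
    scan_cpg <- scan_family(fam_cpg, tree)
    expect <- quartet_null_expectations(fam_cpg, tree, model, config$n_sim,
                                        derive_seed(fseed, 4L))
    eligible <- select_informative_quartets(scan_cpg, expect[, "B"])
    qt <- lapply(eligible, function(qi) {
      q <- scan_cpg$quartets[[qi]]
      list(conversions = call_conversion_tracks(q, fam_cpg$length, fam$family_id),
           crossovers = call_crossover_breakpoints(q, fam_cpg$length,
                                                   family_id = fam$family_id),
           partition = partition_topology_blocks(q, fam_cpg$length),
           complex = flag_complex_events(q, fam_cpg$length))
    })

    id_calls <- call_identity_tracks(fam, permutation_config(
      n_perm = config$n_perm, alpha = config$alpha,
      seed = derive_seed(fseed, 5L)))

    results[[fam$family_id]] <- list(fam = fam, tree = tree, model = model,
                                     excess_full = ex_full,
                                     excess_cpg_minus = ex_cpg,
                                     quartet_tracks = qt,
                                     identity_calls = id_calls)
  }

  all_calls <- do.call(rbind, Filter(function(x) !is.null(x) && nrow(x) > 0,
                                     lapply(results, `[[`, "identity_calls")))
  dedup <- deduplicate_tracks(all_calls)
  rates <- if (length(results))
    family_rate_table(lapply(results, `[[`, "fam"), config$mu) else NULL

  p_full <- vapply(results, function(r) r$excess_full$p_value, numeric(1))
  tested <- !is.na(p_full)
  uniq <- dedup$tracks
  summary <- list(
    n_input = length(families), n_rejected = length(rejected),
    n_tested = sum(tested),
    n_significant = sum(p_full[tested] <= config$alpha),
    frac_significant = if (any(tested))
      mean(p_full[tested] <= config$alpha) else NA_real_,
    n_identity_calls = if (is.null(all_calls)) 0L else nrow(all_calls),
    n_unique_tracks = length(uniq),
    total_converted_bp = if (length(uniq)) sum(GenomicRanges::width(uniq)) else 0L,
    mean_track_length = if (length(uniq)) mean(GenomicRanges::width(uniq)) else NA_real_,
    median_track_length = if (length(uniq))
      stats::median(GenomicRanges::width(uniq)) else NA_real_,
    mean_rate = if (!is.null(rates)) attr(rates, "mean_rate") else NA_real_,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  run <- structure(list(results = results, rejected = rejected,
                        unique_tracks = dedup$tracks, rates = rates,
                        summary = summary, config = config),
                   class = "igc_run")
  if (!is.null(config$out_dir)) write_run_artifacts(run, config$out_dir)
  run
}

#' @export
print.igc_run <- function(x, ...) {
  s <- x$summary
  cat("<igc_run>\n")
  cat(sprintf("  families: %d input, %d rejected, %d tested\n",
              s$n_input, s$n_rejected, s$n_tested))
  cat(sprintf("  R-site excess: %d significant (%.1f%%)\n", s$n_significant,
              100 * (s$frac_significant %||% NA_real_)))
  cat(sprintf("  identity tracks: %d calls -> %d unique tracks, %d bp total\n",
              s$n_identity_calls, s$n_unique_tracks, s$total_converted_bp))
  invisible(x)
}

# per-stage TSV/BED artifacts
write_run_artifacts <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ex <- do.call(rbind, lapply(run$results, function(r) {
    e <- r$excess_full
    data.frame(family_id = e$family_id,
               observed_R = e$observed_R,
               expected_R = e$expected_R %||% NA_real_,
               ci_lo = if (!is.null(e$ci_R)) e$ci_R[1] else NA,
               ci_hi = if (!is.null(e$ci_R)) e$ci_R[2] else NA,
               observed_B = e$observed_B,
               expected_B = e$expected_B %||% NA_real_,
               p_value = e$p_value, p_value_B = e$p_value_B,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(ex))
    utils::write.table(ex, file.path(dir, "excess_tests.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  calls <- do.call(rbind, Filter(function(x) !is.null(x) && nrow(x) > 0,
                                 lapply(run$results, `[[`, "identity_calls")))
  if (!is.null(calls) && nrow(calls)) {
    utils::write.table(calls, file.path(dir, "identity_calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_bed_tracks(calls, file.path(dir, "identity_calls.bed"))
  }
  if (length(run$unique_tracks)) {
    ut <- as.data.frame(run$unique_tracks)
    ut <- ut[, !vapply(ut, is.list, logical(1)), drop = FALSE]
    utils::write.table(ut, file.path(dir, "unique_tracks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$rates))
    utils::write.table(run$rates, file.path(dir, "family_rates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write significant identity-track calls as a BED6 custom track
#'
#' One record per call interval (the first member's genomic interval), named
#' `family|seq1|seq2`, scored `-10 log10(p)` (capped at 1000) using the more
#' significant of the global and pairwise p-values; 0-based half-open, sorted.
#'
#' @param calls a `fragment_calls` data frame with genome coordinates.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_bed_tracks <- function(calls, path) {
  stopifnot(is.data.frame(calls))
  ok <- !is.na(calls$chrom1)
  if (any(!ok)) warning(sum(!ok), " record(s) lack chrom; skipped")
  calls <- calls[ok, , drop = FALSE]
  p <- pmin(calls$p_global, calls$p_pairwise)
  score <- round(pmin(1000, -10 * log10(pmax(p, 1e-100))))
  bed <- data.frame(chrom = calls$chrom1,
                    start = as.integer(calls$gstart1),
                    end = as.integer(calls$gend1),
                    name = paste(calls$family_id, calls$seq1, calls$seq2,
                                 sep = "|"),
                    score = as.integer(score), strand = ".",
                    stringsAsFactors = FALSE)
  bed <- bed[order(bed$chrom, bed$start, bed$end), , drop = FALSE]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
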