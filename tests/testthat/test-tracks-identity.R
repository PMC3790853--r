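test_that("pair fragments are maximal identity runs over polymorphic sites", {
  # pair differing at every polymorphic site: no fragments
  mat <- rbind(s1 = c("A", "A", "C", "A", "G"),
               s2 = c("C", "A", "G", "A", "T"),
               s3 = c("A", "A", "C", "A", "G"),
               s4 = c("A", "A", "C", "A", "G"))
  fr <- score_pair_fragments(mat, c("s1", "s2"))
  expect_equal(nrow(fr), 0L)

  # 10 polymorphic sites, pair identical at sites 3-8: one fragment, score 6
  set.seed(1)
  L <- 40
  m <- matrix("A", 4, L, dimnames = list(paste0("s", 1:4), NULL))
  poly_at <- seq(4, 40, by = 4)             # 10 polymorphic columns
  m[3, poly_at] <- "G"                       # s3 makes every column variable
  m[2, poly_at[c(1, 2, 9, 10)]] <- "T"       # s2 mismatches s1 outside 3-8
  fr2 <- score_pair_fragments(m, c("s1", "s2"))
  expect_equal(nrow(fr2), 1L)
  expect_equal(fr2$first_poly, 3L)
  expect_equal(fr2$last_poly, 8L)
  expect_equal(fr2$n_poly_spanned, 6L)
  expect_equal(fr2$start, poly_at[3])
  expect_equal(fr2$stop, poly_at[8])

  # random fixtures: fragments equal an independent linear re-scan
  for (rep in 1:5) {
    rm <- random_alignment(5, 300, 0.15, seed = 40 + rep)
    poly <- igcscan:::.poly_cols(rm)
    fr3 <- score_pair_fragments(rm, c("s2", "s4"))
    b <- rm["s2", poly] == rm["s4", poly]
    # oracle: explicit walk
    runs <- list(); cur <- NULL
    for (i in seq_along(b)) {
      if (b[i]) { if (is.null(cur)) cur <- c(i, i) else cur[2] <- i }
      else { if (!is.null(cur)) { runs[[length(runs) + 1]] <- cur; cur <- NULL } }
    }
    if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
    expect_equal(nrow(fr3), length(runs))
    if (length(runs)) {
      expect_equal(fr3$first_poly, vapply(runs, `[`, numeric(1), 1))
      expect_equal(fr3$last_poly, vapply(runs, `[`, numeric(1), 2))
    }
  }
})

test_that("fragments are invariant to shuffling monomorphic columns", {
  rm <- random_alignment(4, 200, 0.1, seed = 77)
  poly <- igcscan:::.poly_cols(rm)
  mono <- setdiff(seq_len(ncol(rm)), poly)
  shuffled <- rm
  set.seed(3)
  shuffled[, mono] <- shuffled[, sample(mono), drop = FALSE]
  for (pair in list(c("s1", "s2"), c("s2", "s3"))) {
    a <- score_pair_fragments(rm, pair)
    b <- score_pair_fragments(shuffled, pair)
    expect_equal(a$first_poly, b$first_poly)
    expect_equal(a$n_poly_spanned, b$n_poly_spanned)
  }
})

test_that("a pair identical at all polymorphic sites is never significant", {
  # 4 sequences where s1 == s2 everywhere: their (single) fragment spans all
  # polymorphic sites and every permutation reproduces it
  rm <- random_alignment(4, 300, 0.12, seed = 5)
  rm["s2", ] <- rm["s1", ]
  scan <- permutation_test(rm, permutation_config(n_perm = 300, seed = 9))
  fr <- scan$fragments
  full <- fr[fr$seq1 == "s1" & fr$seq2 == "s2", ]
  expect_equal(nrow(full), 1L)
  expect_equal(full$n_poly_spanned, scan$n_poly)
  expect_equal(full$p_global, 1.0)
})

test_that("permutation p-values match exhaustive site-order enumeration", {
  # 7 polymorphic sites: all 7! = 5040 orderings enumerated exactly
  set.seed(11)
  L <- 60
  m <- matrix("A", 4, L, dimnames = list(paste0("s", 1:4), NULL))
  poly_at <- seq(8, 56, by = 8)              # 7 polymorphic columns
  m[4, poly_at] <- "G"
  m[2, poly_at[c(2, 5)]] <- "T"              # s1-s2 mismatch pattern
  m[3, poly_at[c(1, 2, 6)]] <- "C"           # more pair patterns
  poly <- igcscan:::.poly_cols(m)
  expect_length(poly, 7L)
  pim <- igcscan:::.pair_identity_matrix(m, poly)

  # oracle: enumerate every ordering, record each pair's max run and the
  # alignment-wide max
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  allp <- perms(1:7)
  maxrun <- function(x) { r <- rle(x); m <- r$lengths[r$values == 1]; if (length(m)) max(m) else 0L }
  np <- nrow(pim$B)
  pair_max <- matrix(0L, length(allp), np)
  for (k in seq_along(allp))
    for (p in seq_len(np)) pair_max[k, p] <- maxrun(pim$B[p, allp[[k]]])
  glob <- apply(pair_max, 1, max)

  scan <- permutation_test(m, permutation_config(n_perm = 4000, seed = 13))
  fr <- scan$fragments
  for (i in seq_len(nrow(fr))) {
    s <- fr$n_poly_spanned[i]
    p_exact <- mean(glob >= s)
    mc_se <- sqrt(p_exact * (1 - p_exact) / 4000)
    expect_lt(abs(fr$p_global[i] - p_exact), 4 * mc_se + 1e-9)
    p_pair_exact <- min(1, np * mean(pair_max[, fr$pair[i]] >= s))
    se2 <- np * sqrt(max(p_pair_exact / np * (1 - p_pair_exact / np), 1e-6) / 4000)
    expect_lt(abs(fr$p_pairwise[i] - p_pair_exact), 4 * se2 + 1e-9)
  }
})

test_that("an injected recent conversion yields a significant pair fragment", {
  spec <- family_gen_spec(n_paralogs = 6, length = 8000,
                          target_identity = 0.96, seed = 901)
  g <- generate_null_family(spec, "inj")
  nm <- rownames(g$fam$matrix)
  res <- inject_gene_conversion(g$fam, nm[2], nm[5], 3000, 5000)
  calls <- call_identity_tracks(res$fam, permutation_config(n_perm = 1000,
                                                            seed = 31))
  expect_gt(nrow(calls), 0L)
  hit <- calls[calls$seq1 %in% c(nm[2], nm[5]) & calls$seq2 %in% c(nm[2], nm[5]), ]
  expect_gte(nrow(hit), 1L)
  expect_true(any(hit$p_global < 0.05))
  # called fragment overlaps the injected interval
  expect_true(any(hit$start <= 5000 & hit$stop >= 3000))
  # converted interval is perfectly identical between donor and acceptor
  expect_equal(pairwise_identity(res$fam$matrix[nm[2], 3000:5000],
                                 res$fam$matrix[nm[5], 3000:5000]), 1.0)
})

test_that("deduplication merges overlapping calls into disjoint tracks", {
  mkcall <- function(chrom1, s1, e1, chrom2, s2, e2) {
    data.frame(family_id = "f", seq1 = "a", seq2 = "b", start = 1, stop = 2,
               n_poly_spanned = 5, p_global = 0.01, p_pairwise = 0.2,
               chrom1 = chrom1, gstart1 = s1, gend1 = e1,
               chrom2 = chrom2, gstart2 = s2, gend2 = e2,
               stringsAsFactors = FALSE)
  }
  # the same track reported by three nested families collapses to one
  calls <- rbind(mkcall("chr1", 100, 300, "chr1", 100, 300),
                 mkcall("chr1", 100, 300, "chr1", 100, 300),
                 mkcall("chr1", 100, 300, "chr1", 100, 300))
  dd <- deduplicate_tracks(calls)
  expect_length(dd$tracks, 1L)
  expect_equal(dd$tracks$n_support, 6L)   # both intervals of all three calls

  # disjoint tracks stay separate
  calls2 <- rbind(mkcall("chr1", 100, 300, "chr2", 1000, 1200),
                  mkcall("chr1", 5000, 5200, "chr2", 9000, 9200))
  dd2 <- deduplicate_tracks(calls2)
  expect_length(dd2$tracks, 4L)

  # randomized fixtures: output equals a sort-and-sweep interval union and
  # is pairwise disjoint while conserving coverage
  set.seed(19)
  for (rep in 1:6) {
    n <- 30
    s <- sample(1:5000, n); w <- sample(20:400, n, replace = TRUE)
    calls3 <- do.call(rbind, lapply(seq_len(n), function(i)
      mkcall("chr1", s[i], s[i] + w[i], "chr1", s[i] + 7, s[i] + w[i] + 7)))
    dd3 <- deduplicate_tracks(calls3)
    got <- cbind(GenomicRanges::start(dd3$tracks) - 1L,
                 GenomicRanges::end(dd3$tracks))
    # oracle: classic sweep over sorted endpoints (0-based half-open)
    iv <- rbind(cbind(s, s + w), cbind(s + 7, s + w + 7))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    merged <- list(iv[1, ])
    for (i in 2:nrow(iv)) {
      last <- merged[[length(merged)]]
      if (iv[i, 1] <= last[2]) merged[[length(merged)]][2] <- max(last[2], iv[i, 2])
      else merged[[length(merged) + 1]] <- iv[i, ]
    }
    oracle <- do.call(rbind, merged)
    expect_equal(unname(got), unname(oracle))
    # disjoint and coverage-conserving
    expect_true(all(got[-1, 1] > got[-nrow(got), 2]))
    cov <- logical(10000)
    for (i in seq_len(nrow(iv))) cov[(iv[i, 1] + 1):iv[i, 2]] <- TRUE
    expect_equal(sum(got[, 2] - got[, 1]), sum(cov))
  }
})
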