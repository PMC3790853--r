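test_that("quartet eligibility uses strict B and R thresholds", {
  g <- shared_null_family()
  tree <- build_nj_tree(g$fam, n_boot = 20, seed = 2)
  scan <- scan_family(g$fam, tree)
  nq <- length(scan$quartets)
  n_R <- vapply(scan$quartets, function(q) q$n_R, numeric(1))

  # boundary: expected B = 4.9 with observed R > 5 is eligible
  expB <- rep(4.9, nq)
  expect_identical(select_informative_quartets(scan, expB),
                   which(expB < 5 & n_R > 5))
  # expected B = 5.0 is excluded (strict inequality)
  expect_length(select_informative_quartets(scan, rep(5.0, nq)), 0L)

  # refilter oracle on a randomized expectation table
  set.seed(4)
  expB2 <- runif(nq, 0, 10)
  expect_identical(select_informative_quartets(scan, expB2),
                   which(expB2 < 5 & n_R > 5))
})

test_that("conversion tracks follow the midpoint rule", {
  q <- make_quartet_result(columns = c(100, 200, 300, 400),
                           labels = c("C", "R", "R", "C"))
  tr <- call_conversion_tracks(q, 1000)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$start, 150)
  expect_equal(tr$stop, 350)
  expect_equal(tr$length, 200)
  expect_equal(tr$n_R_support, 2L)

  # a single isolated R site still forms a (short) cluster
  q2 <- make_quartet_result(columns = c(200, 250, 320),
                            labels = c("C", "R", "C"))
  tr2 <- call_conversion_tracks(q2, 1000)
  expect_equal(tr2$start, 225)
  expect_equal(tr2$stop, 285)
  expect_equal(tr2$length, 60)

  # clusters split when consecutive R sites support different topologies
  q3 <- make_quartet_result(columns = c(100, 200, 300, 400),
                            labels = c("C", "R", "R", "C"),
                            alt = c(NA, "AC|BD", "AD|BC", NA))
  tr3 <- call_conversion_tracks(q3, 1000)
  expect_equal(nrow(tr3), 2L)
  expect_equal(tr3$alt_topology, c("AC|BD", "AD|BC"))

  # no R sites: empty call set
  q4 <- make_quartet_result(columns = c(10, 20), labels = c("C", "C"))
  expect_equal(nrow(call_conversion_tracks(q4, 100)), 0L)

  # tracks within a quartet never overlap
  set.seed(8)
  for (rep in 1:5) {
    n <- 30
    cols <- sort(sample(1:5000, n))
    labs <- sample(c("C", "R"), n, replace = TRUE)
    if (!any(labs == "R") || !any(labs == "C")) next
    trr <- call_conversion_tracks(make_quartet_result(cols, labs), 5000)
    if (nrow(trr) >= 2) {
      o <- order(trr$start)
      expect_true(all(trr$start[o][-1] >= trr$stop[o][-nrow(trr)]))
    }
  }
})

test_that("crossover breakpoints require long terminal runs", {
  # terminal run of 6 R sites: window from the flanking C to the first run R
  cols <- c(1000, 2000, 5175, 7532, 8100, 8700, 9300, 9900, 10400)
  labs <- c("C", "C", "C", rep("R", 6))
  q <- make_quartet_result(cols, labs)
  cx <- call_crossover_breakpoints(q, 12000)
  expect_equal(nrow(cx), 1L)
  expect_equal(cx$start, 5175)
  expect_equal(cx$stop, 7532)
  expect_equal(cx$kind, "crossover")

  # a terminal run of only 4 R sites does not qualify (more than 4 needed)
  q4 <- make_quartet_result(c(100, 500, 900, 1300, 1700, 2100),
                            labels = c("C", "C", "R", "R", "R", "R"))
  expect_equal(nrow(call_crossover_breakpoints(q4, 3000)), 0L)

  # an interior run of any length is not a crossover
  qi <- make_quartet_result(c(100, 200, 300, 400, 500, 600, 700, 800),
                            labels = c("C", "R", "R", "R", "R", "R", "C", "C"))
  expect_equal(nrow(call_crossover_breakpoints(qi, 1000)), 0L)

  # crossover windows never lie strictly inside the informative-site range
  start_run <- make_quartet_result(c(50, 180, 300, 460, 600, 820, 900),
                                   labels = c("R", "R", "R", "R", "R", "C", "C"))
  cxs <- call_crossover_breakpoints(start_run, 1000)
  expect_equal(nrow(cxs), 1L)
  expect_equal(cxs$start, 600)   # last R of the run
  expect_equal(cxs$stop, 820)    # flanking C
})

test_that("an injected crossover is localized to the flanking-site window", {
  # high identity keeps the suffix free of homoplasic R sites of a third
  # topology, which would split the terminal run
  gspec <- family_gen_spec(n_paralogs = 4, length = 20000,
                           target_identity = 0.99, seed = 314)
  g <- generate_null_family(gspec)
  nm <- rownames(g$fam$matrix)
  top <- induced_quartet_topology(g$tree, nm)
  pr <- switch(top, "AB|CD" = c(1, 3), "AC|BD" = c(1, 2), "AD|BC" = c(1, 2))
  res <- inject_crossover(g$fam, nm[pr], 12000)
  sc <- scan_family(res$fam, g$tree)
  cx <- call_crossover_breakpoints(sc$quartets[[1]], res$fam$length,
                                   family_id = "cxfam")
  expect_gte(nrow(cx), 1L)
  expect_true(any(cx$start <= 12000 & cx$stop >= 12000))
})

test_that("topology blocks tile the alignment and measure discordance", {
  q_allC <- make_quartet_result(c(100, 300, 700), labels = rep("C", 3))
  p0 <- partition_topology_blocks(q_allC, 1000)
  expect_equal(nrow(p0$segments), 1L)
  expect_equal(p0$fraction_discordant, 0)

  # half the alignment in one alternative block
  q_half <- make_quartet_result(c(200, 400, 600, 800),
                                labels = c("C", "R", "R", "C"),
                                alt = c(NA, "AC|BD", "AC|BD", NA))
  ph <- partition_topology_blocks(q_half, 1000)
  # cuts at 300 and 700: discordant segment [300, 700) = 40% of 1000 bp
  expect_equal(ph$fraction_discordant, 0.4)
  expect_equal(sum(ph$segments$length), 1000)

  # random fixtures: per-bp oracle and exact conservation
  set.seed(15)
  for (rep in 1:8) {
    n <- 25; L <- 3000
    cols <- sort(sample(1:L, n))
    labs <- sample(c("C", "R", "B"), n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    alts <- ifelse(labs == "R", sample(c("AC|BD", "AD|BC"), n, replace = TRUE),
                   NA)
    q <- make_quartet_result(cols, labs, alts)
    p <- partition_topology_blocks(q, L)
    expect_equal(sum(p$segments$length), L)
    expect_true(all(p$segments$topology[-1] !=
                      p$segments$topology[-nrow(p$segments)]))
    # per-bp oracle: label every unit interval by its nearest C/R site
    keep <- labs %in% c("C", "R")
    cc <- cols[keep]
    tt <- ifelse(labs[keep] == "R", alts[keep], "AB|CD")
    if (!length(cc)) next
    bp_mid <- seq(0.5, L - 0.5, by = 1)
    nearest <- vapply(bp_mid, function(x) tt[which.min(abs(cc - x))],
                      character(1))
    frac_oracle <- mean(nearest != "AB|CD")
    # per-unit-bp discretization can differ by half a bp at each block cut
    expect_equal(p$fraction_discordant, frac_oracle,
                 tolerance = (length(cc) + 2) * 0.5 / L)
  }
})

test_that("complex events are flagged only for tight switch clusters", {
  # 4 switches inside 1.5 kb
  q <- make_quartet_result(
    columns = c(500, 900, 1200, 1500, 1800, 2000, 6000),
    labels = c("C", "R", "C", "R", "C", "C", "C"),
    alt = c(NA, "AC|BD", NA, "AD|BC", NA, NA, NA))
  fl <- flag_complex_events(q, 10000, window = 2000)
  expect_equal(nrow(fl), 1L)
  expect_gte(fl$n_switches, 3L)

  # two distant switches: nothing flagged
  q2 <- make_quartet_result(columns = c(500, 1000, 6000, 6500),
                            labels = c("C", "R", "R", "C"),
                            alt = c(NA, "AC|BD", "AC|BD", NA))
  expect_equal(nrow(flag_complex_events(q2, 10000, window = 2000)), 0L)
})

test_that("alignment intervals map to genomic coordinates via col_map", {
  fam <- make_family(c(a = "ACGTACGTAC", b = "ACGTACGAAC",
                       c = "ACTTACGTAC", d = "ACGTACCTAC"))
  g <- map_to_genome(fam, "a", 3, 7)
  expect_equal(g$chrom, "chr1")
  expect_equal(g$start, 2)      # 0-based: column 3 -> position 2
  expect_equal(g$end, 7)        # half-open past column 7
  # reverse strand member counts from its end
  fam$members$strand[2] <- "-"
  fam2 <- igcscan:::new_aligned_family("famA", fam$matrix, fam$members)
  g2 <- map_to_genome(fam2, rownames(fam$matrix)[2], 1, 2)
  expect_equal(g2$end - g2$start, 2)
})
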