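test_that("single-column classification follows the C/R/B rules", {
  expect_equal(classify_quartet_site(c("A", "A", "G", "G"), "AB|CD")$label, "C")
  r <- classify_quartet_site(c("A", "G", "A", "G"), "AB|CD")
  expect_equal(r$label, "R")
  expect_equal(r$alt_topology, "AC|BD")
  expect_equal(classify_quartet_site(c("A", "A", "G", "T"), "AB|CD")$label, "B")
  expect_equal(classify_quartet_site(c("A", "C", "G", "T"), "AD|BC")$label, "B")
  expect_equal(classify_quartet_site(c("A", "A", "A", "G"), "AB|CD")$label,
               "uninformative")
  expect_equal(classify_quartet_site(c("A", "A", "A", "A"), "AB|CD")$label,
               "uninformative")
  expect_equal(classify_quartet_site(c("A", "N", "G", "G"), "AB|CD")$label,
               "skipped")
})

test_that("family scans enumerate quartets and union R columns once", {
  # 4 members: exactly one quartet, union equals its R columns
  tree4 <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
  mat <- rbind(a = c("A", "A", "T", "C", "A"),
               b = c("A", "A", "T", "G", "A"),
               c = c("A", "G", "A", "C", "T"),
               d = c("A", "G", "A", "G", "T"))
  # col2/col3/col5: AB|CD concordant; col4: AC|BD reticulate
  sc <- scan_family(mat, tree4)
  expect_length(sc$quartets, 1L)
  expect_equal(sc$quartets[[1]]$n_C, 3L)
  expect_equal(sc$quartets[[1]]$n_R, 1L)
  expect_equal(sc$R_union, 1L)
  expect_equal(sc$R_union, sc$quartets[[1]]$n_R)

  # 6 members: choose(6, 4) = 15 quartets
  g <- shared_null_family()
  tree <- build_nj_tree(g$fam, n_boot = 20, seed = 2)
  sc6 <- scan_family(g$fam, tree)
  expect_length(sc6$quartets, 15L)
  # union never exceeds the informative-column union
  expect_lte(sc6$R_union, sc6$informative_union)

  # a column reticulate in several quartets counts once in the union
  counts_per_col <- Reduce(`+`, lapply(sc6$quartets, function(q) {
    v <- logical(g$fam$length)
    v[q$columns[q$labels == "R"]] <- TRUE
    v
  }))
  expect_equal(sc6$R_union, sum(counts_per_col > 0))
  expect_true(any(counts_per_col > 1))   # multiplicity does occur
})

test_that("IGC injection never creates new bimutational columns", {
  g <- shared_null_family()
  tree <- build_nj_tree(g$fam, n_boot = 20, seed = 2)
  before <- scan_family(g$fam, tree)
  nm <- rownames(g$fam$matrix)
  inj <- inject_gene_conversion(g$fam, nm[1], nm[5], 1000, 2500)
  inj <- inject_gene_conversion(inj$fam, nm[3], nm[6], 3000, 3800, inj$truth)
  after <- scan_family(inj$fam, tree)
  newB <- setdiff(which(after$Bany), which(before$Bany))
  expect_length(newB, 0L)
})

test_that("excess test flags injected exchange but not null families", {
  g <- shared_null_family()
  tree <- build_nj_tree(g$fam, n_boot = 30, seed = 2)
  model <- g$fam |> fit_substitution_model(tree)
  et0 <- excess_test(g$fam, tree, model, n_boot = 60, n_sim = 60, seed = 5)
  expect_false(et0$skipped)
  expect_gt(et0$p_value, 0.05)

  # ten injected conversions between non-sister paralogs
  fam <- g$fam; truth <- NULL
  nm <- rownames(fam$matrix)
  pairs <- list(c(1, 4), c(2, 5), c(3, 6), c(1, 5), c(2, 6),
                c(1, 6), c(2, 4), c(3, 5), c(4, 2), c(5, 3))
  starts <- seq(200, 4400, length.out = 10)
  for (k in 1:10) {
    res <- inject_gene_conversion(fam, nm[pairs[[k]][1]], nm[pairs[[k]][2]],
                                  round(starts[k]), round(starts[k]) + 380)
    fam <- res$fam
  }
  et1 <- excess_test(fam, tree, model, n_boot = 60, n_sim = 60, seed = 5)
  expect_lte(et1$p_value, 0.05)
  # B-site non-excess is preserved under injection (conservativeness check)
  expect_gte(et1$p_value_B, 0.05)
})

test_that("excess test is skipped when a family has no informative sites", {
  tree4 <- ape::read.tree(text = "((a:0.01,b:0.01):0.01,(c:0.01,d:0.01):0.01);")
  mat <- matrix("A", 4, 200, dimnames = list(letters[1:4], NULL))
  mat[1, 1:3] <- "C"  # singleton differences only: nothing informative
  et <- excess_test(mat, tree4, jc_model(), n_boot = 20, n_sim = 20, seed = 1)
  expect_true(et$skipped)
  expect_true(is.na(et$p_value))
})

test_that("runs test matches exhaustive enumeration and flags clustering", {
  # brute-force oracle over all arrangements of n1 C and n2 R labels
  enum_p <- function(n1, n2, robs) {
    pos <- utils::combn(n1 + n2, n1)
    runs <- apply(pos, 2, function(cpos) {
      lab <- rep("R", n1 + n2); lab[cpos] <- "C"
      length(rle(lab)$lengths)
    })
    mean(runs <= robs)
  }
  rt <- runs_test(c(rep("C", 4), rep("R", 4)))
  expect_equal(rt$runs, 2L)
  expect_true(rt$exact)
  expect_equal(rt$p_one_sided, enum_p(4, 4, 2), tolerance = 1e-12)

  # alternating labels: maximal runs, no evidence of clustering
  alt <- runs_test(rep(c("C", "R"), 4))
  expect_equal(alt$runs, 8L)
  expect_gt(alt$p_one_sided, 0.95)

  # exact distribution equals enumeration for all shapes with n1 + n2 <= 12
  for (n1 in 2:6) for (n2 in 2:min(n1, 12 - n1)) {
    lab <- c(rep("C", n1), rep("R", n2))
    for (robs in c(2L, 3L, min(n1, n2) + 2L)) {
      p_exact <- sum(vapply(2:robs, igcscan:::.runs_pmf, numeric(1),
                            n1 = n1, n2 = n2))
      expect_equal(p_exact, enum_p(n1, n2, robs), tolerance = 1e-12,
                   info = sprintf("n1=%d n2=%d r=%d", n1, n2, robs))
    }
  }
  expect_error(runs_test(rep("C", 10)), "degenerate")
})

test_that("normal approximation tracks the exact runs distribution", {
  # quantify the z-approximation error across all small label multisets;
  # the exact/approximation cutover (n = 20) keeps the error under 0.05
  worst <- 0
  for (n1 in 5:10) for (n2 in 5:10) {
    n <- n1 + n2
    if (n < 18) next
    for (robs in seq(2L, n1 + n2, by = 3L)) {
      p_exact <- sum(vapply(2:robs, igcscan:::.runs_pmf, numeric(1),
                            n1 = n1, n2 = n2))
      e <- 1 + 2 * n1 * n2 / n
      v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
      p_norm <- pnorm((robs + 0.5 - e) / sqrt(v))
      worst <- max(worst, abs(p_exact - p_norm))
    }
  }
  expect_lt(worst, 0.05)
})

test_that("R-run spacing fractions match a direct recount", {
  q <- make_quartet_result(
    columns = c(10, 20, 30, 40, 100, 110, 500, 510, 520, 600),
    labels = c("C", "R", "R", "C", "R", "R", "C", "C", "R", "C"))
  sp <- r_run_spacing(q)
  # two qualifying runs (cols 20-30 and 100-110), nearest gaps 60 and 60 bp
  expect_equal(sp$n_runs, 2L)
  expect_equal(sp$fraction, 1.0)

  close_q <- make_quartet_result(columns = c(10, 20, 28, 36, 50),
                                 labels = c("R", "R", "R", "R", "C"))
  # single run, no neighboring R-run: counts as separated
  expect_equal(r_run_spacing(close_q)$fraction, 1.0)

  two_close <- make_quartet_result(columns = c(10, 20, 25, 28, 38),
                                   labels = c("R", "R", "C", "R", "R"))
  expect_equal(r_run_spacing(two_close)$fraction, 0.0)  # runs 8 bp apart

  # randomized fixtures against an independent recount
  set.seed(9)
  for (rep in 1:10) {
    n <- 40
    cols <- sort(sample(1:2000, n))
    labs <- sample(c("C", "R"), n, replace = TRUE, prob = c(0.7, 0.3))
    sp <- r_run_spacing(cols, labs)
    # oracle: explicit loop over runs
    rl <- rle(labs == "R")
    e <- cumsum(rl$lengths); s <- e - rl$lengths + 1
    ridx <- which(rl$values)
    if (!length(ridx) || !any(rl$lengths[ridx] >= 2)) {
      expect_true(is.na(sp$fraction))
      next
    }
    qual <- ridx[rl$lengths[ridx] >= 2]
    fr <- mean(vapply(qual, function(i) {
      oth <- setdiff(ridx, i)
      if (!length(oth)) return(TRUE)
      gaps <- vapply(oth, function(j) {
        if (s[j] > e[i]) cols[s[j]] - cols[e[i]] else cols[s[i]] - cols[e[j]]
      }, numeric(1))
      min(gaps) > 10
    }, logical(1)))
    expect_equal(sp$fraction, fr)
  }
})

test_that("detection power rises with the number of injected tracks", {
  rates <- vapply(c(0L, 3L, 10L), function(n_inj) {
    ps <- vapply(1:4, function(rep) {
      gspec <- family_gen_spec(n_paralogs = 4, length = 4000,
                               target_identity = 0.94,
                               seed = 1000 * n_inj + rep)
      g <- generate_null_family(gspec)
      fam <- g$fam
      nm <- rownames(fam$matrix)
      tree <- g$tree
      # inject between non-sister paralogs (tree is ((p1,p2),(p3,p4)) shaped
      # only by chance; use the realized topology)
      top <- induced_quartet_topology(tree, nm)
      non_sisters <- switch(top,
        "AB|CD" = list(c(1, 3), c(2, 4)),
        "AC|BD" = list(c(1, 2), c(3, 4)),
        "AD|BC" = list(c(1, 2), c(3, 4)))
      if (n_inj > 0) {
        starts <- round(seq(150, 3400, length.out = n_inj))
        for (k in seq_len(n_inj)) {
          pr <- non_sisters[[1 + (k %% 2)]]
          fam <- inject_gene_conversion(fam, nm[pr[1]], nm[pr[2]],
                                        starts[k], starts[k] + 300)$fam
        }
      }
      excess_test(fam, tree, gspec$model, n_boot = 40, n_sim = 40,
                  seed = 5 + rep)$p_value
    }, numeric(1))
    mean(ps <= 0.05)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], rates[1])
})
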