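# --- group summary / ddCt arithmetic -------------------------------------

test_that("group_summary reproduces the printed ddCt convention", {
  # two published rows force ddCt = mean_target - mean_calibrator
  ds <- make_ds(matrix(c(25.793, 25.793, 21.378, 21.378), 1), feats = "mir")
  tm <- treatment_map(sprintf("s%02d", 1:4), c("OLIGO", "OLIGO", "POLY", "POLY"))
  gs <- group_summary(ds, tm, "mir")
  expect_equal(gs$ddCt, 21.378 - 25.793)
  expect_equal(round(gs$ddCt, 3), -4.415)  # printed -4.414 from unrounded means
  expect_equal(gs$FC, 2^4.415, tolerance = 1e-12)

  expect_equal(fc_from_ddct(0), 1)
  expect_equal(fc_from_ddct(3.300, digits = 3), 0.102)
  expect_error(group_summary(make_ds(matrix(c(NA, NA, 1, 2), 1),
                                     feats = "mir"), tm, "mir"),
               "missing")
})

# --- t-test ---------------------------------------------------------------

test_that("Welch t-test matches the closed-form oracle", {
  ds <- make_ds(matrix(c(1, 2, 3, 4, 5, 6), 1), feats = "g")
  tm <- two_group_tm(3, 3)
  tab <- ttest_de(ds, tm, de_spec("ttest"))
  # oracle: Welch statistic and Welch-Satterthwaite df, closed form
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  se2 <- var(x) / 3 + var(y) / 3
  t_or <- (mean(x) - mean(y)) / sqrt(se2)
  df_or <- se2^2 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  p_or <- 2 * pt(-abs(t_or), df_or)
  expect_equal(tab$t.test, t_or, tolerance = 1e-12)
  expect_equal(tab$p.value, p_or, tolerance = 1e-12)
  expect_equal(t_or, -3.674235, tolerance = 1e-6)
  expect_equal(p_or, 0.02131164, tolerance = 1e-6)
})

test_that("degenerate zero-variance genes are reported, not fatal", {
  ds <- make_ds(rbind(c(5, 5, 5, 5), c(5, 5, 6, 6)), feats = c("eq", "sep"))
  tm <- two_group_tm(2, 2)
  tab <- ttest_de(ds, tm, de_spec("ttest"))
  expect_equal(tab[tab$genes == "eq", "t.test"], 0)
  expect_equal(tab[tab$genes == "eq", "p.value"], 1)
  expect_equal(tab[tab$genes == "sep", "p.value"], 0)
  expect_equal(attr(tab, "degenerate"), 2L)

  # paired with constant differences is the same degenerate path
  ds2 <- make_ds(matrix(c(1, 2, 2, 3), 1), feats = "g")
  tab2 <- ttest_de(ds2, two_group_tm(2, 2), de_spec("ttest", paired = TRUE))
  expect_equal(tab2$p.value, 0)  # differences constant = -1, nonzero
})

test_that("label swap flips signs and inverts FC but keeps two-sided p", {
  set.seed(91)
  ds <- make_ds(matrix(rnorm(40, 25), 5), feats = sprintf("g%d", 1:5))
  tm1 <- treatment_map(sprintf("s%02d", 1:8), rep(c("A", "B"), each = 4))
  # same group membership, but listing a B sample first makes B calibrator
  tm2 <- treatment_map(sprintf("s%02d", c(5:8, 1:4)),
                       rep(c("B", "A"), each = 4))
  t1 <- ttest_de(ds, tm1, de_spec("ttest"))
  t2 <- ttest_de(ds, tm2, de_spec("ttest"))
  t2 <- t2[match(t1$genes, t2$genes), ]
  expect_equal(t1$p.value, t2$p.value, tolerance = 1e-12)
  expect_equal(t1$t.test, -t2$t.test, tolerance = 1e-12)
  expect_equal(t1$ddCt, -t2$ddCt, tolerance = 1e-12)
  expect_equal(t1$FC, 1 / t2$FC, tolerance = 1e-12)
  # FC * 2^ddCt = 1 on every output row
  expect_equal(t1$FC * 2^t1$ddCt, rep(1, 5), tolerance = 1e-12)
})

# --- Wilcoxon -------------------------------------------------------------

test_that("Wilcoxon matches exhaustive rank enumeration at small n", {
  ds <- make_ds(matrix(c(1, 2, 3, 4, 5, 6), 1), feats = "g")
  tab <- wilcoxon_de(ds, two_group_tm(3, 3), de_spec("wilcoxon"))
  expect_equal(tab$W, 0)
  # oracle: enumerate all 20 assignments of ranks to the first group
  vals <- 1:6
  combos <- combn(6, 3)
  u_obs <- 0
  u_all <- apply(combos, 2, function(ix) {
    x <- vals[ix]; y <- vals[-ix]
    sum(outer(x, y, ">"))
  })
  p_or <- mean(u_all <= u_obs) * 2  # symmetric two-sided doubling
  expect_equal(tab$p.value, p_or)
  expect_equal(p_or, 0.1)

  # identical multisets: p = 1
  ds2 <- make_ds(matrix(c(1, 2, 1, 2), 1), feats = "g")
  tab2 <- wilcoxon_de(ds2, two_group_tm(2, 2), de_spec("wilcoxon"))
  expect_equal(tab2$p.value, 1)
})

test_that("large-shift Wilcoxon is significant under the normal approximation", {
  set.seed(92)
  x <- rnorm(10, 25, 0.5); y <- rnorm(10, 35, 0.5)
  ds <- make_ds(matrix(c(x, y), 1), feats = "g")
  tab <- wilcoxon_de(ds, two_group_tm(10, 10), de_spec("wilcoxon"))
  expect_lt(tab$p.value, 0.001)
})

# --- p-value adjustment & categories --------------------------------------

test_that("adjust_pvalues implements the step procedures and validates input", {
  # BH oracle: step-up of p * n / i
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)
  p <- c(0.001, 0.2, 0.04, 0.9)
  expect_identical(adjust_pvalues(p, "none"), p)
  for (m in c("BH", "BY", "holm", "bonferroni"))
    expect_true(all(adjust_pvalues(p, m) >= p))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("category aggregation: stringent = all OK, lenient = majority", {
  expect_identical(aggregate_category(c("OK", "OK", "OK"), TRUE), "OK")
  expect_identical(aggregate_category(c("OK", "OK", "OK"), FALSE), "OK")
  expect_identical(aggregate_category(c("OK", "Undetermined"), TRUE),
                   "Undetermined")
  expect_identical(aggregate_category(c("OK", "OK", "Undetermined"), FALSE),
                   "OK")
  expect_identical(aggregate_category(c("OK", "Undetermined"), FALSE),
                   "Undetermined")  # exactly half is not a majority
  expect_error(aggregate_category(character()), "empty")
})

test_that("replicated features collapse by per-sample mean before testing", {
  ds <- make_ds(rbind(c(10, 12, 20, 22), c(14, 16, 24, 26),
                      c(1, 1, 1, 1)),
                feats = c("dup", "dup", "other"))
  tm <- two_group_tm(2, 2)
  tab <- ttest_de(ds, tm, de_spec("ttest", replicates = TRUE))
  expect_equal(nrow(tab), 2L)
  row <- tab[tab$genes == "dup", ]
  expect_equal(row$meanCalibrator, mean(c(12, 14)))   # means of (10,14),(12,16)
  expect_equal(row$meanTarget, mean(c(22, 24)))
})

# --- rank product ---------------------------------------------------------

test_that("rank product basics: rank-1 gene, label-swap symmetry", {
  # gene 1 most up-regulated in target (lowest Ct difference) in every pair
  ct <- rbind(c(30, 30, 20, 20),
              c(25, 25, 24, 24),
              c(25, 25, 26, 26),
              c(25, 25, 25.5, 25.5))
  ds <- make_ds(ct)
  tm <- two_group_tm(2, 2)
  spec <- de_spec("rankprod", permutations = 50, seed = 5)
  tab <- rankprod_de(ds, tm, spec, exact = TRUE)
  det <- attr(tab, "rp_detail")
  expect_equal(det$RP_up[1], 1)          # geometric mean of all-1 ranks
  expect_equal(tab[tab$genes == "g01", "RP"], 1)

  tm_swap <- treatment_map(sprintf("s%02d", c(3, 4, 1, 2)),
                           c("B", "B", "A", "A"))
  det2 <- attr(rankprod_de(ds, tm_swap, spec, exact = TRUE), "rp_detail")
  expect_equal(det$RP_up, det2$RP_down)
  expect_equal(det$RP_down, det2$RP_up)
})

test_that("exact rank-product pfp equals exhaustive joint-permutation enumeration", {
  set.seed(101)
  ct <- matrix(rnorm(16, 25, 2), 4)
  ds <- make_ds(ct)
  tm <- two_group_tm(2, 2)
  tab <- rankprod_de(ds, tm, de_spec("rankprod", seed = 1), exact = TRUE)
  det <- attr(tab, "rp_detail")

  # oracle: enumerate ALL joint per-pair rank permutations ((4!)^4 = 331776)
  G <- 4; pairs <- expand.grid(i = 1:2, j = 3:4)
  d_obs <- sapply(seq_len(nrow(pairs)),
                  function(p) ct[, pairs$j[p]] - ct[, pairs$i[p]])
  rp_obs_up <- exp(rowMeans(log(apply(d_obs, 2, rank))))
  expect_equal(unname(rp_obs_up), det$RP_up)

  perms <- as.matrix(expand.grid(rep(list(1:factorial(G)), ncol(d_obs))))
  perm_tab <- perms_matrix(G)
  # log-rank lookup per pair: every permutation row is a rank assignment
  lr <- log(perm_tab)
  e_counts <- numeric(G)
  # accumulate E[#{g': RP* <= RP_g}] over the joint distribution by
  # enumerating the joint index space pair-by-pair (vectorized over genes)
  n_j <- nrow(perms)
  logrp_joint <- matrix(0, n_j, G)
  for (p in seq_len(ncol(d_obs)))
    logrp_joint <- logrp_joint + lr[perms[, p], , drop = FALSE]
  rp_joint <- exp(logrp_joint / ncol(d_obs))
  for (g in seq_len(G))
    e_counts[g] <- mean(rowSums(rp_joint <= rp_obs_up[g] + 1e-12))
  pfp_oracle <- e_counts / rank(rp_obs_up)
  expect_equal(det$pfp_up, unname(pfp_oracle), tolerance = 1e-12)
})

test_that("Monte Carlo pfp is reproducible under a fixed seed and close to exact", {
  set.seed(102)
  ct <- matrix(rnorm(5 * 5, 25, 1), 5)
  ct[1, 3:5] <- ct[1, 3:5] - 10
  ds <- make_ds(ct)
  tm <- two_group_tm(2, 3)
  spec <- de_spec("rankprod", permutations = 400, seed = 77)
  t1 <- rankprod_de(ds, tm, spec)
  t2 <- rankprod_de(ds, tm, spec)
  expect_identical(t1, t2)
  t_ex <- rankprod_de(ds, tm, spec, exact = TRUE)
  expect_equal(t1$p.value, t_ex$p.value[match(t1$genes, t_ex$genes)],
               tolerance = 0.15)
  # the spiked gene is the top hit
  expect_identical(t_ex$genes[1], "g01")
})

# --- dispatcher and output ------------------------------------------------

test_that("run_de dispatches; NONE yields an empty table with headers", {
  set.seed(103)
  ds <- make_ds(matrix(rnorm(24, 25), 4))
  tm <- two_group_tm(3, 3)
  tab <- run_de(ds, tm, de_spec("none"))
  expect_equal(nrow(tab), 0L)
  expect_true(all(c("genes", "p.value", "adj.p.value", "ddCt", "FC") %in%
                    names(tab)))
  tt <- run_de(ds, tm, de_spec("ttest"))
  # rows sorted by ascending p, standard column order
  expect_false(is.unsorted(tt$p.value))
  expect_identical(names(tt),
                   c("genes", "t.test", "p.value", "adj.p.value", "ddCt",
                     "FC", "meanCalibrator", "meanTarget",
                     "categoryCalibrator", "categoryTarget"))
  p <- tempfile(fileext = ".tsv")
  write_de_table(tt, p)
  back <- read.delim(p)
  expect_equal(back$p.value, tt$p.value, tolerance = 1e-6)
})
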