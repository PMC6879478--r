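test_that("spline_fill interpolates, extrapolates, and leaves observed values alone", {
  m <- rbind(c(10, NA, 14, 16),
             c(1, 2, 3, 4),
             c(NA, 5, 7, 9),
             c(NA, NA, NA, 2))
  out <- spline_fill(m)
  expect_equal(out[1, 2], 12)                      # collinear interior gap
  expect_equal(out[2, ], c(1, 2, 3, 4))            # complete row untouched
  expect_equal(out[3, 1], 3)                       # natural-spline lead fill
  expect_true(is.na(out[4, 1]))                    # <2 observed: flagged
  expect_identical(attr(out, "unfilled_rows"), 4L)
  # non-missing entries never altered
  expect_equal(out[!is.na(m)], m[!is.na(m)])
})

test_that("global mean centers every sample on zero, missing-aware", {
  ds <- make_ds(cbind(c(20, 22, 24), c(25, 25, 25), c(20, NA, 24)))
  out <- normalize_global_mean(ds)
  expect_equal(unname(out$ct[, 1]), c(-2, 0, 2))
  expect_equal(unname(out$ct[, 2]), c(0, 0, 0))
  expect_equal(unname(out$ct[, 3]), c(-2, NA, 2))
  expect_error(normalize_global_mean(make_ds(cbind(c(1, 2), c(NA, NA)))),
               "observed")
})

test_that("modified global mean uses the common-detected set", {
  # complete data: identical to global mean
  set.seed(1)
  ds <- make_ds(matrix(rnorm(20, 25), 5))
  expect_equal(normalize_modified_global_mean(ds)$ct,
               normalize_global_mean(ds)$ct)
  # hand-computed 2-feature case
  ds2 <- make_ds(cbind(c(20, 22), c(30, 32)))
  out <- normalize_modified_global_mean(ds2)
  expect_equal(unname(out$ct), cbind(c(-1, 1), c(-1, 1)))
  # a feature missing anywhere is excluded from every sample's reference
  ds3 <- make_ds(cbind(c(20, 22, 30), c(30, 32, NA)))
  out3 <- normalize_modified_global_mean(ds3)
  expect_equal(unname(out3$ct[1:2, 1]), c(-1, 1))   # mean over g1,g2 only
  expect_equal(unname(out3$ct[3, 1]), 30 - 21)
})

test_that("geNorm stability matches a brute-force pairwise computation", {
  set.seed(11)
  for (g in c(4L, 7L, 10L)) {
    m <- matrix(rnorm(g * 10, 25, 2), g)
    rep_ <- genorm_stability(m)
    # independent brute force: explicit scalar double loop over pairs
    M_oracle <- numeric(g)
    for (j in seq_len(g)) {
      acc <- 0
      for (k in seq_len(g)) {
        if (k == j) next
        d <- m[j, ] - m[k, ]
        acc <- acc + sqrt(sum((d - mean(d))^2) / (length(d) - 1))
      }
      M_oracle[j] <- acc / (g - 1)
    }
    expect_equal(unname(rep_$scores), M_oracle, tolerance = 1e-12)
  }
})

test_that("geNorm behaviour: constant offsets, added noise, cutoff direction", {
  set.seed(12)
  n <- 20
  base <- rnorm(n, 25, 1)
  m <- rbind(A = base, B = base + 2, C = base + rnorm(n, 0, 1.5))
  rep_ <- genorm_stability(m)
  # A and B differ by a constant: V_AB = 0, so M_A = M_B < M_C
  expect_equal(sd((m["A", ] - m["B", ])), 0)
  expect_equal(rep_$scores[["A"]], rep_$scores[["B"]])
  expect_gt(rep_$scores[["C"]], rep_$scores[["A"]])
  # identical features: all M = 0, all selected
  m0 <- rbind(base, base, base)
  r0 <- genorm_stability(m0)
  expect_equal(unname(r0$scores), c(0, 0, 0))
  expect_length(r0$selected, 3L)
  # direction override
  r_above <- genorm_stability(m, cutoff = 0.5, direction = "above")
  expect_true(all(r_above$scores[r_above$selected] > 0.5))
  expect_error(genorm_stability(m[1:2, ]), "3 features")
})

test_that("NormFinder matches an independent scalar-loop oracle", {
  set.seed(21)
  G <- 5L; n1 <- 4L; n2 <- 4L
  tm <- treatment_map(sprintf("s%02d", 1:8), rep(c("A", "B"), each = 4))
  m <- matrix(rnorm(G * 8, 25, 1), G,
              dimnames = list(paste0("g", 1:G), tm$sample_names))
  m[2, 5:8] <- m[2, 5:8] + 3   # gene with a large fixed group offset
  rep_ <- normfinder_stability(m, tm)

  # oracle: direct scalar-loop implementation of the model-based estimator
  grp <- list(1:4, 5:8)
  z <- m
  for (j in 1:8) z[, j] <- m[, j] - mean(m[, j])
  d_hat <- s2 <- se2 <- matrix(0, G, 2)
  for (i in 1:2) {
    for (g in 1:G) {
      zi <- z[g, grp[[i]]]
      d_hat[g, i] <- mean(zi)
      s2[g, i] <- sum((zi - mean(zi))^2) / (length(zi) - 1)
    }
    mbar <- mean(s2[, i])
    for (g in 1:G)
      s2[g, i] <- max(0, (s2[g, i] - mbar / (G - 1)) * G / (G - 2))
    se2[, i] <- s2[, i] / length(grp[[i]])
  }
  for (g in 1:G) d_hat[g, ] <- d_hat[g, ] - mean(d_hat[g, ])
  rho_or <- numeric(G)
  for (i in 1:2) {
    var_d <- max(0, sum(d_hat[, i]^2) / (G - 1) - mean(se2[, i]))
    for (g in 1:G) {
      gam <- if (var_d + se2[g, i] > 0) var_d / (var_d + se2[g, i]) else 0
      rho_or[g] <- rho_or[g] + (abs(d_hat[g, i] * gam) + sqrt(se2[g, i])) / 2
    }
  }
  expect_equal(unname(rep_$scores), rho_or, tolerance = 1e-12)
  # the offset gene ranks worse than every no-offset gene
  expect_identical(names(which.max(rep_$scores)), "g2")
})

test_that("NormFinder: perfectly stable gene ranks first; duplicates tie", {
  set.seed(22)
  tm <- treatment_map(sprintf("s%02d", 1:8), rep(c("A", "B"), each = 4))
  m <- matrix(rnorm(4 * 8, 25, 1), 4,
              dimnames = list(paste0("g", 1:4), tm$sample_names))
  m <- rbind(m, stable = colMeans(m))  # equals the sample mean of all 5 genes
  # check construction: row "stable" == per-sample mean across the 5 genes
  expect_equal(unname(m["stable", ]), unname(colMeans(m)))
  rep_ <- normfinder_stability(m, tm)
  expect_identical(rep_$selected, "stable")
  expect_equal(rep_$scores[["stable"]], 0)

  m2 <- m[c(1, 1, 2, 3, 4), ]
  r2 <- normfinder_stability(m2, tm)
  expect_equal(r2$scores[[1]], r2$scores[[2]])
})

test_that("delta-Ct normalization zeroes housekeepers and honors selectors", {
  set.seed(31)
  ds <- make_ds(matrix(rnorm(40, 25, 2), 10))
  # single housekeeper: its row becomes exactly 0
  r <- normalize_deltact(ds, housekeepers = "g03")
  expect_equal(unname(r$dataset$ct[3, ]), rep(0, 4))
  # two housekeepers: reference is their mean
  ds2 <- make_ds(rbind(c(20, 21), c(30, 29), c(26, 27)),
                 feats = c("hk1", "hk2", "x"))
  r2 <- normalize_deltact(ds2, housekeepers = c("hk1", "hk2"))
  expect_equal(unname(r2$dataset$ct[, 1]), c(20, 30, 26) - 25)
  # a housekeeper missing in one sample drops out of that sample's mean
  ds3 <- make_ds(rbind(c(20, NA), c(30, 28), c(26, 27)),
                 feats = c("hk1", "hk2", "x"))
  r3 <- normalize_deltact(ds3, housekeepers = c("hk1", "hk2"))
  expect_equal(unname(r3$dataset$ct[3, 2]), 27 - 28)
  expect_error(normalize_deltact(ds, housekeepers = "nope"), "absent")
})

test_that("geNorm selector picks the engineered stable genes", {
  # shift-dominated panel: per-sample technical shifts cancel in pairwise
  # differences, so M reflects only the per-gene noise (small for the
  # stable genes, large for the rest)
  set.seed(32)
  n <- 12
  shift <- rnorm(n, 0, 2)
  gene <- function(mu, sd) mu + shift + rnorm(n, 0, sd)
  m <- rbind(stable0 = gene(24, 0.05), stable1 = gene(26, 0.05),
             stable2 = gene(28, 0.05),
             t(vapply(1:6, function(i) gene(20 + i, 1.6), numeric(n))))
  rownames(m)[4:9] <- sprintf("noisy%d", 1:6)
  ds <- make_ds(m, feats = rownames(m))
  r <- normalize_deltact(ds, selector = "genorm", genorm_cutoff = 1.5)
  expect_true(all(c("stable0", "stable1", "stable2") %in%
                    r$stability$selected))
  expect_true(all(r$stability$scores[r$stability$selected] < 1.5))
  expect_true(all(r$stability$scores[c("stable0", "stable1", "stable2")] <
                    min(r$stability$scores[sprintf("noisy%d", 1:6)])))
})

test_that("quantile normalization: hand-computed case and permutation property", {
  ds <- make_ds(cbind(c(1, 2, 3), c(4, 5, 6)))
  out <- normalize_quantile(ds)
  expect_equal(unname(out$ct), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))

  # identical multisets in any order map to the same sorted reference
  ds2 <- make_ds(cbind(c(3, 1, 2), c(1, 2, 3)))
  out2 <- normalize_quantile(ds2)
  expect_equal(unname(sort(out2$ct[, 1])), unname(sort(out2$ct[, 2])))
  expect_equal(unname(sort(out2$ct[, 1])), c(1, 2, 3))

  # single distinct value per column: every entry = mean of the constants
  ds3 <- make_ds(cbind(c(10, 10), c(20, 20)))
  expect_equal(unname(normalize_quantile(ds3)$ct),
               matrix(15, 2, 2))

  # missing positions preserved; complete columns identical when sorted
  set.seed(41)
  ct <- matrix(rnorm(50, 25, 3), 10)
  ct[c(3, 17, 42)] <- NA
  ds4 <- make_ds(ct)
  out4 <- normalize_quantile(ds4)
  expect_equal(is.na(out4$ct), is.na(ct), ignore_attr = TRUE)
})

test_that("rank-invariant scale mode removes constant shifts exactly", {
  set.seed(51)
  base <- sort(rnorm(40, 25, 3))
  shifts <- c(0, 1.5, -2, 0.7)
  ct <- outer(base, shifts, `+`)
  ds <- make_ds(ct)
  out <- normalize_rank_invariant(ds, "scale")
  for (j in 2:4) expect_equal(out$ct[, 1], out$ct[, j], ignore_attr = TRUE)

  # identical samples: both modes are the identity
  ds_id <- make_ds(matrix(rep(base, 3), ncol = 3))
  expect_equal(normalize_rank_invariant(ds_id, "scale")$ct, ds_id$ct,
               tolerance = 1e-8)
  expect_equal(normalize_rank_invariant(ds_id, "norm")$ct, ds_id$ct,
               tolerance = 1e-8)
})

test_that("strongly shifted features are excluded from the invariant set", {
  set.seed(52)
  n_feat <- 100; n_de <- 20
  base <- rnorm(n_feat, 25, 3)
  ct <- outer(base, c(0, 0.5, -0.5, 1), `+`) +
    matrix(rnorm(n_feat * 4, 0, 0.02), ncol = 4)
  # spike mid-rank features so the spike must reorder them (a spiked
  # feature already at the extreme could be rank-invariant by accident)
  de_rows <- order(base)[41:60]
  ct[de_rows, 3:4] <- ct[de_rows, 3:4] +
    6 * rep_len(c(1, -1), n_de)
  ds <- make_ds(ct)
  ref <- rowMeans(ds$ct)
  inv3 <- ctpipe:::invariant_set(ref, ds$ct[, 3])
  expect_true(length(inv3) >= 5)
  expect_length(intersect(inv3, de_rows), 0L)
})

test_that("all normalizations preserve missingness and per-sample locality where stated", {
  set.seed(61)
  # shift-dominated data so the rank-invariant sets are large
  ct <- outer(rnorm(60, 25, 3), c(0, 0.8, -0.5, 0.3, 1.1), `+`) +
    matrix(rnorm(300, 0, 0.05), 60)
  ct[c(2, 75, 133, 258)] <- NA
  ds <- make_ds(ct)
  na_pattern <- is.na(ct)
  for (f in list(normalize_global_mean, normalize_modified_global_mean,
                 normalize_quantile,
                 function(d) normalize_rank_invariant(d, "scale"),
                 function(d) normalize_rank_invariant(d, "norm"),
                 function(d) normalize_deltact(d, "g05")$dataset)) {
    out <- f(ds)
    expect_equal(is.na(out$ct), na_pattern, ignore_attr = TRUE)
  }
  # per-sample locality: shifting one column leaves the others' output alone
  ds_shift <- ds
  ds_shift$ct[, 2] <- ds_shift$ct[, 2] + 5
  for (f in list(normalize_global_mean, normalize_modified_global_mean,
                 function(d) normalize_deltact(d, "g05")$dataset)) {
    expect_equal(f(ds)$ct[, -2], f(ds_shift)$ct[, -2])
  }
})

test_that("normalize_ct dispatcher routes and reports stability", {
  set.seed(62)
  ds <- make_ds(matrix(rnorm(40, 25, 2), 10))
  r <- normalize_ct(ds, normalization_spec("global_mean"))
  expect_null(r$stability)
  expect_equal(r$dataset$ct, normalize_global_mean(ds)$ct)
  r2 <- normalize_ct(ds, normalization_spec("deltact", housekeepers = "g01"))
  expect_identical(r2$stability$selected, "g01")
  expect_error(normalization_spec("deltact"), "housekeepers")
})
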