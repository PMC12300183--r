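# Abundance pipeline: group merging, channel QC, scaling, normalization,
# S0 permutation-FDR significance, clustering.

test_that("protein-group rows merge by element-wise summation", {
  m <- matrix(c(10, 20, 30, 5,
                1, NA, 3, 4), ncol = 2,
              dimnames = list(c("p1", "p2", "p3", "p4"), c("c1", "c2")))
  out <- merge_protein_groups(m, c(p1 = "G", p2 = "G", p3 = "G"))
  expect_equal(nrow(out), 2)
  expect_equal(out["G", "c1"], 60)
  expect_equal(out["G", "c2"], 4)        # missing member treated as 0
  expect_equal(out["p4", "c1"], 5)
  # all members missing -> merged cell missing
  m2 <- matrix(c(1, 2, NA, NA), 2, dimnames = list(c("a", "b"), c("c1", "c2")))
  out2 <- merge_protein_groups(m2, c(a = "G", b = "G"))
  expect_true(is.na(out2["G", "c2"]))
  # absent members are skipped with a warning; empty map is identity
  expect_warning(out3 <- merge_protein_groups(m, c(p1 = "G", zz = "G")),
                 "absent")
  expect_equal(out3["G", "c1"], 10)
  expect_identical(merge_protein_groups(m, character(0)), m)
})

test_that("an 18-member group reduces the row count by 17", {
  m <- matrix(runif(25 * 3), 25, 3,
              dimnames = list(sprintf("p%02d", 1:25), c("a", "b", "c")))
  gm <- setNames(rep("LHCII", 18), sprintf("p%02d", 1:18))
  out <- merge_protein_groups(m, gm)
  expect_equal(nrow(out), 25 - 17)
  expect_true("LHCII" %in% rownames(out))
})

test_that("channel QC drops dim or hole-riddled channels", {
  set.seed(2)
  n <- 40
  base <- runif(n, 50, 150)
  m <- cbind(c1 = base * 1e8 / sum(base) / 1,
             c2 = base * 9e7 / sum(base),
             c3 = base * 1.2e8 / sum(base),
             c4 = base * 5e5 / sum(base))
  rownames(m) <- paste0("p", 1:n)
  qc <- qc_channels(m)
  expect_equal(qc$dropped, "c4")         # median-other/own = 1e8/5e5 = 200
  expect_equal(qc$report$ratio_vs_median[4], 200, tolerance = 1e-9)
  # missingness rule alone also drops
  m2 <- cbind(c1 = base, c2 = base, c3 = replace(base, 1:24, NA))
  qc2 <- qc_channels(m2, ratio_threshold = 1e9, missing_frac = 0.5)
  expect_equal(qc2$dropped, "c3")
  expect_match(qc2$report$reason[3], "missing")
  # balanced channels: none dropped
  qc3 <- qc_channels(cbind(c1 = base, c2 = base * 1.1))
  expect_equal(qc3$dropped, character(0))
  expect_error(qc_channels(cbind(c1 = base * 0, c2 = base * 0)), "every channel")
})

test_that("global scaling equalizes channel totals and is idempotent", {
  m <- matrix(c(40, 60, 110, 90, 230, 170), 2,
              dimnames = list(c("p1", "p2"), c("a", "b", "c")))
  # totals 100, 200, 400 -> all 233.333...
  sc <- scale_channels(m)
  tot <- colSums(sc)
  expect_equal(unname(tot), rep(700 / 3, 3), tolerance = 1e-12)
  expect_equal(max(abs(tot - mean(tot))) / mean(tot), 0, tolerance = 1e-9)
  expect_equal(unname(attr(scale_channels(matrix(c(1, 2), 1,
                dimnames = list("p", c("a", "b")))), "scaling_factors")),
               c(1.5, 0.75))
  # idempotence
  sc2 <- scale_channels(sc)
  expect_equal(unclass(sc2), unclass(sc), tolerance = 1e-9,
               ignore_attr = TRUE)
  # already-equal totals: identity factors
  eq <- matrix(c(1, 2, 2, 1), 2, dimnames = list(c("p1", "p2"), c("a", "b")))
  expect_equal(unname(attr(scale_channels(eq), "scaling_factors")), c(1, 1))
  expect_error(scale_channels(cbind(a = c(0, 0), b = c(1, 2))), "zero total")
})

test_that("log2 centering gives zero-mean channels and handles zeros", {
  m <- matrix(c(4, 8, 16), 3, 1, dimnames = list(paste0("p", 1:3), "a"))
  lc <- log2_and_center(m)
  expect_equal(unname(lc[, 1]), c(-1, 0, 1))
  single <- log2_and_center(matrix(5, 1, 1, dimnames = list("p", "a")))
  expect_equal(unname(single[1, 1]), 0)
  set.seed(3)
  m2 <- matrix(rlnorm(200), 40, 5,
               dimnames = list(paste0("p", 1:40), paste0("c", 1:5)))
  m2[1, 1] <- 0
  lc2 <- log2_and_center(m2)
  expect_true(is.na(lc2[1, 1]))
  expect_true(all(abs(colMeans(lc2, na.rm = TRUE)) < 1e-12))
  med <- log2_and_center(m2, center = "median")
  expect_true(all(abs(apply(med, 2, median, na.rm = TRUE)) < 1e-12))
})

test_that("centered differences are invariant to per-channel scale factors", {
  set.seed(8)
  m <- matrix(rlnorm(60 * 6, log(1e5), 1), 60, 6,
              dimnames = list(paste0("p", 1:60), paste0("c", 1:6)))
  gr <- list(HT = c("c1", "c2", "c3"), LT = c("c4", "c5", "c6"))
  run <- function(x) {
    norm <- log2_and_center(scale_channels(x))
    differential_abundance(norm, gr, s0 = 1, seed = 1)$table$diff
  }
  fac <- runif(6, 0.2, 5)
  expect_equal(run(m), run(sweep(m, 2, fac, `*`)), tolerance = 1e-9)
})

test_that("with s0 = 0 the moderated statistic is the plain t and flags match exhaustive enumeration", {
  set.seed(12)
  X <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(paste0("p", 1:20), paste0("c", 1:6)))
  X[1:3, 1:3] <- X[1:3, 1:3] + 4      # three strong effects
  gr <- list(A = paste0("c", 1:3), B = paste0("c", 4:6))
  da <- differential_abundance(X, gr, s0 = 0, target_fdr = 0.05,
                               n_perm = 1000, seed = 1)
  expect_true(da$exhaustive)
  expect_equal(da$n_perm_used, choose(6, 3))
  expect_equal(da$table$d, da$table$t, tolerance = 1e-12)
  oracle <- oracle_perm_flags(X, 3, s0 = 0, target_fdr = 0.05)
  expect_identical(da$table$significant, unname(oracle))
})

test_that("permutation machinery is reproducible and capped at distinct assignments", {
  set.seed(30)
  X <- matrix(rnorm(50 * 12), 50, 12,
              dimnames = list(paste0("p", 1:50), paste0("c", 1:12)))
  gr <- list(A = paste0("c", 1:6), B = paste0("c", 7:12))
  d1 <- differential_abundance(X, gr, n_perm = 100, seed = 9)
  d2 <- differential_abundance(X, gr, n_perm = 100, seed = 9)
  expect_identical(d1$fdr_curve, d2$fdr_curve)
  expect_equal(d1$n_perm_used, 100)
  expect_false(d1$exhaustive)
})

test_that("plain-t p-values are uniform under the null (KS test)", {
  set.seed(77)
  X <- matrix(rnorm(1000 * 9), 1000, 9,
              dimnames = list(paste0("p", 1:1000), paste0("c", 1:9)))
  gr <- list(A = paste0("c", 1:4), B = paste0("c", 5:9))
  da <- differential_abundance(X, gr, n_perm = 50, seed = 1)
  ks <- ks.test(da$table$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("row-wise t matches stats::t.test including missing values", {
  set.seed(14)
  X <- matrix(rnorm(30 * 9), 30, 9,
              dimnames = list(paste0("p", 1:30), paste0("c", 1:9)))
  X[2, 1:2] <- NA
  gr <- list(A = paste0("c", 1:4), B = paste0("c", 5:9))
  da <- differential_abundance(X, gr, n_perm = 20, seed = 2)
  for (i in c(1, 2, 30)) {
    ref <- t.test(X[i, 1:4], X[i, 5:9], var.equal = TRUE)
    expect_equal(da$table$p[i], ref$p.value, tolerance = 1e-12)
    expect_equal(da$table$diff[i],
                 unname(ref$estimate[1] - ref$estimate[2]), tolerance = 1e-12)
  }
  # a protein observed once in a group is excluded, not tested
  X[5, 1:3] <- NA
  da2 <- differential_abundance(X, gr, n_perm = 20, seed = 2)
  expect_true(is.na(da2$table$p[5]))
  expect_false(da2$table$significant[5])
  expect_gte(da2$n_excluded, 1)
})

test_that("hierarchical clustering recovers the strain partition", {
  set.seed(19)
  X <- cbind(matrix(rnorm(200 * 4, 1), 200, 4),
             matrix(rnorm(200 * 5, -1), 200, 5))
  dimnames(X) <- list(paste0("p", 1:200),
                      c(paste0("ht", 1:4), paste0("lt", 1:5)))
  cl <- hierarchical_cluster(X)
  part <- cl$partition
  expect_true(all(part[1:4] == part[["ht1"]]))
  expect_true(all(part[5:9] == part[["lt1"]]))
  expect_false(part[["ht1"]] == part[["lt1"]])
  # Z-scored rows have mean 0 and sd 1
  expect_true(all(abs(rowMeans(cl$z)) < 1e-12))
  expect_true(all(abs(apply(cl$z, 1, sd) - 1) < 1e-12))
  # leaf orders are permutations
  expect_setequal(cl$col_order, seq_len(ncol(X)))
  expect_setequal(cl$row_order, seq_len(nrow(cl$z)))
})

test_that("identical columns collapse at height zero and constant rows are dropped", {
  # without row scaling, identical columns merge at height 0
  X <- matrix(rep(c(1, 5, 2, 7), 3), 4, 3,
              dimnames = list(paste0("p", 1:4), paste0("c", 1:3)))
  cl <- hierarchical_cluster(X, scale_rows = FALSE)
  expect_true(all(cl$col_tree$height == 0))
  # with row scaling, a constant row cannot be Z-scored and is dropped
  set.seed(4)
  Y <- matrix(rnorm(12), 4, 3,
              dimnames = list(paste0("p", 1:4), paste0("c", 1:3)))
  Y <- rbind(Y, p5 = c(3, 3, 3))
  expect_warning(cl2 <- hierarchical_cluster(Y), "constant")
  expect_equal(cl2$n_dropped_rows, 1)
  expect_false("p5" %in% rownames(cl2$z))
})
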