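# Redox pipeline: PSM roll-up, stoichiometry, replicate filtering,
# strain comparison and replicate correlations.

redox_design_2rep <- function() {
  data.frame(
    channel_id = c("i126_r1", "i127_r1", "i130_r1", "i131_r1",
                   "i126_r2", "i127_r2", "i130_r2", "i131_r2"),
    strain = rep(c("HT", "LT", "HT", "LT"), 2),
    replicate = rep(1:2, each = 4),
    role = rep(c("reduced", "reduced",
                 "oxidized-complement", "oxidized-complement"), 2),
    stringsAsFactors = FALSE)
}

test_that("PSM roll-up sums per protein and channel, missing-aware", {
  d <- data.frame(channel_id = c("a", "b"), strain = "HT", replicate = 1L,
                  role = "abundance")
  psms <- data.frame(protein_id = c("p1", "p1", "p2", "p3"),
                     peptide_id = paste0("pep", 1:4),
                     run_id = "r1",
                     a = c(100, 200, 7, NA),
                     b = c(50, NA, 9, NA))
  m <- aggregate_psms(psms, d)
  expect_equal(m["p1", "a"], 300)
  expect_equal(m["p1", "b"], 50)          # sum over remaining PSMs
  expect_equal(m["p2", ], c(a = 7, b = 9))
  expect_true(all(is.na(m["p3", ])))      # all contributors missing
  counts <- attr(m, "psm_counts")
  expect_equal(unname(counts["p1", ]), c(2, 1))
  empty <- aggregate_psms(psms[0, ], d)
  expect_equal(nrow(empty), 0)
})

test_that("stoichiometry is light over total with boundary and missing rules", {
  d <- redox_design_2rep()[1:4, ]
  m <- matrix(c(75, 30, 0, 50,    # light HT, light LT
                25, 70, 50, 0),   # heavy HT, heavy LT
              nrow = 4, byrow = FALSE,
              dimnames = list(c("p1", "p2", "p3", "p4"),
                              c("i126_r1", "i130_r1")))
  # build a full 4-channel matrix: LT channels mirror HT values
  full <- cbind(`i126_r1` = c(75, 30, 0, 50), `i127_r1` = c(75, 30, 0, 50),
                `i130_r1` = c(25, 70, 50, 0), `i131_r1` = c(25, 70, 50, 0))
  rownames(full) <- c("p1", "p2", "p3", "p4")
  rt <- compute_stoichiometry(full, d)
  expect_equal(rt$stoich_HT_r1, c(0.75, 0.30, 0.0, 1.0))
  expect_equal(rt$stoich_LT_r1, c(0.75, 0.30, 0.0, 1.0))
  # both channels missing, or total zero -> missing
  full2 <- cbind(`i126_r1` = c(NA, 0), `i127_r1` = c(1, 1),
                 `i130_r1` = c(NA, 0), `i131_r1` = c(1, 1))
  rownames(full2) <- c("q1", "q2")
  rt2 <- compute_stoichiometry(full2, d)
  expect_true(all(is.na(rt2$stoich_HT_r1)))
  # one label missing counts as a zero sum
  full3 <- cbind(`i126_r1` = c(NA, 60), `i127_r1` = c(1, 1),
                 `i130_r1` = c(40, NA), `i131_r1` = c(1, 1))
  rownames(full3) <- c("q1", "q2")
  rt3 <- compute_stoichiometry(full3, d)
  expect_equal(rt3$stoich_HT_r1, c(0, 1))
})

test_that("stoichiometry requires a redox design", {
  d <- data.frame(channel_id = c("a", "b"), strain = c("HT", "LT"),
                  replicate = 1L, role = "abundance")
  m <- matrix(1, 1, 2, dimnames = list("p1", c("a", "b")))
  expect_error(compute_stoichiometry(m, d), "redox")
})

test_that("replicate-presence filter keeps proteins seen in enough replicates", {
  tab <- data.frame(protein_id = c("p1", "p2", "p3"),
                    stoich_HT_r1 = c(0.1, 0.2, NA),
                    stoich_HT_r2 = c(0.1, NA, NA),
                    stoich_HT_r3 = c(0.1, 0.2, 0.3),
                    stoich_HT_r4 = c(0.1, NA, 0.3),
                    stoich_LT_r1 = c(0.1, 0.2, 0.3),
                    stoich_LT_r2 = c(0.1, 0.2, 0.3),
                    stoich_LT_r3 = c(0.1, 0.2, 0.3),
                    stoich_LT_r4 = c(0.1, NA, NA))
  tab$n_reps_HT <- rowSums(!is.na(tab[grep("HT", names(tab))]))
  tab$n_reps_LT <- rowSums(!is.na(tab[grep("LT", names(tab))]))
  class(tab) <- c("redox_table", "data.frame")
  kept <- filter_by_replicate_presence(tab, 3)
  expect_equal(kept$protein_id, "p1")      # p2: 2 HT reps; p3: 2 HT reps
  expect_equal(nrow(filter_by_replicate_presence(tab, 0)), 3)
  expect_error(filter_by_replicate_presence(tab, 5), "exceeds")
})

test_that("fold change of strain means matches direct arithmetic", {
  # a protein averaging 0.28 (HT) and 0.37 (LT) has FC(of means) 0.7568
  full <- cbind(`i126_r1` = 28, `i127_r1` = 37, `i130_r1` = 72, `i131_r1` = 63)
  rownames(full) <- "p1"
  rt <- compute_stoichiometry(full, redox_design_2rep()[1:4, ])
  expect_equal(round(rt$fc_of_means, 4), 0.7568)
  expect_equal(round(rt$fc, 4), 0.7568)    # single replicate: same value
})

test_that("identical strains give FC 1 and a no-shift global test", {
  set.seed(1)
  s <- matrix(runif(20, 0.2, 0.8), 5, 4)
  tab <- data.frame(protein_id = paste0("p", 1:5))
  for (r in 1:4) tab[[sprintf("stoich_HT_r%d", r)]] <- s[, r]
  for (r in 1:4) tab[[sprintf("stoich_LT_r%d", r)]] <- s[, r]
  tab$n_reps_HT <- tab$n_reps_LT <- 4L
  tab$mean_HT <- tab$mean_LT <- rowMeans(s)
  tab$fc <- rowMeans(s / s)
  tab$fc_of_means <- 1
  class(tab) <- c("redox_table", "data.frame")
  cmp <- redox_comparison(tab)
  expect_true(all(cmp$table$fc == 1))
  expect_match(cmp$global$note, "no shift")
  expect_true(is.na(cmp$global$p))
  expect_equal(cmp$fc_summary$frac_below_1, 0)
})

test_that("per-protein tests are homoscedastic t-tests with BH adjustment", {
  set.seed(42)
  n <- 40
  H <- matrix(rnorm(n * 4, 0.3, 0.05), n)
  L <- matrix(rnorm(n * 4, 0.4, 0.05), n)
  tab <- data.frame(protein_id = paste0("p", 1:n))
  for (r in 1:4) tab[[sprintf("stoich_HT_r%d", r)]] <- H[, r]
  for (r in 1:4) tab[[sprintf("stoich_LT_r%d", r)]] <- L[, r]
  tab$n_reps_HT <- tab$n_reps_LT <- 4L
  tab$mean_HT <- rowMeans(H); tab$mean_LT <- rowMeans(L)
  tab$fc <- rowMeans(H / L); tab$fc_of_means <- tab$mean_HT / tab$mean_LT
  class(tab) <- c("redox_table", "data.frame")
  cmp <- redox_comparison(tab)
  ref <- t.test(H[1, ], L[1, ], var.equal = TRUE)
  expect_equal(cmp$table$p[1], ref$p.value, tolerance = 1e-12)
  expect_equal(cmp$table$q, p.adjust(cmp$table$p, "BH"))
  expect_true(all(cmp$table$q >= cmp$table$p, na.rm = TRUE))
  # global paired test agrees with stats::t.test
  ref_g <- t.test(tab$mean_HT, tab$mean_LT, paired = TRUE)
  expect_equal(cmp$global$t, unname(ref_g$statistic), tolerance = 1e-12)
})

test_that("a zero-variance protein gets a missing per-protein p", {
  tab <- data.frame(protein_id = "p1",
                    stoich_HT_r1 = 0.3, stoich_HT_r2 = 0.3,
                    stoich_LT_r1 = 0.4, stoich_LT_r2 = 0.4,
                    n_reps_HT = 2L, n_reps_LT = 2L,
                    mean_HT = 0.3, mean_LT = 0.4,
                    fc = 0.75, fc_of_means = 0.75)
  class(tab) <- c("redox_table", "data.frame")
  cmp <- redox_comparison(tab)
  expect_true(is.na(cmp$table$p))
})

test_that("noiseless end-to-end stoichiometry equals the simulated truth", {
  cfg <- sim_config(n_proteins = 50, n_replicates_redox = 3,
                    peptide_factor_sd = 0.4, noise_cv = 0,
                    missing_rate = 0, seed = 21)
  truth <- simulate_ground_truth(cfg)
  sim <- simulate_iodotmt_psms(truth, cfg)
  rt <- compute_stoichiometry(aggregate_psms(sim$psms, sim$design), sim$design)
  expect_equal(rt$mean_HT, truth$red_frac_ht[match(rt$protein_id, truth$protein_id)],
               tolerance = 1e-12)
  expect_equal(rt$mean_LT, truth$red_frac_lt[match(rt$protein_id, truth$protein_id)],
               tolerance = 1e-12)
  expect_true(all(rt$fc > 0, na.rm = TRUE))
})

test_that("defined stoichiometries always lie in [0, 1] (property)", {
  for (seed in 1:5) {
    cfg <- sim_config(n_proteins = 60, noise_cv = 0.3, missing_rate = 0.2,
                      seed = seed)
    truth <- simulate_ground_truth(cfg)
    sim <- simulate_iodotmt_psms(truth, cfg)
    rt <- compute_stoichiometry(aggregate_psms(sim$psms, sim$design),
                                sim$design)
    vals <- unlist(rt[grep("^stoich_", names(rt))])
    vals <- vals[!is.na(vals)]
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("fraction with FC < 1 equals its brute-force count", {
  s <- make_small_sim(n = 120, seed = 17)
  sim <- simulate_iodotmt_psms(s$truth, s$cfg)
  rt <- compute_stoichiometry(aggregate_psms(sim$psms, sim$design), sim$design)
  cmp <- redox_comparison(rt)
  fc <- rt$fc[!is.na(rt$fc)]
  expect_equal(cmp$fc_summary$frac_below_1, sum(fc < 1) / length(fc))
  expect_equal(sum(cmp$fc_hist$count), length(fc))
})

test_that("replicate correlations match the textbook formula", {
  set.seed(5)
  x <- rnorm(100); y <- 0.7 * x + rnorm(100, sd = 0.4)
  m <- cbind(a = x, b = y, c = -x)
  rc <- replicate_correlation(m)
  expect_equal(rc$r["a", "b"], oracle_pearson(x, y), tolerance = 1e-12)
  expect_equal(rc$r["a", "c"], -1)
  expect_equal(diag(rc$r), c(a = 1, b = 1, c = 1))
  expect_equal(rc$r, t(rc$r))
  # zero-variance column yields missing correlations
  m2 <- cbind(a = x, b = rep(1, 100))
  rc2 <- replicate_correlation(m2)
  expect_true(is.na(rc2$r["a", "b"]))
  expect_equal(diag(rc2$r), c(a = 1, b = 1))
})
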