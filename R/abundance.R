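# TMT differential protein abundance: group merging, channel QC, global
# scaling, log2 mean-centering, S0-moderated permutation-FDR significance
# calling and hierarchical clustering.

#' Merge protein groups into single matrix rows
#'
#' Sums the rows of all member proteins of each group element-wise into a
#' single row named after the group (e.g. collapsing the many
#' chlorophyll a/b-binding LHCII entries to one line before analysis).
#' Within a cell, missing member values count as 0 when at least one
#' member has a value; the cell is missing only when every member is.
#'
#' @param mat protein x channel matrix.
#' @param group_map named character vector protein_id -> group id, or a
#'   data.frame with columns protein_id, group_id.  Members absent from
#'   the matrix are skipped with a warning; an empty map is the identity.
#' @return matrix with member rows replaced by group rows (sorted row
#'   names); merged member ids are kept in attribute `"merged_members"`.
#' @export
merge_protein_groups <- function(mat, group_map) {
  if (is.data.frame(group_map))
    group_map <- stats::setNames(group_map$group_id, group_map$protein_id)
  if (length(group_map) == 0) return(mat)
  absent <- setdiff(names(group_map), rownames(mat))
  if (length(absent)) {
    warning(sprintf("%d group member(s) absent from the matrix were skipped",
                    length(absent)), call. = FALSE)
    group_map <- group_map[setdiff(names(group_map), absent)]
    if (length(group_map) == 0) return(mat)
  }
  groups <- split(names(group_map), unname(group_map))
  members_all <- unlist(groups, use.names = FALSE)
  keep <- !(rownames(mat) %in% members_all)
  rows <- lapply(names(groups), function(g) {
    sub <- mat[groups[[g]], , drop = FALSE]
    any_obs <- colSums(!is.na(sub)) > 0
    s <- colSums(sub, na.rm = TRUE)
    s[!any_obs] <- NA_real_
    s
  })
  grows <- do.call(rbind, rows)
  rownames(grows) <- names(groups)
  out <- rbind(mat[keep, , drop = FALSE], grows)
  out <- out[order(rownames(out)), , drop = FALSE]
  attr(out, "merged_members") <- groups
  out
}

#' Channel quality control
#'
#' Drops a channel when the median of the other channels' summed
#' intensities is at least `ratio_threshold` times its own (a channel two
#' orders of magnitude dimmer than its peers at the default 100), or when
#' more than `missing_frac` of its protein values are missing.
#'
#' @param mat protein x channel matrix.
#' @param ratio_threshold minimum (median other total) / (own total) ratio
#'   that triggers a drop.
#' @param missing_frac maximum tolerated fraction of missing values.
#' @return list with `kept` (the reduced matrix), `dropped` (channel ids)
#'   and `report` (per-channel totals, missing fractions, ratios, reason).
#' @export
qc_channels <- function(mat, ratio_threshold = 100, missing_frac = 0.5) {
  if (ncol(mat) < 2) stopf("channel QC needs at least two channels")
  totals <- colSums(mat, na.rm = TRUE)
  missf <- colMeans(is.na(mat))
  ratio <- vapply(seq_along(totals), function(j) {
    med <- stats::median(totals[-j])
    if (totals[j] == 0) Inf else med / totals[j]
  }, numeric(1))
  low <- ratio >= ratio_threshold
  holey <- missf > missing_frac
  drop <- low | holey
  reason <- rep("", length(drop))
  reason[low] <- "low total intensity"
  reason[holey & !low] <- "excess missingness"
  reason[holey & low] <- "low total intensity; excess missingness"
  report <- data.frame(channel = colnames(mat), total = unname(totals),
                       missing_frac = unname(missf),
                       ratio_vs_median = unname(ratio),
                       dropped = unname(drop), reason = reason,
                       stringsAsFactors = FALSE)
  if (all(drop)) stopf("channel QC would drop every channel")
  list(kept = mat[, !drop, drop = FALSE],
       dropped = colnames(mat)[drop],
       report = report)
}

#' Scale channels to equal total intensity
#'
#' Multiplies each channel by (grand mean of channel totals) / (its own
#' total) so that all channel totals are equal afterwards; the operation
#' is idempotent.
#'
#' @param mat protein x channel matrix (post-QC; no zero-total channels).
#' @return scaled matrix with the factors in attribute
#'   `"scaling_factors"`.
#' @export
scale_channels <- function(mat) {
  totals <- colSums(mat, na.rm = TRUE)
  if (any(totals == 0))
    stopf("channel(s) with zero total intensity: %s (drop them in QC first)",
          paste(colnames(mat)[totals == 0], collapse = ", "))
  fac <- mean(totals) / totals
  out <- sweep(mat, 2, fac, `*`)
  attr(out, "scaling_factors") <- fac
  out
}

#' Log2 transform and per-channel centering
#'
#' Zeros become missing before the log (log2(0) is undefined); each
#' channel is then centered by subtracting its mean (or median) over the
#' proteins with defined values.
#'
#' @param mat strictly nonnegative intensity matrix.
#' @param center "mean" (default) or "median".
#' @return normalized log2 matrix; per-channel centers in attribute
#'   `"centers"`.
#' @export
log2_and_center <- function(mat, center = c("mean", "median")) {
  center <- match.arg(center)
  if (any(mat < 0, na.rm = TRUE)) stopf("negative intensities cannot be logged")
  mat[mat == 0] <- NA_real_
  lg <- log2(mat)
  ctr <- apply(lg, 2, if (center == "mean") function(x) mean(x, na.rm = TRUE)
               else function(x) stats::median(x, na.rm = TRUE))
  out <- sweep(lg, 2, ctr, `-`)
  attr(out, "centers") <- ctr
  out
}

#' @noRd
permutation_assignments <- function(n, n1, n_perm, seed) {
  total <- choose(n, n1)
  if (total <= n_perm) {
    asn <- utils::combn(n, n1, simplify = FALSE)
    attr(asn, "exhaustive") <- TRUE
    return(asn)
  }
  with_seed(seed, {
    seen <- new.env(hash = TRUE)
    asn <- vector("list", n_perm)
    got <- 0L
    while (got < n_perm) {
      cand <- sort(sample.int(n, n1))
      key <- paste(cand, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        got <- got + 1L
        asn[[got]] <- cand
      }
    }
    attr(asn, "exhaustive") <- FALSE
    asn
  })
}

#' S0-moderated differential abundance with permutation FDR
#'
#' For each protein on the normalized log2 matrix: the group-mean
#' difference `diff = mean(group1) - mean(group2)`, the pooled
#' (homoscedastic) standard error `s`, the plain Student t and p, and the
#' SAM-style moderated statistic `d = diff / (s + s0)` whose fudge factor
#' `s0` damps the significance of low-variance, low-effect proteins.
#'
#' Significance is decided by group-label permutation: for every distinct
#' balanced relabeling of the columns (all of them when there are at most
#' `n_perm`, otherwise `n_perm` sampled without replacement) the |d|
#' statistics are recomputed, and for each candidate threshold c on the
#' observed |d| values the false discovery rate is estimated as
#' (mean permutation count of |d| >= c) / (observed count of |d| >= c).
#' The FDR curve is made monotone non-increasing in c before thresholding;
#' proteins are flagged at the smallest c whose smoothed FDR is at or
#' below `target_fdr`.  Plain-t Benjamini-Hochberg q-values are also
#' reported for cross-checking.
#'
#' @param mat normalized log2 matrix (proteins x samples).
#' @param groups named list of two character vectors of column names,
#'   e.g. `list(HT = ..., LT = ...)`; a reference channel simply stays out
#'   of both groups.
#' @param s0 fudge factor added to the standard error (0 recovers the
#'   plain t statistic).
#' @param target_fdr permutation FDR at which proteins are flagged.
#' @param n_perm maximum number of distinct label permutations.
#' @param seed seed for permutation sampling.
#' @return list of class `abundance_result`: `table` (per-protein
#'   statistics, `significant` flags, `fold_change = 2^diff`), `d_threshold`,
#'   `fdr_curve`, `n_perm_used`, `exhaustive`, `n_excluded`, `groups`.
#' @export
differential_abundance <- function(mat, groups, s0 = 1, target_fdr = 0.02,
                                   n_perm = 250, seed = 1L) {
  if (length(groups) != 2 || is.null(names(groups)))
    stopf("groups must be a named list of two channel-id vectors")
  g1 <- groups[[1]]; g2 <- groups[[2]]
  miss <- setdiff(c(g1, g2), colnames(mat))
  if (length(miss)) stopf("matrix lacks group column(s): %s",
                          paste(miss, collapse = ", "))
  if (length(g1) < 2 || length(g2) < 2)
    stopf("need at least two samples per group")
  if (s0 < 0) stopf("s0 must be >= 0")
  X <- mat[, c(g1, g2), drop = FALSE]
  n1 <- length(g1); n2 <- length(g2); n <- n1 + n2

  obs <- row_ttest(X[, seq_len(n1), drop = FALSE],
                   X[, n1 + seq_len(n2), drop = FALSE])
  testable <- obs$n1 >= 2 & obs$n2 >= 2 & !is.na(obs$se)
  d <- ifelse(testable, obs$diff / (obs$se + s0), NA_real_)
  if (s0 == 0) d <- ifelse(testable & obs$se > 0, obs$diff / obs$se, NA_real_)

  asn <- permutation_assignments(n, n1, n_perm, seed)
  B <- length(asn)
  perm_abs <- numeric(0)
  for (idx1 in asn) {
    pt <- row_ttest(X[, idx1, drop = FALSE],
                    X[, setdiff(seq_len(n), idx1), drop = FALSE])
    pd <- ifelse(pt$n1 >= 2 & pt$n2 >= 2 & !is.na(pt$se),
                 pt$diff / (pt$se + s0), NA_real_)
    if (s0 == 0) pd <- ifelse(pt$se > 0, pt$diff / pt$se, NA_real_)
    perm_abs <- c(perm_abs, abs(pd[!is.na(pd)]))
  }
  perm_sorted <- sort(perm_abs)

  obs_abs <- abs(d[testable & !is.na(d)])
  cand <- sort(unique(obs_abs))
  obs_sorted <- sort(obs_abs)
  n_obs_ge <- length(obs_sorted) -
    findInterval(cand, obs_sorted, left.open = TRUE)
  mean_perm_ge <- (length(perm_sorted) -
    findInterval(cand, perm_sorted, left.open = TRUE)) / B
  fdr_raw <- pmin(mean_perm_ge / n_obs_ge, 1)
  fdr <- rev(cummax(rev(fdr_raw)))  # monotone non-increasing in c
  fdr_curve <- data.frame(threshold = cand, n_obs_ge = n_obs_ge,
                          mean_perm_ge = mean_perm_ge,
                          fdr_raw = fdr_raw, fdr = fdr)

  hit <- which(fdr <= target_fdr)
  d_threshold <- if (length(hit)) cand[hit[1]] else Inf
  significant <- !is.na(d) & abs(d) >= d_threshold
  perm_fdr <- rep(NA_real_, nrow(X))
  ok <- !is.na(d)
  perm_fdr[ok] <- fdr[match(abs(d[ok]), cand)]

  tbl <- data.frame(protein_id = rownames(mat),
                    n_1 = obs$n1, n_2 = obs$n2,
                    mean_1 = obs$mean1, mean_2 = obs$mean2,
                    diff = obs$diff, fold_change = 2^obs$diff,
                    se = obs$se, t = obs$t, p = obs$p,
                    q_bh = bh_adjust(obs$p),
                    d = d, perm_fdr = perm_fdr,
                    significant = significant,
                    stringsAsFactors = FALSE)
  names(tbl)[names(tbl) == "n_1"] <- paste0("n_", names(groups)[1])
  names(tbl)[names(tbl) == "n_2"] <- paste0("n_", names(groups)[2])
  names(tbl)[names(tbl) == "mean_1"] <- paste0("mean_", names(groups)[1])
  names(tbl)[names(tbl) == "mean_2"] <- paste0("mean_", names(groups)[2])

  structure(list(table = tbl, d_threshold = d_threshold,
                 fdr_curve = fdr_curve, n_perm_used = B,
                 exhaustive = isTRUE(attr(asn, "exhaustive")),
                 n_excluded = sum(!testable), groups = groups,
                 s0 = s0, target_fdr = target_fdr),
            class = "abundance_result")
}

#' Hierarchical clustering of the expression matrix
#'
#' Rows are Z-scored (mean 0, sd 1); constant or near-empty rows are
#' dropped with a warning.  Rows and columns are clustered with Euclidean
#' distance and average linkage, and the column tree is cut into `k`
#' groups (2 recovers a strain partition when the strains separate).
#'
#' @param mat normalized matrix (proteins x samples).
#' @param k number of column clusters to cut.
#' @param scale_rows Z-score rows before clustering (default); set FALSE
#'   to cluster the matrix as-is (constant rows are then allowed).
#' @return list of class `cluster_result`: `z` (Z-scored matrix),
#'   `row_tree`, `col_tree` (hclust), `row_order`, `col_order`,
#'   `partition` (named column membership), `n_dropped_rows`.
#' @export
hierarchical_cluster <- function(mat, k = 2, scale_rows = TRUE) {
  rm_ <- rowMeans(mat, na.rm = TRUE)
  nobs <- rowSums(!is.na(mat))
  rsd <- sqrt(rowSums((mat - rm_)^2, na.rm = TRUE) / pmax(nobs - 1, 1))
  bad <- if (scale_rows) nobs < 2 | rsd == 0 | is.na(rsd) else nobs < 1
  if (any(bad))
    warning(sprintf("%d constant or near-empty row(s) dropped before clustering",
                    sum(bad)), call. = FALSE)
  if (sum(!bad) < 2) stopf("fewer than two usable rows for clustering")
  z <- if (scale_rows)
    (mat[!bad, , drop = FALSE] - rm_[!bad]) / rsd[!bad]
  else mat[!bad, , drop = FALSE]
  col_tree <- stats::hclust(stats::dist(t(z)), method = "average")
  row_tree <- stats::hclust(stats::dist(z), method = "average")
  partition <- stats::cutree(col_tree, k = min(k, ncol(z)))
  structure(list(z = z, row_tree = row_tree, col_tree = col_tree,
                 row_order = row_tree$order, col_order = col_tree$order,
                 partition = partition, n_dropped_rows = sum(bad)),
            class = "cluster_result")
}
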