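# Cysteine redox stoichiometry from differential iodoTMT labeling.
#
# Per protein and replicate the stoichiometry is the fraction of cysteines
# that were reduced in vivo: summed light-label intensity divided by the
# summed intensity of both labels (reduced / total).  Lower values mean a
# more oxidized protein.

#' Roll PSM intensities up to a protein x channel matrix
#'
#' Sums reporter intensities over all PSMs matched to each protein,
#' ignoring missing entries; a cell is missing only if no contributing PSM
#' had a value.  The number of PSM values summed into each cell is kept as
#' attribute `"psm_counts"`.
#'
#' @param psms PSM table (see [read_psm_table()] / the simulators).
#' @param design channel design; its channels define the columns.
#' @return numeric matrix, rows = proteins (sorted ids), columns = channels.
#' @export
aggregate_psms <- function(psms, design) {
  validate_channel_design(design)
  chans <- design$channel_id
  miss <- setdiff(chans, names(psms))
  if (length(miss))
    stopf("PSM table lacks channel column(s): %s", paste(miss, collapse = ", "))
  if (nrow(psms) == 0) {
    m <- matrix(numeric(0), nrow = 0, ncol = length(chans),
                dimnames = list(NULL, chans))
    attr(m, "psm_counts") <- m
    return(m)
  }
  pid <- factor(psms$protein_id, levels = sort(unique(psms$protein_id)))
  vals <- as.matrix(psms[chans])
  present <- !is.na(vals)
  vals[!present] <- 0
  sums <- rowsum(vals, pid)
  counts <- rowsum(present + 0L, pid)
  sums[counts == 0] <- NA_real_
  attr(sums, "psm_counts") <- counts
  sums
}

#' Compute per-replicate redox stoichiometries
#'
#' For every (strain, replicate) pair the stoichiometry is
#' light / (light + heavy) on the protein-level summed intensities
#' (ratio of sums within a replicate).  A value is missing when both label
#' channels are missing or the total is zero; a single missing label is
#' treated as a zero sum (no PSM observed).  Strain means are
#' mean-of-replicate-ratios; the per-protein fold change `fc` is the mean
#' of per-replicate HT/LT ratios and `fc_of_means` the ratio of strain
#' means.
#'
#' @param mat protein x channel matrix from [aggregate_psms()].
#' @param design a redox channel design.
#' @return data.frame of class `redox_table`: protein_id, one
#'   `stoich_<strain>_r<rep>` column per sample, replicate-presence counts
#'   `n_reps_HT` / `n_reps_LT`, strain means, `fc`, `fc_of_means`.
#' @export
compute_stoichiometry <- function(mat, design) {
  validate_channel_design(design, type = "redox")
  samp <- design[design$strain %in% c("HT", "LT"), ]
  keys <- unique(samp[c("strain", "replicate")])
  keys <- keys[order(keys$strain, keys$replicate), ]

  out <- data.frame(protein_id = rownames(mat), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(keys))) {
    st <- keys$strain[i]; rp <- keys$replicate[i]
    sel <- samp$strain == st & samp$replicate == rp
    lch <- samp$channel_id[sel & samp$role == "reduced"]
    hch <- samp$channel_id[sel & samp$role == "oxidized-complement"]
    L <- mat[, lch]; H <- mat[, hch]
    L0 <- ifelse(is.na(L), 0, L)
    H0 <- ifelse(is.na(H), 0, H)
    tot <- L0 + H0
    s <- ifelse((is.na(L) & is.na(H)) | tot == 0, NA_real_, L0 / tot)
    out[[sprintf("stoich_%s_r%d", st, rp)]] <- s
  }
  ht_cols <- grep("^stoich_HT_", names(out), value = TRUE)
  lt_cols <- grep("^stoich_LT_", names(out), value = TRUE)
  H <- as.matrix(out[ht_cols]); L <- as.matrix(out[lt_cols])
  out$n_reps_HT <- rowSums(!is.na(H))
  out$n_reps_LT <- rowSums(!is.na(L))
  mh <- rowMeans(H, na.rm = TRUE); mh[out$n_reps_HT == 0] <- NA_real_
  ml <- rowMeans(L, na.rm = TRUE); ml[out$n_reps_LT == 0] <- NA_real_
  out$mean_HT <- mh
  out$mean_LT <- ml

  # per-replicate ratios, matched by replicate number
  reps_ht <- as.integer(sub("^stoich_HT_r", "", ht_cols))
  reps_lt <- as.integer(sub("^stoich_LT_r", "", lt_cols))
  common <- intersect(reps_ht, reps_lt)
  if (length(common)) {
    ratios <- vapply(common, function(r) {
      h <- out[[sprintf("stoich_HT_r%d", r)]]
      l <- out[[sprintf("stoich_LT_r%d", r)]]
      ifelse(!is.na(h) & !is.na(l) & l > 0, h / l, NA_real_)
    }, numeric(nrow(out)))
    ratios <- matrix(ratios, nrow = nrow(out))
    fc <- rowMeans(ratios, na.rm = TRUE)
    fc[!is.finite(fc)] <- NA_real_
    out$fc <- fc
  } else {
    out$fc <- NA_real_
  }
  out$fc_of_means <- ifelse(!is.na(mh) & !is.na(ml) & ml > 0, mh / ml, NA_real_)
  class(out) <- c("redox_table", "data.frame")
  out
}

#' Filter proteins by replicate presence
#'
#' Retains proteins with at least `min_reps` defined stoichiometries in
#' each strain.  Keep the unfiltered table too: distribution statistics
#' are typically reported on both the full and the filtered sets.
#'
#' @param table a `redox_table`.
#' @param min_reps minimum defined replicates per strain (0 = identity).
#' @return the filtered `redox_table`.
#' @export
filter_by_replicate_presence <- function(table, min_reps = 3) {
  n_avail <- min(length(grep("^stoich_HT_", names(table))),
                 length(grep("^stoich_LT_", names(table))))
  if (min_reps > n_avail)
    stopf("min_reps (%d) exceeds the number of replicates (%d)",
          min_reps, n_avail)
  keep <- table$n_reps_HT >= min_reps & table$n_reps_LT >= min_reps
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("redox_table", "data.frame")
  out
}

#' Strain-level redox comparison statistics
#'
#' Computes (a) a global two-tailed paired t-test across proteins on the
#' (HT mean, LT mean) stoichiometry pairs, with p-value underflow reported
#' as a floor label, never 0; (b) per-protein two-tailed homoscedastic
#' t-tests on the replicate stoichiometries with Benjamini-Hochberg
#' adjustment (proteins with zero variance in both strains get a missing
#' p); (c) distribution summaries per strain and for the fold change
#' (mean, sd, median, fraction of proteins with FC < 1) plus histogram bin
#' counts of the fold change.
#'
#' @param table a `redox_table` (filtered or not).
#' @param fc_column which fold-change column feeds the summaries:
#'   `"fc"` (mean of per-replicate ratios, default) or `"fc_of_means"`.
#' @param hist_binwidth fold-change histogram bin width.
#' @return list of class `redox_comparison`: `table` (input plus `p`, `q`),
#'   `global` (t, df, p, p_label, note), `strain_summary`, `fc_summary`,
#'   `fc_hist`.
#' @export
redox_comparison <- function(table, fc_column = c("fc", "fc_of_means"),
                             hist_binwidth = 0.1) {
  fc_column <- match.arg(fc_column)
  ht_cols <- grep("^stoich_HT_", names(table), value = TRUE)
  lt_cols <- grep("^stoich_LT_", names(table), value = TRUE)
  H <- as.matrix(table[ht_cols]); L <- as.matrix(table[lt_cols])

  tt <- row_ttest(H, L)
  table$p <- tt$p
  table$q <- bh_adjust(tt$p)

  pairs_ok <- !is.na(table$mean_HT) & !is.na(table$mean_LT)
  x <- table$mean_HT[pairs_ok]; y <- table$mean_LT[pairs_ok]
  d <- x - y
  global <- list(n = length(d), t = NA_real_, df = NA_real_,
                 p = NA_real_, p_label = NA_character_, note = NA_character_)
  if (length(d) >= 2) {
    if (stats::sd(d) == 0) {
      if (all(d == 0)) {
        global$note <- "no shift: all paired differences are zero"
      } else {
        global$t <- sign(mean(d)) * Inf
        global$df <- length(d) - 1
        global$p <- 0
        global$p_label <- format_pvalue(0)
        global$note <- "zero variance of nonzero paired differences"
      }
    } else {
      ht <- stats::t.test(x, y, paired = TRUE)
      global$t <- unname(ht$statistic)
      global$df <- unname(ht$parameter)
      global$p <- ht$p.value
      global$p_label <- format_pvalue(ht$p.value)
    }
  } else {
    global$note <- "fewer than two complete (HT, LT) pairs"
  }

  strain_summary <- data.frame(
    strain = c("HT", "LT"),
    n = c(sum(!is.na(table$mean_HT)), sum(!is.na(table$mean_LT))),
    mean = c(mean(table$mean_HT, na.rm = TRUE), mean(table$mean_LT, na.rm = TRUE)),
    sd = c(stats::sd(table$mean_HT, na.rm = TRUE), stats::sd(table$mean_LT, na.rm = TRUE)))

  fc <- table[[fc_column]]
  fc_def <- fc[!is.na(fc)]
  fc_summary <- list(column = fc_column,
                     n = length(fc_def),
                     mean = mean(fc_def),
                     sd = stats::sd(fc_def),
                     median = stats::median(fc_def),
                     frac_below_1 = mean(fc_def < 1))
  if (length(fc_def)) {
    top <- max(1, ceiling(max(fc_def) / hist_binwidth)) * hist_binwidth
    breaks <- seq(0, top, by = hist_binwidth)
    h <- graphics::hist(fc_def, breaks = breaks, plot = FALSE)
    fc_hist <- data.frame(bin_lo = h$breaks[-length(h$breaks)],
                          bin_hi = h$breaks[-1], count = h$counts)
  } else {
    fc_hist <- data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                          count = integer(0))
  }

  structure(list(table = table, global = global,
                 strain_summary = strain_summary,
                 fc_summary = fc_summary, fc_hist = fc_hist),
            class = "redox_comparison")
}

#' Pairwise Pearson correlations between replicate columns
#'
#' @param x a `redox_table` (its stoichiometry columns are used) or a
#'   numeric matrix with one column per replicate/sample.
#' @param include_pairs also return the long-format scatter data for
#'   multi-scatter plots.
#' @return list with `r` (symmetric Pearson matrix, diagonal 1; pairs
#'   involving a zero-variance column are NA) and, if requested, `pairs`
#'   (data.frame col_x, col_y, x, y over pairwise-complete rows).
#' @export
replicate_correlation <- function(x, include_pairs = FALSE) {
  if (inherits(x, "redox_table")) {
    cols <- grep("^stoich_", names(x), value = TRUE)
    m <- as.matrix(x[cols])
  } else {
    m <- as.matrix(x)
  }
  if (ncol(m) < 2) stopf("need at least two columns to correlate")
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  diag(r) <- 1
  out <- list(r = r)
  if (include_pairs) {
    cn <- colnames(m)
    pairs <- list()
    for (i in seq_len(ncol(m) - 1)) for (j in (i + 1):ncol(m)) {
      ok <- !is.na(m[, i]) & !is.na(m[, j])
      if (any(ok))
        pairs[[length(pairs) + 1]] <- data.frame(
          col_x = cn[i], col_y = cn[j], x = m[ok, i], y = m[ok, j],
          stringsAsFactors = FALSE)
    }
    out$pairs <- do.call(rbind, pairs)
  }
  out
}
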