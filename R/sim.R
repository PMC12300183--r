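# Synthetic two-strain isobaric-labeling experiments with known ground truth.
#
# Two designs are emulated at the PSM (peptide-spectrum match) level:
#   * iodoTMT differential cysteine labeling: per replicate, one 4-channel
#     plex carrying light (reduced) and heavy (oxidized-complement) labels
#     for a high-toxin (HT) and a low-toxin (LT) strain;
#   * an 11-plex TMT abundance experiment: 5 HT + 5 LT sample channels and
#     a pooled reference channel, optionally with one degenerate
#     low-intensity channel that the QC stage is expected to drop.

#' Simulation configuration for the two-strain generator
#'
#' Defaults reproduce the study conditions the pipeline is validated
#' against: per-protein reduced cysteine fractions Beta-distributed with
#' mean 0.28 / sd 0.15 in the high-toxin strain and mean 0.37 / sd 0.19 in
#' the low-toxin strain; differentially abundant proteins with |log2 fold
#' change| spanning log2(1.7) to log2(18); and a degenerate TMT channel two
#' orders of magnitude dimmer than its peers with half its values missing.
#'
#' @param n_proteins number of simulated proteins.
#' @param n_replicates_redox biological replicates per strain in the
#'   iodoTMT design (one 4-channel plex per replicate).
#' @param n_replicates_abundance samples per strain in the TMT design
#'   (2 to 5; channels follow the 11-plex reagent layout).
#' @param psm_mean,psm_dispersion mean and negative-binomial dispersion
#'   (size) of the per-protein peptide/PSM count; counts are 1 + NB so every
#'   protein has at least one peptide.
#' @param peptide_factor_sd log-scale sd of the per-peptide ionization
#'   efficiency factor (log-normal); 0 gives identical peptides.
#' @param noise_cv coefficient of variation of the multiplicative
#'   log-normal measurement noise applied independently per PSM x channel.
#' @param missing_rate probability that a PSM x channel intensity is
#'   missing (missing completely at random).
#' @param dap_fraction fraction of proteins with a true abundance change.
#' @param dap_up_fraction fraction of those that are up in HT.
#' @param log2fc_range length-2 numeric, magnitude range of true log2 fold
#'   changes (uniform).
#' @param redox_mean_ht,redox_sd_ht,redox_mean_lt,redox_sd_lt moments of
#'   the Beta laws for true reduced fractions; must satisfy
#'   sd^2 < mean * (1 - mean).
#' @param paired_redox if TRUE, draw LT from its Beta law and set
#'   HT = r * LT with log(r) normal (median `fc_pairing_median`, sd
#'   `fc_pairing_sigma`), truncated to (0, 1]; if FALSE the two strains are
#'   drawn independently.
#' @param fc_pairing_median,fc_pairing_sigma median and log-scale sd of the
#'   per-protein HT/LT stoichiometry ratio in paired mode.
#' @param channel_loading_sd log-scale sd of per-channel loading factors in
#'   the TMT design (what global scaling must undo); 0 disables.
#' @param degenerate_channel NULL, or a list with elements `channel`,
#'   `attenuation`, `extra_missing` describing one failing TMT channel.
#' @param annotation_scheme list of term specs, each a list with `term`,
#'   `size` (member count), `dap_bias` in \[0, 1\] (0 = members drawn at
#'   random, 1 = members drawn from the up-in-HT differential proteins) and
#'   optionally `within` (a parent term its members also receive).
#' @param merge_group_size if > 0, that many proteins share the merge key
#'   "LHCII" and are meant to be summed to a single row before abundance
#'   analysis (antenna-protein style row merging).
#' @param seed integer seed; the ground truth uses `seed`, the iodoTMT
#'   tables `seed + 1`, the TMT tables `seed + 2`, so each stage is
#'   individually reproducible.
#' @return a validated list of class `sim_config`.
#' @seealso [simulate_ground_truth()], [simulate_iodotmt_psms()],
#'   [simulate_tmt_psms()]
#' @export
sim_config <- function(n_proteins = 2000,
                       n_replicates_redox = 4,
                       n_replicates_abundance = 5,
                       psm_mean = 4,
                       psm_dispersion = 2,
                       peptide_factor_sd = 0.5,
                       noise_cv = 0.1,
                       missing_rate = 0.05,
                       dap_fraction = 0.2,
                       dap_up_fraction = 0.45,
                       log2fc_range = c(log2(1.7), log2(18)),
                       redox_mean_ht = 0.28, redox_sd_ht = 0.15,
                       redox_mean_lt = 0.37, redox_sd_lt = 0.19,
                       paired_redox = FALSE,
                       fc_pairing_median = 0.78,
                       fc_pairing_sigma = 0.1,
                       channel_loading_sd = 0.2,
                       degenerate_channel = list(channel = "129N",
                                                 attenuation = 0.01,
                                                 extra_missing = 0.5),
                       annotation_scheme = default_annotation_scheme(),
                       merge_group_size = 0,
                       seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_replicates_redox = as.integer(n_replicates_redox),
              n_replicates_abundance = as.integer(n_replicates_abundance),
              psm_mean = psm_mean, psm_dispersion = psm_dispersion,
              peptide_factor_sd = peptide_factor_sd,
              noise_cv = noise_cv, missing_rate = missing_rate,
              dap_fraction = dap_fraction,
              dap_up_fraction = dap_up_fraction,
              log2fc_range = log2fc_range,
              redox_mean_ht = redox_mean_ht, redox_sd_ht = redox_sd_ht,
              redox_mean_lt = redox_mean_lt, redox_sd_lt = redox_sd_lt,
              paired_redox = isTRUE(paired_redox),
              fc_pairing_median = fc_pairing_median,
              fc_pairing_sigma = fc_pairing_sigma,
              channel_loading_sd = channel_loading_sd,
              degenerate_channel = degenerate_channel,
              annotation_scheme = annotation_scheme,
              merge_group_size = as.integer(merge_group_size),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' @noRd
validate_sim_config <- function(cfg) {
  if (cfg$n_proteins < 1) stopf("n_proteins must be >= 1")
  if (cfg$n_replicates_redox < 1) stopf("n_replicates_redox must be >= 1")
  if (cfg$n_replicates_abundance < 2 || cfg$n_replicates_abundance > 5)
    stopf("n_replicates_abundance must be between 2 and 5 (11-plex layout)")
  for (fld in c("missing_rate", "dap_fraction", "dap_up_fraction")) {
    v <- cfg[[fld]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stopf("%s must be a rate in [0, 1]", fld)
  }
  if (cfg$noise_cv < 0) stopf("noise_cv must be >= 0")
  if (cfg$psm_mean < 1) stopf("psm_mean must be >= 1")
  if (cfg$psm_dispersion <= 0) stopf("psm_dispersion must be > 0")
  if (length(cfg$log2fc_range) != 2 || cfg$log2fc_range[1] > cfg$log2fc_range[2] ||
      cfg$log2fc_range[1] < 0)
    stopf("log2fc_range must be nonnegative (min, max) magnitudes")
  beta_shapes(cfg$redox_mean_ht, cfg$redox_sd_ht)  # errors if infeasible
  beta_shapes(cfg$redox_mean_lt, cfg$redox_sd_lt)
  if (cfg$fc_pairing_median <= 0) stopf("fc_pairing_median must be > 0")
  if (cfg$fc_pairing_sigma < 0) stopf("fc_pairing_sigma must be >= 0")
  dc <- cfg$degenerate_channel
  if (!is.null(dc)) {
    if (!all(c("channel", "attenuation", "extra_missing") %in% names(dc)))
      stopf("degenerate_channel needs fields channel, attenuation, extra_missing")
    if (dc$attenuation <= 0 || dc$extra_missing < 0 || dc$extra_missing > 1)
      stopf("degenerate_channel parameters out of range")
  }
  invisible(cfg)
}

#' Beta shape parameters from (mean, sd) moments
#'
#' @param mean,sd target moments; feasibility requires sd^2 < mean*(1-mean).
#' @return named numeric c(alpha, beta).
#' @export
beta_shapes <- function(mean, sd) {
  if (mean <= 0 || mean >= 1) stopf("Beta mean must lie in (0, 1)")
  v <- sd^2
  if (v <= 0 || v >= mean * (1 - mean))
    stopf("infeasible Beta moments: need 0 < sd^2 < mean*(1-mean) [mean=%g, sd=%g]",
          mean, sd)
  nu <- mean * (1 - mean) / v - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Default annotation scheme: COG-like letters plus a biased PKS subset
#'
#' The Q_PKS term emulates a polyketide-synthase subset of the secondary
#' metabolite category Q whose members are preferentially drawn from
#' proteins truly more abundant in the high-toxin strain; its 48 members
#' mirror the size of a realistic PKS family in a dinoflagellate dataset.
#' @return list of term specifications, see [sim_config()].
#' @export
default_annotation_scheme <- function() {
  list(
    list(term = "A", size = 120, dap_bias = 0),
    list(term = "C", size = 200, dap_bias = 0),
    list(term = "T", size = 150, dap_bias = 0),
    list(term = "Q", size = 130, dap_bias = 0.5),
    list(term = "Q_PKS", size = 48, dap_bias = 0.8, within = "Q")
  )
}

#' @noRd
assign_annotation_terms <- function(n, is_up_dap, scheme) {
  terms <- vector("list", n)
  base_rate <- mean(is_up_dap)
  for (spec in scheme) {
    size <- min(spec$size, n)
    p_up <- base_rate + spec$dap_bias * (1 - base_rate)
    up_pool <- which(is_up_dap)
    other_pool <- which(!is_up_dap)
    n_up <- min(stats::rbinom(1, size, p_up), length(up_pool))
    n_other <- min(size - n_up, length(other_pool))
    members <- c(sample_idx(up_pool, n_up), sample_idx(other_pool, n_other))
    add <- c(spec$term, spec$within)
    for (i in members) terms[[i]] <- c(terms[[i]], add)
  }
  vapply(terms, function(x) paste(unique(x), collapse = ";"), character(1))
}

#' Simulate per-protein ground truth for both experiments
#'
#' Draws, for each protein: a base abundance (log-normal, arbitrary
#' intensity units), a true log2 fold change HT-LT (0 for non-differential
#' proteins, magnitude uniform in `log2fc_range` otherwise, sign split by
#' `dap_up_fraction`), true reduced cysteine fractions per strain (Beta by
#' moments, or paired HT = r * LT), a cysteine-peptide count, annotation
#' terms, a subcellular compartment, and an optional merge-group key.
#'
#' @param config a [sim_config()].
#' @return data.frame of class `sim_truth` with one row per protein and
#'   the config attached as attribute `"config"`.
#' @export
simulate_ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_proteins
    protein_id <- sprintf("P%05d", seq_len(n))
    base_abundance <- stats::rlnorm(n, meanlog = log(1e6), sdlog = 1)
    n_cys_peptides <- 1L + stats::rnbinom(n, size = config$psm_dispersion,
                                          mu = max(config$psm_mean - 1, 0))

    log2fc <- numeric(n)
    n_dap <- round(config$dap_fraction * n)
    dap_idx <- sample_idx(seq_len(n), n_dap)
    if (n_dap > 0) {
      mag <- stats::runif(n_dap, config$log2fc_range[1], config$log2fc_range[2])
      n_up <- round(n_dap * config$dap_up_fraction)
      sign <- rep(-1, n_dap)
      sign[sample_idx(seq_len(n_dap), n_up)] <- 1
      log2fc[dap_idx] <- mag * sign
    }
    is_dap <- log2fc != 0

    if (config$paired_redox) {
      sh_lt <- beta_shapes(config$redox_mean_lt, config$redox_sd_lt)
      red_lt <- stats::rbeta(n, sh_lt[1], sh_lt[2])
      r <- stats::rlnorm(n, meanlog = log(config$fc_pairing_median),
                         sdlog = config$fc_pairing_sigma)
      red_ht <- pmin(r * red_lt, 1)
    } else {
      sh_ht <- beta_shapes(config$redox_mean_ht, config$redox_sd_ht)
      sh_lt <- beta_shapes(config$redox_mean_lt, config$redox_sd_lt)
      red_ht <- stats::rbeta(n, sh_ht[1], sh_ht[2])
      red_lt <- stats::rbeta(n, sh_lt[1], sh_lt[2])
    }

    is_up <- log2fc > 0
    terms <- assign_annotation_terms(n, is_up, config$annotation_scheme)
    compartment_probs <- c(plastid = 0.22, cytoplasm = 0.35,
                           mitochondrion = 0.10, nucleus = 0.12,
                           ER = 0.06, Golgi = 0.04, extracellular = 0.11)
    compartment <- sample(names(compartment_probs), n, replace = TRUE,
                          prob = compartment_probs)
    merge_key <- rep(NA_character_, n)
    if (config$merge_group_size > 0) {
      k <- min(config$merge_group_size, n)
      merge_key[sample_idx(seq_len(n), k)] <- "LHCII"
    }

    truth <- data.frame(protein_id = protein_id,
                        base_abundance = base_abundance,
                        log2fc = log2fc,
                        is_dap = is_dap,
                        red_frac_ht = red_ht,
                        red_frac_lt = red_lt,
                        n_cys_peptides = n_cys_peptides,
                        terms = terms,
                        compartment = compartment,
                        merge_key = merge_key,
                        stringsAsFactors = FALSE)
    attr(truth, "config") <- config
    class(truth) <- c("sim_truth", "data.frame")
    truth
  })
}

#' Annotation catalog from simulated ground truth
#'
#' @param truth a [simulate_ground_truth()] result.
#' @param include_compartment also add the compartment label as a term.
#' @return named list protein_id -> character vector of terms, class
#'   `annotation_catalog` (proteins with no terms map to `character(0)`).
#' @export
truth_annotations <- function(truth, include_compartment = FALSE) {
  terms <- strsplit(truth$terms, ";", fixed = TRUE)
  terms <- lapply(terms, function(x) x[nzchar(x)])
  if (include_compartment)
    terms <- mapply(function(t, comp) unique(c(t, comp)),
                    terms, truth$compartment, SIMPLIFY = FALSE)
  names(terms) <- truth$protein_id
  class(terms) <- "annotation_catalog"
  terms
}

#' Merge map (protein -> group id) from simulated ground truth
#'
#' @param truth a [simulate_ground_truth()] result.
#' @return named character vector, or an empty one when no merge groups
#'   were simulated.
#' @export
truth_group_map <- function(truth) {
  has <- !is.na(truth$merge_key)
  stats::setNames(truth$merge_key[has], truth$protein_id[has])
}

#' Simulate iodoTMT differential-labeling PSM tables
#'
#' One 4-channel plex per biological replicate: light labels (i126 HT,
#' i127 LT) mark cysteines reduced in vivo; after TCEP reduction the heavy
#' labels (i130 HT, i131 LT) mark the oxidized complement.  For each
#' protein, replicate and cysteine peptide the light-channel expectation is
#' abundance x reduced_fraction x peptide_factor and the heavy-channel
#' expectation is abundance x (1 - reduced_fraction) x peptide_factor; both
#' get independent log-normal noise (CV = `noise_cv`, mean 1) and are
#' masked missing with `missing_rate`.  Channel ids are flattened to
#' "<reagent>_r<replicate>" so a single design table covers all runs.
#'
#' @param truth a [simulate_ground_truth()] result.
#' @param config the same [sim_config()].
#' @return list with elements `psms` (PSM table: protein_id, peptide_id,
#'   run_id and one intensity column per channel) and `design` (channel
#'   design: channel_id, strain, replicate, role).
#' @export
simulate_iodotmt_psms <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    n <- nrow(truth)
    R <- config$n_replicates_redox
    k <- truth$n_cys_peptides
    pidx <- rep.int(seq_len(n), k)
    n_pep <- length(pidx)
    pep_num <- sequence(k)
    pf <- stats::rlnorm(n_pep, 0, config$peptide_factor_sd)

    a_ht <- truth$base_abundance * 2^(truth$log2fc / 2)
    a_lt <- truth$base_abundance * 2^(-truth$log2fc / 2)
    f_ht <- truth$red_frac_ht
    f_lt <- truth$red_frac_lt

    reagents <- c("i126", "i127", "i130", "i131")
    channels <- as.vector(vapply(seq_len(R),
                                 function(r) paste0(reagents, "_r", r),
                                 character(4)))
    design <- data.frame(
      channel_id = channels,
      strain = rep(c("HT", "LT", "HT", "LT"), R),
      replicate = rep(seq_len(R), each = 4),
      role = rep(c("reduced", "reduced",
                   "oxidized-complement", "oxidized-complement"), R),
      stringsAsFactors = FALSE)

    exp_block <- cbind(a_ht[pidx] * f_ht[pidx] * pf,
                       a_lt[pidx] * f_lt[pidx] * pf,
                       a_ht[pidx] * (1 - f_ht[pidx]) * pf,
                       a_lt[pidx] * (1 - f_lt[pidx]) * pf)

    mat <- matrix(NA_real_, nrow = n_pep * R, ncol = 4L * R,
                  dimnames = list(NULL, channels))
    for (r in seq_len(R)) {
      rows <- (r - 1L) * n_pep + seq_len(n_pep)
      cols <- (r - 1L) * 4L + 1:4
      block <- exp_block * matrix(noise_factor(n_pep * 4L, config$noise_cv),
                                  nrow = n_pep)
      if (config$missing_rate > 0)
        block[stats::runif(length(block)) < config$missing_rate] <- NA_real_
      mat[rows, cols] <- block
    }

    psms <- data.frame(
      protein_id = rep(truth$protein_id[pidx], R),
      peptide_id = rep(sprintf("%s_cys%02d", truth$protein_id[pidx], pep_num), R),
      run_id = rep(paste0("run_r", seq_len(R)), each = n_pep),
      stringsAsFactors = FALSE)
    psms <- cbind(psms, as.data.frame(mat))
    list(psms = psms, design = design)
  })
}

#' Simulate TMT 11-plex abundance PSM tables
#'
#' One multiplexed run: HT samples in channels 126, 127N, 127C, 128N, 129N;
#' LT samples in 128C, 129C, 130C, 130N, 131N; pooled reference in 131C.
#' Strain abundances are split symmetrically, HT = base * 2^(lfc/2) and
#' LT = base * 2^(-lfc/2), so the HT-LT log2 difference equals the true
#' log2 fold change; the reference expectation is the arithmetic mean of
#' the ten sample expectations.  Per-channel log-normal loading factors
#' (sd `channel_loading_sd`) emulate unequal channel loadings that global
#' scaling must remove; the optional degenerate channel is attenuated and
#' given extra missingness.
#'
#' @inheritParams simulate_iodotmt_psms
#' @return list with `psms` and `design` as in [simulate_iodotmt_psms()];
#'   the design roles are "abundance" and "reference".
#' @export
simulate_tmt_psms <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 2L, {
    n <- nrow(truth)
    R <- config$n_replicates_abundance
    ht_ch <- c("126", "127N", "127C", "128N", "129N")[seq_len(R)]
    lt_ch <- c("128C", "129C", "130C", "130N", "131N")[seq_len(R)]
    ref_ch <- "131C"
    channels <- c(ht_ch, lt_ch, ref_ch)

    dc <- config$degenerate_channel
    if (!is.null(dc) && !(dc$channel %in% channels))
      stopf("degenerate channel '%s' is not in the 11-plex design", dc$channel)

    design <- data.frame(
      channel_id = channels,
      strain = c(rep("HT", R), rep("LT", R), "REF"),
      replicate = c(seq_len(R), seq_len(R), NA_integer_),
      role = c(rep("abundance", 2L * R), "reference"),
      stringsAsFactors = FALSE)

    n_psms <- 1L + stats::rnbinom(n, size = config$psm_dispersion,
                                  mu = max(config$psm_mean - 1, 0))
    pidx <- rep.int(seq_len(n), n_psms)
    n_rows <- length(pidx)
    pf <- stats::rlnorm(n_rows, 0, config$peptide_factor_sd)

    e_ht <- truth$base_abundance[pidx] * 2^(truth$log2fc[pidx] / 2) * pf
    e_lt <- truth$base_abundance[pidx] * 2^(-truth$log2fc[pidx] / 2) * pf
    e_ref <- (R * e_ht + R * e_lt) / (2 * R)
    expect <- cbind(matrix(e_ht, n_rows, R), matrix(e_lt, n_rows, R), e_ref)
    colnames(expect) <- channels

    loading <- if (config$channel_loading_sd > 0)
      stats::rlnorm(length(channels), 0, config$channel_loading_sd)
    else rep(1, length(channels))
    names(loading) <- channels
    if (!is.null(dc)) loading[dc$channel] <- loading[dc$channel] * dc$attenuation

    mat <- expect * rep(loading, each = n_rows) *
      matrix(noise_factor(n_rows * length(channels), config$noise_cv), n_rows)
    if (config$missing_rate > 0)
      mat[stats::runif(length(mat)) < config$missing_rate] <- NA_real_
    if (!is.null(dc) && dc$extra_missing > 0) {
      j <- match(dc$channel, channels)
      mat[stats::runif(n_rows) < dc$extra_missing, j] <- NA_real_
    }

    psms <- data.frame(
      protein_id = truth$protein_id[pidx],
      peptide_id = sprintf("%s_psm%03d", truth$protein_id[pidx], sequence(n_psms)),
      run_id = "plex1",
      stringsAsFactors = FALSE)
    psms <- cbind(psms, as.data.frame(mat))
    list(psms = psms, design = design)
  })
}
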