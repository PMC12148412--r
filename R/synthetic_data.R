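#' Configuration for the synthetic meltome generator
#'
#' Defaults emulate the study design the pipeline targets: 3 conditions
#' (mock, LPS-primed, nigericin-activated) x 2 biological replicates x the
#' 10-temperature 37-67 degrees Celsius gradient encoded by TMT channels
#' 126-131. Per protein the generator draws a log-normal base abundance
#' and a reciprocal-form sigmoid melting curve; a global per-temperature
#' attenuation reproduces the decreasing total signal at higher
#' temperatures; noise is multiplicative log-normal on intensities;
#' missingness rises with temperature (low-signal dropout). Stability
#' effects (a melting-temperature shift) and abundance effects (a log2
#' fold change at all temperatures) are spiked into the effect condition
#' (by default the last, nigericin) for random subsets of proteins, with
#' the truth recorded exactly.
#'
#' @param n_proteins number of proteins; default 1000.
#' @param conditions condition labels; the first is the reference, the
#'   last carries the spiked effects.
#' @param n_replicates biological replicates per condition; default 2.
#' @param channel_map a [channel_map]; default TMT10 / 37-67 gradient.
#' @param base_intensity_log2_mean,base_intensity_log2_sd log2-normal
#'   base-abundance parameters; defaults 23 and 1.5 (median ~8e6, the
#'   scale of summed TMT reporter signals).
#' @param noise_sd multiplicative noise SD in log2 units; default 0.1.
#' @param signal_decay per-temperature global attenuation factors on top
#'   of the melting-driven signal loss; default all 1. In a TMT-TR design
#'   all temperatures share one labeled mix, so the decreasing signal sum
#'   with temperature is produced by the sigmoid solubility decay itself;
#'   a smooth extra attenuation would be unidentifiable from global
#'   melting. The knob exists for robustness studies of the ratio-based
#'   scoring path, where any per-temperature factor cancels exactly.
#' @param tm_mean,tm_sd,tm_range melting-temperature distribution
#'   (normal, truncated); defaults 52, 4, [42, 62] degrees Celsius.
#' @param slope_range range of the sigmoid slope parameter `a`
#'   (reciprocal form); default [600, 1400].
#' @param plateau_range range of the high-temperature plateau; default
#'   [0.02, 0.15].
#' @param frac_stability_hits fraction of proteins with a spiked Tm
#'   shift; default 0.05.
#' @param delta_tm_range absolute Tm-shift range in degrees Celsius
#'   (sign random); default [2, 5].
#' @param frac_abundance_hits fraction with a spiked abundance change;
#'   default 0.05.
#' @param log2fc_range absolute log2 fold-change range (sign random);
#'   default [0.5, 1.5].
#' @param missing_rate_high_temp missingness probability at the highest
#'   temperature (0 at the lowest, linear ramp in between); default 0.1.
#' @param batch_offsets per-replicate additive log2 offsets; default all
#'   zero.
#' @param seed integer RNG seed; default 1.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 1000,
                       conditions = c("mock", "lps", "nigericin"),
                       n_replicates = 2,
                       channel_map = default_channel_map(),
                       base_intensity_log2_mean = 23,
                       base_intensity_log2_sd = 1.5,
                       noise_sd = 0.1,
                       signal_decay = NULL,
                       tm_mean = 52, tm_sd = 4, tm_range = c(42, 62),
                       slope_range = c(600, 1400),
                       plateau_range = c(0.02, 0.15),
                       frac_stability_hits = 0.05,
                       delta_tm_range = c(2, 5),
                       frac_abundance_hits = 0.05,
                       log2fc_range = c(0.5, 1.5),
                       missing_rate_high_temp = 0.1,
                       batch_offsets = NULL,
                       seed = 1) {
  nT <- length(channel_map$temperatures_c)
  if (is.null(signal_decay)) signal_decay <- rep(1, nT)
  if (is.null(batch_offsets)) batch_offsets <- rep(0, n_replicates)
  cfg <- list(n_proteins = n_proteins, conditions = conditions,
              n_replicates = n_replicates, channel_map = channel_map,
              base_intensity_log2_mean = base_intensity_log2_mean,
              base_intensity_log2_sd = base_intensity_log2_sd,
              noise_sd = noise_sd, signal_decay = signal_decay,
              tm_mean = tm_mean, tm_sd = tm_sd, tm_range = tm_range,
              slope_range = slope_range, plateau_range = plateau_range,
              frac_stability_hits = frac_stability_hits,
              delta_tm_range = delta_tm_range,
              frac_abundance_hits = frac_abundance_hits,
              log2fc_range = log2fc_range,
              missing_rate_high_temp = missing_rate_high_temp,
              batch_offsets = batch_offsets, seed = seed)
  bad <- character(0)
  if (n_proteins < 0) bad <- c(bad, "n_proteins")
  if (length(conditions) < 2 || anyDuplicated(conditions))
    bad <- c(bad, "conditions")
  if (n_replicates < 1) bad <- c(bad, "n_replicates")
  if (!inherits(channel_map, "channel_map")) bad <- c(bad, "channel_map")
  if (noise_sd < 0) bad <- c(bad, "noise_sd")
  if (length(signal_decay) != nT || any(signal_decay <= 0))
    bad <- c(bad, "signal_decay")
  for (fr in c("frac_stability_hits", "frac_abundance_hits",
               "missing_rate_high_temp")) {
    if (cfg[[fr]] < 0 || cfg[[fr]] > 1) bad <- c(bad, fr)
  }
  if (length(batch_offsets) != n_replicates) bad <- c(bad, "batch_offsets")
  if (any(plateau_range < 0) || any(plateau_range >= 0.5))
    bad <- c(bad, "plateau_range")
  if (length(bad) > 0) {
    stop("invalid sim_config field(s): ", paste(unique(bad), collapse = ", "))
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a TPP-TR meltome with known ground truth
#'
#' @param config a [sim_config].
#' @return A list:
#' \describe{
#'   \item{`quant`}{long protein quantification data.frame (`protein_id`,
#'     `condition`, `replicate`, `temperature_c`, `intensity`; `NA` for
#'     dropout), one row per cell of the design.}
#'   \item{`truth`}{one row per protein: per-condition true Tm columns
#'     (`tm_true_<condition>`), `delta_tm_c` and `abundance_log2fc` for
#'     the effect-vs-reference comparison (0 for non-hits),
#'     `is_stability_hit`, `is_abundance_hit`.}
#' }
#' @export
simulate_proteome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cm <- config$channel_map
  temps <- cm$temperatures_c
  nT <- length(temps)
  nP <- config$n_proteins
  conds <- config$conditions
  ref_cond <- conds[1]
  eff_cond <- conds[length(conds)]
  ids <- sprintf("P%05d", seq_len(nP))
  if (nP == 0) {
    quant <- data.frame(protein_id = character(0), condition = character(0),
                        replicate = integer(0), temperature_c = numeric(0),
                        intensity = numeric(0))
    truth <- data.frame(protein_id = character(0))
    attr(truth, "comparison") <- paste0(eff_cond, "_vs_", ref_cond)
    return(list(quant = quant, truth = truth))
  }

  base <- 2^stats::rnorm(nP, config$base_intensity_log2_mean,
                         config$base_intensity_log2_sd)
  tm <- stats::rnorm(nP, config$tm_mean, config$tm_sd)
  tm <- pmin(pmax(tm, config$tm_range[1]), config$tm_range[2])
  a <- stats::runif(nP, config$slope_range[1], config$slope_range[2])
  plateau <- stats::runif(nP, config$plateau_range[1],
                          config$plateau_range[2])

  is_stab <- stats::runif(nP) < config$frac_stability_hits
  is_abund <- stats::runif(nP) < config$frac_abundance_hits
  dtm <- ifelse(is_stab,
                sample(c(-1, 1), nP, replace = TRUE) *
                  stats::runif(nP, config$delta_tm_range[1],
                               config$delta_tm_range[2]),
                0)
  lfc <- ifelse(is_abund,
                sample(c(-1, 1), nP, replace = TRUE) *
                  stats::runif(nP, config$log2fc_range[1],
                               config$log2fc_range[2]),
                0)

  q <- log(0.5 / (0.5 - plateau))
  miss_prob <- config$missing_rate_high_temp * (seq_len(nT) - 1) / (nT - 1)

  pieces <- vector("list", length(conds) * config$n_replicates)
  k <- 0
  for (cond in conds) {
    tm_cond <- tm + if (cond == eff_cond) dtm else 0
    lfc_cond <- if (cond == eff_cond) lfc else rep(0, nP)
    b_cond <- a / tm_cond + q  # so f(Tm) = 0.5
    # soluble fraction: proteins x temperatures
    frac <- (1 - plateau) /
      (1 + exp(-(outer(a, 1 / temps) - b_cond))) + plateau
    for (r in seq_len(config$n_replicates)) {
      k <- k + 1
      noise <- matrix(stats::rnorm(nP * nT, 0, config$noise_sd), nP, nT)
      inten <- base * frac *
        matrix(config$signal_decay, nP, nT, byrow = TRUE) *
        2^(config$batch_offsets[r] + lfc_cond + noise)
      drop_out <- matrix(stats::runif(nP * nT), nP, nT) <
        matrix(miss_prob, nP, nT, byrow = TRUE)
      inten[drop_out] <- NA_real_
      pieces[[k]] <- data.frame(
        protein_id = rep(ids, times = nT),
        condition = cond,
        replicate = r,
        temperature_c = rep(temps, each = nP),
        intensity = as.vector(inten))
    }
  }
  quant <- do.call(rbind, pieces)
  quant <- quant[order(quant$protein_id, quant$condition, quant$replicate,
                       quant$temperature_c), , drop = FALSE]
  rownames(quant) <- NULL

  truth <- data.frame(protein_id = ids)
  for (cond in conds) {
    truth[[paste0("tm_true_", cond)]] <- tm + if (cond == eff_cond) dtm else 0
  }
  truth$delta_tm_c <- dtm
  truth$abundance_log2fc <- lfc
  truth$is_stability_hit <- is_stab
  truth$is_abundance_hit <- is_abund
  truth$curve_a <- a
  truth$curve_plateau <- plateau
  attr(truth, "comparison") <- paste0(eff_cond, "_vs_", ref_cond)
  list(quant = quant, truth = truth)
}

#' Simulate a spectrum-level (PSM) table
#'
#' Splits each simulated protein's channel intensities across
#' `psms_per_protein` spectra with Dirichlet (multinomial-like) weight
#' noise, and draws the two precursor quality measures: s2i ~
#' Beta(`s2i_shape1`, `s2i_shape2`) and p2t ~ log-normal(`p2t_meanlog`,
#' `p2t_sdlog`). The generator records which PSMs fall below the standard
#' (0.5, 4) filter thresholds, so filter arithmetic can be checked
#' against its own bookkeeping.
#'
#' @param config a [sim_config].
#' @param psms_per_protein spectra per protein per sample; default 3.
#' @param s2i_shape1,s2i_shape2 Beta parameters for s2i; defaults 8, 2
#'   (mean 0.8, a few percent below 0.5).
#' @param p2t_meanlog,p2t_sdlog log-normal parameters for p2t; defaults
#'   log(20), 1 (~5\% below 4).
#' @param s2i_min,p2t_min thresholds used for the bookkeeping; defaults
#'   0.5 and 4.
#' @return A list: `psms` (data.frame in [read_psm_table()] layout),
#'   `below_threshold` (logical per PSM, strictly below either
#'   threshold), `n_below_threshold`.
#' @export
simulate_psm_table <- function(config = sim_config(),
                               psms_per_protein = 3,
                               s2i_shape1 = 8, s2i_shape2 = 2,
                               p2t_meanlog = log(20), p2t_sdlog = 1,
                               s2i_min = 0.5, p2t_min = 4) {
  stopifnot(psms_per_protein >= 1)
  sim <- simulate_proteome(config)
  quant <- sim$quant
  cm <- config$channel_map
  labels <- cm$channel_labels
  # wide: one row per protein x condition x replicate
  quant$sample_key <- paste(quant$protein_id, quant$condition,
                            quant$replicate, sep = "\r")
  keys <- unique(quant$sample_key)
  if (length(keys) == 0 || config$n_proteins == 0) {
    psms <- data.frame(spectrum_id = character(0), protein_id = character(0),
                       condition = character(0), replicate = integer(0),
                       s2i = numeric(0), p2t = numeric(0))
    for (cl in labels) psms[[cl]] <- numeric(0)
    return(list(psms = psms, below_threshold = logical(0),
                n_below_threshold = 0L))
  }
  wide <- matrix(NA_real_, length(keys), length(labels))
  ki <- match(quant$sample_key, keys)
  ti <- match(quant$temperature_c, cm$temperatures_c)
  wide[cbind(ki, ti)] <- quant$intensity
  meta <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))

  npsm <- psms_per_protein
  nrow_psm <- length(keys) * npsm
  # Dirichlet weights per PSM per channel: multinomial-like split noise
  out <- matrix(NA_real_, nrow_psm, length(labels))
  for (j in seq_along(labels)) {
    g <- matrix(stats::rgamma(nrow_psm, shape = 5), length(keys), npsm)
    w <- g / rowSums(g)
    out[, j] <- as.vector(t(w * wide[, j]))
  }
  prot <- rep(meta[, 1], each = npsm)
  cond <- rep(meta[, 2], each = npsm)
  repl <- rep(as.integer(meta[, 3]), each = npsm)
  s2i <- stats::rbeta(nrow_psm, s2i_shape1, s2i_shape2)
  p2t <- stats::rlnorm(nrow_psm, p2t_meanlog, p2t_sdlog)
  below <- s2i < s2i_min | p2t < p2t_min
  psms <- data.frame(
    spectrum_id = sprintf("spec%07d", seq_len(nrow_psm)),
    protein_id = prot, condition = cond, replicate = repl,
    s2i = s2i, p2t = p2t)
  for (j in seq_along(labels)) psms[[labels[j]]] <- out[, j]
  list(psms = psms, below_threshold = below,
       n_below_threshold = sum(below))
}
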