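#' Define a pairwise comparison
#'
#' @param name label for the comparison, e.g. `"nigericin_vs_lps"`.
#' @param treatment treatment condition label.
#' @param reference reference condition label; must differ from
#'   `treatment`.
#' @return A list of class `comparison_def`.
#' @export
comparison_def <- function(name, treatment, reference) {
  stopifnot(is.character(name), is.character(treatment),
            is.character(reference))
  if (treatment == reference) stop("treatment and reference must differ")
  structure(list(name = name, treatment = treatment, reference = reference),
            class = "comparison_def")
}

#' Per-temperature log2 comparison ratios
#'
#' For each protein, temperature and replicate, the comparison-group ratio
#' is the treatment-minus-reference difference of normalized (glog2)
#' values, pairing replicates by index. Either side missing makes the
#' ratio missing.
#'
#' @param matrix normalized data.frame (`protein_id`, `condition`,
#'   `replicate`, `temperature_c`, `norm_value`).
#' @param comparison a [comparison_def].
#' @return Long data.frame: `protein_id`, `comparison`, `temperature_c`,
#'   `replicate`, `ratio`.
#' @export
compute_log2_ratios <- function(matrix, comparison) {
  conds <- unique(matrix$condition)
  for (side in c(comparison$treatment, comparison$reference)) {
    if (!side %in% conds) {
      stop("comparison condition not present in data: ", side)
    }
  }
  tr <- matrix[matrix$condition == comparison$treatment, , drop = FALSE]
  rf <- matrix[matrix$condition == comparison$reference, , drop = FALSE]
  key_tr <- paste(tr$protein_id, tr$replicate, tr$temperature_c, sep = "\r")
  key_rf <- paste(rf$protein_id, rf$replicate, rf$temperature_c, sep = "\r")
  i <- match(key_tr, key_rf)
  out <- data.frame(protein_id = tr$protein_id,
                    comparison = comparison$name,
                    temperature_c = tr$temperature_c,
                    replicate = tr$replicate,
                    ratio = tr$norm_value - rf$norm_value[i])
  out <- out[!is.na(i), , drop = FALSE]
  out <- out[order(out$protein_id, out$temperature_c, out$replicate), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# deterministic 31-bit hash of a protein id, for per-protein RNG substreams
.protein_hash <- function(id) {
  h <- 0
  for (code in utf8ToInt(id)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

.protein_seed <- function(seed, id) {
  as.integer((as.numeric(seed) + .protein_hash(id)) %% 2147483647)
}

#' Bootstrap abundance and stability draws for one ratio profile
#'
#' Implements the resampling scheme at the heart of the stability/abundance
#' scoring. A profile is eligible if it has at least two measured ratio
#' values among the (two lowest temperatures) x (replicates) cells. In
#' each of `n_iter` iterations, for every temperature with at least one
#' non-missing ratio, one replicate's ratio is drawn uniformly at random
#' among the non-missing ones; the abundance draw is the mean of the drawn
#' ratios at the two lowest temperatures, and the stability draw is the
#' sum over all drawn temperatures of (ratio - abundance draw), i.e. the
#' baseline-subtracted area of the ratio profile.
#'
#' @param ratio_matrix numeric matrix, temperatures (rows, gradient order)
#'   x replicates (columns), of log2 comparison ratios; NAs allowed.
#' @param n_iter bootstrap iterations; default 500.
#' @param seed optional integer seed set before drawing.
#' @return A list: `eligible` (logical); when eligible also
#'   `abundance_mean`, `abundance_sd`, `stability_mean`, `stability_sd`
#'   (mean/SD over the draw distributions) and `n_points` (temperatures
#'   with at least one non-missing ratio).
#' @export
bootstrap_scores <- function(ratio_matrix, n_iter = 500, seed = NULL) {
  stopifnot(is.matrix(ratio_matrix), n_iter >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_low_cells <- sum(!is.na(ratio_matrix[1:2, , drop = FALSE]))
  if (n_low_cells < 2) {
    return(list(eligible = FALSE))
  }
  nT <- nrow(ratio_matrix)
  D <- matrix(NA_real_, n_iter, nT)
  for (t in seq_len(nT)) {
    v <- ratio_matrix[t, ]
    v <- v[!is.na(v)]
    k <- length(v)
    if (k == 0) next
    D[, t] <- if (k == 1) v else v[sample.int(k, n_iter, replace = TRUE)]
  }
  abundance <- rowMeans(D[, 1:2, drop = FALSE], na.rm = TRUE)
  stability <- rowSums(D - abundance, na.rm = TRUE)
  list(eligible = TRUE,
       abundance_mean = mean(abundance),
       abundance_sd = stats::sd(abundance),
       stability_mean = mean(stability),
       stability_sd = stats::sd(stability),
       n_points = sum(colSums(!is.na(D)) > 0))
}

#' Bootstrap scores for every protein of a comparison
#'
#' Runs [bootstrap_scores()] per protein with a deterministic per-protein
#' RNG substream derived from `(seed, hash(protein_id))`, so results do
#' not depend on protein order.
#'
#' @param ratios long ratio data.frame from [compute_log2_ratios()].
#' @param channel_map a [channel_map] defining the gradient order.
#' @param n_iter bootstrap iterations; default 500.
#' @param seed integer seed.
#' @return data.frame with columns `protein_id`, `comparison`,
#'   `score_type` (`"abundance"`/`"stability"`), `boot_mean`, `boot_sd`,
#'   `n_points`. Ineligible proteins (fewer than two measured points at
#'   the two lowest temperatures) are skipped; their ids are in the
#'   `"skipped"` attribute.
#' @export
bootstrap_all <- function(ratios, channel_map = default_channel_map(),
                          n_iter = 500, seed = 1) {
  temps <- channel_map$temperatures_c
  reps <- sort(unique(ratios$replicate))
  groups <- split(seq_len(nrow(ratios)), ratios$protein_id)
  ids <- names(groups)
  skipped <- character(0)
  rows <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    g <- groups[[ids[j]]]
    m <- matrix(NA_real_, length(temps), length(reps))
    m[cbind(match(ratios$temperature_c[g], temps),
            match(ratios$replicate[g], reps))] <- ratios$ratio[g]
    bs <- bootstrap_scores(m, n_iter = n_iter,
                           seed = .protein_seed(seed, ids[j]))
    if (!bs$eligible) {
      skipped <- c(skipped, ids[j])
      next
    }
    rows[[j]] <- data.frame(
      protein_id = ids[j],
      comparison = ratios$comparison[g[1]],
      score_type = c("abundance", "stability"),
      boot_mean = c(bs$abundance_mean, bs$stability_mean),
      boot_sd = c(bs$abundance_sd, bs$stability_sd),
      n_points = bs$n_points)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(0), comparison = character(0),
                      score_type = character(0), boot_mean = numeric(0),
                      boot_sd = numeric(0), n_points = integer(0))
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' P-value for a bootstrap score distribution
#'
#' Tests whether a score's draw distribution differs from zero: the
#' statistic `boot_mean / boot_sd` is referred to a Student's
#' t-distribution with `n_points - 1` degrees of freedom (two-sided).
#' A zero bootstrap SD gives p = 1 when the mean is also zero, and the
#' smallest positive double otherwise.
#'
#' @param boot_mean,boot_sd,n_points vectors of equal length (recycled).
#' @return Vector of two-sided p-values in `(0, 1]`.
#' @export
score_pvalue <- function(boot_mean, boot_sd, n_points) {
  n <- max(length(boot_mean), length(boot_sd), length(n_points))
  boot_mean <- rep_len(boot_mean, n)
  boot_sd <- rep_len(boot_sd, n)
  n_points <- rep_len(n_points, n)
  if (any(n_points < 2)) stop("n_points must be >= 2")
  if (any(boot_sd < 0, na.rm = TRUE)) stop("boot_sd must be >= 0")
  p <- numeric(n)
  deg <- boot_sd == 0
  p[deg & boot_mean == 0] <- 1
  p[deg & boot_mean != 0] <- .Machine$double.xmin
  i <- !deg
  p[i] <- 2 * stats::pt(-abs(boot_mean[i] / boot_sd[i]), df = n_points[i] - 1)
  pmax(p, .Machine$double.xmin)
}

#' Robust z-standardization of scores across the proteome
#'
#' Transforms raw score averages into z-scores using the proteome-wide
#' robust center and scale: `z = (x - median(x)) / (1.4826 * MAD(x))`,
#' computed over all eligible proteins of one comparison and score type.
#'
#' @param means numeric vector of per-protein score averages (>= 10 finite
#'   values required).
#' @return Vector of z-scores (NA where the input is NA).
#' @export
standardize_scores <- function(means) {
  x <- means[is.finite(means)]
  if (length(x) < 10) stop("need at least 10 finite score values")
  s <- stats::mad(x)  # already includes the 1.4826 consistency constant
  if (s == 0) stop("degenerate proteome: MAD of scores is zero")
  (means - stats::median(x)) / s
}

#' Global FDR (q-values) from the z-score distribution
#'
#' Fits an empirical null to the central mass of the z-scores
#' (`mu = median(z)`, `sigma = 1.4826 * MAD(z)`), converts each z to a
#' two-sided normal tail p-value under that null, and applies the
#' Benjamini-Hochberg step-up to obtain monotone q-values. The global FDR
#' therefore tracks effect size (distance from the bulk of the score
#' distribution). Setting `null = "theoretical"` uses N(0, 1) instead.
#'
#' @param z numeric vector of z-scores (>= 10 finite values).
#' @param null `"empirical"` (default) or `"theoretical"`.
#' @return Vector of q-values in `(0, 1]`.
#' @export
global_fdr_from_z <- function(z, null = c("empirical", "theoretical")) {
  null <- match.arg(null)
  zf <- z[is.finite(z)]
  if (length(zf) < 10) stop("need at least 10 finite z-scores")
  if (null == "empirical") {
    mu <- stats::median(zf)
    sig <- stats::mad(zf)
    if (sig == 0) stop("degenerate empirical null: sigma is zero")
  } else {
    mu <- 0
    sig <- 1
  }
  p <- 2 * stats::pnorm(abs(z - mu) / sig, lower.tail = FALSE)
  q <- rep(NA_real_, length(z))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  pmax(q, .Machine$double.xmin)
}

#' Benjamini-Hochberg adjustment (local FDR)
#'
#' The local FDR reported for expression and bootstrap scores is the BH
#' multiple-testing adjustment of the per-protein p-values within a
#' comparison, reflecting replicate reproducibility rather than effect
#' size.
#'
#' @param p vector of p-values in `(0, 1]`.
#' @return BH-adjusted vector.
#' @export
local_fdr_bh <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1)) stop("p-values must lie in (0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Moderated expression scores for a comparison
#'
#' Protein expression change is read from the abundance-representative
#' channels: the `n_baseline` lowest temperatures (default 2, i.e. 37 and
#' 41 degrees Celsius), where thermal denaturation has not yet set in.
#' Per protein, `logfc` is the mean treatment-minus-reference difference
#' of normalized values over those channels; significance uses an
#' empirical-Bayes moderated t with variance shrinkage toward the
#' proteome-wide median residual variance `s0^2` with prior degrees of
#' freedom `prior_df` (default 4): posterior variance
#' `(d0*s0^2 + d*s^2) / (d0 + d)`, t referred to `d0 + d` degrees of
#' freedom. With `prior_df = 0` this reduces to the ordinary pooled
#' two-sample t-test. z is the signed inverse-normal transform of the
#' two-sided p.
#'
#' @param matrix normalized data.frame from [normalize_per_temperature()].
#' @param comparison a [comparison_def].
#' @param channel_map a [channel_map].
#' @param n_baseline number of lowest temperatures used; default 2.
#' @param prior_df prior degrees of freedom for variance shrinkage;
#'   default 4.
#' @return data.frame: `protein_id`, `comparison`, `logfc`, `moderated_t`,
#'   `p_value`, `z`, `fdr_global`, `fdr_local`. Proteins without at least
#'   two values per side are flagged in the `"skipped"` attribute.
#' @export
expression_scores <- function(matrix, comparison,
                              channel_map = default_channel_map(),
                              n_baseline = 2, prior_df = 4) {
  temps <- sort(channel_map$temperatures_c)[seq_len(n_baseline)]
  sub <- matrix[matrix$temperature_c %in% temps &
                  matrix$condition %in% c(comparison$treatment,
                                          comparison$reference), ,
                drop = FALSE]
  if (nrow(sub) == 0) stop("no data at the baseline temperatures")
  groups <- split(seq_len(nrow(sub)), sub$protein_id)
  ids <- names(groups)
  logfc <- s2 <- rep(NA_real_, length(ids))
  d <- n1 <- n2 <- rep(NA_integer_, length(ids))
  for (j in seq_along(ids)) {
    g <- groups[[j]]
    x <- sub$norm_value[g][sub$condition[g] == comparison$treatment]
    y <- sub$norm_value[g][sub$condition[g] == comparison$reference]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) next
    n1[j] <- length(x); n2[j] <- length(y)
    logfc[j] <- mean(x) - mean(y)
    d[j] <- n1[j] + n2[j] - 2L
    s2[j] <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / d[j]
  }
  ok <- !is.na(logfc)
  skipped <- ids[!ok]
  if (sum(ok) == 0) stop("no protein has >= 2 values per side")
  s02 <- stats::median(s2[ok])
  post_var <- (prior_df * s02 + d * s2) / (prior_df + d)
  tstat <- logfc / sqrt(post_var * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tstat), df = prior_df + d)
  p <- pmax(p, .Machine$double.xmin)
  z <- -sign(logfc) * stats::qnorm(p / 2)  # lower tail: stable for tiny p
  out <- data.frame(protein_id = ids[ok],
                    comparison = comparison$name,
                    logfc = logfc[ok],
                    moderated_t = tstat[ok],
                    p_value = p[ok],
                    z = z[ok])
  out$fdr_global <- global_fdr_from_z(out$z)
  out$fdr_local <- local_fdr_bh(out$p_value)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Finalize bootstrap scores: p-values, z-scores and FDRs
#'
#' Takes the raw bootstrap output of [bootstrap_all()] and adds, per
#' score type within the comparison: the t-based p-value
#' ([score_pvalue()]), the proteome-standardized z ([standardize_scores()]),
#' the global FDR from the z distribution ([global_fdr_from_z()]) and the
#' local FDR as BH-adjusted p ([local_fdr_bh()]).
#'
#' @param boot data.frame from [bootstrap_all()].
#' @param null null model for the global FDR; see [global_fdr_from_z()].
#' @return The input with columns `p_value`, `z`, `fdr_global`,
#'   `fdr_local` appended.
#' @export
finalize_scores <- function(boot, null = "empirical") {
  if (nrow(boot) == 0) return(boot)
  boot$p_value <- score_pvalue(boot$boot_mean, boot$boot_sd, boot$n_points)
  boot$z <- NA_real_
  boot$fdr_global <- NA_real_
  boot$fdr_local <- NA_real_
  for (st in unique(boot$score_type)) {
    i <- boot$score_type == st
    boot$z[i] <- standardize_scores(boot$boot_mean[i])
    boot$fdr_global[i] <- global_fdr_from_z(boot$z[i], null = null)
    boot$fdr_local[i] <- local_fdr_bh(boot$p_value[i])
  }
  boot
}

#' Score one comparison end to end
#'
#' Convenience driver: log2 ratios, bootstrap, p/z/FDR finalization, and
#' moderated expression scores for a single pairwise comparison.
#'
#' @inheritParams bootstrap_all
#' @inheritParams expression_scores
#' @param matrix normalized data.frame.
#' @return List with elements `scores` (bootstrap score table) and
#'   `expression` (expression score table).
#' @export
score_comparison <- function(matrix, comparison,
                             channel_map = default_channel_map(),
                             n_iter = 500, seed = 1, prior_df = 4) {
  ratios <- compute_log2_ratios(matrix, comparison)
  boot <- bootstrap_all(ratios, channel_map, n_iter = n_iter, seed = seed)
  scores <- finalize_scores(boot)
  expr <- expression_scores(matrix, comparison, channel_map,
                            prior_df = prior_df)
  list(scores = scores, expression = expr)
}

#' Call significant hits from score tables
#'
#' Two criteria are supported:
#' \describe{
#'   \item{`"dual_fdr_001"`}{hit iff both the local and the global FDR are
#'     below 0.01 (the stringent dual cutoff).}
#'   \item{`"z196_fdr005"`}{hit iff `|z|` exceeds the standard-normal
#'     two-sided 5\% critical value (`qnorm(0.975)`, 1.96) and the global
#'     FDR is below 0.05.}
#' }
#'
#' @param scores data.frame carrying `protein_id`, `comparison`, `z`,
#'   `fdr_global`, `fdr_local`, and optionally `score_type` (expression
#'   tables are labeled `"expression"`).
#' @param criterion `"dual_fdr_001"` or `"z196_fdr005"`.
#' @param z_cutoff the |z| cutoff of the second criterion; default
#'   `qnorm(0.975)`.
#' @return data.frame of hits: `protein_id`, `comparison`, `score_type`,
#'   `z`, `direction` (`"stabilized"`/`"destabilized"` for stability
#'   scores, `"up"`/`"down"` otherwise).
#' @export
call_hits <- function(scores, criterion = c("dual_fdr_001", "z196_fdr005"),
                      z_cutoff = stats::qnorm(0.975)) {
  criterion <- match.arg(criterion)
  if (!"score_type" %in% names(scores)) scores$score_type <- "expression"
  if (nrow(scores) == 0) {
    return(data.frame(protein_id = character(0), comparison = character(0),
                      score_type = character(0), z = numeric(0),
                      direction = character(0)))
  }
  keep <- switch(criterion,
                 dual_fdr_001 = scores$fdr_local < 0.01 &
                   scores$fdr_global < 0.01,
                 z196_fdr005 = abs(scores$z) > z_cutoff &
                   scores$fdr_global < 0.05)
  keep[is.na(keep)] <- FALSE
  hits <- scores[keep, c("protein_id", "comparison", "score_type", "z"),
                 drop = FALSE]
  hits$direction <- ifelse(hits$score_type == "stability",
                           ifelse(hits$z > 0, "stabilized", "destabilized"),
                           ifelse(hits$z > 0, "up", "down"))
  rownames(hits) <- NULL
  hits
}
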