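#' Per-temperature variance-stabilizing normalization
#'
#' TPP-TR reporter intensities shrink as the heating temperature rises, so
#' each temperature is normalized in an independent run. Within a
#' temperature: (1) a per-sample scale factor is estimated as the median,
#' over proteins quantified in every sample at that temperature, of the
#' ratio of the sample's intensity to the per-protein geometric mean
#' across samples; (2) intensities are divided by their sample factor and
#' by the run level (the median positive scaled intensity of that
#' temperature), which puts every temperature's independent run on a
#' common dimensionless scale; (3) a generalized log2 transform
#' \deqn{glog2(x) = log2((x + sqrt(x^2 + c_t^2)) / 2)}
#' is applied, with the per-temperature offset `c_t` set to the
#' `glog_percentile` quantile (default 5th) of positive scaled intensities
#' at that temperature, tying the linear-to-log transition to the noise
#' floor.
#'
#' A sample is one (condition, replicate) pair. Missing intensities stay
#' missing. If no protein is complete at a temperature, scale factors fall
#' back to pairwise median ratios against the first sample.
#'
#' @param table long protein quantification data.frame with columns
#'   `protein_id`, `condition`, `replicate`, `temperature_c`, `intensity`.
#' @param glog_percentile percentile (0-100) of positive scaled
#'   intensities used as the glog offset; default 5.
#' @return A data.frame with columns `protein_id`, `condition`,
#'   `replicate`, `temperature_c`, `norm_value` (glog2 scale). The
#'   attribute `"calibration"` is a data.frame of per-sample scale factors
#'   and per-temperature glog offsets.
#' @export
normalize_per_temperature <- function(table, glog_percentile = 5) {
  stopifnot(glog_percentile > 0, glog_percentile < 100)
  if (nrow(table) == 0) stop("empty quantification table")
  if (any(table$intensity < 0, na.rm = TRUE)) {
    stop("negative intensities are not allowed")
  }
  table$sample <- paste(table$condition, table$replicate, sep = ".")
  temps <- sort(unique(table$temperature_c))
  out_pieces <- vector("list", length(temps))
  calib <- vector("list", length(temps))
  for (i in seq_along(temps)) {
    tt <- temps[i]
    sub <- table[table$temperature_c == tt, , drop = FALSE]
    samples <- sort(unique(sub$sample))
    if (length(samples) < 2) {
      stop("temperature ", tt, " has fewer than 2 samples")
    }
    if (all(is.na(sub$intensity))) {
      stop("temperature ", tt, " has no observed intensities")
    }
    # wide protein x sample matrix at this temperature
    prot <- sort(unique(sub$protein_id))
    m <- matrix(NA_real_, length(prot), length(samples),
                dimnames = list(prot, samples))
    m[cbind(match(sub$protein_id, prot), match(sub$sample, samples))] <-
      sub$intensity
    pos <- m > 0
    complete <- rowSums(!is.na(m) & pos, na.rm = TRUE) == ncol(m)
    if (any(complete)) {
      mc <- m[complete, , drop = FALSE]
      gm <- exp(rowMeans(log(mc)))
      sf <- apply(mc / gm, 2, stats::median)
    } else {
      # fallback: pairwise median ratio to the first sample
      ref <- m[, 1]
      sf <- vapply(seq_len(ncol(m)), function(j) {
        r <- m[, j] / ref
        r <- r[is.finite(r) & r > 0]
        if (length(r) == 0) 1 else stats::median(r)
      }, numeric(1))
      names(sf) <- samples
    }
    if (any(!is.finite(sf) | sf <= 0)) {
      stop("degenerate scale factor at temperature ", tt)
    }
    scaled <- sweep(m, 2, sf, "/")
    posvals <- scaled[!is.na(scaled) & scaled > 0]
    if (length(posvals) == 0) stop("no positive intensities at ", tt)
    # each temperature is an independent run: rescale to a common level so
    # norm values are comparable across temperatures regardless of the
    # shrinking absolute signal (and invariant to the run's overall scale)
    gt <- stats::median(posvals)
    scaled <- scaled / gt
    posvals <- posvals / gt
    ct <- stats::quantile(posvals, glog_percentile / 100, names = FALSE)
    nv <- log2((scaled + sqrt(scaled^2 + ct^2)) / 2)
    idx <- which(!is.na(m), arr.ind = TRUE)
    sm <- samples[idx[, 2]]
    cr <- do.call(rbind, strsplit(sm, ".", fixed = TRUE))
    out_pieces[[i]] <- data.frame(
      protein_id = prot[idx[, 1]],
      condition = cr[, 1],
      replicate = as.integer(cr[, 2]),
      temperature_c = tt,
      norm_value = nv[idx])
    calib[[i]] <- data.frame(temperature_c = tt, sample = samples,
                             scale_factor = unname(sf), run_level = gt,
                             glog_offset = ct)
  }
  out <- do.call(rbind, out_pieces)
  out <- out[order(out$protein_id, out$condition, out$replicate,
                   out$temperature_c), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "calibration") <- do.call(rbind, calib)
  out
}

#' Remove additive batch effects from normalized values
#'
#' Per protein and temperature, fits by least squares the linear model
#' `norm_value ~ condition + batch` (treatment coding, first batch as
#' reference) across the samples and subtracts the fitted batch terms, so
#' condition differences are preserved while systematic replicate/batch
#' offsets are removed. In the study design the biological replicate index
#' is the only batch structure, so `batch` defaults to the replicate.
#'
#' Proteins/temperatures whose non-missing values cannot support the
#' design (fewer observations than coefficients, or a batch level absent)
#' are passed through unchanged and flagged in the `"unadjusted"`
#' attribute.
#'
#' @param matrix normalized data.frame from [normalize_per_temperature()].
#' @param batch_of_sample optional named character vector mapping sample
#'   keys (`"condition.replicate"`) to batch labels; default: the
#'   replicate index.
#' @return The data.frame with batch terms subtracted from `norm_value`.
#' @export
remove_batch_effects <- function(matrix, batch_of_sample = NULL) {
  df <- matrix
  df$sample <- paste(df$condition, df$replicate, sep = ".")
  samples <- sort(unique(df$sample))
  scond <- vapply(strsplit(samples, ".", fixed = TRUE), `[`, "", 1)
  if (is.null(batch_of_sample)) {
    sbatch <- vapply(strsplit(samples, ".", fixed = TRUE), `[`, "", 2)
    names(sbatch) <- samples
  } else {
    if (!all(samples %in% names(batch_of_sample))) {
      stop("batch_of_sample is missing sample(s): ",
           paste(setdiff(samples, names(batch_of_sample)), collapse = ", "))
    }
    sbatch <- batch_of_sample[samples]
  }
  batch_f <- factor(sbatch)
  cond_f <- factor(scond)
  if (nlevels(batch_f) == 1) {
    attr(df, "unadjusted") <- character(0)
    df$sample <- NULL
    return(df)
  }
  X <- stats::model.matrix(~ cond_f + batch_f)
  if (qr(X)$rank < ncol(X)) {
    stop("batch is confounded with condition; aliased design columns: ",
         paste(colnames(X)[-seq_len(qr(X)$rank)], collapse = ", "))
  }
  batch_cols <- grep("^batch_f", colnames(X))
  key <- paste(df$protein_id, df$temperature_c, sep = "\r")
  groups <- split(seq_len(nrow(df)), key)
  unadjusted <- character(0)
  adj <- df$norm_value
  # cache least-squares solves per missingness pattern across samples
  solver_cache <- new.env(parent = emptyenv())
  for (g in groups) {
    y <- df$norm_value[g]
    srow <- match(df$sample[g], samples)
    obs <- !is.na(y)
    rows_present <- sort(srow[obs])
    pat <- paste(rows_present, collapse = ",")
    sol <- solver_cache[[pat]]
    if (is.null(sol)) {
      Xp <- X[rows_present, , drop = FALSE]
      keep_lv <- vapply(seq_len(ncol(Xp)), function(j) {
        j == 1 || any(Xp[, j] != 0)
      }, logical(1))
      Xp2 <- Xp[, keep_lv, drop = FALSE]
      ok <- nrow(Xp2) >= ncol(Xp2) && qr(Xp2)$rank == ncol(Xp2)
      sol <- list(ok = ok)
      if (ok) {
        sol$coefmap <- which(keep_lv)
        sol$pinv <- solve(crossprod(Xp2), t(Xp2))
      }
      solver_cache[[pat]] <- sol
    }
    if (!sol$ok) {
      unadjusted <- c(unadjusted, df$protein_id[g[1]])
      next
    }
    yp <- y[obs][order(srow[obs])]  # align with rows_present order
    beta <- drop(sol$pinv %*% yp)
    full_beta <- numeric(ncol(X))
    full_beta[sol$coefmap] <- beta
    batch_effect <- drop(X[, batch_cols, drop = FALSE] %*%
                           full_beta[batch_cols])
    adj[g] <- y - batch_effect[srow]
  }
  df$norm_value <- adj
  df$sample <- NULL
  attr(df, "unadjusted") <- unique(unadjusted)
  df
}
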