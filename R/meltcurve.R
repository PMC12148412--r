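#' Sigmoid melting model
#'
#' The non-denatured (soluble) fraction of a protein along the heating
#' gradient is modeled with a three-parameter sigmoid. Two
#' parameterizations are supported:
#' \describe{
#'   \item{`"reciprocal"`}{\eqn{f(T) = (1 - plateau) / (1 + e^{-(a/T - b)}) + plateau},
#'     the canonical TPP melting equation: for `a > 0` it decreases with
#'     temperature and approaches 1 at low T.}
#'   \item{`"linear"`}{\eqn{f(T) = (1 - plateau) / (1 + e^{aT - b}) + plateau},
#'     a logistic directly in T, with the sign convention chosen so that
#'     `a > 0` again gives melting (decreasing) behavior.}
#' }
#' `plateau` in `[0, 1)` is the residual soluble fraction at high
#' temperature.
#'
#' @param a slope parameter (> 0 for a melting curve).
#' @param b offset parameter.
#' @param plateau high-temperature plateau, in `[0, 1)`.
#' @param form `"reciprocal"` (default) or `"linear"`.
#' @return An object of class `melting_model`.
#' @export
melting_model <- function(a, b, plateau = 0, form = c("reciprocal", "linear")) {
  form <- match.arg(form)
  stopifnot(is.finite(a), is.finite(b), is.finite(plateau),
            plateau >= 0, plateau < 1)
  structure(list(a = a, b = b, plateau = plateau, form = form),
            class = "melting_model")
}

#' Evaluate the sigmoid soluble fraction
#'
#' @param t_c temperature(s) in degrees Celsius (> 0 for the reciprocal
#'   form).
#' @param model a [melting_model].
#' @return Numeric vector of fractions in `(plateau, 1)` for finite T.
#' @examples
#' m <- melting_model(a = 2500, b = 50, plateau = 0)
#' sigmoid_fraction(50, m)  # 0.5: a/T - b = 0 is the midpoint
#' @export
sigmoid_fraction <- function(t_c, model) {
  p <- model$plateau
  x <- switch(model$form,
              reciprocal = -(model$a / t_c - model$b),
              linear = model$a * t_c - model$b)
  (1 - p) / (1 + exp(x)) + p
}

#' Melting temperature of a sigmoid model
#'
#' Tm is the temperature at which the soluble fraction equals 0.5,
#' obtained in closed form. With \eqn{q = \ln(0.5 / (0.5 - plateau))}:
#' reciprocal form \eqn{Tm = a / (b - q)}; linear form
#' \eqn{Tm = (b + q) / a}. Undefined (NA) when `plateau >= 0.5` (the curve
#' never crosses 0.5) or when the closed form lands at a non-physical
#' (non-positive) temperature.
#'
#' @param model a [melting_model].
#' @return Tm in degrees Celsius, or `NA_real_` when undefined.
#' @export
compute_tm <- function(model) {
  p <- model$plateau
  if (p >= 0.5) return(NA_real_)
  q <- log(0.5 / (0.5 - p))
  tm <- switch(model$form,
               reciprocal = {
                 den <- model$b - q
                 if (den <= 0) NA_real_ else model$a / den
               },
               linear = (model$b + q) / model$a)
  if (!is.finite(tm) || tm <= 0) NA_real_ else tm
}

#' Fractional solubility relative to the lowest temperature
#'
#' Divides a per-temperature intensity profile by its value at the lowest
#' gradient temperature Tmin, so the fraction at Tmin is fixed at exactly
#' 1 (at 37 degrees Celsius in the default gradient). Missing
#' intensities stay missing.
#'
#' @param intensities numeric vector of intensities ordered as
#'   `channel_map$temperatures_c`.
#' @param channel_map a [channel_map].
#' @return Numeric vector of fractions, or `NULL` (with a warning) when
#'   the Tmin value is missing or non-positive — the profile is
#'   unfittable.
#' @export
compute_fractions <- function(intensities, channel_map = default_channel_map()) {
  if (length(intensities) != length(channel_map$temperatures_c)) {
    stop("profile length does not match the channel map")
  }
  ref <- intensities[1]
  if (is.na(ref) || ref <= 0) {
    warning("reference (Tmin) intensity missing or non-positive; unfittable")
    return(NULL)
  }
  intensities / ref
}

#' Fit the sigmoid melting curve to one fraction profile
#'
#' Nonlinear least squares (Levenberg-Marquardt with box bounds) over
#' `(a, b, plateau)` with `a > 0` and `plateau` in `[0, 0.5]` so that Tm
#' exists whenever the fit converges. Starts from a small grid of slope
#' guesses with `b` matched to the temperature at which the observed
#' profile first crosses 0.5 (the plateau seeded at the smallest observed
#' fraction); the best converged start by residual sum of squares wins.
#'
#' @param temperatures numeric vector of temperatures (degrees Celsius).
#' @param fractions numeric vector of observed soluble fractions, same
#'   length; NAs allowed.
#' @param form model parameterization, `"reciprocal"` (default) or
#'   `"linear"`.
#' @param min_points minimum number of non-missing points; default 5.
#' @param plateau_max upper bound for the plateau; default 0.5.
#' @return A list of class `curve_fit` with elements `model`
#'   ([melting_model] or `NULL`), `tm_c`, `r2` (`NA` when the profile has
#'   zero total variance), `converged`, `n_points`.
#' @export
fit_melting_curve <- function(temperatures, fractions,
                              form = c("reciprocal", "linear"),
                              min_points = 5, plateau_max = 0.5) {
  form <- match.arg(form)
  ok <- is.finite(temperatures) & is.finite(fractions)
  tt <- temperatures[ok]
  ff <- fractions[ok]
  res <- structure(list(model = NULL, tm_c = NA_real_, r2 = NA_real_,
                        converged = FALSE, n_points = length(ff)),
                   class = "curve_fit")
  if (length(ff) < min_points) return(res)
  sstot <- sum((ff - mean(ff))^2)
  # seed b from the first downward crossing of 0.5
  below <- which(ff < 0.5)
  t_half <- if (length(below) > 0) {
    i <- below[1]
    if (i == 1) tt[1] else {
      # linear interpolation between the bracketing points
      t0 <- tt[i - 1]; t1 <- tt[i]; f0 <- ff[i - 1]; f1 <- ff[i]
      t0 + (0.5 - f0) * (t1 - t0) / (f1 - f0)
    }
  } else max(tt)
  p0 <- max(0, min(min(ff), plateau_max - 1e-3))
  starts <- lapply(c(550, 1500, 3000), function(a0) {
    if (form == "reciprocal") {
      list(a = a0, b = a0 / t_half, plateau = p0)
    } else {
      aa <- a0 / t_half^2  # comparable midpoint steepness
      list(a = aa, b = aa * t_half, plateau = p0)
    }
  })
  fn <- if (form == "reciprocal") {
    function(a, b, plateau, T) (1 - plateau) / (1 + exp(-(a / T - b))) + plateau
  } else {
    function(a, b, plateau, T) (1 - plateau) / (1 + exp(a * T - b)) + plateau
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        ff ~ fn(a, b, plateau, tt),
        start = st,
        lower = c(a = 1e-9, b = -Inf, plateau = 0),
        upper = c(a = Inf, b = Inf, plateau = plateau_max),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(stats::residuals(fit)^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) return(res)
  cf <- stats::coef(best$fit)
  model <- melting_model(cf[["a"]], cf[["b"]], min(cf[["plateau"]], 1 - 1e-12),
                         form = form)
  res$model <- model
  res$converged <- TRUE
  res$r2 <- if (sstot > 0) 1 - best$ssr / sstot else NA_real_
  res$tm_c <- if (model$plateau < 0.5 && sstot > 0) compute_tm(model) else NA_real_
  res
}

#' @export
print.curve_fit <- function(x, ...) {
  if (is.null(x$model)) {
    cat("melting-curve fit: not converged (n =", x$n_points, ")\n")
  } else {
    cat(sprintf(
      "melting-curve fit (%s form): a=%.4g b=%.4g plateau=%.4g Tm=%.2f C r2=%.4f (n=%d)\n",
      x$model$form, x$model$a, x$model$b, x$model$plateau,
      x$tm_c, x$r2, x$n_points))
  }
  invisible(x)
}

#' Fit melting curves for every protein/condition/replicate profile
#'
#' Computes fractional solubility with [compute_fractions()] and fits the
#' sigmoid per (protein, condition, replicate) profile. Profiles with a
#' missing or non-positive Tmin intensity, or too few points, are reported
#' with `converged = FALSE`.
#'
#' @param table long quantification data.frame (`protein_id`, `condition`,
#'   `replicate`, `temperature_c`, `intensity`). Raw or normalized
#'   intensities may be used; fractions are relative so per-temperature
#'   scale factors cancel only if applied uniformly — fitting on raw or
#'   per-sample-scaled intensities is recommended.
#' @param channel_map a [channel_map] defining the gradient.
#' @param form model parameterization.
#' @return data.frame with one row per profile: `protein_id`, `condition`,
#'   `replicate`, `a`, `b`, `plateau`, `tm_c`, `r2`, `converged`,
#'   `n_points`.
#' @export
fit_melting_curves <- function(table, channel_map = default_channel_map(),
                               form = c("reciprocal", "linear")) {
  form <- match.arg(form)
  temps <- channel_map$temperatures_c
  key <- paste(table$protein_id, table$condition, table$replicate, sep = "\r")
  groups <- split(seq_len(nrow(table)), key)
  rows <- lapply(names(groups), function(k) {
    g <- groups[[k]]
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    prof <- rep(NA_real_, length(temps))
    prof[match(table$temperature_c[g], temps)] <- table$intensity[g]
    base <- data.frame(protein_id = parts[1], condition = parts[2],
                       replicate = as.integer(parts[3]))
    fr <- suppressWarnings(compute_fractions(prof, channel_map))
    if (is.null(fr)) {
      return(cbind(base, a = NA_real_, b = NA_real_, plateau = NA_real_,
                   tm_c = NA_real_, r2 = NA_real_, converged = FALSE,
                   n_points = sum(is.finite(prof))))
    }
    ft <- fit_melting_curve(temps, fr, form = form)
    cbind(base,
          a = if (is.null(ft$model)) NA_real_ else ft$model$a,
          b = if (is.null(ft$model)) NA_real_ else ft$model$b,
          plateau = if (is.null(ft$model)) NA_real_ else ft$model$plateau,
          tm_c = ft$tm_c, r2 = ft$r2, converged = ft$converged,
          n_points = ft$n_points)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$protein_id, out$condition, out$replicate), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
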