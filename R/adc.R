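#' Construct a multi-b-value DWI series
#'
#' A 4D diffusion-weighted stack bound to its b-value schedule. The first
#' axis indexes b-values; the remaining three form the voxel grid.
#'
#' @param values numeric 4D array, dimension (n_b, nx, ny, nz).
#' @param b_values numeric vector of diffusion weightings in s/mm^2,
#'   strictly increasing, starting at 0; at least two values (three or
#'   more recommended when the nonlinear refinement is used).
#' @param spacing numeric length-3 voxel spacing in mm.
#' @return An object of class \code{dwi_series}.
#' @export
dwi_series <- function(values, b_values, spacing) {
  if (!is.array(values) || length(dim(values)) != 4L)
    stop("'values' must be a 4D array (b-value, x, y, z)", call. = FALSE)
  b_values <- as.numeric(b_values)
  if (length(b_values) < 2L)
    stop("at least 2 b-values are required", call. = FALSE)
  if (b_values[1] != 0)
    stop("the first b-value must be 0 s/mm^2", call. = FALSE)
  if (any(diff(b_values) <= 0))
    stop("b-values must be strictly increasing", call. = FALSE)
  if (dim(values)[1] != length(b_values))
    stop("first axis length must equal the number of b-values",
         call. = FALSE)
  spacing <- check_spacing(spacing)
  structure(list(values = values, b_values = b_values, spacing = spacing),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  d <- dim(x$values)
  cat("<dwi_series> ", paste(d[-1], collapse = " x "), " voxels, ",
      d[1], " b-values (", x$b_values[1], "-", max(x$b_values),
      " s/mm^2) @ ", paste(format(x$spacing), collapse = " x "), " mm\n",
      sep = "")
  invisible(x)
}

#' Default 13-b-value schedule
#'
#' A dense low-b schedule of 13 values spanning 0-1000 s/mm^2, the kind
#' typically used for mono-exponential ADC mapping of pelvic tumours.
#' Fully replaceable; no result in the package depends on the exact
#' spacing of the schedule.
#'
#' @return Numeric vector of 13 b-values in s/mm^2.
#' @export
default_b_values <- function() {
  c(0, 25, 50, 75, 100, 150, 200, 300, 400, 500, 600, 800, 1000)
}

#' Mono-exponential DWI signal model
#'
#' Predicted signal \eqn{S_b = S_0 e^{-b \cdot ADC}} at diffusion
#' weighting \code{b}.
#'
#' @param s0 signal at b = 0 (non-negative).
#' @param adc apparent diffusion coefficient in mm^2/s (non-negative).
#' @param b diffusion weighting in s/mm^2 (non-negative). Arguments are
#'   recycled as usual.
#' @return Predicted signal, same units as \code{s0}.
#' @export
predict_signal <- function(s0, adc, b) {
  if (any(s0 < 0) || any(adc < 0) || any(b < 0))
    stop("s0, adc and b must all be non-negative", call. = FALSE)
  s0 * exp(-b * adc)
}

#' Voxel-wise mono-exponential ADC fit
#'
#' Fits \eqn{S_b = S_0 e^{-b \cdot ADC}} independently in every voxel of a
#' DWI series. A log-linear least-squares fit of \eqn{\ln S_b} against
#' \eqn{b} provides the initial estimate; by default it is refined by
#' damped (Levenberg-Marquardt) nonlinear least squares minimising
#' \eqn{\sum_b (S_b - S_0 e^{-b \cdot ADC})^2} on the untransformed
#' signal. All voxels are iterated simultaneously with per-voxel damping,
#' so the fit is fast even for whole-volume maps.
#'
#' Voxels with non-positive signal at some b-values use only the positive
#' samples for the log-linear initialisation; voxels with fewer than two
#' usable samples, or that fail to converge, are flagged \code{fit_ok =
#' FALSE} rather than aborting the fit. Negative ADC estimates (possible
#' in noise) are clamped to 0 and recorded in \code{adc_clamped}.
#'
#' Background air voxels carry no tissue signal and are excluded:
#' any voxel whose b = 0 signal falls below \code{background_frac} of the
#' robust (99th percentile) maximum over the fitted region is skipped.
#' Set \code{background_frac = 0} to fit everything.
#'
#' @param series a \code{\link{dwi_series}}.
#' @param mask optional \code{\link{vol_mask}} restricting the fit; by
#'   default the whole grid (minus background) is fitted.
#' @param method \code{"nls"} (log-linear initialisation + LM refinement,
#'   the default) or \code{"loglinear"} (initialisation only).
#' @param background_frac background-exclusion fraction of the robust
#'   maximum b = 0 signal (default 0.05).
#' @param tol relative parameter-change convergence tolerance for the
#'   LM refinement (default 1e-8).
#' @param max_iter maximum LM iterations (default 200).
#' @return An object of class \code{adc_fit} with 3D maps \code{adc}
#'   (mm^2/s), \code{s0}, \code{fit_ok}, \code{adc_clamped} and
#'   \code{residual_rms}; voxels outside the fitted region are NA.
#' @export
fit_adc <- function(series, mask = NULL, method = c("nls", "loglinear"),
                    background_frac = 0.05, tol = 1e-8, max_iter = 200L) {
  stopifnot(inherits(series, "dwi_series"))
  method <- match.arg(method)
  b <- series$b_values
  nb <- length(b)
  d <- dim(series$values)[-1]

  if (is.null(mask)) {
    in_fit <- rep(TRUE, prod(d))
  } else {
    stopifnot(inherits(mask, "vol_mask"))
    if (!identical(dim(mask$values), d) ||
        max(abs(mask$spacing - series$spacing)) > 1e-6)
      stop("mask must share the DWI series' grid", call. = FALSE)
    in_fit <- as.vector(mask$values)
  }

  # voxels x b matrix of signals
  S <- matrix(aperm(series$values, c(2, 3, 4, 1)), nrow = prod(d), ncol = nb)
  S <- S[in_fit, , drop = FALSE]

  if (background_frac > 0 && nrow(S) > 0) {
    s_b0 <- S[, 1]
    robust_max <- stats::quantile(s_b0, 0.99, names = FALSE, na.rm = TRUE)
    tissue <- is.finite(s_b0) & s_b0 >= background_frac * robust_max
  } else {
    tissue <- rep(TRUE, nrow(S))
  }

  fit <- fit_monoexp_matrix(S[tissue, , drop = FALSE], b,
                            refine = (method == "nls"),
                            tol = tol, max_iter = max_iter)
  if (!any(fit$fit_ok))
    stop("no voxel yielded a usable mono-exponential fit", call. = FALSE)

  expand <- function(vals, default = NA_real_) {
    full <- rep(default, prod(d))
    inner <- rep(default, length(tissue))
    inner[tissue] <- vals
    full[in_fit] <- inner
    array(full, dim = d)
  }

  structure(list(
    adc = expand(fit$adc),
    s0 = expand(fit$s0),
    fit_ok = expand(as.numeric(fit$fit_ok), 0) > 0,
    adc_clamped = expand(as.numeric(fit$adc_clamped), 0) > 0,
    residual_rms = expand(fit$residual_rms),
    spacing = series$spacing,
    b_values = b,
    method = method,
    n_fitted = sum(fit$fit_ok),
    n_voxels = sum(tissue)
  ), class = "adc_fit")
}

# Core fitter on an (n voxels) x (n b-values) signal matrix.
# Log-linear initialisation on positive samples, then vectorised LM with
# per-voxel damping; the 2x2 damped normal equations are solved in closed
# form for all active voxels at once.
fit_monoexp_matrix <- function(S, b, refine = TRUE, tol = 1e-8,
                               max_iter = 200L) {
  nv <- nrow(S)
  nb <- length(b)
  if (nv == 0L)
    return(list(adc = numeric(0), s0 = numeric(0), fit_ok = logical(0),
                adc_clamped = logical(0), residual_rms = numeric(0)))

  B <- matrix(b, nrow = nv, ncol = nb, byrow = TRUE)
  W <- is.finite(S) & S > 0
  n <- rowSums(W)
  usable <- n >= 2

  Y <- ifelse(W, log(pmax(S, .Machine$double.xmin)), 0)
  sb <- rowSums(W * B); sbb <- rowSums(W * B * B)
  sy <- rowSums(Y); sby <- rowSums(B * Y)
  denom <- n * sbb - sb * sb
  usable <- usable & abs(denom) > 0
  slope <- ifelse(usable, (n * sby - sb * sy) / denom, NA_real_)
  icpt <- ifelse(usable, (sy - slope * sb) / n, NA_real_)
  adc <- -slope
  s0 <- exp(icpt)
  converged <- usable

  if (refine && any(usable)) {
    # Keep adc bounded below so exp(-b*adc) cannot overflow at large b.
    adc_floor <- -10 / max(b)
    idx <- which(usable)
    a <- pmax(adc[idx], adc_floor)
    s <- pmax(s0[idx], 0)
    Si <- S[idx, , drop = FALSE]
    Wi <- is.finite(Si)
    Si[!Wi] <- 0
    Bi <- B[idx, , drop = FALSE]
    lam <- rep(1e-3, length(idx))
    done <- rep(FALSE, length(idx))

    sse_of <- function(s, a) {
      E <- exp(-Bi * a)
      rowSums(Wi * (Si - s * E)^2)
    }
    sse <- sse_of(s, a)

    for (it in seq_len(max_iter)) {
      act <- which(!done)
      if (length(act) == 0L) break
      E <- exp(-Bi[act, , drop = FALSE] * a[act])
      R <- Wi[act, , drop = FALSE] *
        (Si[act, , drop = FALSE] - s[act] * E)
      J2 <- -s[act] * Bi[act, , drop = FALSE] * E
      a11 <- rowSums(Wi[act, , drop = FALSE] * E * E)
      a22 <- rowSums(Wi[act, , drop = FALSE] * J2 * J2)
      a12 <- rowSums(Wi[act, , drop = FALSE] * E * J2)
      g1 <- rowSums(E * R)
      g2 <- rowSums(J2 * R)
      m11 <- a11 * (1 + lam[act])
      m22 <- a22 * (1 + lam[act])
      det <- m11 * m22 - a12 * a12
      ok <- is.finite(det) & abs(det) > .Machine$double.xmin
      d1 <- ifelse(ok, (m22 * g1 - a12 * g2) / det, 0)
      d2 <- ifelse(ok, (m11 * g2 - a12 * g1) / det, 0)
      s_new <- pmax(s[act] + d1, 0)
      a_new <- pmax(a[act] + d2, adc_floor)
      E2 <- exp(-Bi[act, , drop = FALSE] * a_new)
      sse_new <- rowSums(Wi[act, , drop = FALSE] *
                           (Si[act, , drop = FALSE] - s_new * E2)^2)
      accept <- is.finite(sse_new) & sse_new <= sse[act] & ok
      rel <- pmax(abs(d1) / (abs(s[act]) + 1e-12),
                  abs(d2) / (abs(a[act]) + 1e-12))
      s[act][accept] <- s_new[accept]
      a[act][accept] <- a_new[accept]
      sse[act][accept] <- sse_new[accept]
      lam[act][accept] <- pmax(lam[act][accept] / 3, 1e-12)
      lam[act][!accept] <- lam[act][!accept] * 8
      done[act] <- (accept & rel < tol) | (!ok) |
        (!accept & lam[act] > 1e12)
    }
    adc[idx] <- a
    s0[idx] <- s
    converged[idx] <- done
  }

  clamped <- usable & is.finite(adc) & adc < 0
  adc[clamped] <- 0
  fit_ok <- usable & converged & is.finite(adc) & is.finite(s0)

  E <- exp(-B * ifelse(is.finite(adc), adc, 0))
  resid <- ifelse(is.finite(S), S, 0) - ifelse(is.finite(s0), s0, 0) * E
  rms <- sqrt(rowSums(resid^2 * is.finite(S)) / pmax(rowSums(is.finite(S)), 1))
  rms[!fit_ok] <- NA_real_

  list(adc = adc, s0 = s0, fit_ok = fit_ok, adc_clamped = clamped,
       residual_rms = rms)
}

#' @export
print.adc_fit <- function(x, ...) {
  cat("<adc_fit> mono-exponential ADC map (method: ", x$method, ")\n",
      "  ", x$n_fitted, " / ", x$n_voxels,
      " voxels fitted successfully\n", sep = "")
  ok <- x$fit_ok & !is.na(x$adc)
  if (any(ok)) {
    cat(sprintf("  median ADC: %.3f x10^-3 mm^2/s; median S0: %.1f\n",
                1000 * stats::median(x$adc[ok]),
                stats::median(x$s0[ok])))
  }
  invisible(x)
}

#' @export
summary.adc_fit <- function(object, ...) {
  ok <- object$fit_ok & !is.na(object$adc)
  out <- list(
    n_fitted = object$n_fitted,
    n_voxels = object$n_voxels,
    n_clamped = sum(object$adc_clamped, na.rm = TRUE),
    adc_quartiles = stats::quantile(object$adc[ok], c(.25, .5, .75)),
    s0_quartiles = stats::quantile(object$s0[ok], c(.25, .5, .75)),
    median_residual_rms = stats::median(object$residual_rms[ok])
  )
  class(out) <- "summary.adc_fit"
  out
}

#' @export
print.summary.adc_fit <- function(x, ...) {
  cat("Mono-exponential ADC fit\n")
  cat(sprintf("  fitted voxels: %d / %d (%d clamped to ADC = 0)\n",
              x$n_fitted, x$n_voxels, x$n_clamped))
  cat(sprintf("  ADC quartiles (x10^-3 mm^2/s): %.3f / %.3f / %.3f\n",
              1000 * x$adc_quartiles[1], 1000 * x$adc_quartiles[2],
              1000 * x$adc_quartiles[3]))
  cat(sprintf("  S0 quartiles: %.1f / %.1f / %.1f\n",
              x$s0_quartiles[1], x$s0_quartiles[2], x$s0_quartiles[3]))
  cat(sprintf("  median residual RMS: %.4g\n", x$median_residual_rms))
  invisible(x)
}

#' Predicted signals from a fitted ADC map
#'
#' Evaluates the fitted mono-exponential model at the requested b-values,
#' returning one 3D volume per b-value.
#'
#' @param object an \code{\link{fit_adc}} result.
#' @param b b-values at which to predict (default: the fitted schedule).
#' @param ... unused.
#' @return A 4D array (b-value, x, y, z).
#' @export
predict.adc_fit <- function(object, b = object$b_values, ...) {
  d <- dim(object$adc)
  out <- array(NA_real_, dim = c(length(b), d))
  for (i in seq_along(b)) {
    out[i, , , ] <- object$s0 * exp(-b[i] * object$adc)
  }
  out
}
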