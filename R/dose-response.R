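#' Four-parameter logistic curve
#'
#' \eqn{y = bottom + (top - bottom) / (1 + (x / ic50)^{hill})}. With a
#' positive Hill slope the response falls from `top` at low dose to
#' `bottom` at high dose; a negative slope gives a rising curve. At
#' `x = ic50` the response is the midpoint `(top + bottom) / 2` for any
#' slope.
#'
#' @param x Dose (same units as `ic50`), strictly positive.
#' @param bottom,top Lower/upper response asymptotes.
#' @param ic50 Midpoint dose, > 0.
#' @param hill Hill slope, non-zero.
#' @return Response at `x`.
#' @export
fourpl <- function(x, bottom, top, ic50, hill) {
  bottom + (top - bottom) / (1 + (x / ic50)^hill)
}

#' Invert a four-parameter logistic curve
#'
#' Dose at which the curve attains response `y`; defined only strictly
#' between the asymptotes.
#'
#' @param y Response strictly between `bottom` and `top`.
#' @inheritParams fourpl
#' @return Dose, > 0.
#' @export
fourpl_inverse <- function(y, bottom, top, ic50, hill) {
  r <- (top - y) / (y - bottom)
  if (any(r <= 0)) stop("response outside the open (bottom, top) range")
  ic50 * r^(1 / hill)
}

#' Fit a four-parameter logistic dose-response model
#'
#' Multi-start nonlinear least squares on log10 dose: starting values are
#' taken over a log-spaced grid of candidate IC50s crossed with Hill
#' slopes of both signs, each polished with Levenberg-Marquardt, and the
#' converged fit with the lowest residual sum of squares is kept.
#' Residuals are unweighted. The fit is canonicalized so `bottom <= top`
#' (the 4PL is invariant under swapping asymptotes and negating the
#' slope). If no start converges, `converged` is `FALSE` and no
#' parameters are fabricated.
#'
#' @param data data.frame with columns `dose` (strictly positive, at least
#'   4 distinct values) and `response`; replicates as extra rows.
#' @return Object of class `fourpl_fit`: list with `bottom`, `top`,
#'   `ic50`, `hill`, `converged`, `rss`, `n`, `data`, and `diagnostics`
#'   when the fit failed.
#' @export
fit_4pl <- function(data) {
  stopifnot(is.data.frame(data), all(c("dose", "response") %in% names(data)))
  x <- data$dose
  y <- data$response
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("doses and responses must be finite")
  if (any(x <= 0)) stop("doses must be strictly positive")
  if (length(unique(x)) < 4)
    stop("need at least 4 distinct doses to fit a 4PL")

  lx <- log10(x)
  lic_grid <- seq(min(lx), max(lx), length.out = 5)
  hill_grid <- c(0.5, 1, 2, -0.5, -1, -2)
  b0 <- min(y); t0 <- max(y)
  if (t0 == b0) t0 <- b0 + 1 # flat data: let the optimizer collapse it back

  best <- NULL
  msgs <- character()
  for (lic in lic_grid) for (h in hill_grid) {
    fit <- fourpl_lm(lx, y, c(b0, t0, lic, h))
    if (is.character(fit)) { msgs <- c(msgs, fit); next }
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }

  if (is.null(best)) {
    out <- list(bottom = NA_real_, top = NA_real_, ic50 = NA_real_,
                hill = NA_real_, converged = FALSE, rss = NA_real_,
                n = length(y), data = data,
                diagnostics = unique(msgs))
    class(out) <- "fourpl_fit"
    return(out)
  }

  p <- best$par
  bottom <- p[1]; top <- p[2]
  ic50 <- 10^p[3]; hill <- p[4]
  if (bottom > top) { tmp <- bottom; bottom <- top; top <- tmp; hill <- -hill }
  out <- list(bottom = bottom, top = top, ic50 = ic50, hill = hill,
              converged = TRUE, rss = best$deviance, n = length(y),
              data = data)
  class(out) <- "fourpl_fit"
  out
}

# One Levenberg-Marquardt descent on (bottom, top, log10 ic50, hill);
# returns the nls.lm result, or the failure message as a string.
fourpl_lm <- function(lx, y, par0, maxiter = 300) {
  resid_fn <- function(p)
    y - (p[1] + (p[2] - p[1]) / (1 + 10^(p[4] * (lx - p[3]))))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = maxiter, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) conditionMessage(e))
  if (is.character(fit)) return(fit)
  if (!fit$info %in% 1:4) return(fit$message)
  fit
}

#' @export
print.fourpl_fit <- function(x, ...) {
  if (!x$converged) {
    cat("4PL fit: did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("4PL fit (n = %d): bottom %.4g, top %.4g, IC50 %.4g, hill %.3g, RSS %.4g\n",
              x$n, x$bottom, x$top, x$ic50, x$hill, x$rss))
  invisible(x)
}

#' @export
predict.fourpl_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$dose else newdata$dose
  fourpl(x, object$bottom, object$top, object$ic50, object$hill)
}

#' Percentile bootstrap confidence interval for the IC50
#'
#' Nonparametric case resampling: within each dose, replicate rows are
#' resampled with replacement and the 4PL refit (starting from the
#' original estimates); the 2.5/97.5 percentiles of the resampled IC50s
#' form the interval. Seed-deterministic.
#'
#' @param data Dose-response table passed to [fit_4pl()].
#' @param fit A converged `fourpl_fit`.
#' @param n_boot Number of bootstrap refits (default 1000; below 100 a
#'   warning is recorded in the result).
#' @param seed Integer seed.
#' @return List with `ci_low`, `ci_high`, `n_boot`, `n_failed`, `warning`.
#' @export
bootstrap_ci <- function(data, fit, n_boot = 1000, seed = 1) {
  if (!inherits(fit, "fourpl_fit") || !fit$converged)
    stop("bootstrap_ci requires a converged fourpl_fit")
  warn <- if (n_boot < 100)
    sprintf("n_boot = %d is below 100; interval will be unstable", n_boot)
  else NA_character_
  idx_by_dose <- split(seq_len(nrow(data)), data$dose)
  start <- c(fit$bottom, fit$top, log10(fit$ic50), fit$hill)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      rows <- unlist(lapply(idx_by_dose, function(i)
        i[sample.int(length(i), length(i), replace = TRUE)]))
      d <- data[rows, , drop = FALSE]
      f <- fourpl_lm(log10(d$dose), d$response, start, maxiter = 100)
      if (is.character(f)) NA_real_ else 10^f$par[3]
    }, numeric(1))
  })
  ok <- boots[is.finite(boots)]
  ci <- stats::quantile(ok, c(0.025, 0.975), names = FALSE, type = 7)
  list(ci_low = ci[1], ci_high = ci[2], n_boot = n_boot,
       n_failed = n_boot - length(ok), warning = warn)
}

#' Cheng-Prusoff conversion of IC50 to Ki
#'
#' For competitive binding against a tracer at concentration `tracer_conc`
#' with dissociation constant `tracer_kd`:
#' \eqn{K_i = IC_{50} / (1 + [L]/K_d)}. Always <= IC50, approaching it as
#' the tracer concentration vanishes.
#'
#' @param ic50 Fitted half-maximal displacement concentration (> 0).
#' @param tracer_conc Tracer concentration, same units as `tracer_kd` (> 0).
#' @param tracer_kd Tracer dissociation constant (> 0).
#' @return Ki in the units of `ic50`.
#' @export
cheng_prusoff_ki <- function(ic50, tracer_conc, tracer_kd) {
  if (any(c(ic50, tracer_conc, tracer_kd) <= 0))
    stop("ic50, tracer_conc and tracer_kd must all be positive")
  ic50 / (1 + tracer_conc / tracer_kd)
}

#' Endpoint growth inhibition from impedance-style growth curves
#'
#' Each dose's cell-index curve is normalized to its value at the
#' treatment time (normalized cell index, NCI), and inhibition at the
#' endpoint is \eqn{1 - NCI_d(t_{end}) / NCI_{vehicle}(t_{end})}, clipped
#' to \[0, 1\] (clipping is reported). The vehicle is the dose-0 curve.
#'
#' @param curves data.frame with columns `time_h`, `dose` (0 = vehicle)
#'   and `cell_index`; all doses must share the time grid, which must
#'   contain `t_treat` and `t_end`.
#' @param t_treat Treatment time (h) used for normalization.
#' @param t_end Endpoint time (h).
#' @return List with `data` (data.frame `dose`, `response` = inhibition
#'   fraction, nonzero doses only), `nci_end` per dose, and `clipped`
#'   (doses whose raw inhibition fell outside \[0, 1\]).
#' @export
growth_endpoint_inhibition <- function(curves, t_treat, t_end) {
  stopifnot(all(c("time_h", "dose", "cell_index") %in% names(curves)))
  if (!any(curves$dose == 0)) stop("vehicle (dose 0) curve is required")
  nci_end <- vapply(split(curves, curves$dose), function(cc) {
    ci_tr <- cc$cell_index[cc$time_h == t_treat]
    ci_end <- cc$cell_index[cc$time_h == t_end]
    if (length(ci_tr) == 0 || length(ci_end) == 0)
      stop("t_treat/t_end not on the shared time grid")
    ci_tr <- mean(ci_tr); ci_end <- mean(ci_end)
    if (ci_tr <= 0) stop("cell index at treatment time must be positive")
    ci_end / ci_tr
  }, numeric(1))
  doses <- as.numeric(names(nci_end))
  veh <- nci_end[doses == 0]
  inhib <- 1 - nci_end / veh
  keep <- doses > 0
  raw <- inhib[keep]
  clipped <- doses[keep][raw < 0 | raw > 1]
  list(data = data.frame(dose = doses[keep], response = pmin(pmax(raw, 0), 1)),
       nci_end = nci_end, clipped = clipped)
}
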