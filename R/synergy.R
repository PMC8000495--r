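#' Two-drug combination grid
#'
#' Container for a dose-matrix combination experiment on the effect
#' scale: `observed[i, j]` is the fraction-of-control effect (0 = no
#' effect, 1 = complete inhibition) at `doses_a[i]` of drug A combined
#' with `doses_b[j]` of drug B. Both axes must include dose 0, so the
#' first row and column are the single-agent margins and the (0, 0) cell
#' is the vehicle.
#'
#' @param doses_a,doses_b Strictly increasing dose axes starting at 0.
#' @param observed Effect matrix, `length(doses_a)` x `length(doses_b)`.
#' @param drug_a,drug_b Optional drug labels.
#' @return Object of class `combination_grid`.
#' @export
combination_grid <- function(doses_a, doses_b, observed,
                             drug_a = "A", drug_b = "B") {
  if (doses_a[1] != 0 || doses_b[1] != 0)
    stop("dose axes must start at 0 (single-agent margins)")
  if (is.unsorted(doses_a, strictly = TRUE) ||
      is.unsorted(doses_b, strictly = TRUE))
    stop("dose axes must be strictly increasing")
  if (!all(dim(observed) == c(length(doses_a), length(doses_b))))
    stop("observed matrix dimensions must match the dose axes")
  structure(list(doses_a = doses_a, doses_b = doses_b,
                 observed = observed, drug_a = drug_a, drug_b = drug_b),
            class = "combination_grid")
}

#' Fit the single-agent margins of a combination grid
#'
#' Delegates to [fit_4pl()] on the dose-B = 0 row (drug A alone) and the
#' dose-A = 0 column (drug B alone); each margin needs at least 4
#' nonzero doses.
#'
#' @param grid A [combination_grid()].
#' @return List with converged `fourpl_fit`s `fit_a` and `fit_b`.
#' @export
fit_single_agents <- function(grid) {
  stopifnot(inherits(grid, "combination_grid"))
  da <- grid$doses_a[-1]; db <- grid$doses_b[-1]
  if (length(da) < 4 || length(db) < 4)
    stop("each margin needs at least 4 nonzero doses")
  fit_a <- fit_4pl(data.frame(dose = da, response = grid$observed[-1, 1]))
  fit_b <- fit_4pl(data.frame(dose = db, response = grid$observed[1, -1]))
  if (!fit_a$converged) stop("single-agent fit for drug A did not converge")
  if (!fit_b$converged) stop("single-agent fit for drug B did not converge")
  list(fit_a = fit_a, fit_b = fit_b)
}

# asymptotic effect range of a fitted 4PL read as an effect-vs-dose curve
fit_effect_range <- function(fit) {
  if (fit$hill < 0) c(e0 = fit$bottom, einf = fit$top)
  else c(e0 = fit$top, einf = fit$bottom)
}

#' Model-expected combination surface
#'
#' Computes the reference (null-interaction) surface for a combination
#' grid from the fitted single-agent curves, under one of three models on
#' the effect-fraction scale:
#' \describe{
#'   \item{bliss}{probabilistic independence,
#'     \eqn{E = E_A + E_B - E_A E_B};}
#'   \item{hsa}{highest single agent, \eqn{E = \max(E_A, E_B)};}
#'   \item{loewe}{dose additivity: the expected effect solves
#'     \eqn{d_A / D_A(E) + d_B / D_B(E) = 1}, with \eqn{D_X(E)} the
#'     fitted single-agent dose of drug X alone producing effect E,
#'     found by monotone root bracketing (tolerance 1e-8). Cells whose
#'     additive effect lies outside the effect range achievable by both
#'     drugs are flagged `out_of_range`, never extrapolated.}
#' }
#' On the single-agent margins the expected surface is set to the
#' observed margins, so synergy deltas vanish there by construction.
#'
#' @param grid A [combination_grid()].
#' @param fits Single-agent fits from [fit_single_agents()].
#' @param model `"loewe"`, `"bliss"` or `"hsa"`.
#' @return Object of class `synergy_surface`: list with `model`,
#'   `expected` matrix and `flags` matrix (`"ok"`, `"margin"`,
#'   `"out_of_range"`).
#' @export
expected_surface <- function(grid, fits, model = c("loewe", "bliss", "hsa")) {
  model <- match.arg(model)
  fa <- fits$fit_a; fb <- fits$fit_b
  if (model == "loewe" && (fa$hill == 0 || fb$hill == 0))
    stop("Loewe needs strictly monotone fitted curves; use bliss or hsa")
  na <- length(grid$doses_a); nb <- length(grid$doses_b)
  ea <- c(0, predict(fa, data.frame(dose = grid$doses_a[-1])))
  eb <- c(0, predict(fb, data.frame(dose = grid$doses_b[-1])))
  expected <- matrix(NA_real_, na, nb)
  flags <- matrix("ok", na, nb)
  flags[1, ] <- "margin"; flags[, 1] <- "margin"
  expected[1, ] <- grid$observed[1, ]
  expected[, 1] <- grid$observed[, 1]

  if (model %in% c("bliss", "hsa")) {
    if (model == "bliss" && (any(ea < 0 | ea > 1) || any(eb < 0 | eb > 1)))
      stop("Bliss requires effects on a [0, 1] fraction scale")
    for (i in 2:na) for (j in 2:nb) {
      expected[i, j] <- if (model == "bliss")
        ea[i] + eb[j] - ea[i] * eb[j] else max(ea[i], eb[j])
    }
    return(structure(list(model = model, expected = expected, flags = flags),
                     class = "synergy_surface"))
  }

  ra <- fit_effect_range(fa); rb <- fit_effect_range(fb)
  elo <- max(ra["e0"], rb["e0"]); ehi <- min(ra["einf"], rb["einf"])
  if (!(ehi > elo))
    stop("fitted single-agent effect ranges do not overlap; Loewe undefined")
  eps <- 1e-12 * (ehi - elo)
  loewe_gap <- function(E, da, db) {
    da / fourpl_inverse(E, fa$bottom, fa$top, fa$ic50, fa$hill) +
      db / fourpl_inverse(E, fb$bottom, fb$top, fb$ic50, fb$hill) - 1
  }
  for (i in 2:na) for (j in 2:nb) {
    da <- grid$doses_a[i]; db <- grid$doses_b[j]
    lo <- elo + max(eps, 1e-9); hi <- ehi - max(eps, 1e-9)
    f_hi <- loewe_gap(hi, da, db)
    if (f_hi > 0) { # additive effect exceeds what both drugs can reach
      flags[i, j] <- "out_of_range"
      next
    }
    root <- stats::uniroot(loewe_gap, c(lo, hi), da = da, db = db,
                           tol = 1e-8)
    expected[i, j] <- root$root
  }
  structure(list(model = model, expected = expected, flags = flags),
            class = "synergy_surface")
}

#' Pointwise synergy deltas and summary score
#'
#' `delta = observed - expected` on the effect scale, so positive values
#' mean more effect than the additive/null reference (synergy) and
#' negative values antagonism. The summary score is the mean delta over
#' interior cells (both doses > 0); out-of-range Loewe cells are dropped
#' from the mean.
#'
#' @param grid A [combination_grid()].
#' @param surface A [expected_surface()] result for that grid.
#' @return The surface with `delta` matrix and `summary_score` added.
#' @export
synergy_matrix <- function(grid, surface) {
  stopifnot(inherits(surface, "synergy_surface"))
  delta <- grid$observed - surface$expected
  interior <- surface$flags != "margin"
  surface$delta <- delta
  surface$summary_score <- mean(delta[interior], na.rm = TRUE)
  surface
}

#' @export
print.synergy_surface <- function(x, ...) {
  cat(sprintf("Synergy surface (%s model)", x$model))
  if (!is.null(x$summary_score))
    cat(sprintf(": summary score %.4g (positive = synergy)", x$summary_score))
  cat("\n")
  invisible(x)
}

#' Bliss-independence expected effect
#'
#' @param e_a,e_b Single-agent effect fractions in \[0, 1\].
#' @return Expected combined effect \eqn{E_A + E_B - E_A E_B}.
#' @examples
#' bliss_expected(0.5, 0.5) # 0.75
#' @export
bliss_expected <- function(e_a, e_b) {
  if (any(e_a < 0 | e_a > 1) || any(e_b < 0 | e_b > 1))
    stop("Bliss requires effect fractions in [0, 1]")
  e_a + e_b - e_a * e_b
}
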