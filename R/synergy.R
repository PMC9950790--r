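# Chou-Talalay median-effect model: fa/fu = (D/Dm)^m, so the median-effect
# plot log10(fa/fu) vs log10(D) is a line with slope m and intercept
# -m*log10(Dm). CI for a combination observed at (d_a, d_b, fa) compares the
# combined doses with the single-agent doses producing the same effect.

FA_CLIP_EPS <- 0.005

#' Fit the median-effect model to a single-agent dose-response curve
#'
#' Fits `fa/fu = (D/Dm)^m` by least squares on the median-effect plot
#' (`log10(fa/fu)` against `log10(D)`). Zero-dose rows are excluded;
#' fraction-affected values at 0 or 1 are clipped to `[0.005, 0.995]`
#' (the log transform is undefined at the boundary) and the clip is
#' recorded. Replicate wells at the same dose are averaged before fitting.
#'
#' @param doses doses in umol/L, strictly positive after removing dose 0.
#' @param fa fraction affected (inhibition rate / 100) in `[0, 1]`.
#' @return an object of class `median_effect_fit`: list with `m` (slope),
#'   `dm` (median dose, umol/L), `r2`, `n` (points used), `clipped`
#'   (number of boundary fa values clipped) and `degenerate` (`TRUE` when
#'   every point was clipped or the slope is non-positive).
#' @export
fit_median_effect <- function(doses, fa) {
  if (length(doses) != length(fa))
    format_error("doses and fa must have equal length")
  keep <- doses > 0
  doses <- doses[keep]; fa <- fa[keep]
  if (any(fa < 0 | fa > 1)) format_error("fa values must lie in [0, 1]")
  # average replicate wells per dose
  if (anyDuplicated(doses)) {
    agg <- aggregate(fa, list(dose = doses), mean)
    doses <- agg$dose; fa <- agg$x
  }
  clipped <- sum(fa < FA_CLIP_EPS | fa > 1 - FA_CLIP_EPS)
  fa <- pmin(pmax(fa, FA_CLIP_EPS), 1 - FA_CLIP_EPS)
  if (length(doses) < 3)
    degenerate_input_error("median-effect fit needs >= 3 positive-dose points, got %d", length(doses))
  x <- log10(doses)
  y <- log10(fa / (1 - fa))
  fit <- lm(y ~ x)
  m <- unname(coef(fit)[2])
  b <- unname(coef(fit)[1])
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot < 1e-24) 0 else 1 - sum(fit$residuals^2) / ss_tot
  degenerate <- clipped == length(doses) || !is.finite(m) || m <= 0
  if (degenerate)
    warning("median-effect fit is degenerate (non-positive slope or fully clipped data)")
  out <- list(m = m, dm = 10^(-b / m), r2 = r2, n = length(doses),
              clipped = clipped, degenerate = degenerate)
  class(out) <- "median_effect_fit"
  out
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("median-effect fit: m = %.4g, Dm = %.4g umol/L, r2 = %.4f (n = %d)%s\n",
              x$m, x$dm, x$r2, x$n, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Dose needed for a given effect level
#'
#' Inverts the median-effect equation: `Dx = Dm * (fa/(1-fa))^(1/m)`.
#'
#' @param fit a `median_effect_fit`.
#' @param fa target fraction affected, strictly inside (0, 1).
#' @return dose in umol/L; strictly increasing in `fa`.
#' @export
dose_for_effect <- function(fit, fa) {
  stopifnot(inherits(fit, "median_effect_fit"))
  if (any(fa <= 0 | fa >= 1))
    degenerate_input_error("fa must lie strictly inside (0, 1); the dose is unbounded at the boundary")
  fit$dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Half-maximal inhibitory concentration implied by a fit
#'
#' Under the median-effect model the IC50 equals the median dose Dm. When
#' the fitted Dm exceeds `max_dose` (the top of the tested range) the value
#' is censored and reported as a `"> max_dose"` string in formatted output.
#'
#' @param fit a `median_effect_fit`.
#' @param max_dose optional top tested dose used for censoring in `label`.
#' @return list with `ic50` (numeric, umol/L) and `label` (character,
#'   either the rounded value or `"> max_dose"`).
#' @export
ic50_of <- function(fit, max_dose = NULL) {
  stopifnot(inherits(fit, "median_effect_fit"))
  if (fit$degenerate) degenerate_input_error("IC50 undefined for a degenerate fit")
  label <- if (!is.null(max_dose) && fit$dm > max_dose) {
    paste0("> ", format(max_dose))
  } else {
    format(round(fit$dm, 2))
  }
  list(ic50 = fit$dm, label = label)
}

#' Chou-Talalay combination index
#'
#' `CI = d_a/(D_A)_x + d_b/(D_B)_x`, where `(D_A)_x` and `(D_B)_x` are the
#' single-agent doses producing the combination's observed effect
#' `fa_combo`. CI below 1 is synergy, 1 additivity, above 1 antagonism.
#'
#' @param fit_a,fit_b `median_effect_fit` objects for the two agents.
#' @param d_a,d_b doses of the two agents in the combination (umol/L).
#' @param fa_combo fraction affected observed for the combination, in (0,1).
#' @return list with `ci`, `dx_a`, `dx_b`, and `verdict` in
#'   `c("synergistic", "additive", "antagonistic")` (additive within 1e-9).
#' @export
combination_index <- function(fit_a, fit_b, d_a, d_b, fa_combo) {
  if (fa_combo <= 0 || fa_combo >= 1)
    degenerate_input_error("fa_combo must lie strictly inside (0, 1)")
  dx_a <- dose_for_effect(fit_a, fa_combo)
  dx_b <- dose_for_effect(fit_b, fa_combo)
  ci <- d_a / dx_a + d_b / dx_b
  verdict <- if (abs(ci - 1) <= 1e-9) "additive" else if (ci < 1) "synergistic" else "antagonistic"
  list(ci = ci, dx_a = dx_a, dx_b = dx_b, verdict = verdict)
}

#' Combination-index table for a set of combination observations
#'
#' One CI per observed dose pair (no CI-vs-fa interpolation), plus the
#' per-pair minimum CI across its dose pairs.
#'
#' @param combos data frame with columns `agent_a`, `agent_b`, `dose_a`,
#'   `dose_b`, `fa`.
#' @param fits named list of `median_effect_fit` objects keyed by agent id.
#' @return data frame `agent_a, agent_b, dose_a, dose_b, fa, ci, verdict,
#'   pair_min_ci`.
#' @export
ci_table <- function(combos, fits) {
  need <- c("agent_a", "agent_b", "dose_a", "dose_b", "fa")
  if (!all(need %in% names(combos)))
    format_error("combination table must have columns %s", paste(need, collapse = ", "))
  missing <- setdiff(unique(c(combos$agent_a, combos$agent_b)), names(fits))
  if (length(missing))
    format_error("no median-effect fit for agent(s): %s", paste(missing, collapse = ", "))
  res <- lapply(seq_len(nrow(combos)), function(i) {
    r <- combos[i, ]
    ci <- combination_index(fits[[r$agent_a]], fits[[r$agent_b]],
                            r$dose_a, r$dose_b, r$fa)
    data.frame(r, ci = ci$ci, verdict = ci$verdict)
  })
  out <- do.call(rbind, res)
  key <- paste(out$agent_a, out$agent_b, sep = "\r")
  out$pair_min_ci <- stats::ave(out$ci, key, FUN = min)
  rownames(out) <- NULL
  out
}
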