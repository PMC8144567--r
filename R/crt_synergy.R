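#' Bliss-independence additive effect of two inhibitors
#'
#' Predicted combined killing effect of two independently acting
#' inhibitors: `E_total = E1 + E2 - E1 * E2`, where E1 is the inhibitory
#' effect of ionizing radiation at the screen dose (4 Gy) and E2 the
#' inhibitory effect of the drug at a given concentration. Symmetric,
#' monotone in each argument, and bounded in `[max(E1, E2), 1]`.
#'
#' @param e1,e2 Inhibition fractions in `[0, 1]` (vectorized).
#' @return Predicted additive inhibition fraction.
#' @export
#' @examples
#' bliss_additive(0.5, 0.5) # 0.75
bliss_additive <- function(e1, e2) {
  check_fraction(e1, "e1")
  check_fraction(e2, "e2")
  e1 + e2 - e1 * e2
}

#' Additive-prediction curve for a drug + IR combination
#'
#' Applies [bliss_additive()] elementwise along the drug dose-response
#' curve at a fixed IR inhibition, returning both the inhibition-scale and
#' the viability-scale (`100 * (1 - E)`) prediction for plotting against
#' the observed combination curve.
#'
#' @param drug_inhibition Per-dose drug inhibition fractions in `[0, 1]`.
#' @param ir_inhibition Single IR inhibition fraction in `[0, 1]`.
#' @return data.frame `inhibition`, `viability_pct` (one row per dose).
#' @export
additive_curve <- function(drug_inhibition, ir_inhibition) {
  check_fraction(ir_inhibition, "ir_inhibition")
  e <- bliss_additive(rep(ir_inhibition, length(drug_inhibition)), drug_inhibition)
  data.frame(inhibition = e, viability_pct = 100 * (1 - e))
}

#' Convert a viability curve to inhibition fractions
#'
#' @param viability_pct Percent viability values.
#' @return `1 - viability/100`, clipped to `[0, 1]`.
#' @export
inhibition_from_viability <- function(viability_pct) {
  clip(1 - viability_pct / 100, 0, 1)
}

#' Classify a chemoradiotherapy combination as synergistic
#'
#' A combination is synergistic when its observed dose-response curve lies
#' below the Bliss additive-effect curve: here, when combination viability
#' is more than `tol` percentage points below the additive prediction at
#' `min_points` or more doses. It is additive when the two curves agree
#' within `tol` everywhere, and antagonistic-or-none otherwise.
#'
#' @param combo_viability Observed combination viability (\%) per dose.
#' @param additive_viability Additive-prediction viability (\%) on the same
#'   dose grid.
#' @param tol Tolerance in viability percentage points (default 2).
#' @param min_points Minimum number of doses below the additive curve
#'   (default 3, i.e. half of the six-dose design).
#' @return List of class `synergy_call`: `verdict` in
#'   `{synergistic, additive, antagonistic-or-none}`,
#'   `n_doses_below_additive`, `tol`, `min_points`.
#' @export
classify_synergy <- function(combo_viability, additive_viability,
                             tol = 2, min_points = 3) {
  if (length(combo_viability) != length(additive_viability)) {
    stop("combination and additive curves must share the dose grid", call. = FALSE)
  }
  stopifnot(tol >= 0, min_points >= 1)
  diff <- combo_viability - additive_viability
  n_below <- sum(diff < -tol)
  verdict <- if (n_below >= min_points) {
    "synergistic"
  } else if (all(abs(diff) <= tol)) {
    "additive"
  } else {
    "antagonistic-or-none"
  }
  structure(list(verdict = verdict, n_doses_below_additive = n_below,
                 tol = tol, min_points = min_points),
            class = "synergy_call")
}

#' IC50 fold change of a CRT combination
#'
#' Fold change is the IC50 of the drug alone divided by the IC50 of the
#' combinational treatment, both censored to the tested 0.08--20 uM range
#' first (see [ic50_with_proxy()]); a combination with fold change
#' strictly over 3 is flagged as having good combinational effect.
#'
#' @param ic50_mono,ic50_combo `ic50_estimate` objects (bare numerics are
#'   censored on the fly).
#' @param cutoff Fold-change cutoff (default 3; strict `>`).
#' @return List `fold_change`, `good_combination`, `ic50_mono`,
#'   `ic50_combo`.
#' @export
#' @examples
#' crt_fold_change(18, 3) # fold 6, good combination
crt_fold_change <- function(ic50_mono, ic50_combo, cutoff = 3) {
  m <- ic50_with_proxy(ic50_mono)
  cb <- ic50_with_proxy(ic50_combo)
  fold <- m$value / cb$value
  list(fold_change = fold, good_combination = fold > cutoff,
       ic50_mono = m$value, ic50_combo = cb$value)
}

#' Full synergy evaluation of one drug x IR pair
#'
#' Composes the stage: fit a 4PL curve to each arm, build the additive
#' prediction from the fitted mono curve and the IR inhibition at the
#' screen dose, classify synergy by comparing the fitted combination
#' curve to the additive curve at the plate doses, and compute the IC50
#' fold change. Comparing fitted curves (the curves a screen reports)
#' rather than raw replicate means pools information across doses and
#' suppresses per-dose replicate noise; if an arm's fit does not
#' converge, its replicate-averaged curve is used instead.
#'
#' @param mono_plate,combo_plate Tidy plate data.frames for the drug-alone
#'   and drug + 4 Gy IR arms (same dose grid).
#' @param ir_inhibition IR inhibition fraction E1 at the screen dose.
#' @param tol,min_points Passed to [classify_synergy()].
#' @param fold_cutoff Passed to [crt_fold_change()].
#' @return List of class `crt_evaluation`: `verdict`, `synergy`
#'   (`synergy_call`), `fold` (fold-change record), `curves` (per-dose
#'   fitted mono/combo and additive viability).
#' @export
evaluate_crt_pair <- function(mono_plate, combo_plate, ir_inhibition,
                              tol = 2, min_points = 3, fold_cutoff = 3) {
  mono <- dose_means(mono_plate)
  combo <- dose_means(combo_plate)
  if (!isTRUE(all.equal(mono$dose, combo$dose))) {
    stop("mono and combo arms must share the dose grid", call. = FALSE)
  }
  fit_mono <- fit_4pl(mono_plate)
  fit_combo <- fit_4pl(combo_plate)
  curve_of <- function(fit, fallback) {
    if (fit$converged) {
      four_pl(mono$dose, fit$ic50_raw, fit$hill, fit$top, fit$bottom)
    } else {
      fallback
    }
  }
  mono_v <- curve_of(fit_mono, mono$viability)
  combo_v <- curve_of(fit_combo, combo$viability)
  add <- additive_curve(inhibition_from_viability(mono_v), ir_inhibition)
  syn <- classify_synergy(combo_v, add$viability_pct,
                          tol = tol, min_points = min_points)
  fold <- crt_fold_change(fit_mono, fit_combo, cutoff = fold_cutoff)
  structure(list(
    verdict = syn$verdict, synergy = syn, fold = fold,
    curves = data.frame(dose_uM = mono$dose, mono_viability = mono_v,
                        combo_viability = combo_v,
                        additive_viability = add$viability_pct)
  ), class = "crt_evaluation")
}
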