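#' Normalize raw well signal against control wells
#'
#' Luminescence readout from treated wells normalized against the control
#' well mean and expressed as percent cell viability. Negative raw signal
#' is clipped to 0 before division.
#'
#' @param raw_signal Numeric vector of treated-well readouts.
#' @param control_wells Numeric vector of control-well readouts (>= 1 well,
#'   positive mean).
#' @return Percent viability vector (`100 * raw / mean(controls)`).
#' @export
#' @examples
#' normalize_viability(c(1000, 500), c(900, 1100)) # 100, 50
normalize_viability <- function(raw_signal, control_wells) {
  if (length(control_wells) < 1) stop("need at least one control well", call. = FALSE)
  m <- mean(control_wells)
  if (!is.finite(m) || m <= 0) {
    stop("control well mean must be positive (dead control plate?)", call. = FALSE)
  }
  100 * pmax(raw_signal, 0) / m
}

# average replicates per dose; accepts a plate data.frame or dose/viability
# vectors, returns a two-column data.frame ordered by dose
dose_means <- function(doses, viability = NULL) {
  if (is.data.frame(doses)) {
    viability <- doses$viability_pct
    doses <- doses$dose_uM
  }
  stopifnot(length(doses) == length(viability), all(is.finite(viability)))
  agg <- stats::aggregate(list(viability = viability), list(dose = doses), mean)
  agg[order(agg$dose), , drop = FALSE]
}

#' Fit a four-parameter log-logistic (Hill) curve to a dose series
#'
#' Replicates are averaged per dose, then
#' `v(d) = bottom + (top - bottom) / (1 + (d / ic50)^hill)` is fitted by
#' box-constrained Levenberg-Marquardt least squares on log-dose
#' (`bottom >= 0`, `top <= 120`), with multi-start initialisation (IC50 at
#' the dose geometric mean, min and max; Hill slope +-1). The fit is
#' flagged non-converged when the optimizer fails or the fitted curve is
#' flat (dynamic range `top - bottom` under 5 percentage points). Reversed
#' (viability increasing with dose) series fit with a negative Hill slope.
#'
#' @param doses Dose vector (uM), or a plate data.frame with `dose_uM` and
#'   `viability_pct` columns.
#' @param viability Percent viability per entry of `doses` (ignored when a
#'   plate data.frame is given).
#' @return Object of class `four_pl_fit`: `top`, `bottom`, `ic50_raw`,
#'   `hill`, `converged`, `residual_sse`, `n_doses`.
#' @export
fit_4pl <- function(doses, viability = NULL) {
  d <- dose_means(doses, viability)
  if (nrow(d) < 4) stop("need >= 4 distinct doses to fit a 4PL curve", call. = FALSE)
  if (any(d$dose <= 0)) stop("doses must be positive", call. = FALSE)
  v <- d$viability
  ld <- log(d$dose)
  flat_fit <- function() {
    structure(list(top = max(v), bottom = min(v), ic50_raw = NA_real_,
                   hill = NA_real_, converged = FALSE,
                   residual_sse = sum((v - mean(v))^2), n_doses = nrow(d)),
              class = "four_pl_fit")
  }
  if (max(v) - min(v) < 5) return(flat_fit())

  # linearized start: with provisional asymptotes just outside the data
  # range, log((top - v)/(v - bottom)) is linear in log-dose with slope hill
  top0 <- max(v) + 0.5
  bot0 <- max(min(v) - 0.5, 0)
  z <- log((top0 - v) / pmax(v - bot0, 1e-6))
  lin <- stats::lm.fit(cbind(1, ld), z)$coefficients
  hill0 <- unname(lin[2])
  lic0 <- if (abs(hill0) > 1e-6) -unname(lin[1]) / hill0 else mean(ld)
  lic0 <- min(max(lic0, min(ld) - log(1e3)), max(ld) + log(1e3))
  starts <- list(
    c(top = top0, bottom = bot0, lic50 = lic0, hill = hill0),
    c(top = max(v), bottom = min(v), lic50 = mean(ld), hill = 1),
    c(top = max(v), bottom = min(v), lic50 = min(ld), hill = 2),
    c(top = max(v), bottom = min(v), lic50 = max(ld), hill = 0.5),
    c(top = max(v), bottom = min(v), lic50 = mean(ld), hill = -1)
  )
  lower <- c(top = 0, bottom = 0, lic50 = min(ld) - log(1e4), hill = -20)
  upper <- c(top = 120, bottom = 120, lic50 = max(ld) + log(1e4), hill = 20)
  resid_fn <- function(p) {
    v - (p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
           (1 + exp(p[["hill"]] * (ld - p[["lic50"]]))))
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = st, fn = resid_fn, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      sse <- sum(resid_fn(fit$par)^2)
      if (is.null(best) || sse < best$sse - 1e-12) {
        best <- list(par = fit$par, sse = sse)
      }
    }
  }
  if (is.null(best)) return(flat_fit())
  p <- best$par
  if (p[["top"]] < p[["bottom"]]) { # same curve, canonical orientation
    tmp <- p[["top"]]; p[["top"]] <- p[["bottom"]]; p[["bottom"]] <- tmp
    p[["hill"]] <- -p[["hill"]]
  }
  converged <- (p[["top"]] - p[["bottom"]]) >= 5
  structure(list(
    top = unname(p[["top"]]), bottom = unname(p[["bottom"]]),
    ic50_raw = exp(unname(p[["lic50"]])), hill = unname(p[["hill"]]),
    converged = converged, residual_sse = best$sse, n_doses = nrow(d)
  ), class = "four_pl_fit")
}

#' @export
print.four_pl_fit <- function(x, ...) {
  cat(sprintf("4PL fit: top %.1f, bottom %.1f, IC50 %s uM, hill %s (%s)\n",
              x$top, x$bottom,
              ifelse(is.na(x$ic50_raw), "NA", signif(x$ic50_raw, 4)),
              ifelse(is.na(x$hill), "NA", signif(x$hill, 3)),
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Censor a fitted IC50 to the tested dose range
#'
#' IC50 values outside the tested 0.08--20 uM range are replaced by the
#' range limit as a proxy: raw IC50 above 20 uM becomes 20
#' (`clipped_high`), below 0.08 uM becomes 0.08 (`clipped_low`).
#' Non-converged fits (including flat, fully resistant curves) are assigned
#' the maximally resistant proxy 20 uM with censoring `nonconverged`.
#' Applying the rule twice equals applying it once.
#'
#' @param fit A `four_pl_fit`, an `ic50_estimate`, or a bare numeric raw
#'   IC50 (treated as a converged fit).
#' @param dose_range Censoring limits in uM (default `c(0.08, 20)`).
#' @return Object of class `ic50_estimate`: `value` (uM, always within
#'   `dose_range`) and `censoring` in
#'   `{none, clipped_high, clipped_low, nonconverged}`.
#' @export
#' @examples
#' ic50_with_proxy(35)   # 20 uM, clipped_high
#' ic50_with_proxy(0.01) # 0.08 uM, clipped_low
ic50_with_proxy <- function(fit, dose_range = c(0.08, 20)) {
  stopifnot(length(dose_range) == 2, dose_range[1] < dose_range[2])
  if (inherits(fit, "ic50_estimate")) return(fit) # idempotent
  if (is.numeric(fit)) fit <- list(ic50_raw = fit, converged = is.finite(fit))
  est <- if (!isTRUE(fit$converged) || !is.finite(fit$ic50_raw)) {
    list(value = dose_range[2], censoring = "nonconverged")
  } else if (fit$ic50_raw > dose_range[2]) {
    list(value = dose_range[2], censoring = "clipped_high")
  } else if (fit$ic50_raw < dose_range[1]) {
    list(value = dose_range[1], censoring = "clipped_low")
  } else {
    list(value = fit$ic50_raw, censoring = "none")
  }
  structure(est, class = "ic50_estimate")
}

#' Summarize an ionizing-radiation survival series
#'
#' Aggregates an IR viability series (doses in Gy, typically 0--10 Gy in
#' 2 Gy steps) to per-dose mean viability and spread; the profile supplies
#' the IR inhibitory effect E1 for the Bliss additive model.
#'
#' @param doses Dose vector in Gy, or a plate data.frame (`dose_uM` column
#'   read as Gy when `ir_gy` is absent as the dose axis).
#' @param viability Percent viability per entry.
#' @param allowed Permitted dose levels (default `c(0, 2, 4, 6, 8, 10)`).
#' @return data.frame `dose_gy`, `mean_viability`, `sd_viability`,
#'   `inhibition` (= `1 - mean/100`, clipped to `[0, 1]`).
#' @export
ir_survival <- function(doses, viability = NULL, allowed = c(0, 2, 4, 6, 8, 10)) {
  d <- dose_means(doses, viability)
  if (!all(d$dose %in% allowed)) {
    stop("IR doses outside the allowed grid: ",
         paste(setdiff(d$dose, allowed), collapse = ", "), call. = FALSE)
  }
  if (is.data.frame(doses)) { doses_v <- doses$dose_uM; via <- doses$viability_pct
  } else { doses_v <- doses; via <- viability }
  sds <- stats::aggregate(list(sd = via), list(dose = doses_v),
                          function(x) if (length(x) > 1) stats::sd(x) else 0)
  out <- merge(d, sds, by = "dose")
  out <- out[order(out$dose), ]
  data.frame(dose_gy = out$dose, mean_viability = out$viability,
             sd_viability = out$sd,
             inhibition = clip(1 - out$viability / 100, 0, 1))
}

#' IR inhibitory effect at a chosen dose
#'
#' @param profile data.frame from [ir_survival()].
#' @param dose_gy Dose at which E1 is taken (default 4 Gy, the
#'   chemoradiotherapy screen dose).
#' @return Inhibition fraction in `[0, 1]`.
#' @export
ir_inhibition_at <- function(profile, dose_gy = 4) {
  i <- match(dose_gy, profile$dose_gy)
  if (is.na(i)) stop("dose ", dose_gy, " Gy absent from the IR profile", call. = FALSE)
  profile$inhibition[i]
}

#' Fit all sample/drug/arm combinations of a tidy plate table
#'
#' Convenience wrapper: splits a tidy plate table by `sample`, `drug` and
#' `ir_gy`, fits each series with [fit_4pl()] and censors with
#' [ic50_with_proxy()].
#'
#' @param plate Tidy plate data.frame (`sample`, `drug`, `dose_uM`,
#'   `ir_gy`, `replicate`, `viability_pct`).
#' @param dose_range IC50 censoring limits (uM).
#' @return data.frame, one row per (sample, drug, ir_gy): fitted
#'   parameters, `ic50_proxy`, `censoring`, `converged`.
#' @export
fit_plate <- function(plate, dose_range = c(0.08, 20)) {
  stopifnot(all(c("sample", "drug", "dose_uM", "ir_gy", "viability_pct")
                %in% names(plate)))
  keys <- unique(plate[c("sample", "drug", "ir_gy")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- plate[plate$sample == keys$sample[i] & plate$drug == keys$drug[i] &
                 plate$ir_gy == keys$ir_gy[i], ]
    f <- fit_4pl(sub)
    e <- ic50_with_proxy(f, dose_range)
    data.frame(sample = keys$sample[i], drug = keys$drug[i],
               ir_gy = keys$ir_gy[i], top = f$top, bottom = f$bottom,
               ic50_raw = f$ic50_raw, hill = f$hill, ic50_proxy = e$value,
               censoring = e$censoring, converged = f$converged,
               residual_sse = f$residual_sse, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
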