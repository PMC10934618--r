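# Converts k_obs ladders into kinact/KI with the substrate-competition
# correction, and implements the 25 uM screening triage.

#' Second-order inactivation constant from a k_obs ladder
#'
#' Fits the pseudo-first-order relation `k_obs = m [I]` through the origin
#' (inverse-variance weighted when per-point standard errors are available)
#' and applies the substrate-competition correction:
#' `kinact/KI = m * (1 + S/KM)`. The relation has zero intercept by
#' construction, but a free-intercept fit is also reported as a diagnostic,
#' and departure from proportionality (inhibitor saturation) is flagged when
#' the through-origin R-squared falls below `r2_threshold`; saturating
#' ladders are flagged, not refitted with a hyperbolic model.
#'
#' When no curve in the ladder resolved a positive `k_obs`, a bounded
#' ("no measurable inactivation") result is returned instead of a number.
#'
#' @param kobs_by_I data.frame with columns `I` (M) and `k_obs` (s^-1);
#'   optional `se_kobs` (used as weights `1/se^2`) and `status` (only
#'   `"ok"` rows enter the fit).
#' @param S Substrate concentration during the read, M.
#' @param KM Michaelis constant, M; required — there is no default.
#' @param r2_threshold Through-origin R-squared below which the ladder is
#'   flagged nonlinear (default 0.9).
#' @return An object of class `second_order_result`: `kinact_over_KI`,
#'   `se`, `slope`, `se_slope`, `correction_factor`, `r2_origin`,
#'   `intercept_diagnostic` (free-intercept coef and p), `ladder`,
#'   `n_curves`, `saturating`, `bounded` (logical), `reason`.
#' @export
#' @examples
#' I <- c(1, 2, 5) * 1e-6
#' k <- kobs_from_second_order(2e5, I, S = 8e-5, KM = 8e-5)
#' second_order_constant(data.frame(I = I, k_obs = k), S = 8e-5, KM = 8e-5)
second_order_constant <- function(kobs_by_I, S, KM, r2_threshold = 0.9) {
  if (missing(KM) || is.null(KM) || !is.finite(KM) || KM <= 0)
    stop("`KM` (Michaelis constant, M) is required: set kinetics$KM in the ",
         "assay configuration for this enzyme/substrate pair", call. = FALSE)
  stopifnot(is.data.frame(kobs_by_I),
            all(c("I", "k_obs") %in% names(kobs_by_I)),
            is.numeric(S), length(S) == 1L, S >= 0)

  d <- kobs_by_I
  if ("status" %in% names(d)) d <- d[d$status %in% "ok", , drop = FALSE]
  d <- d[is.finite(d$I) & is.finite(d$k_obs) & d$I > 0, , drop = FALSE]
  cf <- 1 + S / KM

  bounded <- function(reason) {
    structure(list(kinact_over_KI = NA_real_, se = NA_real_,
                   slope = NA_real_, se_slope = NA_real_,
                   correction_factor = cf, r2_origin = NA_real_,
                   intercept_diagnostic = NULL,
                   ladder = kobs_by_I$I, n_curves = nrow(d),
                   saturating = NA, bounded = TRUE, reason = reason),
              class = "second_order_result")
  }
  if (nrow(d) == 0L)
    return(bounded("no resolvable k_obs in the ladder"))
  if (all(d$k_obs <= 0))
    return(bounded("no measurable inactivation (all k_obs = 0)"))
  if (length(unique(d$I)) < 2L)
    stop("need at least 2 distinct positive inhibitor concentrations",
         call. = FALSE)

  w <- if ("se_kobs" %in% names(d) && all(is.finite(d$se_kobs)) &&
           all(d$se_kobs > 0)) 1 / d$se_kobs^2 else rep(1, nrow(d))

  m <- sum(w * d$I * d$k_obs) / sum(w * d$I^2)
  resid <- d$k_obs - m * d$I
  n <- nrow(d)
  se_m <- if (n >= 2) sqrt(sum(w * resid^2) / (n - 1) / sum(w * d$I^2))
          else NA_real_
  r2 <- 1 - sum(resid^2) / sum(d$k_obs^2)

  free <- stats::lm(k_obs ~ I, data = d, weights = w)
  fsm <- suppressWarnings(summary(free)$coefficients)
  intercept_diag <- list(intercept = unname(stats::coef(free)[1]),
                         p_value = if (nrow(fsm) >= 1) unname(fsm[1, 4])
                                   else NA_real_)

  structure(list(kinact_over_KI = m * cf, se = se_m * cf,
                 slope = m, se_slope = se_m,
                 correction_factor = cf, r2_origin = r2,
                 intercept_diagnostic = intercept_diag,
                 ladder = sort(unique(d$I)), n_curves = n,
                 saturating = is.finite(r2) && r2 < r2_threshold,
                 bounded = FALSE, reason = NA_character_),
            class = "second_order_result")
}

#' @export
print.second_order_result <- function(x, ...) {
  cat("<second_order_result>\n")
  if (x$bounded) {
    cat("  bounded:", x$reason, "\n")
  } else {
    cat(sprintf("  kinact/KI = %.6g +/- %.3g M^-1 s^-1 (correction factor %.4g, n = %d, origin R2 = %.4f)\n",
                x$kinact_over_KI, x$se, x$correction_factor, x$n_curves,
                x$r2_origin))
    if (isTRUE(x$saturating))
      cat("  warning: k_obs vs [I] departs from proportionality (saturation?)\n")
  }
  invisible(x)
}

#' Second-order constants from a fitted dataset
#'
#' Groups the per-curve fit table of [fit_dataset()] by replicate (or pools
#' all replicates) and runs [second_order_constant()] on each ladder, using
#' the substrate conditions stored in the dataset.
#'
#' @param dataset An `assay_dataset` (for its condition), or NULL if `S`
#'   and `KM` are given.
#' @param fits Optional precomputed [fit_dataset()] table; computed from
#'   `dataset` when omitted.
#' @param per_replicate If TRUE return one result per replicate, else one
#'   pooled result.
#' @param S,KM Override substrate concentration / Michaelis constant, M.
#' @param ... Passed to [fit_dataset()].
#' @return A single `second_order_result` (pooled) or a named list of them
#'   (per replicate).
#' @export
estimate_second_order <- function(dataset = NULL, fits = NULL,
                                  per_replicate = FALSE, S = NULL, KM = NULL,
                                  ...) {
  if (is.null(fits)) {
    stopifnot(inherits(dataset, "assay_dataset"))
    fits <- fit_dataset(dataset, ...)
  }
  if (is.null(S)) S <- dataset$condition$S
  if (is.null(KM)) KM <- dataset$condition$KM
  samp <- fits[fits$role == "sample", , drop = FALSE]
  cols <- c(I = "I", k_obs = "k_obs", se_kobs = "se_kobs", status = "status")
  if (!per_replicate) {
    return(second_order_constant(
      stats::setNames(samp[, cols], names(cols)), S = S, KM = KM))
  }
  reps <- sort(unique(samp$replicate))
  out <- lapply(reps, function(r) {
    second_order_constant(
      stats::setNames(samp[samp$replicate == r, cols], names(cols)),
      S = S, KM = KM)
  })
  stats::setNames(out, paste0("replicate_", reps))
}

#' Fractional inhibition from paired velocities
#'
#' `1 - v_inhibited / v_control`, clipped to the unit interval; noise can
#' push the raw ratio outside it, in which case the result carries
#' attribute `clipped = TRUE`.
#'
#' @param v_inhibited,v_control Velocities in the same units;
#'   `v_control > 0`.
#' @return Inhibition fraction in the unit interval, with attribute `clipped`.
#' @export
inhibition_fraction <- function(v_inhibited, v_control) {
  stopifnot(is.numeric(v_inhibited), is.numeric(v_control))
  if (any(!is.finite(v_control)) || any(v_control <= 0))
    stop("`v_control` must be positive", call. = FALSE)
  raw <- 1 - v_inhibited / v_control
  out <- pmin(pmax(raw, 0), 1)
  attr(out, "clipped") <- raw < 0 | raw > 1
  out
}

#' Screening triage of the 25 uM inhibition fraction
#'
#' The screening decision tree: below 5% inhibition the compound is assumed
#' inactive; from 5% to 40% (closed interval) the second-order constant is
#' assumed below 50 M^-1 s^-1 and not measured; above 40% the constant is
#' quantified from a full ladder.
#'
#' @param fraction Inhibition fraction(s) in the unit interval.
#' @param thresholds Lower/upper band edges (default `c(0.05, 0.40)`).
#' @return Ordered factor with levels `no_inhibition < bounded_below_50 <
#'   quantify`.
#' @export
#' @examples
#' triage(c(0.03, 0.20, 0.60))
triage <- function(fraction, thresholds = c(0.05, 0.40)) {
  stopifnot(is.numeric(fraction), all(is.finite(fraction)),
            all(fraction >= 0), all(fraction <= 1),
            length(thresholds) == 2L, thresholds[1] < thresholds[2])
  cls <- ifelse(fraction < thresholds[1], "no_inhibition",
                ifelse(fraction <= thresholds[2], "bounded_below_50",
                       "quantify"))
  factor(cls, levels = c("no_inhibition", "bounded_below_50", "quantify"),
         ordered = TRUE)
}

# Round half away from zero at `digits` decimals (printed fold convention;
# base round() is round-half-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Fold change between two second-order constants
#'
#' Potency ratio `a / b`. For reporting, the ratio is rounded half-up to one
#' decimal, the convention used for printed fold comparisons; comparisons
#' and downstream arithmetic should use `rounded = FALSE`.
#'
#' @param a,b Second-order constants, M^-1 s^-1; `b > 0`.
#' @param rounded Round half-up to 1 decimal (default TRUE).
#' @return The (possibly rounded) ratio.
#' @export
#' @examples
#' fold_change(1626200, 229000)   # 7.1
fold_change <- function(a, b, rounded = TRUE) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (any(!is.finite(b)) || any(b <= 0))
    stop("reference constant `b` must be positive", call. = FALSE)
  r <- a / b
  if (rounded) round_half_up(r, 1) else r
}

#' Self-consistency of the screening bound
#'
#' The triage convention maps 5--40% inhibition at 25 uM / 15 min to
#' "kinact/KI < 50 M^-1 s^-1". Under the substrate-free preincubation model
#' in its linear regime, a compound at exactly the bound would show
#' `1 - exp(-50 * I * t)` inhibition (about 67.5% at the default screen),
#' above the 40% band edge, and 40% inhibition corresponds to about
#' 22.7 M^-1 s^-1. This function reports that tension; it is a logged
#' diagnostic, not an assertion, since the convention may reflect a
#' different effective readout.
#'
#' @param bound The constant at the convention's bound, M^-1 s^-1.
#' @param I Screening concentration, M.
#' @param preincubation Preincubation time, s.
#' @param band_upper Upper inhibition-band edge (fraction).
#' @param quiet Suppress the message.
#' @return List with `inhibition_at_bound` (fraction) and
#'   `implied_constant_at_band` (M^-1 s^-1).
#' @export
screen_boundary_note <- function(bound = 50, I = 25e-6, preincubation = 900,
                                 band_upper = 0.40, quiet = FALSE) {
  inh <- 1 - exp(-bound * I * preincubation)
  implied <- -log(1 - band_upper) / (I * preincubation)
  if (!quiet)
    message(sprintf(
      paste0("screen boundary check: %g M^-1 s^-1 implies %.1f%% inhibition ",
             "at %g M / %g s (band edge %.0f%% implies %.1f M^-1 s^-1)"),
      bound, 100 * inh, I, preincubation, 100 * band_upper, implied))
  list(inhibition_at_bound = inh, implied_constant_at_band = implied)
}
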