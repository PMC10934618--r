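# Kinetic core: closed-form progress model, pseudo-first-order relation,
# and the mass-action mechanism used as simulator engine and oracle.

#' Kinetic constants of the two-step covalent inhibition scheme
#'
#' Bundles the rate constants of the standard mechanism for irreversible
#' active-site-directed inhibition,
#' \deqn{E + I \rightleftharpoons EI \rightarrow E\!-\!I \;(\mathrm{covalent}),}
#' together with Michaelis--Menten turnover of the fluorogenic reporter
#' substrate, \eqn{E + S \rightleftharpoons ES \rightarrow E + P}.
#'
#' Published potencies are usually available only as the lumped second-order
#' constant \eqn{k_\mathrm{inact}/K_I} (in M\eqn{^{-1}}s\eqn{^{-1}}). When no
#' split is supplied, the constant is split with a default
#' \eqn{K_I = 100\,\mu}M, well above typical assay concentrations, so that
#' simulations stay in the linear (non-saturating) regime where
#' \eqn{k_\mathrm{obs}} is proportional to [I]. Supplying both a split and a
#' lumped value that disagree (beyond 1e-9 relative) is an error.
#'
#' Microscopic binding constants for the mass-action simulator are derived
#' under rapid equilibrium: the dissociation rate is
#' `equilibration_factor` times the chemical step, and the association rate
#' follows from the steady-state definition of \eqn{K_I} (or \eqn{K_M}).
#'
#' @param kinact_over_KI Second-order inactivation constant, M^-1 s^-1.
#' @param kinact First-order inactivation rate of the reversible complex,
#'   s^-1. Give together with `KI` or not at all.
#' @param KI Inhibition constant of the reversible encounter complex, M.
#' @param kcat Substrate turnover number, s^-1. Needed only for mechanistic
#'   (ODE) simulation of product formation.
#' @param KM Michaelis constant of the reporter substrate, M.
#' @param kcat_over_KM Specificity constant, M^-1 s^-1; consistency-checked
#'   against `kcat/KM` when both are given.
#' @param equilibration_factor Ratio of the complex dissociation rate to the
#'   chemical step used to derive microscopic on/off rates (dimensionless,
#'   default 100; larger values approach rapid equilibrium more closely at
#'   the price of stiffness).
#'
#' @return An object of class `rate_parameters`: a list with elements
#'   `kinact_over_KI`, `kinact`, `KI`, `kon`, `koff`, and (when substrate
#'   constants were given) `kcat`, `KM`, `kcat_over_KM`, `k1`, `km1`.
#' @seealso [kobs_from_second_order()], [integrate_mechanism()]
#' @export
#' @examples
#' rate_parameters(kinact_over_KI = 229000)            # reference-compound potency
#' rate_parameters(kinact = 0.02, KI = 1e-4, kcat = 20, KM = 8e-5)
rate_parameters <- function(kinact_over_KI = NULL, kinact = NULL, KI = NULL,
                            kcat = NULL, KM = NULL, kcat_over_KM = NULL,
                            equilibration_factor = 100) {
  if (is.null(kinact) && !is.null(KI)) {
    # KI chosen explicitly, kinact implied by the lumped constant
    if (is.null(kinact_over_KI))
      stop("`KI` alone needs `kinact` or `kinact_over_KI`", call. = FALSE)
    stopifnot(is.finite(KI), KI > 0)
    kinact <- kinact_over_KI * KI
  }
  if (!is.null(kinact) && is.null(KI))
    stop("give `KI` together with `kinact`", call. = FALSE)
  if (!is.null(kinact)) {
    stopifnot(is.finite(kinact), kinact >= 0, is.finite(KI), KI > 0)
    ratio <- kinact / KI
    if (!is.null(kinact_over_KI) &&
        abs(ratio - kinact_over_KI) > 1e-9 * max(kinact_over_KI, 1e-300))
      stop("`kinact`/`KI` = ", format(ratio),
           " disagrees with `kinact_over_KI` = ", format(kinact_over_KI),
           call. = FALSE)
    kinact_over_KI <- ratio
  } else if (!is.null(kinact_over_KI)) {
    stopifnot(is.finite(kinact_over_KI), kinact_over_KI >= 0)
    KI <- 1e-4
    kinact <- kinact_over_KI * KI
  } else {
    stop("supply `kinact_over_KI` or the (`kinact`, `KI`) split", call. = FALSE)
  }

  if (is.null(kcat) != is.null(KM)) {
    stop("give both `kcat` and `KM`, or neither", call. = FALSE)
  }
  if (!is.null(kcat)) {
    stopifnot(is.finite(kcat), kcat >= 0, is.finite(KM), KM > 0)
    sratio <- kcat / KM
    if (!is.null(kcat_over_KM) &&
        abs(sratio - kcat_over_KM) > 1e-9 * max(kcat_over_KM, 1e-300))
      stop("`kcat`/`KM` disagrees with `kcat_over_KM`", call. = FALSE)
    kcat_over_KM <- sratio
  }

  stopifnot(is.finite(equilibration_factor), equilibration_factor > 0)
  koff <- equilibration_factor * max(kinact, .Machine$double.xmin)
  kon <- (koff + kinact) / KI

  out <- list(
    kinact_over_KI = kinact_over_KI,
    kinact = kinact, KI = KI, kon = kon, koff = koff,
    kcat = kcat, KM = KM, kcat_over_KM = kcat_over_KM,
    equilibration_factor = equilibration_factor
  )
  if (!is.null(kcat)) {
    out$km1 <- equilibration_factor * max(kcat, .Machine$double.xmin)
    out$k1 <- (out$km1 + kcat) / KM
  }
  class(out) <- "rate_parameters"
  out
}

#' @export
print.rate_parameters <- function(x, ...) {
  cat("<rate_parameters>\n")
  cat(sprintf("  kinact/KI: %g M^-1 s^-1  (kinact = %g s^-1, KI = %g M)\n",
              x$kinact_over_KI, x$kinact, x$KI))
  if (!is.null(x$kcat))
    cat(sprintf("  kcat: %g s^-1, KM = %g M (kcat/KM = %g M^-1 s^-1)\n",
                x$kcat, x$KM, x$kcat_over_KM))
  invisible(x)
}

#' Closed-form progress curve for irreversible inhibition
#'
#' Accumulated product under pseudo-first-order inactivation:
#' \deqn{P(t) = \frac{v_i}{k_\mathrm{obs}}\left(1 - e^{-k_\mathrm{obs} t}\right),}
#' the single-exponential model fitted to every inhibited progress curve.
#' The curve rises with initial slope \eqn{v_i} and saturates at the plateau
#' \eqn{v_i/k_\mathrm{obs}}.
#'
#' When `k_obs * max(t) < 1e-6` the series limit \eqn{v_i t} is returned
#' instead, which avoids 0/0 at `k_obs = 0` and reproduces the linear
#' control curve observed without inhibitor.
#'
#' @param t Time, s (vector, all >= 0).
#' @param v_i Initial velocity, signal units per s (>= 0).
#' @param k_obs Apparent first-order inactivation constant, s^-1 (>= 0).
#' @return Accumulated signal at each `t` (same units as `v_i * t`).
#' @export
#' @examples
#' progress_closed_form(c(0, 60, 600), v_i = 1, k_obs = 0.01)
progress_closed_form <- function(t, v_i, k_obs) {
  stopifnot(is.numeric(t), all(is.finite(t)),
            is.numeric(v_i), length(v_i) == 1L, is.finite(v_i), v_i >= 0,
            is.numeric(k_obs), length(k_obs) == 1L, is.finite(k_obs),
            k_obs >= 0)
  if (any(t < 0)) stop("negative time is not allowed", call. = FALSE)
  if (length(t) == 0L) return(numeric(0))
  if (k_obs * max(t) < 1e-6) return(v_i * t)
  (v_i / k_obs) * (-expm1(-k_obs * t))
}

#' Observed inactivation rate from the second-order constant
#'
#' The pseudo-first-order relation linking the lumped second-order constant
#' to the rate observed in the presence of competing substrate:
#' \deqn{k_\mathrm{obs} = \frac{(k_\mathrm{inact}/K_I)\,[I]}{1 + [S]/K_M}.}
#' This is the model inverted by [second_order_constant()]; the two are
#' exact inverses on noiseless ladders.
#'
#' @param kinact_over_KI Second-order constant, M^-1 s^-1.
#' @param I Inhibitor concentration, M.
#' @param S Substrate concentration, M (0 for substrate-free incubation).
#' @param KM Michaelis constant of the substrate, M (> 0).
#' @return `k_obs` in s^-1 (vectorized over `I`).
#' @export
#' @examples
#' kobs_from_second_order(229000, I = 1e-6, S = 0, KM = 8e-5)   # 0.229 s^-1
kobs_from_second_order <- function(kinact_over_KI, I, S, KM) {
  stopifnot(is.numeric(kinact_over_KI), all(kinact_over_KI >= 0),
            is.numeric(I), all(I >= 0),
            is.numeric(S), length(S) == 1L, S >= 0,
            is.numeric(KM), length(KM) == 1L)
  if (!is.finite(KM) || KM <= 0)
    stop("`KM` must be a positive Michaelis constant (in M)", call. = FALSE)
  kinact_over_KI * I / (1 + S / KM)
}

#' Mechanism state vector
#'
#' Molar concentrations of every species in the two-step covalent
#' inhibition mechanism: free enzyme `E`, enzyme--substrate complex `ES`,
#' reversible enzyme--inhibitor complex `EI`, dead-end covalent complex
#' `EIx`, free substrate `S`, free inhibitor `I`, and product `P`.
#'
#' @param E,S,I,ES,EI,EIx,P Concentrations in M (all >= 0).
#' @return Named numeric vector of class `mechanism_state`.
#' @export
mechanism_state <- function(E, S, I, ES = 0, EI = 0, EIx = 0, P = 0) {
  x <- c(E = E, ES = ES, EI = EI, EIx = EIx, S = S, I = I, P = P)
  if (any(!is.finite(x)) || any(x < 0))
    stop("all concentrations must be finite and non-negative", call. = FALSE)
  class(x) <- c("mechanism_state", "numeric")
  x
}

#' Mass-action derivatives of the covalent inhibition mechanism
#'
#' Time derivatives of [mechanism_state()] under mass action:
#' substrate binding/turnover with rates `k1`, `km1`, `kcat` and inhibitor
#' binding/inactivation with `kon`, `koff`, `kinact`. The derivatives
#' conserve total enzyme (E + ES + EI + EIx), total substrate (S + ES + P)
#' and total inhibitor (I + EI + EIx) identically.
#'
#' @param state A [mechanism_state()].
#' @param rates A [rate_parameters()] including substrate constants.
#' @return Named numeric vector of derivatives, M/s, same order as `state`.
#' @export
mechanism_rhs <- function(state, rates) {
  stopifnot(inherits(rates, "rate_parameters"))
  if (is.null(rates$kcat))
    stop("`rates` must include `kcat` and `KM` for mechanistic simulation",
         call. = FALSE)
  s <- unclass(state)
  bindS <- rates$k1 * s[["E"]] * s[["S"]]
  turnS <- rates$kcat * s[["ES"]]
  offS <- rates$km1 * s[["ES"]]
  bindI <- rates$kon * s[["E"]] * s[["I"]]
  offI <- rates$koff * s[["EI"]]
  inact <- rates$kinact * s[["EI"]]
  c(E = -bindS + offS + turnS - bindI + offI,
    ES = bindS - offS - turnS,
    EI = bindI - offI - inact,
    EIx = inact,
    S = -bindS + offS,
    I = -bindI + offI,
    P = turnS)
}

#' Integrate the covalent inhibition mechanism
#'
#' Solves the mass-action mechanism on a time grid with `deSolve::lsoda`.
#' Only the complexes and the product are integrated; free enzyme,
#' substrate and inhibitor are reconstructed from the conservation laws,
#' so the mass balances hold exactly at every grid point and the stiff
#' binding equilibria do not erode them.
#'
#' @param state0 Initial [mechanism_state()].
#' @param rates [rate_parameters()] with substrate constants.
#' @param times Strictly increasing time grid starting at 0, s.
#' @param rtol,atol Relative / absolute integrator tolerances.
#' @return A data.frame with columns `time, E, ES, EI, EIx, S, I, P` (M).
#' @export
#' @examples
#' r <- rate_parameters(kinact_over_KI = 2e5, kcat = 20, KM = 8e-5)
#' s0 <- mechanism_state(E = 1e-9, S = 4e-5, I = 2e-6)
#' traj <- integrate_mechanism(s0, r, seq(0, 60, by = 5))
integrate_mechanism <- function(state0, rates, times,
                                rtol = 1e-10, atol = 1e-18) {
  stopifnot(inherits(state0, "mechanism_state"),
            inherits(rates, "rate_parameters"),
            is.numeric(times), length(times) >= 2L)
  if (times[1] != 0 || any(diff(times) <= 0))
    stop("`times` must be strictly increasing and start at 0", call. = FALSE)
  if (is.null(rates$kcat))
    stop("`rates` must include `kcat` and `KM` for mechanistic simulation",
         call. = FALSE)

  s0 <- unclass(state0)
  totals <- c(E = s0[["E"]] + s0[["ES"]] + s0[["EI"]] + s0[["EIx"]],
              S = s0[["S"]] + s0[["ES"]] + s0[["P"]],
              I = s0[["I"]] + s0[["EI"]] + s0[["EIx"]])

  rhs <- function(t, y, p) {
    E <- totals[["E"]] - y[1] - y[2] - y[3]
    S <- totals[["S"]] - y[1] - y[4]
    I <- totals[["I"]] - y[2] - y[3]
    dES <- p$k1 * E * S - (p$km1 + p$kcat) * y[1]
    dEI <- p$kon * E * I - (p$koff + p$kinact) * y[2]
    list(c(dES, dEI, p$kinact * y[2], p$kcat * y[1]))
  }

  y0 <- c(s0[["ES"]], s0[["EI"]], s0[["EIx"]], s0[["P"]])
  sol <- deSolve::lsoda(y0, times, rhs, parms = rates,
                        rtol = rtol, atol = atol)
  diagn <- attr(sol, "istate")
  if (anyNA(sol) || (!is.null(diagn) && diagn[1] < 0))
    stop("mechanism integration failed (lsoda istate = ",
         if (is.null(diagn)) "NA" else diagn[1], ")", call. = FALSE)

  ES <- sol[, 2]; EI <- sol[, 3]; EIx <- sol[, 4]; P <- sol[, 5]
  data.frame(
    time = sol[, 1],
    E = totals[["E"]] - ES - EI - EIx,
    ES = ES, EI = EI, EIx = EIx,
    S = totals[["S"]] - ES - P,
    I = totals[["I"]] - EI - EIx,
    P = P
  )
}
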