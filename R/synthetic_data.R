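# Mechanistic generator of plate-reader-like fluorogenic assay data:
# exponential progress curves on a read grid, seven-concentration ladders in
# triplicate, and the 25 uM / 15 min preincubation screening mode.

#' Assay condition for one enzyme/substrate pair
#'
#' Buffer, temperature and instrument settings are carried as a free-form
#' tag; the quantities that matter to the kinetics are the enzyme and
#' substrate concentrations, the Michaelis constant of the reporter
#' substrate, and the detector gain/baseline.
#'
#' @param enzyme_id Enzyme label, e.g. `"HNE"`, `"PR3"`, `"CatG"`.
#' @param enzyme_conc Active-enzyme concentration, M (default 1 nM).
#' @param substrate_id Substrate label.
#' @param S Substrate concentration during the read, M (> 0).
#' @param KM Michaelis constant of the substrate, M (> 0). Not published for
#'   the canonical assays, so it is always an explicit configuration input.
#' @param kcat Substrate turnover number used by the simulator, s^-1.
#' @param gain Detector gain, signal units per M product.
#' @param baseline Detector offset, signal units.
#' @param read_interval Sampling interval, s.
#' @param duration Read duration, s (>= 10 read intervals).
#' @param buffer Free-form buffer/temperature tag.
#' @return An object of class `assay_condition`.
#' @export
assay_condition <- function(enzyme_id, enzyme_conc = 1e-9,
                            substrate_id = "substrate", S, KM, kcat = 20,
                            gain = 1e9, baseline = 50,
                            read_interval = 10, duration = 600,
                            buffer = "0.1 M HEPES, 0.5 M NaCl, 0.03% Triton X-100, pH 7.5, 37C") {
  stopifnot(is.character(enzyme_id), length(enzyme_id) == 1L,
            enzyme_conc > 0, S > 0, KM > 0, kcat > 0, gain > 0,
            read_interval > 0, duration >= 10 * read_interval)
  structure(list(enzyme_id = enzyme_id, enzyme_conc = enzyme_conc,
                 substrate_id = substrate_id, S = S, KM = KM, kcat = kcat,
                 gain = gain, baseline = baseline,
                 read_interval = read_interval, duration = duration,
                 buffer = buffer),
            class = "assay_condition")
}

#' Default assay conditions for the three neutrophil serine proteases
#'
#' Substrate concentrations follow the canonical continuous assays
#' (MeO-Suc-AAPV-AFC at 40 uM for elastase and 125 uM for proteinase 3;
#' Suc-AAPF-AFC at 250 uM for cathepsin G). The Michaelis constants are not
#' published for these assays and the defaults here are package
#' placeholders chosen to span substrate-competition factors of 1.5, 2 and
#' 3; override them with measured values for real data. Enzyme
#' concentrations: elastase is sold by activity, so a nominal 1 nM is used;
#' proteinase 3 and cathepsin G use their stated molar concentrations.
#'
#' @return Named list of [assay_condition()] objects (`HNE`, `PR3`, `CatG`).
#' @export
default_assay_conditions <- function() {
  list(
    HNE = assay_condition("HNE", enzyme_conc = 1e-9,
                          substrate_id = "MeO-Suc-AAPV-AFC",
                          S = 40e-6, KM = 80e-6),
    PR3 = assay_condition("PR3", enzyme_conc = 7e-9,
                          substrate_id = "MeO-Suc-AAPV-AFC",
                          S = 125e-6, KM = 125e-6),
    CatG = assay_condition("CatG", enzyme_conc = 20e-9,
                           substrate_id = "Suc-AAPF-AFC",
                           S = 250e-6, KM = 125e-6)
  )
}

#' Measurement noise model
#'
#' Per-point Gaussian noise: a relative component proportional to the
#' noiseless product signal above baseline plus an additive component in
#' signal units. Replicate scatter of assay constants is expected to stay
#' within 10%; a per-point `relative_sd` of 0.05 respects that after
#' averaging over a read grid.
#'
#' @param relative_sd Relative SD (fraction of signal above baseline, >= 0).
#' @param additive_sd Additive SD, signal units (>= 0).
#' @param seed Integer seed; identical seeds give bit-identical curves.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(relative_sd = 0.05, additive_sd = 0, seed = 1L) {
  stopifnot(relative_sd >= 0, additive_sd >= 0,
            is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(relative_sd = relative_sd, additive_sd = additive_sd,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' A compound with its true (simulation) rate constants
#'
#' @param compound_id Identifier (character).
#' @param rates Named list mapping enzyme_id to a [rate_parameters()] object
#'   (or a bare `kinact_over_KI` number, coerced).
#' @param metadata Free-form list (sequence label, P1-P3 residues,
#'   stereochemistry tag, ...).
#' @return An object of class `compound_spec`.
#' @export
compound_spec <- function(compound_id, rates, metadata = list()) {
  stopifnot(is.character(compound_id), length(compound_id) == 1L,
            is.list(rates), length(rates) >= 1L,
            !is.null(names(rates)), all(nzchar(names(rates))))
  rates <- lapply(rates, function(r) {
    if (inherits(r, "rate_parameters")) r else rate_parameters(kinact_over_KI = r)
  })
  structure(list(compound_id = compound_id, rates = rates,
                 metadata = metadata),
            class = "compound_spec")
}

compound_rates <- function(compound, enzyme_id) {
  r <- compound$rates[[enzyme_id]]
  if (is.null(r))
    stop("compound ", compound$compound_id, " has no rates for enzyme ",
         enzyme_id, call. = FALSE)
  r
}

# Derive a reproducible 31-bit child seed for curve i of a determination.
child_seed <- function(seed, i) as.integer((seed + 1009 * i) %% 2147483647L)

add_noise <- function(clean_above_baseline, baseline, noise) {
  if (is.null(noise) || (noise$relative_sd == 0 && noise$additive_sd == 0))
    return(baseline + clean_above_baseline)
  n <- length(clean_above_baseline)
  withr::with_seed(noise$seed, {
    eps_rel <- stats::rnorm(n)
    eps_add <- stats::rnorm(n)
    baseline + clean_above_baseline * (1 + noise$relative_sd * eps_rel) +
      noise$additive_sd * eps_add
  })
}

#' Simulate one progress curve
#'
#' Generates `signal(t) = baseline + gain * P(t) + noise` on the read grid.
#' With `method = "closed_form"` the product trace follows the
#' single-exponential model with `k_obs` from the pseudo-first-order
#' relation (exactly linear in [I], no substrate depletion); with
#' `method = "ode"` the full mass-action mechanism is integrated, which
#' exhibits inhibitor saturation and substrate depletion when the
#' conditions impose them.
#'
#' @param cond An [assay_condition()].
#' @param compound A [compound_spec()], a [rate_parameters()] object, or a
#'   bare `kinact_over_KI` number.
#' @param I Inhibitor concentration, M (>= 0).
#' @param noise A [noise_model()] or NULL for noiseless output.
#' @param method `"closed_form"` (default) or `"ode"`.
#' @param replicate,role Metadata stamped on the returned curve.
#' @return A [progress_curve()]; the true `(v_i, k_obs)` used are attached
#'   as attribute `"truth"`.
#' @export
simulate_progress_curve <- function(cond, compound, I, noise = NULL,
                                    method = c("closed_form", "ode"),
                                    replicate = 1L, role = if (I > 0) "sample" else "control") {
  stopifnot(inherits(cond, "assay_condition"), is.numeric(I),
            length(I) == 1L, I >= 0)
  method <- match.arg(method)
  if (inherits(compound, "compound_spec")) {
    rates <- compound_rates(compound, cond$enzyme_id)
    cid <- compound$compound_id
  } else if (inherits(compound, "rate_parameters")) {
    rates <- compound
    cid <- NA_character_
  } else {
    rates <- rate_parameters(kinact_over_KI = compound)
    cid <- NA_character_
  }

  times <- seq(0, cond$duration, by = cond$read_interval)
  vi_molar <- cond$kcat * cond$enzyme_conc * cond$S / (cond$KM + cond$S)
  kobs <- kobs_from_second_order(rates$kinact_over_KI, I, cond$S, cond$KM)

  if (method == "closed_form") {
    P <- progress_closed_form(times, vi_molar, kobs)
  } else {
    mech <- rate_parameters(kinact = rates$kinact, KI = rates$KI,
                            kcat = cond$kcat, KM = cond$KM,
                            equilibration_factor = rates$equilibration_factor)
    traj <- integrate_mechanism(
      mechanism_state(E = cond$enzyme_conc, S = cond$S, I = I),
      mech, times)
    P <- traj$P
  }

  signal <- add_noise(cond$gain * P, cond$baseline, noise)
  out <- progress_curve(times, signal, enzyme_id = cond$enzyme_id,
                        compound_id = cid, I = I,
                        replicate = as.integer(replicate), role = role)
  attr(out, "truth") <- list(v_i = cond$gain * vi_molar, k_obs = kobs,
                             kinact_over_KI = rates$kinact_over_KI)
  out
}

#' Design an identifiable inhibitor-concentration ladder
#'
#' Chooses concentrations so the noiseless `k_obs * duration` spans
#' `span` (default 0.5 to 5, log-spaced): low enough that the early slope
#' is measurable, high enough that curvature is resolvable against a
#' straight line.
#'
#' @param kinact_over_KI Anticipated second-order constant, M^-1 s^-1 (> 0).
#' @param S,KM Substrate concentration and Michaelis constant, M.
#' @param duration Read duration, s.
#' @param n Number of concentrations (default 7).
#' @param span Target range of `k_obs * duration` (length 2, increasing).
#' @return Strictly increasing vector of `n` concentrations, M.
#' @export
design_ladder <- function(kinact_over_KI, S, KM, duration, n = 7,
                          span = c(0.5, 5)) {
  stopifnot(kinact_over_KI > 0, duration > 0, n >= 2,
            length(span) == 2L, span[1] > 0, span[2] > span[1])
  targets <- exp(seq(log(span[1]), log(span[2]), length.out = n))
  targets / duration * (1 + S / KM) / kinact_over_KI
}

#' Simulate a full kinetic determination
#'
#' One determination is `replicates` independent experiments, each a ladder
#' of inhibitor concentrations (default: seven, auto-designed) plus an
#' uninhibited control, all sampled on the condition's read grid.
#'
#' @param cond An [assay_condition()].
#' @param compound A [compound_spec()] (or coercible, see
#'   [simulate_progress_curve()]).
#' @param ladder Strictly increasing positive concentrations, M; default
#'   [design_ladder()] from the compound's true constant. At least 2.
#' @param replicates Number of independent experiments (default 3).
#' @param noise A [noise_model()] or NULL; per-curve child seeds are derived
#'   from its seed so the whole dataset is reproducible.
#' @param n_controls Controls per replicate (default 1).
#' @param method Curve generation method, see [simulate_progress_curve()].
#' @return An object of class `assay_dataset`: list with `condition`,
#'   `compound_id`, `ladder`, `curves` (named by well), `layout`
#'   (data.frame: well, enzyme, compound, I_molar, replicate, role),
#'   `truth` (true constant and per-concentration `k_obs`), and `seed`.
#' @export
simulate_determination <- function(cond, compound, ladder = NULL,
                                   replicates = 3, noise = NULL,
                                   n_controls = 1,
                                   method = c("closed_form", "ode")) {
  stopifnot(inherits(cond, "assay_condition"), replicates >= 1,
            n_controls >= 0)
  method <- match.arg(method)
  if (!inherits(compound, "compound_spec")) {
    compound <- compound_spec("anon", stats::setNames(list(compound),
                                                      cond$enzyme_id))
  }
  rates <- compound_rates(compound, cond$enzyme_id)
  if (is.null(ladder)) {
    ladder <- design_ladder(rates$kinact_over_KI, cond$S, cond$KM,
                            cond$duration)
  }
  if (length(ladder) < 2L)
    stop("`ladder` needs at least 2 concentrations", call. = FALSE)
  if (any(ladder <= 0) || any(diff(ladder) <= 0))
    stop("`ladder` must be strictly increasing and positive", call. = FALSE)

  curves <- list()
  layout <- list()
  idx <- 0L
  for (r in seq_len(replicates)) {
    for (I in c(rep(0, n_controls), ladder)) {
      idx <- idx + 1L
      nm <- if (is.null(noise)) NULL else
        noise_model(noise$relative_sd, noise$additive_sd,
                    child_seed(noise$seed, idx))
      cv <- simulate_progress_curve(cond, compound, I, noise = nm,
                                    method = method, replicate = r)
      well <- sprintf("W%03d", idx)
      curves[[well]] <- cv
      layout[[well]] <- data.frame(
        well = well, enzyme = cond$enzyme_id,
        compound = compound$compound_id, I_molar = I, replicate = r,
        role = cv$role, stringsAsFactors = FALSE)
    }
  }

  structure(
    list(condition = cond, compound_id = compound$compound_id,
         ladder = ladder, curves = curves,
         layout = do.call(rbind, unname(layout)),
         truth = list(
           kinact_over_KI = rates$kinact_over_KI,
           kobs_by_I = data.frame(
             I = ladder,
             k_obs = kobs_from_second_order(rates$kinact_over_KI, ladder,
                                            cond$S, cond$KM))),
         seed = if (is.null(noise)) NA_integer_ else noise$seed),
    class = "assay_dataset")
}

#' @export
print.assay_dataset <- function(x, ...) {
  cat(sprintf(
    "<assay_dataset> %s / compound %s: %d curves (%d-point ladder x %d replicates)\n",
    x$condition$enzyme_id, x$compound_id, length(x$curves),
    length(x$ladder), max(x$layout$replicate)))
  invisible(x)
}

#' Simulate the 25 uM preincubation screen
#'
#' Models the screening protocol: the compound is preincubated with the
#' enzyme in the absence of substrate, so the enzyme decays at
#' `kinact * [I] / (KI + [I])` (no substrate-competition term); substrate is
#' then added and activity is read against an uninhibited control.
#'
#' Two readouts are exposed because the protocol does not pin one down:
#' `"rate"` compares post-addition initial velocities (residual fraction
#' `exp(-kobs_pre * preincubation)`), `"endpoint"` compares accumulated
#' product at the end of the read window, where inactivation continues
#' (with competition) during the read.
#'
#' @param cond An [assay_condition()].
#' @param compound A [compound_spec()], [rate_parameters()] or bare constant.
#' @param I Screening concentration, M (default 25 uM).
#' @param preincubation Preincubation time, s (default 900 = 15 min).
#' @param noise A [noise_model()] or NULL; relative noise is applied to the
#'   measured velocities (or endpoints).
#' @param readout `"rate"` (default) or `"endpoint"`.
#' @return Residual activity fraction (inhibited / control), clipped at 0.
#' @export
#' @examples
#' cond <- default_assay_conditions()$HNE
#' simulate_screen(cond, rate_parameters(kinact_over_KI = 50, KI = 1))
simulate_screen <- function(cond, compound, I = 25e-6, preincubation = 900,
                            noise = NULL, readout = c("rate", "endpoint")) {
  stopifnot(inherits(cond, "assay_condition"), I >= 0, preincubation >= 0)
  readout <- match.arg(readout)
  rates <- if (inherits(compound, "compound_spec"))
    compound_rates(compound, cond$enzyme_id)
  else if (inherits(compound, "rate_parameters")) compound
  else rate_parameters(kinact_over_KI = compound)

  kobs_pre <- rates$kinact * I / (rates$KI + I)
  frac_active <- exp(-kobs_pre * preincubation)

  if (readout == "rate") {
    v_ctrl <- 1
    v_inh <- frac_active
  } else {
    kobs_read <- kobs_from_second_order(rates$kinact_over_KI, I, cond$S,
                                        cond$KM)
    tread <- cond$duration
    v_ctrl <- tread                                   # per unit velocity
    v_inh <- frac_active * progress_closed_form(tread, 1, kobs_read)
  }

  if (!is.null(noise) && (noise$relative_sd > 0 || noise$additive_sd > 0)) {
    withr::with_seed(noise$seed, {
      eps <- stats::rnorm(2)
      v_inh <- v_inh * (1 + noise$relative_sd * eps[1])
      v_ctrl <- v_ctrl * (1 + noise$relative_sd * eps[2])
    })
  }
  max(v_inh / v_ctrl, 0)
}

#' Compound library fixture with transcribed published constants
#'
#' Returns the library of phosphonic tripeptide inhibitors whose
#' second-order constants are quoted in the source study's comparative
#' discussion: compounds 2, 27 (the reference), 29, 62, 65, 70, 75, 77, 78,
#' 79, 80, 100, 111 and 113, with elastase constants for all, proteinase 3
#' constants where quoted (111, 113), and cathepsin G entries censored at
#' the "< 50 M^-1 s^-1" inactivity convention for the selectivity-panel
#' members. The transcription is incomplete relative to the study's full
#' tables, which are not reproduced here.
#'
#' Optionally appends randomized synthetic compounds (ids `SYN..`) whose
#' elastase/proteinase 3 constants are log-uniform on 50 to 9e6 M^-1 s^-1
#' and whose cathepsin G entries are censored, for stress-testing ranking
#' and profiling.
#'
#' @param n_synthetic Number of synthetic compounds to append (default 0).
#' @param seed Seed for the synthetic constants (required if
#'   `n_synthetic > 0`).
#' @return A data.frame with columns `compound_id`, `enzyme`,
#'   `kinact_over_KI` (NA when censored), `censored` (logical), `bound`
#'   (the censoring bound, M^-1 s^-1), `source`
#'   (`"published"`/`"synthetic"`).
#' @export
nsp_compound_library <- function(n_synthetic = 0, seed = NULL) {
  path <- system.file("extdata", "published_constants.csv",
                      package = "covkin", mustWork = TRUE)
  lib <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(compound_id = "character"))
  lib$censored <- as.logical(lib$censored)
  lib$kinact_over_KI <- as.numeric(lib$kinact_over_KI)
  lib$bound <- as.numeric(lib$bound)
  lib$source <- "published"

  if (n_synthetic > 0) {
    if (is.null(seed)) stop("`seed` is required for synthetic compounds",
                            call. = FALSE)
    syn <- withr::with_seed(as.integer(seed), {
      ids <- sprintf("SYN%02d", seq_len(n_synthetic))
      k_hne <- 10^stats::runif(n_synthetic, log10(50), log10(9e6))
      k_pr3 <- 10^stats::runif(n_synthetic, log10(50), log10(9e6))
      rbind(
        data.frame(compound_id = ids, enzyme = "HNE",
                   kinact_over_KI = k_hne, censored = FALSE, bound = NA_real_,
                   stringsAsFactors = FALSE),
        data.frame(compound_id = ids, enzyme = "PR3",
                   kinact_over_KI = k_pr3, censored = FALSE, bound = NA_real_,
                   stringsAsFactors = FALSE),
        data.frame(compound_id = ids, enzyme = "CatG",
                   kinact_over_KI = NA_real_, censored = TRUE, bound = 50,
                   stringsAsFactors = FALSE))
    })
    syn$source <- "synthetic"
    lib <- rbind(lib, syn)
  }
  lib
}
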