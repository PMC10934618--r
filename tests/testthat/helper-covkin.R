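# Shared fixture builders: everything is generated in code at test time.

hne_condition <- function(...) {
  cond <- default_assay_conditions()$HNE
  dots <- list(...)
  for (nm in names(dots)) cond[[nm]] <- dots[[nm]]
  cond
}

# condition with an arbitrary substrate-competition factor 1 + S/KM
condition_with_ratio <- function(s_over_km, KM = 8e-5, ...) {
  assay_condition("HNE", substrate_id = "MeO-Suc-AAPV-AFC",
                  S = s_over_km * KM, KM = KM, ...)
}

# noiseless single-exponential curve with known truth
make_exp_curve <- function(v_i = 1.5, k_obs = 0.008, baseline = 50,
                           duration = 600, by = 10, ...) {
  tt <- seq(0, duration, by = by)
  progress_curve(tt, baseline + progress_closed_form(tt, v_i, k_obs), ...)
}

make_linear_curve <- function(slope = 2, baseline = 50, duration = 600,
                              by = 10, noise_sd = 0, seed = 1, ...) {
  tt <- seq(0, duration, by = by)
  y <- baseline + slope * tt
  if (noise_sd > 0)
    y <- withr::with_seed(seed, y + stats::rnorm(length(tt), 0, noise_sd))
  progress_curve(tt, y, ...)
}
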