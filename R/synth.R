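#' Synthetic patient specification
#'
#' Defines a synthetic levodopa-test patient: an archetype (parameter pool
#' drawn from the fitted subjects - "stable" around group 1 subjects 1-2,
#' "wearing-off" around group 2, "borderline" around group 1 subject 3),
#' measurement noise levels, the RNG seed, and the clinical sampling
#' schedule (plasma every 15 min to 90 min then every 30 min to 3 h;
#' tapping at the same times extended to 4 h post-dose).
#'
#' @param archetype `"stable"`, `"wearing-off"` or `"borderline"`.
#' @param noise_plasma Multiplicative coefficient of variation on plasma
#'   samples (log-normal; assay-like noise). Default 5%.
#' @param noise_tapping Additive standard deviation on tapping samples
#'   \[taps/min\] (count-jitter-like). Default 5.
#' @param seed RNG seed (integer).
#' @param plasma_times,tapping_times Sampling schedules \[min\].
#' @param pk_jitter Log-normal coefficient of variation applied to the
#'   archetype's rate constants so synthetic patients are not exact copies
#'   of the pool subjects.
#' @return An object of class `synth_spec`.
#' @examples
#' synth_spec("wearing-off", seed = 1)
#' @export
synth_spec <- function(archetype = c("stable", "wearing-off", "borderline"),
                       noise_plasma = 0.05, noise_tapping = 5, seed = 1,
                       plasma_times = c(seq(0, 90, by = 15), seq(120, 180, by = 30)),
                       tapping_times = c(seq(0, 90, by = 15), seq(120, 240, by = 30)),
                       pk_jitter = 0.05) {
  archetype <- match.arg(archetype)
  if (noise_plasma < 0 || noise_tapping < 0 || pk_jitter < 0) {
    stop("synth_spec: noise parameters must be >= 0", call. = FALSE)
  }
  structure(list(archetype = archetype, noise_plasma = noise_plasma,
                 noise_tapping = noise_tapping, seed = as.integer(seed),
                 plasma_times = plasma_times, tapping_times = tapping_times,
                 pk_jitter = pk_jitter),
            class = "synth_spec")
}

archetype_pool <- function(archetype) {
  tab <- ld_patients()
  switch(archetype,
         "stable" = tab[tab$group == 1L & tab$subject %in% c(1L, 2L), ],
         "wearing-off" = tab[tab$group == 2L, ],
         "borderline" = tab[tab$group == 1L & tab$subject == 3L, ])
}

#' Generate a synthetic patient record
#'
#' Draws a parameter set from the archetype pool (one pool subject chosen
#' at random, rate constants jittered log-normally), simulates the
#' ground-truth plasma and tapping curves through the full model chain,
#' and adds measurement noise at the scheduled sample times: multiplicative
#' log-normal on plasma, additive Gaussian on taps/min. The ground-truth
#' parameters are attached so that recovery studies can compare against
#' them. Identical seeds give identical records.
#'
#' @param spec A [synth_spec()].
#' @param dose_ug,duration_min Dosing (100 mg over 30 min by default).
#' @param curve Optional precomputed [d_to_frequency_curve()]; built once
#'   when absent.
#' @param protocol,params,weights Network configuration for the tapping
#'   arm.
#' @return A [patient_record()] with `observed_plasma` and
#'   `observed_tapping` filled in, plus attributes `truth` (list with the
#'   noise-free series) and `spec`.
#' @examples
#' rec <- make_patient(synth_spec("stable", seed = 7,
#'                                noise_plasma = 0, noise_tapping = 0))
#' rec$id
#' @export
make_patient <- function(spec, dose_ug = 1e5, duration_min = 30,
                         curve = NULL, protocol = tapping_protocol(),
                         params = bg_params(), weights = bg_weights()) {
  stopifnot(inherits(spec, "synth_spec"))
  pool <- archetype_pool(spec$archetype)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  row <- pool[sample.int(nrow(pool), 1L), ]
  jit <- function(x) x * exp(stats::rnorm(1, 0, spec$pk_jitter))
  pk <- pk_params(k12 = jit(row$k12), k21 = jit(row$k21),
                  ketot = jit(row$ketot))
  eff <- effect_params(ke3_over_V3 = row$ke3_over_V3, T_delay = row$T_delay,
                       D0 = row$D0, Dmax = row$Dmax, Dc50 = row$Dc50,
                       N = row$N)
  sched <- infusion_schedule(dose_ug, duration_min)
  rec <- patient_record(
    id = sprintf("synth-%s-%d", spec$archetype, spec$seed),
    group = row$group, pk = pk, effect = eff, schedule = sched)

  sim <- simulate_patient(
    rec, sample_times = sort(unique(c(spec$plasma_times, spec$tapping_times))),
    mode = "curve", curve = curve, protocol = protocol, params = params,
    weights = weights)

  pl_idx <- match(spec$plasma_times, sim$time)
  tp_idx <- match(spec$tapping_times, sim$time)
  plasma_true <- sim$c1[pl_idx]
  taps_true <- sim$taps_per_min[tp_idx]

  plasma_obs <- plasma_true *
    exp(stats::rnorm(length(plasma_true), 0, spec$noise_plasma))
  taps_obs <- pmax(taps_true +
                     stats::rnorm(length(taps_true), 0, spec$noise_tapping), 0)

  rec$observed_plasma <- ts_series(spec$plasma_times, plasma_obs,
                                   unit = "ug/ml")
  rec$observed_tapping <- ts_series(spec$tapping_times, taps_obs,
                                    unit = "taps/min")
  attr(rec, "truth") <- list(
    pk = pk, effect = eff, pool_subject = row$subject, group = row$group,
    plasma = ts_series(spec$plasma_times, plasma_true, unit = "ug/ml"),
    tapping = ts_series(spec$tapping_times, taps_true, unit = "taps/min"),
    sim = sim)
  attr(rec, "spec") <- spec
  rec
}
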