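# Synthetic SPR sensograms under the closed-form 1:1 Langmuir model.
#
# Association: R(t) = R_eq(C) (1 - exp(-(kon C + koff) t)) with
# R_eq(C) = rmax C / (C + koff/kon); dissociation: exponential decay at koff
# from the response reached at the end of association.

#' Configuration for synthetic SPR sensograms
#'
#' @param kon Association rate constant in 1/(M s).
#' @param koff Dissociation rate constant in 1/s.
#' @param rmax Saturation response in RU.
#' @param concentrations Analyte concentrations in M.
#' @param association_duration,dissociation_duration Phase lengths in s.
#' @param sampling_interval Time step in s.
#' @param noise_sd Additive response noise s.d. in RU.
#' @param seed Integer seed (optional).
#' @return Object of class `spr_gen_config`.
#' @export
spr_gen_config <- function(kon = 6.54e3, koff = 3.18e-3, rmax = 100,
                           concentrations = c(5e-6, 2.5e-6),
                           association_duration = 300,
                           dissociation_duration = 600,
                           sampling_interval = 1,
                           noise_sd = 0,
                           seed = NULL) {
  if (kon <= 0 || koff <= 0 || rmax <= 0)
    abort("kon, koff and rmax must be positive", "smelt_config_error")
  if (any(concentrations <= 0))
    abort("concentrations must be positive", "smelt_config_error")
  if (association_duration <= 0 || dissociation_duration < 0 ||
      sampling_interval <= 0 || noise_sd < 0)
    abort("invalid timing or noise settings", "smelt_config_error")
  structure(list(kon = kon, koff = koff, rmax = rmax,
                 concentrations = concentrations,
                 association_duration = association_duration,
                 dissociation_duration = dissociation_duration,
                 sampling_interval = sampling_interval,
                 noise_sd = noise_sd, seed = seed),
            class = "spr_gen_config")
}

spr_model_response <- function(time, association_end, conc, kon, koff, rmax) {
  kobs <- kon * conc + koff
  req <- rmax * conc / (conc + koff / kon)
  r_end <- req * (1 - exp(-kobs * association_end))
  ifelse(time <= association_end,
         req * (1 - exp(-kobs * time)),
         r_end * exp(-koff * (time - association_end)))
}

#' Generate synthetic SPR sensograms
#'
#' @param config An [spr_gen_config()].
#' @return List of `sensogram` objects (class `sensogram_set`), one per
#'   concentration, each with `time` (s), `response` (RU),
#'   `analyte_concentration` (M), `association_end` (s), and generator truth
#'   in `metadata`.
#' @export
gen_sensograms <- function(config) {
  stopifnot(inherits(config, "spr_gen_config"))
  with_seed(config$seed, {
    time <- seq(0, config$association_duration + config$dissociation_duration,
                by = config$sampling_interval)
    out <- lapply(config$concentrations, function(conc) {
      resp <- spr_model_response(time, config$association_duration, conc,
                                 config$kon, config$koff, config$rmax)
      if (config$noise_sd > 0) resp <- resp + rnorm(length(resp), sd = config$noise_sd)
      structure(list(time = time, response = resp,
                     analyte_concentration = conc,
                     association_end = config$association_duration,
                     reference_subtracted = TRUE,
                     metadata = list(kon = config$kon, koff = config$koff,
                                     rmax = config$rmax)),
                class = "sensogram")
    })
    structure(out, class = "sensogram_set")
  })
}
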