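#' Packaged patient fixtures
#'
#' Named configurations used in the worked examples: the invasively
#' characterised severe-stenosis patient (`dekker_av_stenosis`; Ees 3.3,
#' Eed 0.1 mmHg/mL, Vd 39.3 mL, LVEDP 11 mmHg, AVA 0.6 cm^2) and the
#' dobutamine rest/stress pair (`dobutamine_rest`, `dobutamine_stress`;
#' AVA 0.88 cm^2 with stroke-volume targets 67 and 87 mL).
#'
#' @param name One of `"dekker_av_stenosis"`, `"dobutamine_rest"`,
#'   `"dobutamine_stress"`.
#' @return List with `cardiac` ([cardiac_params()]), `valve`
#'   ([valve_params()]), and for the dobutamine pair `sv_target` (mL).
#' @export
patient_fixture <- function(name = c("dekker_av_stenosis",
                                     "dobutamine_rest",
                                     "dobutamine_stress")) {
  name <- match.arg(name)
  switch(name,
    dekker_av_stenosis = list(
      cardiac = cardiac_params(ees = 3.3, eed = 0.1, lvedp = 11, vd = 39.3),
      valve = valve_params(ava = 0.6),
      sv_target = NULL),
    dobutamine_rest = list(
      cardiac = cardiac_params(),
      valve = valve_params(ava = 0.88),
      sv_target = 67),
    dobutamine_stress = list(
      cardiac = cardiac_params(),
      valve = valve_params(ava = 0.88),
      sv_target = 87))
}

#' Write a simulation configuration to YAML
#'
#' @param cardiac,valve Parameter objects.
#' @param path Output file.
#' @param extra Optional named list merged into the file (e.g. afterload
#'   targets).
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(cardiac, valve, path, extra = list()) {
  cfg <- c(list(
    cardiac = list(ees = cardiac$ees, eed = cardiac$eed,
                   t_hp = cardiac$t_hp, t_max = cardiac$t_max,
                   lvedp = cardiac$lvedp, vd = cardiac$vd,
                   atrial_pressure = cardiac$atrial_pressure,
                   mitral_resistance = cardiac$mitral_resistance),
    valve = list(ava_cm2 = valve$ava, leff_cm = valve$leff,
                 ao_cm2 = valve$ao, kt = valve$kt, kvo = valve$kvo,
                 rho = valve$rho)),
    extra)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file as written by [write_sim_config()].
#' @return List with `cardiac`, `valve`, and any extra entries.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cardiac <- do.call(cardiac_params, c(
    cfg$cardiac[c("ees", "eed", "t_hp", "t_max", "lvedp", "vd")],
    list(atrial_pressure = cfg$cardiac$atrial_pressure,
         mitral_resistance = cfg$cardiac$mitral_resistance)))
  v <- cfg$valve
  valve <- valve_params(ava = v$ava_cm2, leff = v$leff_cm, ao = v$ao_cm2,
                        kt = v$kt, kvo = v$kvo, rho = v$rho)
  c(list(cardiac = cardiac, valve = valve),
    cfg[setdiff(names(cfg), c("cardiac", "valve"))])
}
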