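#' Controlled vital-sign channel vocabulary
#'
#' The channels monitored intraoperatively and understood by every stage of
#' the pipeline. Units: bpm for `HR`/`PULSE`, mmHg for the pressure channels
#' and `ETCO2`, breaths/min for `RR`, % for `SPO2`, degrees C for `TEMP`.
#' `NIBP_SYS`/`NIBP_DIA` are the non-invasive cuff pressures, sampled sparsely
#' by protocol rather than continuously.
#'
#' @return Character vector of canonical channel names.
#' @export
#' @examples
#' ioh_channels()
ioh_channels <- function() {
  c("HR", "PULSE", "SBP", "DBP", "MAP", "NIBP_SYS", "NIBP_DIA",
    "RR", "SPO2", "ETCO2", "TEMP")
}

#' Default alias map from common monitor labels to canonical channel names
#'
#' Extendable by the user: `read_case()` accepts an `aliases` argument that is
#' merged over these defaults. Unknown channel names are preserved verbatim.
#'
#' @return Named character vector mapping alias -> canonical name.
#' @export
ioh_channel_aliases <- function() {
  c(
    "HEART_RATE" = "HR", "HRATE" = "HR", "PR" = "PULSE", "PULSE_RATE" = "PULSE",
    "ABP_SYS" = "SBP", "ART_SBP" = "SBP", "ABP_DIA" = "DBP", "ART_DBP" = "DBP",
    "ABP_MEAN" = "MAP", "ART_MBP" = "MAP", "MBP" = "MAP",
    "NIBP_SBP" = "NIBP_SYS", "NIBP_DBP" = "NIBP_DIA",
    "RESP" = "RR", "RSP" = "RR", "SPO2_PCT" = "SPO2", "ETCO2_MMHG" = "ETCO2",
    "BT" = "TEMP", "BODY_TEMP" = "TEMP"
  )
}

canonical_channel <- function(x, aliases = NULL) {
  map <- ioh_channel_aliases()
  if (!is.null(aliases)) map[names(aliases)] <- unname(aliases)
  out <- toupper(x)
  hit <- out %in% names(map)
  out[hit] <- unname(map[out[hit]])
  out
}
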