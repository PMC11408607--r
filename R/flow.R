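#' Stimulator flow configuration
#'
#' Describes the air-dilution plumbing of the odor stimulator: each odorant
#' channel releases headspace-saturated air at `odorant_flow` and mixes it
#' with `dilution_air_flow` of clean air (one such 3:297 mL/min stage gives a
#' 1:100 dilution); `n_dilution_stages` such stages act in series. All
#' channels are then combined and injected into the carrier stream.
#'
#' @param odorant_flow Odorant release rate, mL/min (default 3).
#' @param dilution_air_flow Dilution air per stage, mL/min (default 297).
#' @param n_dilution_stages Number of serial dilution stages (default 1,
#'   the high-concentration configuration).
#' @param n_channels Number of odorant channels combined (default 2).
#' @param carrier_flow Carrier air stream, mL/min (default 1500).
#' @return An object of class `flow_config`.
#' @export
flow_config <- function(odorant_flow = 3, dilution_air_flow = 297,
                        n_dilution_stages = 1, n_channels = 2,
                        carrier_flow = 1500) {
  stopifnot(odorant_flow >= 0, dilution_air_flow >= 0, carrier_flow >= 0,
            n_dilution_stages >= 1, n_channels >= 1)
  structure(
    list(odorant_flow = odorant_flow, dilution_air_flow = dilution_air_flow,
         n_dilution_stages = n_dilution_stages, n_channels = n_channels,
         carrier_flow = carrier_flow),
    class = "flow_config"
  )
}

#' Air-dilution arithmetic
#'
#' Computes the total outlet airflow and the final air-dilution fraction of
#' one odorant channel. The per-stage dilution is
#' `odorant_flow / (odorant_flow + dilution_air_flow)`, raised to the number
#' of serial stages; the diluted channel flow is then further diluted by its
#' share of the total outlet flow. With the default configuration (3 mL/min
#' odorant, 297 mL/min dilution air, one stage, two channels, 1.5 L/min
#' carrier) this reproduces the printed stimulator figures: total outlet flow
#' 2.1 L/min and a high-concentration dilution of 1.43e-3.
#'
#' @param cfg A [flow_config()].
#' @return List with `dilution_fraction` (dimensionless) and `total_flow`
#'   (L/min).
#' @export
compute_air_dilution <- function(cfg) {
  stopifnot(inherits(cfg, "flow_config"))
  channel_flow <- cfg$odorant_flow + cfg$dilution_air_flow
  total_ml <- cfg$n_channels * channel_flow + cfg$carrier_flow
  if (total_ml <= 0) stop("total flow must be positive")
  if (cfg$odorant_flow == 0) {
    frac <- 0
  } else {
    per_stage <- cfg$odorant_flow / channel_flow
    frac <- per_stage^cfg$n_dilution_stages * (channel_flow / total_ml)
  }
  list(dilution_fraction = frac, total_flow = total_ml / 1000)
}
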