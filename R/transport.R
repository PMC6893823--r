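# Two-chamber transport summaries (luminal/abluminal endothelial assay).

#' Summarize a two-chamber transport measurement
#'
#' Reduces a luminal/abluminal concentration pair from a trans-well
#' endothelial assay (upper chamber = blood-facing/luminal, lower chamber =
#' brain-facing/abluminal) to the ratios used to report barrier crossing:
#' the upper/lower concentration ratio, the dosed/upper ratio (loss from
#' the donor medium), and the recovery fraction
#' \code{(upper + lower) / dosed}. A lower-chamber concentration of zero
#' makes the upper/lower ratio undefined; it is reported as \code{NA} with
#' \code{ratio_computable = FALSE}, never as infinity.
#'
#' @param measurement data.frame (one row per compound) with columns
#'   \code{compound_id}, \code{dosed_conc}, \code{upper_conc},
#'   \code{lower_conc} (micromolar) and optionally
#'   \code{incubation_time} (hours).
#' @return data.frame with columns compound_id, upper_lower_ratio,
#'   dosed_upper_ratio, recovery_fraction, ratio_computable.
#' @examples
#' summarizeTransport(data.frame(compound_id = "pvl-sulfate",
#'   dosed_conc = 5, upper_conc = 0.42, lower_conc = 0.05))
#' @export
summarizeTransport <- function(measurement) {
  m <- measurement
  need <- c("compound_id", "dosed_conc", "upper_conc", "lower_conc")
  if (!all(need %in% colnames(m)))
    stop("measurement needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(m$dosed_conc <= 0))
    stop("dosed_conc must be positive", call. = FALSE)
  if (any(m$upper_conc < 0 | m$lower_conc < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  computable <- m$lower_conc > 0
  data.frame(
    compound_id = m$compound_id,
    upper_lower_ratio = ifelse(computable, m$upper_conc / m$lower_conc,
                               NA_real_),
    dosed_upper_ratio = ifelse(m$upper_conc > 0,
                               m$dosed_conc / m$upper_conc, NA_real_),
    recovery_fraction = (m$upper_conc + m$lower_conc) / m$dosed_conc,
    ratio_computable = computable,
    stringsAsFactors = FALSE)
}

#' Apparent permeability (optional extension)
#'
#' Standard two-chamber apparent-permeability coefficient
#' \eqn{P_{app} = (C_{lower} V_{lower}) / (t \, A \, C_0)}. This is an
#' extension beyond the ratio summaries: it requires the receiver volume
#' and insert area, which ratio reporting does not.
#'
#' @param lower_conc receiver (abluminal) concentration, micromolar.
#' @param dosed_conc donor concentration at t = 0, micromolar.
#' @param volume_lower_mL receiver volume, mL.
#' @param area_cm2 insert membrane area, cm^2.
#' @param time_h incubation time, hours.
#' @return Papp in cm/s.
#' @export
apparentPermeability <- function(lower_conc, dosed_conc, volume_lower_mL,
                                 area_cm2, time_h) {
  stopifnot(dosed_conc > 0, volume_lower_mL > 0, area_cm2 > 0, time_h > 0)
  (lower_conc * volume_lower_mL) / (time_h * 3600 * area_cm2 * dosed_conc)
}
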