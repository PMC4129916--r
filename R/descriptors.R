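#' Per-particle pulse descriptors
#'
#' For every event and channel computes the descriptors used as cytogram
#' axes: `total` (area under the pulse by the trapezoidal rule at unit
#' spacing; a length-1 pulse degenerates to `sum x spacing`), `maximum`
#' (peak value, mV) and `length` (number of samples), plus the derived
#' orange-fluorescence / sideward-scatter peak ratio. Events whose `max_SWS`
#' is zero get an `NA` ratio and are flagged (`ratio_defined = FALSE`)
#' rather than carrying an infinity.
#'
#' @param sample a `listmode_sample` (or a bare events data.table with the
#'   same columns).
#' @return a `data.table` with one row per event: `event_id`,
#'   `total_<CH>`, `max_<CH>`, `len_<CH>` for each channel, `ratio_FLO_SWS`
#'   and `ratio_defined`. Row order follows first appearance in the events
#'   table.
#' @export
compute_descriptors <- function(sample) {
  ev <- if (inherits(sample, "listmode_sample")) sample$events else sample
  stopifnot(is.data.frame(ev))
  ev <- data.table::as.data.table(ev)
  per <- ev[, .(
    total = if (.N == 1) sum(value_mV) else sum(value_mV) - (value_mV[1] + value_mV[.N]) / 2,
    maximum = max(value_mV),
    length = .N
  ), by = .(event_id, channel)]
  wide <- data.table::dcast(per, event_id ~ channel,
                            value.var = c("total", "maximum", "length"))
  for (ch in cyto_channels()) {
    data.table::setnames(wide, paste0(c("total_", "maximum_", "length_"), ch),
                         paste0(c("total_", "max_", "len_"), ch),
                         skip_absent = TRUE)
  }
  wide[, ratio_defined := !is.na(max_SWS) & max_SWS > 0]
  wide[, ratio_FLO_SWS := ifelse(ratio_defined, max_FLO / max_SWS, NA_real_)]
  # restore first-appearance order
  first <- unique(ev$event_id)
  wide[match(first, event_id)]
}

#' Apply an acquisition trigger threshold to a descriptor table
#'
#' Retains events whose pulse maximum on the trigger channel is at or above
#' the threshold (boundary inclusive). Retention is monotone non-increasing
#' in the level.
#'
#' @param desc descriptor table from [compute_descriptors()].
#' @param channel trigger channel name (e.g. `"FLR"`).
#' @param level_mV threshold in mV.
#' @return filtered descriptor table.
#' @export
apply_trigger <- function(desc, channel = "FLR", level_mV) {
  col <- paste0("max_", channel)
  if (!col %in% names(desc)) stop("unknown trigger channel: ", channel, call. = FALSE)
  desc[desc[[col]] >= level_mV, ]
}

#' Analysed sample volume
#'
#' `flow rate x duration x volume efficiency`, converted mm3 to cm3. If the
#' metadata carries an explicit measured `volume_cm3`, that value overrides
#' the nominal product.
#'
#' @param meta sample metadata list (fields `flow_rate_mm3s`, `duration_s`,
#'   optional `volume_efficiency`, optional measured `volume_cm3`).
#' @return volume in cm3.
#' @export
analyzed_volume <- function(meta) {
  if (!is.null(meta$volume_cm3)) {
    v <- meta$volume_cm3
    if (!is.finite(v) || v <= 0) stop("measured volume must be positive", call. = FALSE)
    return(v)
  }
  eff <- if (is.null(meta$volume_efficiency)) 1 else meta$volume_efficiency
  if (is.null(meta$flow_rate_mm3s) || is.null(meta$duration_s) ||
      meta$flow_rate_mm3s <= 0 || meta$duration_s <= 0 || eff <= 0) {
    stop("flow rate, duration and efficiency must be positive", call. = FALSE)
  }
  meta$flow_rate_mm3s * meta$duration_s * eff / 1000
}

#' Event count to cell concentration
#'
#' @param count non-negative event count.
#' @param volume_cm3 analysed volume (> 0).
#' @return cells/cm3.
#' @export
abundance_from_count <- function(count, volume_cm3) {
  if (any(count < 0)) stop("count must be non-negative", call. = FALSE)
  if (any(volume_cm3 <= 0)) stop("volume must be positive", call. = FALSE)
  count / volume_cm3
}
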