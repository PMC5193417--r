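# Inspection-derived colony metrics: hexagon-grid brood area, Varroa
# infestation rates, feed accounting, and dose-unit conversion.

#' Capped-brood area from hexagon-grid counts
#'
#' In the hexagon-grid field method a transparent sheet of regular hexagons
#' (23.4 cm2 each) is laid on the comb and occupied hexagons counted,
#' rounding up when a cell is more than half filled. The rounding happens
#' at counting time in the field; this function takes the resulting integer
#' count and converts to area.
#'
#' @param count Integer hexagon count, >= 0.
#' @param cell_area_cm2 Area of one grid hexagon (default 23.4).
#' @return Brood area in cm2 (`count * cell_area_cm2`).
#' @export
brood_area_from_hexagons <- function(count, cell_area_cm2 = 23.4) {
  if (any(!is.finite(count) | count < 0 | count != round(count)))
    stopf("hexagon count must be a non-negative integer")
  count * cell_area_cm2
}

#' Varroa infestation rate from board or wash counts
#'
#' Two field methods are supported: sticky-board mite fall (mites per
#' exposure day, boards typically left 3 days) and alcohol wash (mites per
#' bee from a sample of adult bees; the protocol calls for at least 230
#' bees, smaller samples are accepted with a below-minimum note).
#'
#' @param mites Mite count, >= 0.
#' @param method `"board"` or `"wash"`.
#' @param exposure_days Board exposure in days (board method; > 0).
#' @param bee_count Number of bees washed (wash method; > 0).
#' @param hive_id,date Optional identifiers carried through.
#' @param min_bees Protocol minimum wash sample (default 230).
#' @return A one-row data.frame of class `hb_varroa`: `hive_id, date,
#'   method, mites, denominator, rate, below_min_sample` (rate is mites/day
#'   for boards, mites/bee for washes).
#' @export
varroa_rate <- function(mites, method = c("board", "wash"),
                        exposure_days = NULL, bee_count = NULL,
                        hive_id = NA_character_, date = NA,
                        min_bees = 230) {
  method <- match.arg(method)
  if (!is.finite(mites) || mites < 0) stopf("mite count must be >= 0")
  if (method == "board") {
    if (is.null(exposure_days) || !is.finite(exposure_days) || exposure_days <= 0)
      stopf("board method needs exposure_days > 0")
    den <- exposure_days
  } else {
    if (is.null(bee_count) || !is.finite(bee_count) || bee_count <= 0)
      stopf("wash method needs bee_count > 0")
    den <- bee_count
  }
  below <- method == "wash" && den < min_bees
  if (below) warnf("wash sample of %g bees is below the %g-bee protocol minimum",
                   den, min_bees)
  out <- data.frame(hive_id = hive_id, date = date, method = method,
                    mites = mites, denominator = den, rate = mites / den,
                    below_min_sample = below, stringsAsFactors = FALSE)
  class(out) <- c("hb_varroa", "data.frame")
  out
}

#' Cumulative syrup fed to a hive
#'
#' Sum of the syrup masses offered to one hive over its scheduled feeding
#' events (e.g. 1 kg three times per week for 4 weeks gives the 12 kg
#' cumulative total of the standard feeding design).
#'
#' @param schedule An [`hb_schedule`][feeding_schedule].
#' @param hive_id Hive to total.
#' @return Total kg offered.
#' @export
cumulative_feed <- function(schedule, hive_id) {
  stopifnot(inherits(schedule, "hb_schedule") || is.data.frame(schedule))
  if (nrow(schedule) == 0L) return(0)
  if (!hive_id %in% schedule$hive_id)
    stopf("hive %s not present in the feeding schedule", hive_id)
  sum(schedule$mass_kg[schedule$hive_id == hive_id])
}

#' Per-group summary of unconsumed syrup
#'
#' Totals the recorded unconsumed syrup per hive and summarises by
#' treatment group (mean, SD, n); hives with no unconsumed record are
#' excluded and counted in `n_missing`.
#'
#' @param schedule An [`hb_schedule`][feeding_schedule] with
#'   `unconsumed_kg` recorded.
#' @param design An [treatment_design()] mapping hives to groups.
#' @return Data.frame `group, mean_unconsumed_kg, sd_unconsumed_kg, n,
#'   n_missing`.
#' @export
unconsumed_summary <- function(schedule, design) {
  stopifnot(is.data.frame(schedule), is.data.frame(design))
  per_hive <- lapply(split(schedule, schedule$hive_id), function(s) {
    data.frame(hive_id = s$hive_id[1],
               unconsumed = if (all(is.na(s$unconsumed_kg))) NA_real_
                            else sum(s$unconsumed_kg, na.rm = TRUE))
  })
  ph <- do.call(rbind, per_hive)
  ph <- merge(design[, c("hive_id", "group")], ph, by = "hive_id", all.x = TRUE)
  out <- do.call(rbind, lapply(split(ph, ph$group), function(g) {
    ok <- !is.na(g$unconsumed)
    data.frame(group = g$group[1],
               mean_unconsumed_kg = if (any(ok)) mean(g$unconsumed[ok]) else NA_real_,
               sd_unconsumed_kg = if (sum(ok) > 1) sd(g$unconsumed[ok]) else NA_real_,
               n = sum(ok), n_missing = sum(!ok), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Convert a micromolar concentration to ppm (mg/L)
#'
#' `ppm = uM * molar_mass / 1000`; e.g. a 300 uM nicotine solution
#' (162.23 g/mol) is about 48.7 ppm.
#'
#' @param conc_uM Concentration in micromoles per litre, >= 0.
#' @param molar_mass_g_per_mol Molar mass of the solute, > 0.
#' @return Concentration in ppm (mg/L).
#' @export
ppm_from_micromolar <- function(conc_uM, molar_mass_g_per_mol) {
  stopifnot(all(conc_uM >= 0), molar_mass_g_per_mol > 0)
  conc_uM * molar_mass_g_per_mol / 1000
}
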