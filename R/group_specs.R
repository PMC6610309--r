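# Experimental-arm specifications: the stated world the simulator reproduces.

REGIONS <- c("SUB", "EC", "PC", "TC")
PHASES  <- c("baseline", "intervention", "washout")

#' Construct an experimental-arm specification
#'
#' A `group_spec` captures everything the synthetic generator needs to emulate
#' one arm of a three-phase (baseline / drug intervention / wash-out) slice
#' pharmacology experiment in the 4-AP model: seizure-like event (SLE) rates
#' per phase, event duration and DC-shift amplitude distributions, regional
#' intrinsic-optical-signal (IOS) amplitudes and involvement areas, and the
#' probability that an SLE starts in each anatomical region.
#'
#' @param group_label short arm label, e.g. `"LAC_33"`.
#' @param drug drug name (`"none"`, `"LAC"`, `"ZNS"`, `"LEV"`).
#' @param conc_um bath concentration in micromolar (0 for control).
#' @param n_slices default cohort size for this arm.
#' @param phase_durations_min length-3 numeric, phase durations in minutes;
#'   each must lie in \[40, 60\] (the protocol's stated range).
#' @param baseline_rate_per_min mean SLE rate during baseline, events/min.
#' @param rate_sd_per_min between-slice SD of the baseline rate.
#' @param rate_ratio_intervention,rate_ratio_washout dimensionless scalings of
#'   each slice's own baseline rate during intervention and wash-out
#'   (0 = full SLE block).
#' @param ratio_sd between-slice SD of the intervention/wash-out rate ratios.
#' @param duration_mean_s,duration_sd_s length-3 per-phase event-duration
#'   mean and per-event SD, seconds.
#' @param dc_mean_mV,dc_sd_mV length-3 per-phase DC-shift amplitude mean and
#'   per-event SD, millivolts (magnitude of the negative deflection).
#' @param ios_peak_dtt_pct 4 x 3 matrix (region x phase) of target peak ROI
#'   dT/T in percent; `NA` where no SLE exists to image (full block).
#' @param area_fraction_pct 4 x 3 matrix (region x phase) of involved area as
#'   percent of each region's mask.
#' @param onset_region_weights named probabilities over `c("SUB","EC","PC","TC")`
#'   for the SLE onset region; must sum to 1.
#' @param persistent_effect logical; `TRUE` when the drug effect does not
#'   revert during wash-out (zonisamide-like).
#' @return object of class `group_spec`.
#' @export
group_spec <- function(group_label,
                       drug = "none",
                       conc_um = 0,
                       n_slices = 10L,
                       phase_durations_min = c(60, 60, 60),
                       baseline_rate_per_min = 0.17,
                       rate_sd_per_min = 0.03,
                       rate_ratio_intervention = 1,
                       rate_ratio_washout = 1,
                       ratio_sd = 0.15,
                       duration_mean_s = c(53.3, 53.3, 53.3),
                       duration_sd_s = c(10, 10, 10),
                       dc_mean_mV = c(1.64, 1.64, 1.64),
                       dc_sd_mV = c(0.25, 0.25, 0.25),
                       ios_peak_dtt_pct = default_ios_dtt(),
                       area_fraction_pct = default_ios_area(),
                       onset_region_weights = c(SUB = 0.05, EC = 0.5,
                                                PC = 0.15, TC = 0.3),
                       persistent_effect = FALSE) {
  spec <- structure(
    list(group_label = group_label, drug = drug, conc_um = conc_um,
         n_slices = as.integer(n_slices),
         phase_durations_min = stats::setNames(phase_durations_min, PHASES),
         baseline_rate_per_min = baseline_rate_per_min,
         rate_sd_per_min = rate_sd_per_min,
         rate_ratio_intervention = rate_ratio_intervention,
         rate_ratio_washout = rate_ratio_washout,
         ratio_sd = ratio_sd,
         duration_mean_s = stats::setNames(duration_mean_s, PHASES),
         duration_sd_s = stats::setNames(duration_sd_s, PHASES),
         dc_mean_mV = stats::setNames(dc_mean_mV, PHASES),
         dc_sd_mV = stats::setNames(dc_sd_mV, PHASES),
         ios_peak_dtt_pct = ios_peak_dtt_pct,
         area_fraction_pct = area_fraction_pct,
         onset_region_weights = onset_region_weights[REGIONS],
         persistent_effect = isTRUE(persistent_effect)),
    class = "group_spec")
  validate_group_spec(spec)
  spec
}

#' @rdname group_spec
#' @param spec object to validate.
#' @export
validate_group_spec <- function(spec) {
  stopifnot(inherits(spec, "group_spec"))
  err <- character(0)
  pd <- spec$phase_durations_min
  if (length(pd) != 3L || any(!is.finite(pd)))
    err <- c(err, "phase_durations_min: three finite values required")
  else if (any(pd < 40 | pd > 60))
    err <- c(err, "phase_durations_min: each phase must lie in [40, 60] min")
  rates <- spec$baseline_rate_per_min *
    c(1, spec$rate_ratio_intervention, spec$rate_ratio_washout)
  if (any(rates < 0)) err <- c(err, "event rates must be >= 0")
  w <- spec$onset_region_weights
  if (length(w) != 4L || any(is.na(w)) || abs(sum(w) - 1) > 1e-6)
    err <- c(err, "onset_region_weights: 4 values summing to 1 required")
  af <- spec$area_fraction_pct
  if (!is.matrix(af) || !identical(dim(af), c(4L, 3L)))
    err <- c(err, "area_fraction_pct must be a 4 x 3 region-by-phase matrix")
  else if (any(af < 0 | af > 100, na.rm = TRUE))
    err <- c(err, "area_fraction_pct must lie in [0, 100]")
  if (!is.matrix(spec$ios_peak_dtt_pct) ||
      !identical(dim(spec$ios_peak_dtt_pct), c(4L, 3L)))
    err <- c(err, "ios_peak_dtt_pct must be a 4 x 3 region-by-phase matrix")
  if (length(err) > 0L)
    stop("invalid group_spec: ", paste(err, collapse = "; "), call. = FALSE)
  invisible(spec)
}

region_phase_matrix <- function(values) {
  matrix(values, nrow = 4L, ncol = 3L,
         dimnames = list(REGIONS, PHASES))
}

# Generic regional IOS amplitudes (% dT/T) for arms where the study reports no
# change: within the typical 0.4-4% ictal range, constant across phases.
default_ios_dtt <- function() {
  region_phase_matrix(rep(c(SUB = 1.2, EC = 1.5, PC = 1.3, TC = 1.2), 3L))
}

# Generic involvement areas (% of region) for arms with no reported change.
default_ios_area <- function() {
  region_phase_matrix(rep(c(SUB = 60, EC = 80, PC = 70, TC = 55), 3L))
}

#' Default specifications for all ten experimental arms
#'
#' Returns the control arm plus the nine drug/dose arms (lacosamide 10/33/100,
#' zonisamide 33/100/300, levetiracetam 33/100/300 micromolar), parameterised
#' with the study's group-level results:
#'
#' * control: baseline SLE frequency 0.17 (SD 0.03) per min; second-hour /
#'   baseline frequency ratio 0.90; duration 53.3 / 56.9 / 52.5 s and DC shift
#'   1.64 / 1.52 / 1.43 mV over the three hours.
#' * frequency ratios (intervention/baseline): LAC 33 uM 0.54, LAC 100 uM 0
#'   (full block), ZNS 100 uM 0.56, ZNS 300 uM 0 (full block), LEV 300 uM
#'   0.66, LEV 33 uM 0.81 (= reported 0.13/0.16, not significant).
#' * subiculum IOS: LAC 10 uM dT/T 1.43 -> 1.13 %, area 70.9 -> 61.7 %;
#'   LAC 33 uM dT/T 1.10 -> 0.38 %, area 58.9 -> 37.8 %; ZNS 100 uM dT/T
#'   1.17 -> 0.78 %, area 51.3 -> 40.2 %. Temporal cortex, LEV 300 uM:
#'   area 54.8 -> 37.6 %.
#' * zonisamide arms carry `persistent_effect = TRUE` (frequency does not
#'   recover fully during wash-out); full-block arms have `NA` intervention
#'   IOS parameters (no SLE to image).
#'
#' Arms for which no ratio was reported (LAC 10, ZNS 33, LEV 100) use
#' dose-ordered interpolations; these arms are generator plumbing, not
#' recovery targets.
#'
#' @return named list of [group_spec] objects, length 10.
#' @export
default_group_specs <- function() {
  ios_sub <- function(base_dtt, int_dtt, base_area, int_area,
                      washout_like_baseline = TRUE) {
    dtt <- default_ios_dtt(); area <- default_ios_area()
    dtt["SUB", ] <- c(base_dtt, int_dtt,
                      if (washout_like_baseline) base_dtt else int_dtt)
    area["SUB", ] <- c(base_area, int_area,
                       if (washout_like_baseline) base_area else int_area)
    list(dtt = dtt, area = area)
  }
  block_ios <- function() {
    dtt <- default_ios_dtt(); area <- default_ios_area()
    dtt[, "intervention"] <- NA_real_
    area[, "intervention"] <- NA_real_
    list(dtt = dtt, area = area)
  }

  specs <- list()

  specs$control <- group_spec(
    "control", drug = "none", conc_um = 0, n_slices = 22L,
    baseline_rate_per_min = 0.17, rate_sd_per_min = 0.03,
    rate_ratio_intervention = 0.90, rate_ratio_washout = 0.88,
    ratio_sd = 0.12,
    duration_mean_s = c(53.3, 56.9, 52.5),
    dc_mean_mV = c(1.64, 1.52, 1.43))

  lac10 <- ios_sub(1.43, 1.13, 70.9, 61.7)
  specs$LAC_10 <- group_spec(
    "LAC_10", drug = "LAC", conc_um = 10, n_slices = 13L,
    rate_ratio_intervention = 0.70, rate_ratio_washout = 0.92,
    ios_peak_dtt_pct = lac10$dtt, area_fraction_pct = lac10$area)

  lac33 <- ios_sub(1.10, 0.38, 58.9, 37.8)
  specs$LAC_33 <- group_spec(
    "LAC_33", drug = "LAC", conc_um = 33, n_slices = 10L,
    rate_ratio_intervention = 0.54, rate_ratio_washout = 0.92,
    dc_mean_mV = c(1.64, 1.50, 1.45),
    ios_peak_dtt_pct = lac33$dtt, area_fraction_pct = lac33$area)

  blk <- block_ios()
  specs$LAC_100 <- group_spec(
    "LAC_100", drug = "LAC", conc_um = 100, n_slices = 5L,
    rate_ratio_intervention = 0, rate_ratio_washout = 0.90,
    ios_peak_dtt_pct = blk$dtt, area_fraction_pct = blk$area)

  specs$ZNS_33 <- group_spec(
    "ZNS_33", drug = "ZNS", conc_um = 33, n_slices = 10L,
    rate_ratio_intervention = 0.60, rate_ratio_washout = 0.75,
    duration_mean_s = c(60.1, 68.1, 60.6),
    dc_mean_mV = c(1.64, 1.52, 1.48),
    persistent_effect = TRUE)

  zns100 <- ios_sub(1.17, 0.78, 51.3, 40.2)
  specs$ZNS_100 <- group_spec(
    "ZNS_100", drug = "ZNS", conc_um = 100, n_slices = 13L,
    rate_ratio_intervention = 0.56, rate_ratio_washout = 0.75,
    ios_peak_dtt_pct = zns100$dtt, area_fraction_pct = zns100$area,
    persistent_effect = TRUE)

  specs$ZNS_300 <- group_spec(
    "ZNS_300", drug = "ZNS", conc_um = 300, n_slices = 5L,
    rate_ratio_intervention = 0, rate_ratio_washout = 0.50,
    ios_peak_dtt_pct = blk$dtt, area_fraction_pct = blk$area,
    persistent_effect = TRUE)

  specs$LEV_33 <- group_spec(
    "LEV_33", drug = "LEV", conc_um = 33, n_slices = 9L,
    baseline_rate_per_min = 0.16, rate_sd_per_min = 0.02,
    rate_ratio_intervention = 0.81, rate_ratio_washout = 0.92)

  specs$LEV_100 <- group_spec(
    "LEV_100", drug = "LEV", conc_um = 100, n_slices = 11L,
    rate_ratio_intervention = 0.75, rate_ratio_washout = 0.92)

  lev300 <- {
    dtt <- default_ios_dtt(); area <- default_ios_area()
    area["TC", ] <- c(54.8, 37.6, 54.8)  # LEV reduces TC area, not intensity
    list(dtt = dtt, area = area)
  }
  specs$LEV_300 <- group_spec(
    "LEV_300", drug = "LEV", conc_um = 300, n_slices = 11L,
    rate_ratio_intervention = 0.66, rate_ratio_washout = 0.85,
    duration_mean_s = c(58.2, 46.2, 37.7),
    dc_mean_mV = c(1.64, 1.50, 1.45),
    ios_peak_dtt_pct = lev300$dtt, area_fraction_pct = lev300$area)

  specs
}

#' @export
print.group_spec <- function(x, ...) {
  cat(sprintf("<group_spec> %s (%s %g uM), n=%d\n", x$group_label, x$drug,
              x$conc_um, x$n_slices))
  cat(sprintf("  baseline rate %.3g /min; ratios int=%.3g wash=%.3g%s\n",
              x$baseline_rate_per_min, x$rate_ratio_intervention,
              x$rate_ratio_washout,
              if (x$persistent_effect) " (persistent)" else ""))
  invisible(x)
}
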