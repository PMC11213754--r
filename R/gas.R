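#' Describe a closed assay bottle
#'
#' Geometry and initial headspace state of one serum bottle. Headspace
#' volume is `total_volume_ml - liquid_volume_ml`.
#'
#' @param total_volume_ml Bottle volume in mL (study convention: 120).
#' @param liquid_volume_ml Medium volume in mL (45 anaerobic, 50 aerobic).
#' @param temperature_c Incubation temperature in degrees C (55
#'   thermophilic, 37 mesophilic). Headspace mole accounting uses this
#'   temperature; the STP basis for reported volumes is 0 degC, 1 atm.
#' @param initial_pressure_pa Initial headspace pressure in Pa.
#' @param initial_composition Named mole fractions over
#'   `c("n2","co2","o2","ch4")`; missing gases default to 0; must sum
#'   to 1 within 1e-9.
#' @return Object of class `bottle_spec`.
#' @examples
#' bottle_anaerobic() # 120 mL, 45 mL medium, N2/CO2 80:20 at 1.7e5 Pa
#' @export
bottle_spec <- function(total_volume_ml, liquid_volume_ml, temperature_c,
                        initial_pressure_pa,
                        initial_composition = c(n2 = 0.8, co2 = 0.2)) {
  stopifnot(is.numeric(total_volume_ml), is.numeric(liquid_volume_ml))
  if (!(liquid_volume_ml > 0 && liquid_volume_ml < total_volume_ml)) {
    stop("need 0 < liquid_volume_ml < total_volume_ml", call. = FALSE)
  }
  if (!(temperature_c > 0)) stop("temperature must be > 0 degC", call. = FALSE)
  if (!(initial_pressure_pa > 0)) stop("initial pressure must be > 0", call. = FALSE)
  comp <- stats::setNames(numeric(4), c("n2", "co2", "o2", "ch4"))
  if (is.list(initial_composition)) initial_composition <- unlist(initial_composition)
  bad <- setdiff(names(initial_composition), names(comp))
  if (length(bad)) stop("unknown gas in composition: ", bad[[1]], call. = FALSE)
  comp[names(initial_composition)] <- initial_composition
  if (any(comp < 0 | comp > 1)) stop("mole fractions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(comp) - 1) > 1e-9) {
    stop("initial composition must sum to 1 (got ", sum(comp), ")", call. = FALSE)
  }
  structure(
    list(total_volume_ml = total_volume_ml,
         liquid_volume_ml = liquid_volume_ml,
         headspace_volume_ml = total_volume_ml - liquid_volume_ml,
         temperature_c = temperature_c,
         initial_pressure_pa = initial_pressure_pa,
         initial_composition = comp),
    class = "bottle_spec"
  )
}

#' @rdname bottle_spec
#' @export
bottle_anaerobic <- function(temperature_c = 55) {
  bottle_spec(120, 45, temperature_c, 1.7e5, c(n2 = 0.8, co2 = 0.2))
}

#' @rdname bottle_spec
#' @export
bottle_aerobic <- function(temperature_c = 55) {
  # sealed at atmospheric pressure with air; argon lumped into n2
  bottle_spec(120, 50, temperature_c, ATM_PRESSURE_PA,
              c(n2 = 1 - AIR_O2_FRACTION, o2 = AIR_O2_FRACTION))
}

#' Moles of a tracked gas in the headspace
#'
#' Ideal-gas accounting: `n = fraction * pressure * V_headspace / (R T)`
#' with the incubation temperature of the bottle.
#'
#' @param spec A [bottle_spec()].
#' @param fraction Mole fraction(s) of the tracked gas, in \[0, 1\].
#' @param pressure Headspace pressure(s) in Pa; defaults to the bottle's
#'   initial pressure (constant-pressure assumption).
#' @return Moles of the tracked gas (vectorized).
#' @export
headspace_moles <- function(spec, fraction, pressure = spec$initial_pressure_pa) {
  stopifnot(inherits(spec, "bottle_spec"))
  if (any(fraction < 0 | fraction > 1, na.rm = TRUE)) {
    stop("mole fractions must lie in [0, 1]", call. = FALSE)
  }
  if (any(pressure <= 0, na.rm = TRUE)) stop("pressure must be > 0", call. = FALSE)
  t_k <- spec$temperature_c + 273.15
  fraction * pressure * (spec$headspace_volume_ml * 1e-6) / (GAS_CONSTANT * t_k)
}

#' Construct a cumulative gas curve
#'
#' One bottle's cumulative gas produced (CH4) or consumed (O2) in
#' litres at STP, starting at 0 at time 0. Monotonicity is not enforced
#' on data-derived curves: decreases beyond 2% of the running maximum
#' add a `"nonmonotonic"` flag, negative values a `"negative"` flag.
#'
#' @param time_days Strictly increasing observation times (days since
#'   inoculation); a leading `(0, 0)` point is prepended if absent.
#' @param cumulative_l Cumulative litres at STP.
#' @param mode `"methane_production"` or `"oxygen_consumption"`.
#' @param flags Character vector of data-quality flags to carry along.
#' @return A data.frame of class `gas_curve` with columns `time_days`,
#'   `cumulative_l` and attributes `mode` and `flags`.
#' @export
gas_curve <- function(time_days, cumulative_l,
                      mode = c("methane_production", "oxygen_consumption"),
                      flags = character()) {
  mode <- match.arg(mode)
  stopifnot(length(time_days) == length(cumulative_l), length(time_days) >= 1)
  if (any(diff(time_days) <= 0)) {
    stop("times within one curve must be strictly increasing", call. = FALSE)
  }
  if (time_days[1] > 0) {
    time_days <- c(0, time_days)
    cumulative_l <- c(0, cumulative_l)
  }
  run_max <- cummax(pmax(cumulative_l, 0))
  drop <- run_max - cumulative_l
  # 2e-3 L (2 mL STP) absolute floor: drops within instrument
  # resolution are not data-quality events
  if (any(drop > 0.02 * pmax(run_max, .Machine$double.eps) & drop > 2e-3)) {
    flags <- union(flags, "nonmonotonic")
    warning("cumulative curve decreases by more than 2% of its running maximum",
            call. = FALSE)
  }
  if (any(cumulative_l < -1e-9)) flags <- union(flags, "negative")
  structure(
    data.frame(time_days = time_days, cumulative_l = cumulative_l),
    mode = mode, flags = flags,
    class = c("gas_curve", "data.frame")
  )
}

curve_mode <- function(curve) attr(curve, "mode")
curve_flags <- function(curve) attr(curve, "flags")

#' @export
print.gas_curve <- function(x, ...) {
  cat("<gas_curve>", attr(x, "mode"), "-", nrow(x), "points over",
      max(x$time_days), "days; final", signif(x$cumulative_l[nrow(x)], 4),
      "L (STP)\n")
  if (length(attr(x, "flags"))) {
    cat("  flags:", paste(attr(x, "flags"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.gas_curve <- function(x, ...) {
  graphics::plot(x$time_days, x$cumulative_l, type = "b",
                 xlab = "time (days)", ylab = "cumulative gas (L, STP)", ...)
  invisible(x)
}

resolve_pressure <- function(readings, spec, constant_pressure) {
  p <- if ("pressure_pa" %in% names(readings)) readings$pressure_pa
       else rep(NA_real_, nrow(readings))
  if (anyNA(p) && !constant_pressure) {
    stop("readings lack pressures and the constant-pressure assumption ",
         "is disabled", call. = FALSE)
  }
  ifelse(is.na(p), spec$initial_pressure_pa, p)
}

check_readings <- function(readings) {
  req <- c("time_days", "mole_fraction")
  if (!all(req %in% names(readings))) {
    stop("readings need columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (nrow(readings) < 1) stop("no readings supplied", call. = FALSE)
  if (any(diff(readings$time_days) <= 0)) {
    stop("reading times must be strictly increasing", call. = FALSE)
  }
  if (any(readings$mole_fraction < 0 | readings$mole_fraction > 1)) {
    stop("mole fractions must lie in [0, 1]", call. = FALSE)
  }
  invisible(readings)
}

#' Cumulative methane production from headspace readings
#'
#' Converts periodic headspace CH4 mole-fraction measurements into a
#' cumulative production curve in litres at STP. The first reading
#' (expected at or near day 0) anchors the initial CH4 inventory;
#' production at each later time is the headspace mole increase times
#' 22.4 L/mol. Without a per-reading `pressure_pa` column the bottle's
#' initial pressure is assumed throughout (constant-pressure mode).
#'
#' @param spec A [bottle_spec()].
#' @param readings data.frame with columns `time_days`, `mole_fraction`
#'   (CH4) and optionally `pressure_pa`.
#' @param constant_pressure Allow falling back to the bottle's initial
#'   pressure for readings without a pressure (default TRUE).
#' @return A [gas_curve()] in `methane_production` mode.
#' @export
cumulative_methane <- function(spec, readings, constant_pressure = TRUE) {
  stopifnot(inherits(spec, "bottle_spec"))
  check_readings(readings)
  p <- resolve_pressure(readings, spec, constant_pressure)
  n <- headspace_moles(spec, readings$mole_fraction, p)
  gas_curve(readings$time_days, (n - n[1]) * MOLAR_VOLUME_STP,
            mode = "methane_production")
}

#' Cumulative oxygen consumption with air re-flushing
#'
#' Piecewise accounting for closed-bottle respirometry: within each
#' inter-flush segment the O2 consumed equals the segment-start O2
#' moles minus the moles at each reading; the total curve is the
#' running sum across segments. A flush event closes the current
#' segment at the last reading before it (consumption between that
#' reading and the flush is unobservable and counted as zero) and the
#' next segment starts from the post-flush composition and pressure —
#' replenished O2 is never counted as consumed.
#'
#' @param spec A [bottle_spec()].
#' @param readings data.frame with columns `time_days`, `mole_fraction`
#'   (O2) and optionally `pressure_pa`.
#' @param flushes Optional data.frame with columns `time_days`,
#'   `post_flush_fraction`, `post_flush_pressure_pa`.
#' @param constant_pressure As in [cumulative_methane()].
#' @return A [gas_curve()] in `oxygen_consumption` mode (litres O2 at
#'   STP); see [curve_grams_o2()] for the mass scale.
#' @export
cumulative_o2_consumed <- function(spec, readings, flushes = NULL,
                                   constant_pressure = TRUE) {
  stopifnot(inherits(spec, "bottle_spec"))
  check_readings(readings)
  p <- resolve_pressure(readings, spec, constant_pressure)
  n <- headspace_moles(spec, readings$mole_fraction, p)
  if (is.null(flushes) || nrow(flushes) == 0) {
    flushes <- data.frame(time_days = numeric(), post_flush_fraction = numeric(),
                          post_flush_pressure_pa = numeric())
  }
  req <- c("time_days", "post_flush_fraction", "post_flush_pressure_pa")
  if (!all(req %in% names(flushes))) {
    stop("flushes need columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  flushes <- flushes[order(flushes$time_days), , drop = FALSE]
  if (nrow(flushes) && flushes$time_days[1] < readings$time_days[1]) {
    stop("flush event precedes the first reading: segment state undefined",
         call. = FALSE)
  }
  consumed <- numeric(nrow(readings))
  seg_start_n <- n[1]
  carried <- 0 # consumption completed in closed segments
  fi <- 1
  for (i in seq_len(nrow(readings))[-1]) {
    # flushes strictly between the previous and current reading (or at
    # the previous reading time) reset the segment state
    while (fi <= nrow(flushes) && flushes$time_days[fi] < readings$time_days[i]) {
      if (flushes$time_days[fi] < readings$time_days[i - 1]) {
        stop("reading at day ", readings$time_days[i - 1],
             " is later than an unapplied flush at day ",
             flushes$time_days[fi], ": events out of order", call. = FALSE)
      }
      carried <- carried + (seg_start_n - n[i - 1])
      seg_start_n <- headspace_moles(spec, flushes$post_flush_fraction[fi],
                                     flushes$post_flush_pressure_pa[fi])
      fi <- fi + 1
    }
    consumed[i] <- carried + (seg_start_n - n[i])
  }
  gas_curve(readings$time_days, consumed * MOLAR_VOLUME_STP,
            mode = "oxygen_consumption")
}

#' Oxygen mass scale of a consumption curve
#'
#' @param curve A [gas_curve()] in `oxygen_consumption` mode.
#' @return Cumulative grams of O2 (molar mass 31.9988 g/mol).
#' @export
curve_grams_o2 <- function(curve) {
  stopifnot(inherits(curve, "gas_curve"))
  if (curve_mode(curve) != "oxygen_consumption") {
    stop("mass scale applies to oxygen-consumption curves", call. = FALSE)
  }
  curve$cumulative_l / MOLAR_VOLUME_STP * O2_MOLAR_MASS
}

#' Blank-correct a gas curve
#'
#' Subtracts the time-wise mean of the blank curves, linearly
#' interpolated onto the sample's time grid. Negative corrected values
#' are kept (and flagged), never clipped.
#'
#' @param sample A [gas_curve()].
#' @param blanks List of [gas_curve()]s from blank bottles (>= 1).
#' @param end_hold If `TRUE`, blank curves are held at their endpoint
#'   values outside their observed range; otherwise a blank range not
#'   covering the sample range is an error.
#' @return A [gas_curve()] on the sample's grid.
#' @export
blank_correct <- function(sample, blanks, end_hold = FALSE) {
  stopifnot(inherits(sample, "gas_curve"))
  if (inherits(blanks, "gas_curve")) blanks <- list(blanks)
  if (length(blanks) < 1) stop("at least one blank curve required", call. = FALSE)
  rule <- if (end_hold) 2L else 1L
  mat <- vapply(blanks, function(b) {
    stats::approx(b$time_days, b$cumulative_l, xout = sample$time_days,
                  rule = rule)$y
  }, numeric(nrow(sample)))
  mat <- matrix(mat, nrow = nrow(sample))
  if (anyNA(mat)) {
    stop("blank curves do not cover the sample time range; ",
         "set end_hold = TRUE to hold endpoint values", call. = FALSE)
  }
  corrected <- sample$cumulative_l - rowMeans(mat)
  withCallingHandlers(
    gas_curve(sample$time_days, corrected, mode = curve_mode(sample),
              flags = union(curve_flags(sample), "blank_corrected")),
    warning = function(w) {
      # decreases are expected after subtracting an active blank
      if (grepl("running maximum", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

#' Aggregate replicate curves into mean and standard deviation
#'
#' Curves are linearly resampled onto a common grid (by default the
#' first curve's times restricted to the range shared by all
#' replicates); the per-time mean and sample standard deviation
#' (n - 1 denominator) are returned.
#'
#' @param curves List of [gas_curve()]s of one mode.
#' @param grid Optional time grid; default as described.
#' @return data.frame of class `aggregated_gas_curve` with columns
#'   `time_days`, `mean_l`, `sd_l`; attributes `mode` and `n`.
#' @export
aggregate_replicates <- function(curves, grid = NULL) {
  if (inherits(curves, "gas_curve")) curves <- list(curves)
  stopifnot(length(curves) >= 1)
  modes <- unique(vapply(curves, curve_mode, character(1)))
  if (length(modes) != 1) stop("curves mix production and consumption modes",
                               call. = FALSE)
  if (length(curves) == 1) {
    warning("single curve: standard deviation undefined", call. = FALSE)
  }
  if (is.null(grid)) {
    lo <- max(vapply(curves, function(c) min(c$time_days), numeric(1)))
    hi <- min(vapply(curves, function(c) max(c$time_days), numeric(1)))
    grid <- curves[[1]]$time_days
    grid <- grid[grid >= lo & grid <= hi]
  }
  mat <- vapply(curves, function(c) {
    stats::approx(c$time_days, c$cumulative_l, xout = grid)$y
  }, numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  out <- data.frame(
    time_days = grid,
    mean_l = rowMeans(mat),
    sd_l = if (ncol(mat) >= 2) apply(mat, 1, stats::sd) else NA_real_
  )
  structure(out, mode = modes, n = length(curves),
            class = c("aggregated_gas_curve", "data.frame"))
}

#' Read per-bottle gas readings from CSV
#'
#' Expected columns: `bottle_id`, `time_days`, `gas` (`CH4` or `O2`),
#' `mole_fraction`, optional `pressure_pa`.
#'
#' @param path CSV file path.
#' @return data.frame sorted by bottle and time.
#' @export
read_gas_readings <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("bottle_id", "time_days", "gas", "mole_fraction")
  if (!all(req %in% names(d))) {
    stop("gas readings CSV needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  d[order(d$bottle_id, d$time_days), , drop = FALSE]
}

#' Read flush events from CSV
#'
#' Expected columns: `bottle_id`, `time_days`, `post_flush_fraction`,
#' `post_flush_pressure_pa`.
#'
#' @param path CSV file path.
#' @return data.frame sorted by bottle and time.
#' @export
read_flush_events <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("bottle_id", "time_days", "post_flush_fraction",
           "post_flush_pressure_pa")
  if (!all(req %in% names(d))) {
    stop("flush events CSV needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  d[order(d$bottle_id, d$time_days), , drop = FALSE]
}
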