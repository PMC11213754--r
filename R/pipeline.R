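#' Bundle one assay group (sample + blank triplicates)
#'
#' The unit of biodegradation computation: one polymer under one
#' condition, its bottle specification, the sample replicate curves and
#' the blank replicate curves. Triplicates are the expected design;
#' other replicate counts are allowed with a warning.
#'
#' @param label Group label, e.g. `"PCL-anaerobic-LL"`.
#' @param condition `"anaerobic"` or `"aerobic"`.
#' @param formula Polymer repeat-unit formula ([elemental_formula()] or
#'   string).
#' @param plastic_mass_g Plastic load per bottle in grams (study
#'   convention: 0.0625 g).
#' @param bottle A [bottle_spec()].
#' @param sample_curves,blank_curves Lists of [gas_curve()]s whose mode
#'   matches the condition (methane for anaerobic, oxygen for aerobic).
#' @return Object of class `assay_group`.
#' @export
assay_group <- function(label, condition = c("anaerobic", "aerobic"),
                        formula, plastic_mass_g, bottle,
                        sample_curves, blank_curves) {
  condition <- match.arg(condition)
  formula <- as_formula(formula)
  stopifnot(inherits(bottle, "bottle_spec"))
  if (!(plastic_mass_g > 0)) stop("plastic mass must be > 0", call. = FALSE)
  if (inherits(sample_curves, "gas_curve")) sample_curves <- list(sample_curves)
  if (inherits(blank_curves, "gas_curve")) blank_curves <- list(blank_curves)
  want <- if (condition == "anaerobic") "methane_production" else "oxygen_consumption"
  for (curve in c(sample_curves, blank_curves)) {
    stopifnot(inherits(curve, "gas_curve"))
    if (curve_mode(curve) != want) {
      stop("curve mode '", curve_mode(curve), "' does not match condition '",
           condition, "'", call. = FALSE)
    }
  }
  if (length(sample_curves) != 3 || length(blank_curves) != 3) {
    warning("group '", label, "': expected triplicates, got ",
            length(sample_curves), " sample and ", length(blank_curves),
            " blank curves", call. = FALSE)
  }
  structure(
    list(label = label, condition = condition, formula = formula,
         plastic_mass_g = plastic_mass_g, bottle = bottle,
         sample_curves = sample_curves, blank_curves = blank_curves),
    class = "assay_group"
  )
}

new_biodeg_result <- function(group, percents, per_g, basis, flags) {
  horizon <- max(vapply(group$sample_curves,
                        function(c) max(c$time_days), numeric(1)))
  if (any(percents > 100)) flags <- union(flags, "above_100_percent")
  structure(
    list(label = group$label, condition = group$condition, basis = basis,
         percent_mean = mean(percents),
         percent_sd = if (length(percents) >= 2) stats::sd(percents) else NA_real_,
         percent_replicates = percents,
         measured_per_g = per_g,
         n_replicates = length(percents),
         horizon_days = horizon,
         flags = flags),
    class = "biodegradation_result"
  )
}

#' @export
print.biodegradation_result <- function(x, ...) {
  cat(sprintf("<biodegradation_result> %s [%s]\n", x$label, x$condition))
  cat(sprintf("  %.1f +/- %.1f %% (basis %s, n = %d, %g days)\n",
              x$percent_mean, x$percent_sd, x$basis, x$n_replicates,
              x$horizon_days))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

final_value <- function(curve) curve$cumulative_l[nrow(curve)]

corrected_sample_curves <- function(group, correct_blank, end_hold = TRUE) {
  if (!correct_blank) return(group$sample_curves)
  lapply(group$sample_curves, blank_correct, blanks = group$blank_curves,
         end_hold = end_hold)
}

#' Percent biodegradation under anaerobic (methane) conditions
#'
#' Per replicate, the experimental methane potential is the
#' blank-corrected final cumulative CH4 (L STP) divided by the plastic
#' mass; percent biodegradation is `100 * BMP_exp / BMP_theoric`, and
#' the group result is the replicate mean and standard deviation.
#' Values above 100% are reported unmodified and flagged.
#'
#' @param group An [assay_group()] with `condition = "anaerobic"`.
#' @param potentials Optional [theoretical_potentials()]; computed from
#'   the group's formula when omitted.
#' @param correct_blank Subtract the mean blank curve before taking the
#'   endpoint (default TRUE; the theoretical ratio itself carries no
#'   blank term, but residual-substrate methane in the inoculum is
#'   shared by blanks and samples).
#' @return A `biodegradation_result` with basis `"BMP"`.
#' @export
biodegradation_anaerobic <- function(group, potentials = NULL,
                                     correct_blank = TRUE) {
  stopifnot(inherits(group, "assay_group"))
  if (group$condition != "anaerobic") {
    stop("group condition is not anaerobic", call. = FALSE)
  }
  if (is.null(potentials)) potentials <- theoretical_potentials(group$formula)
  if (!(potentials$bmp_theoric > 0)) {
    stop("theoretical methane potential must be > 0", call. = FALSE)
  }
  curves <- corrected_sample_curves(group, correct_blank)
  bmp_exp <- vapply(curves, final_value, numeric(1)) / group$plastic_mass_g
  flags <- unique(unlist(lapply(curves, curve_flags)))
  new_biodeg_result(group, 100 * bmp_exp / potentials$bmp_theoric,
                    bmp_exp, basis = "BMP", flags = flags)
}

#' Percent biodegradation under aerobic (oxygen) conditions
#'
#' Per replicate, the net O2 consumed (sample minus mean blank, in
#' grams via the 31.9988 g/mol molar mass) per gram of plastic is
#' divided by the theoretical oxygen demand:
#' `100 * (O2_sample - O2_blank) / (ThOD * mass)`.
#'
#' @param group An [assay_group()] with `condition = "aerobic"`.
#' @inheritParams biodegradation_anaerobic
#' @return A `biodegradation_result` with basis `"ThOD"`.
#' @export
biodegradation_aerobic <- function(group, potentials = NULL,
                                   correct_blank = TRUE) {
  stopifnot(inherits(group, "assay_group"))
  if (group$condition != "aerobic") {
    stop("group condition is not aerobic", call. = FALSE)
  }
  if (is.null(potentials)) potentials <- theoretical_potentials(group$formula)
  if (is.na(potentials$thod) || !(potentials$thod > 0)) {
    stop("theoretical oxygen demand must be > 0", call. = FALSE)
  }
  curves <- corrected_sample_curves(group, correct_blank)
  o2_g <- vapply(curves, function(curve) {
    final_value(curve) / MOLAR_VOLUME_STP * O2_MOLAR_MASS
  }, numeric(1)) / group$plastic_mass_g
  flags <- unique(unlist(lapply(curves, curve_flags)))
  new_biodeg_result(group, 100 * o2_g / potentials$thod,
                    o2_g, basis = "ThOD", flags = flags)
}

#' Validate an inoculum against the cellulose-control criterion
#'
#' Anaerobic positive controls with microcrystalline cellulose must
#' convert 82--95% of the theoretical methane potential (band endpoints
#' inclusive). Aerobic controls have no established band and are
#' reported descriptively (`pass = NA`).
#'
#' @param cellulose_group An [assay_group()] for the cellulose control
#'   (monomer formula C6H10O5).
#' @param potentials Optional [theoretical_potentials()].
#' @param band Acceptance band in percent (default `c(82, 95)`).
#' @return List of class `inoculum_validation`: `result`
#'   (biodegradation_result), `pass` (TRUE/FALSE, or NA for aerobic),
#'   `band`, `note`.
#' @export
validate_inoculum <- function(cellulose_group, potentials = NULL,
                              band = c(82, 95)) {
  stopifnot(inherits(cellulose_group, "assay_group"))
  res <- if (cellulose_group$condition == "anaerobic") {
    biodegradation_anaerobic(cellulose_group, potentials)
  } else {
    biodegradation_aerobic(cellulose_group, potentials)
  }
  if (cellulose_group$condition == "anaerobic") {
    pass <- res$percent_mean >= band[1] && res$percent_mean <= band[2]
    note <- sprintf("anaerobic cellulose control: %.1f%% vs band [%g, %g]",
                    res$percent_mean, band[1], band[2])
  } else {
    pass <- NA
    note <- sprintf(
      "aerobic cellulose control: %.1f%% (descriptive only, no published band)",
      res$percent_mean)
  }
  structure(list(result = res, pass = pass, band = band, note = note),
            class = "inoculum_validation")
}

#' @export
print.inoculum_validation <- function(x, ...) {
  status <- if (isTRUE(x$pass)) "PASS" else if (isFALSE(x$pass)) "FAIL"
            else "descriptive"
  cat("<inoculum_validation>", status, "-", x$note, "\n")
  invisible(x)
}

read_config <- function(config) {
  if (is.character(config)) {
    dir <- dirname(normalizePath(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    # resolve CSV paths relative to the config file
    for (key in c("gas_readings_csv", "flush_events_csv")) {
      if (!is.null(config[[key]]) && !file.exists(config[[key]])) {
        config[[key]] <- file.path(dir, config[[key]])
      }
    }
  }
  config
}

config_bottle <- function(b) {
  bottle_spec(b$total_volume_ml, b$liquid_volume_ml, b$temperature_c,
              b$initial_pressure_pa, unlist(b$initial_composition))
}

build_group <- function(gdef, config, readings, flushes) {
  spec <- config_bottle(config$bottles[[gdef$bottle]])
  formula <- config$polymers[[gdef$polymer]]
  if (is.null(formula)) {
    stop("polymer '", gdef$polymer, "' not found in config", call. = FALSE)
  }
  make_curve <- function(id) {
    r <- readings[readings$bottle_id == id, , drop = FALSE]
    if (nrow(r) == 0) stop("no readings for bottle '", id, "'", call. = FALSE)
    if (gdef$condition == "anaerobic") {
      cumulative_methane(spec, r)
    } else {
      fl <- flushes[flushes$bottle_id == id, , drop = FALSE]
      cumulative_o2_consumed(spec, r, fl)
    }
  }
  assay_group(
    label = gdef$label, condition = gdef$condition, formula = formula,
    plastic_mass_g = gdef$plastic_mass_g, bottle = spec,
    sample_curves = lapply(unlist(gdef$sample_bottles), make_curve),
    blank_curves = lapply(unlist(gdef$blank_bottles), make_curve)
  )
}

#' Run the full biodegradation analysis pipeline
#'
#' Executes stoichiometry, curve construction, blank correction and
#' percent-biodegradation computation for every group in a run
#' configuration, then (optionally) writes `results.json`,
#' `results.csv` and `warnings.log`. A failing group is recorded with
#' its stage and error message; remaining groups still run.
#'
#' The configuration (JSON file or equivalent list) contains:
#' `polymers` (name -> formula), `bottles` (name -> bottle fields),
#' `gas_readings_csv`, optional `flush_events_csv`, and `groups`, each
#' with `label`, `condition`, `polymer`, `bottle`, `plastic_mass_g`,
#' `sample_bottles`, `blank_bottles` and optional `is_control`.
#'
#' @param config Path to a JSON run configuration, or the equivalent
#'   list.
#' @param out_dir Optional output directory for report files.
#' @return List of class `biodeg_report` with elements `results`
#'   (per-group result or validation objects), `table` (summary
#'   data.frame), `warnings`, `errors`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- read_config(config)
  groups <- config$groups
  if (is.data.frame(groups)) {
    groups <- lapply(seq_len(nrow(groups)), function(i) {
      g <- as.list(groups[i, , drop = FALSE])
      g$sample_bottles <- unlist(g$sample_bottles)
      g$blank_bottles <- unlist(g$blank_bottles)
      g
    })
  }
  warnings_log <- character()
  errors <- character()
  results <- list()
  if (length(groups) == 0) {
    warning("empty group list: nothing to analyse", call. = FALSE)
    warnings_log <- "empty group list: nothing to analyse"
  } else {
    readings <- read_gas_readings(config$gas_readings_csv)
    flushes <- if (!is.null(config$flush_events_csv) &&
                   file.exists(config$flush_events_csv)) {
      read_flush_events(config$flush_events_csv)
    } else {
      data.frame(bottle_id = character(), time_days = numeric(),
                 post_flush_fraction = numeric(),
                 post_flush_pressure_pa = numeric())
    }
    for (gdef in groups) {
      stage <- "curve construction"
      res <- withCallingHandlers(
        tryCatch({
          group <- build_group(gdef, config, readings, flushes)
          stage <- "biodegradation"
          if (isTRUE(gdef$is_control)) {
            validate_inoculum(group)
          } else if (gdef$condition == "anaerobic") {
            biodegradation_anaerobic(group)
          } else {
            biodegradation_aerobic(group)
          }
        }, error = function(e) {
          msg <- paste0("group '", gdef$label, "' failed at stage ", stage,
                        ": ", conditionMessage(e))
          errors <<- c(errors, msg)
          NULL
        }),
        warning = function(w) {
          warnings_log <<- c(warnings_log,
                             paste0("group '", gdef$label, "': ",
                                    conditionMessage(w)))
          invokeRestart("muffleWarning")
        }
      )
      if (!is.null(res)) results[[gdef$label]] <- res
    }
  }
  report <- structure(
    list(results = results, table = report_table(results),
         warnings = warnings_log, errors = errors),
    class = "biodeg_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

report_table <- function(results) {
  rows <- lapply(names(results), function(label) {
    r <- results[[label]]
    v <- if (inherits(r, "inoculum_validation")) r$result else r
    data.frame(
      label = label, condition = v$condition, basis = v$basis,
      percent_mean = v$percent_mean, percent_sd = v$percent_sd,
      n_replicates = v$n_replicates, horizon_days = v$horizon_days,
      validation = if (inherits(r, "inoculum_validation")) {
        if (isTRUE(r$pass)) "pass" else if (isFALSE(r$pass)) "fail"
        else "descriptive"
      } else NA_character_,
      flags = paste(v$flags, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  if (length(rows) == 0) {
    return(data.frame(label = character(), condition = character(),
                      basis = character(), percent_mean = numeric(),
                      percent_sd = numeric(), n_replicates = integer(),
                      horizon_days = numeric(), validation = character(),
                      flags = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Write a pipeline report to disk
#'
#' @param report A `biodeg_report` from [run_pipeline()].
#' @param out_dir Directory (created if absent) receiving
#'   `results.json`, `results.csv` and `warnings.log`.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  serializable <- lapply(report$results, function(r) {
    v <- if (inherits(r, "inoculum_validation")) r$result else r
    out <- v[c("label", "condition", "basis", "percent_mean", "percent_sd",
               "percent_replicates", "n_replicates", "horizon_days", "flags")]
    if (inherits(r, "inoculum_validation")) {
      out$validation <- list(pass = r$pass, band = r$band, note = r$note)
    }
    out
  })
  jsonlite::write_json(
    list(results = serializable, warnings = report$warnings,
         errors = report$errors),
    file.path(out_dir, "results.json"),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null", pretty = TRUE
  )
  utils::write.csv(report$table, file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  writeLines(c(report$warnings, report$errors),
             file.path(out_dir, "warnings.log"))
  invisible(out_dir)
}

#' @export
print.biodeg_report <- function(x, ...) {
  cat("<biodeg_report>", length(x$results), "group(s),",
      length(x$warnings), "warning(s),", length(x$errors), "error(s)\n")
  if (nrow(x$table)) print(x$table)
  invisible(x)
}
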