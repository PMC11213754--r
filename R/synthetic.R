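#' Ground-truth model for a synthetic gas curve
#'
#' Parameters of the generator's sigmoidal (modified Gompertz) gas
#' curve. The functional form expresses the features seen in real
#' closed-bottle assays — a lag of roughly 10 days, a sigmoidal rise
#' and a plateau at the mineralized fraction of the theoretical
#' potential — with interpretable parameters; the analysis pipeline
#' never fits this model, so the choice cannot bias results.
#'
#' @param target_fraction True biodegradation fraction f in \[0, 1.1\]
#'   (values slightly above 1 emulate replicates overshooting 100%).
#' @param lag_days Lag phase before gas production attributable to the
#'   polymer (default 10 d).
#' @param rate_l_per_day_g Maximum specific gas rate in L (STP) per day
#'   per g of plastic; `NULL` (default) picks `asymptote_per_g / 15`,
#'   which reaches > 99.9% of the plateau by a 60-day horizon with the
#'   default lag.
#' @param noise_sd Relative (multiplicative) measurement noise on mole
#'   fractions, emulating GC scatter (default 0.02).
#' @param blank_asymptote_l Residual-substrate gas produced (CH4) or
#'   consumed (O2-equivalent) by the inoculum alone, L STP per bottle
#'   (default 0.005); shared between sample and blank bottles so blank
#'   correction removes it exactly in the noise-free limit.
#' @param blank_tau_days Exponential time constant of the residual
#'   substrate component (default 5 d: blanks are active immediately).
#' @param seed Random seed recorded with all outputs.
#' @return Object of class `curve_model`.
#' @export
curve_model <- function(target_fraction, lag_days = 10,
                        rate_l_per_day_g = NULL, noise_sd = 0.02,
                        blank_asymptote_l = 0.005, blank_tau_days = 5,
                        seed = NULL) {
  if (target_fraction < 0 || target_fraction > 1.1) {
    stop("target_fraction must lie in [0, 1.1]", call. = FALSE)
  }
  stopifnot(lag_days >= 0, noise_sd >= 0, blank_asymptote_l >= 0,
            blank_tau_days > 0)
  if (!is.null(rate_l_per_day_g) && rate_l_per_day_g <= 0) {
    stop("rate must be > 0", call. = FALSE)
  }
  structure(
    list(target_fraction = target_fraction, lag_days = lag_days,
         rate_l_per_day_g = rate_l_per_day_g, noise_sd = noise_sd,
         blank_asymptote_l = blank_asymptote_l,
         blank_tau_days = blank_tau_days, seed = seed),
    class = "curve_model"
  )
}

# Modified Gompertz cumulative curve through (0, ~0) with asymptote A,
# maximum rate mu (units of A per day) and lag lambda (days).
gompertz_cumulative <- function(t, asymptote, mu, lag) {
  if (asymptote <= 0) return(rep(0, length(t)))
  asymptote * exp(-exp(mu * exp(1) / asymptote * (lag - t) + 1))
}

apply_noise <- function(fraction, noise_sd) {
  if (noise_sd == 0) return(fraction)
  pmin(1, pmax(0, fraction * (1 + stats::rnorm(length(fraction), 0, noise_sd))))
}

default_schedule <- function(horizon_days = 60, interval_days = 3.5) {
  seq(0, horizon_days, by = interval_days)
}

synth_readings_anaerobic <- function(model, spec, asymptote_l, mu_l_day,
                                     times) {
  blank_l <- model$blank_asymptote_l *
    (1 - exp(-times / model$blank_tau_days))
  total_l <- blank_l +
    gompertz_cumulative(times, asymptote_l, mu_l_day, model$lag_days)
  n_ch4 <- spec$initial_composition[["ch4"]] *
    headspace_moles(spec, 1) + total_l / MOLAR_VOLUME_STP
  t_k <- spec$temperature_c + 273.15
  fraction <- n_ch4 * GAS_CONSTANT * t_k /
    (spec$initial_pressure_pa * spec$headspace_volume_ml * 1e-6)
  if (any(fraction > 1)) {
    stop("simulated CH4 exceeds the headspace capacity; reduce the load",
         call. = FALSE)
  }
  data.frame(time_days = times,
             mole_fraction = apply_noise(fraction, model$noise_sd))
}

# Sequential aerobic simulation. Demand follows the sigmoid; actual
# consumption is capped by the O2 present (unmet demand is carried
# over — degradation pauses when the bottle runs out of oxygen and
# resumes after the next flush, as in a real O2-limited incubation).
# Flushing is triggered at a reading when the headspace O2 fraction
# falls below `o2_floor`; fresh air is injected with a syringe, so the
# post-flush headspace is pressurized above atmospheric.
synth_readings_aerobic <- function(model, spec, asymptote_l, mu_l_day,
                                   times, o2_floor, post_flush_fraction,
                                   post_flush_pressure_pa) {
  blank_l <- model$blank_asymptote_l *
    (1 - exp(-times / model$blank_tau_days))
  demand_l <- blank_l +
    gompertz_cumulative(times, asymptote_l, mu_l_day, model$lag_days)
  t_k <- spec$temperature_c + 273.15
  n_o2 <- headspace_moles(spec, spec$initial_composition[["o2"]])
  pressure <- spec$initial_pressure_pa
  backlog <- 0
  frac_true <- numeric(length(times))
  flush_rows <- list()
  for (i in seq_along(times)) {
    if (i > 1) {
      want <- (demand_l[i] - demand_l[i - 1]) / MOLAR_VOLUME_STP + backlog
      got <- min(want, n_o2)
      backlog <- want - got
      n_o2 <- n_o2 - got
    }
    frac_true[i] <- n_o2 * GAS_CONSTANT * t_k /
      (pressure * spec$headspace_volume_ml * 1e-6)
    if (frac_true[i] < o2_floor && i < length(times)) {
      flush_rows[[length(flush_rows) + 1]] <- data.frame(
        time_days = times[i], post_flush_fraction = post_flush_fraction,
        post_flush_pressure_pa = post_flush_pressure_pa)
      n_o2 <- headspace_moles(spec, post_flush_fraction,
                              post_flush_pressure_pa)
      pressure <- post_flush_pressure_pa
    }
  }
  pressures <- rep(spec$initial_pressure_pa, length(times))
  if (length(flush_rows)) {
    ft <- vapply(flush_rows, function(r) r$time_days, numeric(1))
    for (i in seq_along(times)) {
      prior <- ft[ft < times[i]]
      if (length(prior)) pressures[i] <- post_flush_pressure_pa
    }
  }
  list(
    readings = data.frame(time_days = times,
                          mole_fraction = apply_noise(frac_true,
                                                      model$noise_sd),
                          pressure_pa = pressures),
    flushes = if (length(flush_rows)) do.call(rbind, flush_rows)
              else data.frame(time_days = numeric(),
                              post_flush_fraction = numeric(),
                              post_flush_pressure_pa = numeric())
  )
}

resolve_rate <- function(model, asymptote_per_g) {
  if (!is.null(model$rate_l_per_day_g)) return(model)
  model$rate_l_per_day_g <- max(asymptote_per_g, 1e-6) / 15
  model
}

#' Generate a synthetic assay group with known ground truth
#'
#' Simulates sample and blank bottle readings for one polymer under one
#' condition, then runs them through the package's own curve
#' construction so the returned group is exactly what the pipeline
#' would build from measured data. Sample curves are the shared
#' residual-substrate (blank) component plus a modified-Gompertz
#' production/consumption term whose asymptote is
#' `target_fraction * potential * plastic_mass`; blanks carry the
#' residual component only. Aerobic simulations emit a flush schedule
#' triggered when headspace O2 drops below `o2_floor`.
#'
#' @param model A [curve_model()].
#' @param formula Polymer repeat-unit formula (string or
#'   [elemental_formula()]).
#' @param condition `"anaerobic"` or `"aerobic"`.
#' @param label Group label (default built from condition).
#' @param bottle A [bottle_spec()]; defaults to the study design
#'   ([bottle_anaerobic()] / [bottle_aerobic()] at 55 degC).
#' @param plastic_mass_g Plastic load (default 0.0625 g).
#' @param n_sample,n_blank Replicate counts (default 3).
#' @param times Sampling schedule in days (default twice weekly over
#'   60 days).
#' @param o2_floor Headspace O2 fraction triggering a flush (default
#'   0.05).
#' @param post_flush_fraction,post_flush_pressure_pa Post-flush
#'   headspace state (defaults: ambient air fraction 0.2095,
#'   1.7e5 Pa — air injected by syringe pressurizes the bottle).
#' @return List of class `synthetic_assay`: `group` (an
#'   [assay_group()]), `readings` and `flushes` (per-bottle
#'   data.frames in the CSV dialect the pipeline reads) and `truth`
#'   (target fraction, lag, rate, noise, seed, asymptote).
#' @export
synth_assay_group <- function(model, formula,
                              condition = c("anaerobic", "aerobic"),
                              label = NULL, bottle = NULL,
                              plastic_mass_g = 0.0625,
                              n_sample = 3, n_blank = 3,
                              times = default_schedule(),
                              o2_floor = 0.05,
                              post_flush_fraction = AIR_O2_FRACTION,
                              post_flush_pressure_pa = 1.7e5) {
  stopifnot(inherits(model, "curve_model"))
  condition <- match.arg(condition)
  formula <- as_formula(formula)
  if (is.null(bottle)) {
    bottle <- if (condition == "anaerobic") bottle_anaerobic()
              else bottle_aerobic()
  }
  if (is.null(label)) label <- paste0("synthetic-", condition)
  pot <- theoretical_potentials(formula)
  asymptote_l <- if (condition == "anaerobic") {
    model$target_fraction * pot$bmp_theoric * plastic_mass_g
  } else {
    model$target_fraction * pot$thod * plastic_mass_g /
      O2_MOLAR_MASS * MOLAR_VOLUME_STP
  }
  model <- resolve_rate(model, asymptote_l / plastic_mass_g)
  rise_days <- if (asymptote_l > 0) {
    asymptote_l / (model$rate_l_per_day_g * plastic_mass_g)
  } else 0
  if (max(times) < model$lag_days + rise_days) {
    warning("sampling schedule ends before lag + rise time: ",
            "ground truth may be unrecoverable", call. = FALSE)
  }
  mu_l_day <- model$rate_l_per_day_g * plastic_mass_g
  # measurement noise routinely produces small apparent decreases; the
  # data-quality warning stays as a flag on the curves but is not
  # re-raised for data we know to be synthetic
  muffle_monotonicity <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("running maximum", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  }
  with_local_seed(model$seed, {
    one_bottle <- function(id, is_blank) {
      a <- if (is_blank) 0 else asymptote_l
      if (condition == "anaerobic") {
        r <- synth_readings_anaerobic(model, bottle, a, mu_l_day, times)
        r$pressure_pa <- NA_real_
        list(readings = data.frame(bottle_id = id, time_days = r$time_days,
                                   gas = "CH4",
                                   mole_fraction = r$mole_fraction,
                                   pressure_pa = r$pressure_pa),
             flushes = NULL,
             curve = muffle_monotonicity(cumulative_methane(bottle, r)))
      } else {
        sim <- synth_readings_aerobic(model, bottle, a, mu_l_day, times,
                                      o2_floor, post_flush_fraction,
                                      post_flush_pressure_pa)
        list(readings = data.frame(bottle_id = id,
                                   time_days = sim$readings$time_days,
                                   gas = "O2",
                                   mole_fraction = sim$readings$mole_fraction,
                                   pressure_pa = sim$readings$pressure_pa),
             flushes = if (nrow(sim$flushes))
               cbind(bottle_id = id, sim$flushes) else NULL,
             curve = muffle_monotonicity(
               cumulative_o2_consumed(bottle, sim$readings, sim$flushes)))
      }
    }
    ids_s <- paste0(label, "-S", seq_len(n_sample))
    ids_b <- paste0(label, "-B", seq_len(n_blank))
    sims <- c(lapply(ids_s, one_bottle, is_blank = FALSE),
              lapply(ids_b, one_bottle, is_blank = TRUE))
    group <- assay_group(
      label = label, condition = condition, formula = formula,
      plastic_mass_g = plastic_mass_g, bottle = bottle,
      sample_curves = lapply(sims[seq_len(n_sample)], `[[`, "curve"),
      blank_curves = lapply(sims[n_sample + seq_len(n_blank)], `[[`, "curve")
    )
    structure(
      list(
        group = group,
        readings = do.call(rbind, lapply(sims, `[[`, "readings")),
        flushes = {
          fl <- do.call(rbind, Filter(Negate(is.null),
                                      lapply(sims, `[[`, "flushes")))
          if (is.null(fl)) data.frame(bottle_id = character(),
                                      time_days = numeric(),
                                      post_flush_fraction = numeric(),
                                      post_flush_pressure_pa = numeric())
          else fl
        },
        truth = list(target_fraction = model$target_fraction,
                     lag_days = model$lag_days,
                     rate_l_per_day_g = model$rate_l_per_day_g,
                     noise_sd = model$noise_sd,
                     blank_asymptote_l = model$blank_asymptote_l,
                     asymptote_l = asymptote_l,
                     seed = model$seed)
      ),
      class = "synthetic_assay"
    )
  })
}

#' Write a complete synthetic study to disk
#'
#' Emulates the full study design — PE, PET and PCL plus a cellulose
#' control, under anaerobic and aerobic conditions, in triplicate with
#' triplicate blanks — and writes `gas_readings.csv`,
#' `flush_events.csv`, a pipeline run configuration `study.json` and a
#' ground-truth manifest `truth.json`. PE and PET default to a true
#' fraction of 0 (recalcitrant); PCL to 0.87 (anaerobic) and 0.99
#' (aerobic); cellulose to 0.88 and 0.71.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed controlling all randomness.
#' @param f_anaerobic,f_aerobic Named true fractions per polymer.
#' @param noise_sd Relative measurement noise (default 0.02).
#' @param times Sampling schedule (default twice weekly over 60 days).
#' @return Path to the written `study.json`, invisibly.
#' @export
synth_study <- function(dir, seed = 1,
                        f_anaerobic = c(PE = 0, PET = 0, PCL = 0.87,
                                        cellulose = 0.88),
                        f_aerobic = c(PE = 0, PET = 0, PCL = 0.99,
                                      cellulose = 0.71),
                        noise_sd = 0.02, times = default_schedule()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  polymers <- read_polymer_registry()
  readings <- list(); flushes <- list(); groups <- list(); truth <- list()
  sub_seed <- seed
  for (condition in c("anaerobic", "aerobic")) {
    fs <- if (condition == "anaerobic") f_anaerobic else f_aerobic
    for (name in names(fs)) {
      sub_seed <- (sub_seed + 9973) %% .Machine$integer.max
      label <- paste(name, condition, sep = "-")
      model <- curve_model(fs[[name]], noise_sd = noise_sd, seed = sub_seed)
      syn <- synth_assay_group(model, polymers[[name]], condition,
                               label = label, times = times)
      readings[[label]] <- syn$readings
      if (nrow(syn$flushes)) flushes[[label]] <- syn$flushes
      groups[[label]] <- list(
        label = label, condition = condition, polymer = name,
        bottle = condition, plastic_mass_g = syn$group$plastic_mass_g,
        sample_bottles = paste0(label, "-S", 1:3),
        blank_bottles = paste0(label, "-B", 1:3),
        is_control = identical(name, "cellulose")
      )
      truth[[label]] <- syn$truth
    }
  }
  utils::write.csv(do.call(rbind, readings),
                   file.path(dir, "gas_readings.csv"), row.names = FALSE)
  fl <- if (length(flushes)) do.call(rbind, flushes) else
    data.frame(bottle_id = character(), time_days = numeric(),
               post_flush_fraction = numeric(),
               post_flush_pressure_pa = numeric())
  utils::write.csv(fl, file.path(dir, "flush_events.csv"), row.names = FALSE)
  ana <- bottle_anaerobic(); aer <- bottle_aerobic()
  config <- list(
    polymers = as.list(polymers),
    bottles = list(
      anaerobic = list(total_volume_ml = ana$total_volume_ml,
                       liquid_volume_ml = ana$liquid_volume_ml,
                       temperature_c = ana$temperature_c,
                       initial_pressure_pa = ana$initial_pressure_pa,
                       initial_composition = as.list(ana$initial_composition)),
      aerobic = list(total_volume_ml = aer$total_volume_ml,
                     liquid_volume_ml = aer$liquid_volume_ml,
                     temperature_c = aer$temperature_c,
                     initial_pressure_pa = aer$initial_pressure_pa,
                     initial_composition = as.list(aer$initial_composition))
    ),
    gas_readings_csv = "gas_readings.csv",
    flush_events_csv = "flush_events.csv",
    groups = unname(groups)
  )
  cfg_path <- file.path(dir, "study.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  jsonlite::write_json(list(seed = seed, groups = truth),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cfg_path)
}

#' Generate a synthetic taxon count table
#'
#' Draws per-sample compositions from a Dirichlet distribution centred
#' on the target percentages (concentration = `overdispersion`), then
#' multinomial read counts at the requested depth.
#'
#' @param targets Named numeric vector of target percentages summing to
#'   100; names are semicolon-delimited lineages (kingdom to genus).
#' @param depth Reads per sample (default 1e5).
#' @param overdispersion Dirichlet concentration parameter; larger
#'   means compositions closer to the targets (default 500).
#' @param n_samples Number of samples (default 1).
#' @param seed Random seed.
#' @return A `taxon_table` with attribute `truth` recording the
#'   targets, depth, overdispersion and seed.
#' @export
generate_taxon_table <- function(targets, depth = 1e5,
                                 overdispersion = 500, n_samples = 1,
                                 seed = NULL) {
  stopifnot(is.numeric(targets), !is.null(names(targets)), depth >= 1)
  if (abs(sum(targets) - 100) > 1e-6) {
    stop("target percentages must sum to 100", call. = FALSE)
  }
  if (any(targets < 0)) stop("negative target percentage", call. = FALSE)
  with_local_seed(seed, {
    k <- length(targets)
    counts <- vapply(seq_len(n_samples), function(s) {
      alpha <- targets / 100 * overdispersion
      g <- stats::rgamma(k, shape = pmax(alpha, 1e-12))
      p <- if (sum(g) > 0) g / sum(g) else rep(1 / k, k)
      as.numeric(stats::rmultinom(1, size = depth, prob = p))
    }, numeric(k))
    counts <- matrix(counts, nrow = k,
                     dimnames = list(NULL,
                                     paste0("sample", seq_len(n_samples))))
    out <- taxon_table(names(targets), counts)
    attr(out, "truth") <- list(targets = targets, depth = depth,
                               overdispersion = overdispersion, seed = seed)
    out
  })
}

#' Preset community composition for a thermophilic anaerobic digest
#'
#' A dominant-genus structure typical of a landfill-leachate
#' methanogenic community degrading a polyester: a dominant
#' hydrogenotrophic methanogen genus, several proteolytic/fermentative
#' bacterial genera, a large kingdom-only bacterial fraction and a
#' tail of minor genera. Archaea total 23%, Bacteria 77%.
#'
#' @return Named percentage vector for [generate_taxon_table()].
#' @export
preset_anaerobic_community <- function() {
  c(
    "Archaea;Euryarchaeota;Methanobacteria;Methanobacteriales;Methanobacteriaceae;Methanothermobacter" = 20.9,
    "Archaea;Euryarchaeota;Methanobacteria;Methanobacteriales;Methanobacteriaceae;Methanobacterium" = 2.1,
    "Bacteria;Firmicutes;Clostridia;Clostridiales;Clostridiaceae;Caloramator" = 11.0,
    "Bacteria;Coprothermobacterota;Coprothermobacteria;Coprothermobacterales;Coprothermobacteraceae;Coprothermobacter" = 6.8,
    "Bacteria;Thermotogae;Thermotogae;Petrotogales;Petrotogaceae;Defluviitoga" = 6.1,
    "Bacteria;Synergistetes;Synergistia;Synergistales;Synergistaceae;Acetomicrobium" = 2.3,
    "Bacteria;Actinobacteria;Actinomycetia;Micrococcales;Microbacteriaceae;Leucobacter" = 1.5,
    "Bacteria;Firmicutes;Bacilli;Lactobacillales;Lactobacillaceae;Lactobacillus" = 1.3,
    "Bacteria;Proteobacteria;Gammaproteobacteria;Pseudomonadales;Pseudomonadaceae;Pseudomonas" = 0.6,
    "Bacteria" = 31.0,
    "Bacteria;Firmicutes;Clostridia;Clostridiales;MinorA" = 4.1,
    "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;MinorB" = 4.1,
    "Bacteria;Proteobacteria;Deltaproteobacteria;Syntrophobacterales;MinorC" = 4.1,
    "Bacteria;Chloroflexi;Anaerolineae;Anaerolineales;MinorD" = 4.1
  )
}
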