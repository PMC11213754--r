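# Builds a group whose blank-corrected replicate endpoints are known
# exactly: blanks are flat zero, samples rise to the requested final
# litres.
exact_group <- function(finals_l, condition = "anaerobic",
                        formula = "C6H10O2", mass = 0.0625) {
  mode <- if (condition == "anaerobic") "methane_production"
          else "oxygen_consumption"
  bottle <- if (condition == "anaerobic") bottle_anaerobic()
            else bottle_aerobic()
  blanks <- replicate(3, gas_curve(c(0, 30, 60), c(0, 0, 0), mode),
                      simplify = FALSE)
  samples <- lapply(finals_l, flat_rise_curve, mode = mode,
                    times = c(0, 30, 60))
  assay_group("test", condition, formula, mass, bottle, samples, blanks)
}

test_that("anaerobic percent is the BMP ratio, averaged over replicates", {
  pot <- theoretical_potentials("C6H10O2")
  mass <- 0.0625
  # replicate at exactly the theoretical potential -> 100%
  g <- exact_group(rep(pot$bmp_theoric * mass, 3))
  r <- biodegradation_anaerobic(g)
  expect_equal(r$percent_mean, 100, tolerance = 1e-9)
  expect_equal(r$percent_sd, 0, tolerance = 1e-9)
  expect_identical(r$basis, "BMP")
  expect_equal(r$horizon_days, 60)

  # BMPexp 0.37 L/g against 0.74 L/g -> 50%
  g <- exact_group(rep(0.37 * mass, 3))
  r <- biodegradation_anaerobic(g)
  expect_equal(r$percent_mean, 100 * 0.37 / pot$bmp_theoric,
               tolerance = 1e-12)
  expect_equal(round(r$percent_mean), 50)

  expect_error(biodegradation_aerobic(g), "not aerobic")
})

test_that("aerobic percent is net O2 mass over ThOD", {
  pot <- theoretical_potentials("C6H10O2")
  mass <- 0.0625
  # net 0.1319 g O2 over ThOD 2.11 g/g on 62.5 mg is ~100%
  net_g <- 0.1319
  finals_l <- rep(net_g / 31.9988 * 22.4, 3)
  g <- exact_group(finals_l, condition = "aerobic")
  r <- biodegradation_aerobic(g)
  expect_equal(r$percent_mean, 100 * net_g / (pot$thod * mass),
               tolerance = 1e-9)
  expect_equal(r$percent_mean, 100, tolerance = 0.02) # hand arithmetic
  expect_identical(r$basis, "ThOD")
})

test_that("blank dominance: samples equal to blanks give zero percent", {
  mode <- "methane_production"
  active <- replicate(3, gas_curve(c(0, 30, 60), c(0, 0.01, 0.02), mode),
                      simplify = FALSE)
  g <- assay_group("blankish", "anaerobic", "C6H10O2", 0.0625,
                   bottle_anaerobic(), active, active)
  r <- biodegradation_anaerobic(g)
  expect_equal(r$percent_mean, 0, tolerance = 1e-12)
})

test_that("scale invariance: scaling mass and gas together is a no-op", {
  for (k in c(0.5, 2, 10)) {
    g1 <- exact_group(c(0.02, 0.025, 0.03))
    gk <- exact_group(k * c(0.02, 0.025, 0.03), mass = k * 0.0625)
    r1 <- biodegradation_anaerobic(g1)
    rk <- biodegradation_anaerobic(gk)
    expect_equal(rk$percent_mean, r1$percent_mean, tolerance = 1e-12)
    expect_equal(rk$percent_sd, r1$percent_sd, tolerance = 1e-9)
  }
})

test_that("percentages above 100 are flagged but never truncated", {
  pot <- theoretical_potentials("C6H10O2")
  g <- exact_group(rep(1.06 * pot$bmp_theoric * 0.0625, 3))
  r <- biodegradation_anaerobic(g)
  expect_equal(r$percent_mean, 106, tolerance = 1e-9)
  expect_true("above_100_percent" %in% r$flags)
})

test_that("group construction validates condition/mode and replicates", {
  mode_o2 <- gas_curve(c(0, 10), c(0, 0.01), "oxygen_consumption")
  blanks <- replicate(3, gas_curve(c(0, 10), c(0, 0), "methane_production"),
                      simplify = FALSE)
  expect_error(
    assay_group("bad", "anaerobic", "C6H10O2", 0.0625, bottle_anaerobic(),
                list(mode_o2), blanks),
    "does not match condition")
  expect_warning(
    assay_group("duo", "anaerobic", "C6H10O2", 0.0625, bottle_anaerobic(),
                blanks[1:2], blanks),
    "triplicates")
  expect_error(
    assay_group("nomass", "anaerobic", "C6H10O2", 0, bottle_anaerobic(),
                blanks, blanks),
    "mass")
})

test_that("inoculum validation applies the 82-95% band inclusively", {
  pot <- theoretical_potentials("C6H10O5") # cellulose monomer
  mass <- 0.0625
  make <- function(pct, condition = "anaerobic") {
    finals <- rep(pct / 100 * mass *
                    (if (condition == "anaerobic") pot$bmp_theoric
                     else pot$thod / 31.9988 * 22.4), 3)
    exact_group(finals, condition = condition, formula = "C6H10O5",
                mass = mass)
  }
  expect_true(validate_inoculum(make(88))$pass)
  expect_false(validate_inoculum(make(50))$pass)
  expect_true(validate_inoculum(make(82))$pass)  # inclusive bounds
  expect_true(validate_inoculum(make(95))$pass)
  expect_false(validate_inoculum(make(95.6))$pass)
  aero <- validate_inoculum(make(71, "aerobic"))
  expect_true(is.na(aero$pass)) # descriptive only
  expect_match(aero$note, "descriptive")
})

test_that("run_pipeline processes a config end to end and writes reports", {
  tmp <- withr::local_tempdir()
  study <- file.path(tmp, "study")
  cfg <- suppressWarnings(synth_study(study, seed = 11,
                     f_anaerobic = c(PCL = 0.87),
                     f_aerobic = c(PCL = 0.99)))
  out <- file.path(tmp, "out")
  report <- suppressWarnings(run_pipeline(cfg, out_dir = out))
  expect_s3_class(report, "biodeg_report")
  expect_setequal(names(report$results),
                  c("PCL-anaerobic", "PCL-aerobic"))
  expect_identical(report$results[["PCL-anaerobic"]]$basis, "BMP")
  expect_identical(report$results[["PCL-aerobic"]]$basis, "ThOD")
  expect_true(file.exists(file.path(out, "results.json")))
  expect_true(file.exists(file.path(out, "results.csv")))
  expect_true(file.exists(file.path(out, "warnings.log")))
  tab <- read.csv(file.path(out, "results.csv"))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$percent_mean[tab$label == "PCL-anaerobic"],
               report$results[["PCL-anaerobic"]]$percent_mean)
})

test_that("run_pipeline records failures per group and continues", {
  tmp <- withr::local_tempdir()
  study <- file.path(tmp, "study")
  cfg_path <- suppressWarnings(
    synth_study(study, seed = 12, f_anaerobic = c(PCL = 0.5),
                f_aerobic = c(PCL = 0.5)))
  cfg <- jsonlite::read_json(cfg_path, simplifyVector = FALSE)
  cfg$groups[[3]] <- list(label = "broken", condition = "anaerobic",
                          polymer = "nope", bottle = "anaerobic",
                          plastic_mass_g = 0.0625,
                          sample_bottles = list("missing-1"),
                          blank_bottles = list("missing-2"))
  cfg$gas_readings_csv <- file.path(study, "gas_readings.csv")
  cfg$flush_events_csv <- file.path(study, "flush_events.csv")
  report <- suppressWarnings(run_pipeline(cfg))
  expect_length(report$errors, 1)
  expect_match(report$errors, "broken")
  expect_length(report$results, 2) # other groups unaffected
})

test_that("an empty group list yields an empty report with a warning", {
  expect_warning(report <- run_pipeline(list(groups = list())), "empty")
  expect_length(report$results, 0)
  expect_equal(nrow(report$table), 0)
})

test_that("recovery sweep: truth recovered with small bias at 1% noise", {
  for (f in c(0.1, 0.5, 0.9)) {
    est <- vapply(1:20, function(i) {
      syn <- synth_assay_group(
        curve_model(f, noise_sd = 0.01, seed = 5000 + 31 * i + round(1000 * f)),
        "C6H10O2", "anaerobic")
      suppressWarnings(biodegradation_anaerobic(syn$group))$percent_mean
    }, numeric(1))
    expect_lt(abs(mean(est) - 100 * f), 2, label = paste("f =", f))
  }
})

test_that("full mineralization scores 100% under both bases (noise-free)", {
  for (cond in c("anaerobic", "aerobic")) {
    syn <- synth_assay_group(curve_model(1, noise_sd = 0, seed = 1),
                             "C6H10O2", cond,
                             times = seq(0, 80, by = 3.5))
    r <- if (cond == "anaerobic") biodegradation_anaerobic(syn$group)
         else biodegradation_aerobic(syn$group)
    expect_equal(r$percent_mean, 100, tolerance = 0.005, label = cond)
    expect_equal(r$percent_sd, 0, tolerance = 1e-6, label = cond)
  }
})
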