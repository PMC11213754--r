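spec_ana <- bottle_anaerobic()
spec_aer <- bottle_aerobic()

test_that("headspace_moles implements ideal-gas accounting", {
  expect_equal(headspace_moles(spec_ana, 0), 0)
  # hand computation: 0.20 * 1.7e5 Pa * 75 mL / (R * 328.15 K)
  expect_equal(headspace_moles(spec_ana, 0.20, 1.7e5),
               0.20 * 1.7e5 * 75e-6 / (8.314 * 328.15))
  expect_equal(headspace_moles(spec_ana, 0.20, 2 * 1.7e5),
               2 * headspace_moles(spec_ana, 0.20, 1.7e5))
  expect_error(headspace_moles(spec_ana, 1.2), "\\[0, 1\\]")
})

test_that("bottle_spec validates geometry and composition", {
  expect_error(bottle_spec(120, 130, 55, 1e5), "liquid_volume")
  expect_error(bottle_spec(120, 45, 55, 1e5, c(n2 = 0.5, co2 = 0.2)),
               "sum to 1")
  expect_error(bottle_spec(120, 45, 55, 1e5, c(xe = 1)), "unknown gas")
  expect_equal(spec_ana$headspace_volume_ml, 75)
  expect_equal(spec_aer$initial_composition[["o2"]], 0.2095)
})

test_that("cumulative methane accumulates headspace mole increases", {
  flat <- data.frame(time_days = c(0, 10, 20), mole_fraction = 0)
  curve <- cumulative_methane(spec_ana, flat)
  expect_s3_class(curve, "gas_curve")
  expect_equal(curve$cumulative_l, c(0, 0, 0))

  # a rise of 9.35e-4 mol above the initial reading is 0.0209 L at STP
  dn <- 9.35e-4
  f1 <- dn * 8.314 * 328.15 / (1.7e5 * 75e-6)
  r <- data.frame(time_days = c(0, 30), mole_fraction = c(0, f1))
  curve <- cumulative_methane(spec_ana, r)
  expect_equal(curve$cumulative_l[2], dn * 22.4, tolerance = 1e-9)

  # per-reading pressures override the constant-pressure assumption
  r$pressure_pa <- c(1.7e5, 1.7e5 / 2)
  half <- cumulative_methane(spec_ana, r)
  expect_equal(half$cumulative_l[2], dn * 22.4 / 2, tolerance = 1e-9)
  r$pressure_pa <- NA_real_
  expect_error(cumulative_methane(spec_ana, r, constant_pressure = FALSE),
               "constant-pressure")
})

test_that("curve construction prepends time zero and flags anomalies", {
  c1 <- gas_curve(c(5, 10), c(0.01, 0.02), "methane_production")
  expect_equal(c1$time_days[1], 0)
  expect_equal(c1$cumulative_l[1], 0)
  expect_warning(c2 <- gas_curve(c(0, 5, 10), c(0, 0.05, 0.02),
                                 "methane_production"),
                 "running maximum")
  expect_true("nonmonotonic" %in% attr(c2, "flags"))
  expect_error(gas_curve(c(0, 5, 5), c(0, 1, 2), "methane_production"),
               "strictly increasing")
})

o2_reading <- function(spec, n_mol, pressure = spec$initial_pressure_pa) {
  n_mol * 8.314 * (spec$temperature_c + 273.15) /
    (pressure * spec$headspace_volume_ml * 1e-6)
}

# a larger respirometer vessel (1 L headspace) so that mole-scale
# consumption examples fit inside the O2 inventory
spec_big <- bottle_spec(1100, 100, 25, 101325,
                        c(n2 = 0.7905, o2 = 0.2095))

test_that("oxygen consumption accounts across flush segments", {
  spec_aer <- spec_big
  n0 <- headspace_moles(spec_aer, 0.2095)
  # constant fraction, no flushes: nothing consumed
  r <- data.frame(time_days = c(0, 7, 14), mole_fraction = 0.2095)
  expect_equal(cumulative_o2_consumed(spec_aer, r)$cumulative_l,
               rep(0, 3))

  # two segments each consuming 1e-3 mol -> 2e-3 mol = 0.0640 g
  f_low <- o2_reading(spec_aer, n0 - 1e-3)
  r <- data.frame(time_days = c(0, 7, 14), mole_fraction = c(0.2095, f_low, f_low))
  fl <- data.frame(time_days = 7, post_flush_fraction = 0.2095,
                   post_flush_pressure_pa = spec_aer$initial_pressure_pa)
  r$mole_fraction[3] <- f_low # after flush restored to 0.2095, drops again
  curve <- cumulative_o2_consumed(spec_aer, r, fl)
  expect_equal(curve$cumulative_l[3], 2e-3 * 22.4, tolerance = 1e-9)
  expect_equal(curve_grams_o2(curve)[3], 2e-3 * 31.9988, tolerance = 1e-9)

  # flushing never counts replenished O2 as consumed
  expect_lt(curve$cumulative_l[3], headspace_moles(spec_aer, 1) * 22.4)
})

test_that("flush invariance: restoring the pre-flush state changes nothing", {
  spec_aer <- spec_big
  n0 <- headspace_moles(spec_aer, 0.2095)
  fr <- o2_reading(spec_aer, n0 - c(0, 4e-4, 8e-4, 1.2e-3))
  r <- data.frame(time_days = c(0, 5, 10, 15), mole_fraction = fr)
  base <- cumulative_o2_consumed(spec_aer, r)
  null_flush <- data.frame(time_days = 5, post_flush_fraction = fr[2],
                           post_flush_pressure_pa = spec_aer$initial_pressure_pa)
  expect_equal(cumulative_o2_consumed(spec_aer, r, null_flush)$cumulative_l,
               base$cumulative_l, tolerance = 1e-12)
})

test_that("segment additivity holds at any interior reading", {
  spec_aer <- spec_big
  n0 <- headspace_moles(spec_aer, 0.2095)
  fr <- o2_reading(spec_aer, n0 - c(0, 3e-4, 7e-4, 9e-4, 1.4e-3))
  t <- c(0, 4, 8, 12, 16)
  full <- cumulative_o2_consumed(
    spec_aer, data.frame(time_days = t, mole_fraction = fr))
  for (b in 2:4) {
    left <- cumulative_o2_consumed(
      spec_aer, data.frame(time_days = t[1:b], mole_fraction = fr[1:b]))
    right <- cumulative_o2_consumed(
      spec_aer, data.frame(time_days = t[b:5] - t[b],
                           mole_fraction = fr[b:5]))
    expect_equal(left$cumulative_l[b] + right$cumulative_l[5 - b + 1],
                 full$cumulative_l[5], tolerance = 1e-12)
  }
})

test_that("out-of-order flush events are rejected", {
  r <- data.frame(time_days = c(0, 7, 14), mole_fraction = c(0.2, 0.15, 0.1))
  fl <- data.frame(time_days = -1, post_flush_fraction = 0.2,
                   post_flush_pressure_pa = 1e5)
  expect_error(cumulative_o2_consumed(spec_aer, r, fl),
               "precedes the first reading")
})

test_that("blank correction subtracts the interpolated blank mean", {
  blank1 <- gas_curve(c(0, 10, 20), c(0, 0.02, 0.04), "methane_production")
  blank2 <- gas_curve(c(0, 10, 20), c(0, 0.04, 0.08), "methane_production")
  sample <- gas_curve(c(0, 5, 15), c(0, 0.06, 0.10), "methane_production")

  # identical to the blank mean -> all zero
  mean_curve <- gas_curve(c(0, 10, 20), c(0, 0.03, 0.06), "methane_production")
  z <- blank_correct(mean_curve, list(blank1, blank2))
  expect_equal(z$cumulative_l, rep(0, 3), tolerance = 1e-12)

  # hand interpolation: blank mean at t = 5 is 0.015, at t = 15 is 0.045
  bc <- blank_correct(sample, list(blank1, blank2))
  expect_equal(bc$cumulative_l, c(0, 0.06 - 0.015, 0.10 - 0.045),
               tolerance = 1e-12)
  expect_true("blank_corrected" %in% attr(bc, "flags"))

  # additivity in a constant offset
  shifted <- gas_curve(sample$time_days, sample$cumulative_l + 0.05,
                       "methane_production")
  bc2 <- blank_correct(shifted, list(blank1, blank2))
  expect_equal(bc2$cumulative_l[-1], bc$cumulative_l[-1] + 0.05,
               tolerance = 1e-12)

  # coverage: blanks stopping early require explicit end-hold
  long_sample <- gas_curve(c(0, 25), c(0, 0.1), "methane_production")
  expect_error(blank_correct(long_sample, list(blank1)), "cover")
  held <- blank_correct(long_sample, list(blank1), end_hold = TRUE)
  expect_equal(held$cumulative_l[2], 0.1 - 0.04)

  # negative corrected values are kept and flagged
  weak <- gas_curve(c(0, 10, 20), c(0, 0.001, 0.002), "methane_production")
  neg <- blank_correct(weak, list(blank1, blank2))
  expect_true(all(neg$cumulative_l[-1] < 0))
  expect_true("negative" %in% attr(neg, "flags"))
})

test_that("replicate aggregation gives mean and n-1 standard deviation", {
  base <- gas_curve(c(0, 10, 20), c(0, 0.02, 0.04), "methane_production")
  agg <- aggregate_replicates(list(base, base, base))
  expect_equal(agg$mean_l, base$cumulative_l)
  expect_equal(agg$sd_l, rep(0, 3))
  expect_equal(attr(agg, "n"), 3)

  c1 <- gas_curve(c(0, 10), c(0, 1), "methane_production")
  c2 <- gas_curve(c(0, 10), c(0, 2), "methane_production")
  c3 <- gas_curve(c(0, 10), c(0, 3), "methane_production")
  agg <- aggregate_replicates(list(c1, c2, c3))
  expect_equal(agg$mean_l[2], 2)
  expect_equal(agg$sd_l[2], 1)

  expect_warning(single <- aggregate_replicates(list(base)), "undefined")
  expect_true(all(is.na(single$sd_l)))
  o2 <- gas_curve(c(0, 10), c(0, 1), "oxygen_consumption")
  expect_error(aggregate_replicates(list(base, o2)), "mix")
})

test_that("replicate scatter from the generator matches the noise scale", {
  syn <- synth_assay_group(curve_model(0.8, noise_sd = 0.05, seed = 99),
                           "C6H10O2", "anaerobic")
  agg <- suppressWarnings(aggregate_replicates(syn$group$sample_curves))
  late <- agg$time_days > 30
  # cumulative noise scale: noise_sd * total headspace CH4 inventory
  n_scale <- with(syn$truth, noise_sd *
                    (asymptote_l + blank_asymptote_l))
  expect_gt(stats::median(agg$sd_l[late]), 0.2 * n_scale)
  expect_lt(stats::median(agg$sd_l[late]), 3 * n_scale)
})

test_that("gas readings and flush CSV round-trip through the readers", {
  tmp <- withr::local_tempdir()
  gr <- data.frame(bottle_id = c("b1", "b1"), time_days = c(0, 7),
                   gas = "CH4", mole_fraction = c(0, 0.1),
                   pressure_pa = NA_real_)
  write.csv(gr, file.path(tmp, "gas.csv"), row.names = FALSE)
  back <- read_gas_readings(file.path(tmp, "gas.csv"))
  expect_equal(back$mole_fraction, gr$mole_fraction)
  expect_error(read_gas_readings(textConnection("a,b\n1,2")), "columns")

  fl <- data.frame(bottle_id = "b1", time_days = 7,
                   post_flush_fraction = 0.2095,
                   post_flush_pressure_pa = 101325)
  write.csv(fl, file.path(tmp, "flush.csv"), row.names = FALSE)
  expect_equal(read_flush_events(file.path(tmp, "flush.csv"))$time_days, 7)
})
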