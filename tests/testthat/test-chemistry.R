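test_that("protein mass balance follows the three-step formulas", {
  expect_equal(protein_mass_in_feed(100, 40.42), 40.42)
  expect_equal(protein_mass_in_feed(50, 0), 0)
  expect_equal(protein_mass_in_feed(50, 100), 50)

  expect_equal(protein_mass_in_isolate(15, 80), 12)
  expect_equal(protein_mass_in_isolate(15, 100), 15)
  expect_equal(protein_mass_in_isolate(0, 80), 0)

  expect_equal(extraction_yield(40.42, 40.42), 100)
  expect_equal(extraction_yield(40.42, 0), 0)
  # chained worked example: 100 g cake at 40.42% -> 15 g isolate at 80%
  m1 <- protein_mass_in_feed(100, 40.42)
  m3 <- protein_mass_in_isolate(15, 80)
  expect_equal(extraction_yield(m1, m3), 12 / 40.42 * 100, tolerance = 1e-12)
  expect_equal(extraction_yield(m1, m3), 29.6883, tolerance = 1e-4)

  expect_error(extraction_yield(0, 1), "positive")
  expect_error(protein_mass_in_feed(-1, 50), "non-negative")
  expect_error(protein_mass_in_feed(10, 101), "<= 100")
})

test_that("extraction yield is scale-free in simultaneous mass scaling", {
  y1 <- extraction_yield(protein_mass_in_feed(100, 40.42),
                         protein_mass_in_isolate(15, 80))
  for (k in c(0.1, 2, 55)) {
    yk <- extraction_yield(protein_mass_in_feed(100 * k, 40.42),
                           protein_mass_in_isolate(15 * k, 80))
    expect_equal(yk, y1, tolerance = 1e-12)
  }
})

test_that("Bradford concentration applies the calibration factor", {
  expect_equal(bradford_concentration(1.0, 1, 1), 1.9899)
  expect_equal(bradford_concentration(0, 3, 0.5), 0)
  expect_equal(bradford_concentration(0.5, 2, 0.5), 3.9798, tolerance = 1e-12)
  expect_error(bradford_concentration(1, 1, 0), "positive")
  expect_error(bradford_concentration(1, 0.5, 1), "at least 1")
})

test_that("Folin-Ciocalteu GAE quantitation follows the linear calibration", {
  expect_equal(tpc_gae(0.2, slope = 1, intercept = 0.2), 0)
  expect_equal(tpc_gae(0.5, slope = 1, intercept = 0, extract_volume = 10,
                       sample_mass = 1, dilution = 1), 500)
  expect_equal(tpc_gae(0.5, slope = 1, intercept = 0, extract_volume = 10,
                       sample_mass = 2), 250)
  expect_error(tpc_gae(0.1, slope = 1, intercept = 0.2), "intercept")
  expect_error(tpc_gae(0.5, slope = 0), "positive")
})

test_that("packaged isolate profiles reproduce every printed summary cell", {
  profiles <- read_aa_profiles(aa_fixture_path())
  printed <- read.csv(aa_printed_path(), check.names = FALSE)
  rownames(printed) <- printed$row
  expect_length(profiles, 5)
  for (s in names(profiles)) {
    sm <- aa_summary(profiles[[s]])
    expect_equal(sm$eaa_sum, printed["EAA", s], tolerance = 0.011)
    expect_equal(sm$neaa_sum, printed["NEAA", s], tolerance = 0.011)
    expect_equal(sm$taa_sum, printed["TAA", s], tolerance = 0.011)
    expect_equal(round_half_up(sm$eaa_over_neaa_pct),
                 printed["EAA_over_NEAA_pct", s])
    expect_equal(round_half_up(sm$eaa_over_taa_pct),
                 printed["EAA_over_TAA_pct", s])
    # lysine clears the WHO adult minimum in every isolate
    expect_true(sm$who_flags[["Lys"]])
  }
})

test_that("amino-acid sums satisfy the TAA identity on random profiles", {
  panel <- c(ESSENTIAL_AA, NONESSENTIAL_AA)
  set.seed(31)
  for (i in 1:25) {
    v <- setNames(runif(16, 0.1, 20), panel)
    sm <- aa_summary(aa_profile(v))
    expect_equal(sm$taa_sum, sm$eaa_sum + sm$neaa_sum, tolerance = 1e-9)
    expect_equal(sm$taa_sum, sum(v), tolerance = 1e-9)
  }
})

test_that("profile construction rejects missing or unknown analytes", {
  panel <- c(ESSENTIAL_AA, NONESSENTIAL_AA)
  v <- setNames(rep(1, 16), panel)
  expect_silent(aa_profile(v))
  expect_error(aa_profile(v[-3]), "missing analyte")
  expect_error(aa_profile(c(v, Trp = 1)), "unknown analyte")
  expect_error(aa_summary(aa_profile(v), who_thresholds = c(Glu = 1)),
               "non-essential")
  z <- v; z[] <- 0
  expect_error(aa_summary(aa_profile(z)), "undefined")
})

test_that("digestibility gain is a signed difference with a warning when negative", {
  expect_equal(digestibility_gain(2, 5), 3)
  expect_equal(digestibility_gain(4, 4), 0)
  expect_warning(g <- digestibility_gain(5, 2), "negative")
  expect_equal(g, -3)
})

test_that("half-away-from-zero rounding matches the printed-table convention", {
  expect_equal(round_half_up(72.5), 73)
  expect_equal(round_half_up(-72.5), -73)
  expect_equal(round_half_up(72.49), 72)
})
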