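test_that("urea proxy reproduces the published arithmetic in both modes", {
  expect_equal(urea_to_aa_consumption(392, 136.5, 1.45), 77.6, tolerance = 0.05)
  expect_equal(urea_to_aa_consumption(0, 136.5, 1.45), 0)
  expect_equal(urea_to_aa_consumption(392, 136.5, 1.0), 53.5, tolerance = 0.05)
  # per-urea-nitrogen accounting: 2 N per urea, divided by N per AA
  expect_equal(urea_to_aa_consumption(392, 136.5, 1.45,
                                      mode = "per_urea_nitrogen"),
               73.8, tolerance = 0.05)
})

test_that("lactate conversion gives 37 mmol/h at 80 g/day", {
  expect_equal(lactate_input_rate(80, 90.08), 37.0, tolerance = 0.05)
  expect_equal(lactate_input_rate(40, 90.08), 18.5, tolerance = 0.05)
  expect_equal(lactate_input_rate(1e-12, 90.08), 0, tolerance = 1e-10)
})

test_that("adipose blood flow scales to 31.5 l/h at 15 kg fat", {
  expect_equal(adipose_blood_flow(15, 3.5), 31.5)
  expect_equal(adipose_blood_flow(0, 3.5), 0)
  expect_equal(adipose_blood_flow(10, 3.0), 18.0)
})

test_that("adipose lipolysis releases FA and glycerol at the 3:1 ratio", {
  r <- adipose_fa_glycerol_release(1)
  expect_equal(r$fa_mmol_h, 1.8)
  expect_equal(r$glycerol_mmol_h, 0.6)
  r0 <- adipose_fa_glycerol_release(0)
  expect_equal(r0$fa_mmol_h, 0); expect_equal(r0$glycerol_mmol_h, 0)
  r15 <- adipose_fa_glycerol_release(15)
  expect_equal(r15$fa_mmol_h, 27.0); expect_equal(r15$glycerol_mmol_h, 9.0)
})

test_that("muscle AA release is linear with glutamine+alanine at 60 percent", {
  prof <- aa_profiles()
  r1 <- muscle_aa_release(10, prof)
  r2 <- muscle_aa_release(20, prof)
  expect_equal(r2, 2 * r1)
  expect_equal(unname((r1["gln"] + r1["ala"]) / sum(r1)), 0.60)
  expect_true(all(muscle_aa_release(0, prof) == 0))
  badprof <- prof; badprof$muscle_fraction[1] <- badprof$muscle_fraction[1] + 0.1
  expect_error(muscle_aa_release(10, badprof), "normalized")
})

test_that("adipose AA release converts concentration times flow correctly", {
  prof <- aa_profiles()
  prof$adipose_conc_umol_l <- rep(100, nrow(prof))
  # 15 kg fat at 3.5 ml/min/100g = 31.5 l/h; 100 umol/l * 31.5 l/h = 3.15 mmol/h
  r <- adipose_aa_release(15, prof)
  expect_equal(unname(r["ala"]), 3.15)
  prof$adipose_conc_umol_l <- rep(0, nrow(prof))
  expect_true(all(adipose_aa_release(15, prof) == 0))
  # linear in fat mass
  prof2 <- aa_profiles()
  expect_equal(adipose_aa_release(30, prof2), 2 * adipose_aa_release(15, prof2))
})

test_that("autophagy distributes the AA shortfall with exact mass closure", {
  prof <- aa_profiles()
  r <- autophagy_aa_input(77.6, 35, prof)
  expect_equal(sum(r * prof$molar_mass) * 24 / 1000, 42.6, tolerance = 1e-9)
  expect_true(all(r >= 0))
  expect_true(all(autophagy_aa_input(50, 50, prof) == 0))
  expect_warning(r2 <- autophagy_aa_input(30, 40, prof), "exceeds")
  expect_true(all(r2 == 0))
})

test_that("glucose and ketone bounds follow weight-scaled glycogenolysis", {
  g <- glucose_and_ketone_bounds(97)
  expect_equal(g$gng_min_mmol_h, 16.7)
  expect_equal(g$glycogenolysis_mmol_h, 5.5 * 97 * 60 / 1000, tolerance = 1e-9)
  expect_equal(g$glycogenolysis_g_h, 5.77, tolerance = 0.01)
  expect_equal(g$ketone_lb_mmol_h, 0.1)
  expect_equal(g$glucose_output_lb_mmol_h,
               16.7 + g$glycogenolysis_mmol_h)
})

test_that("assembled subject bounds compose the boundary model correctly", {
  s <- fixture_subject(bmi = 29.7, fat_mass = NA)
  eb <- assemble_subject_bounds(s)
  fa <- eb[eb$metabolite == "fa" & eb$direction == "uptake", ]
  expect_equal(fa$upper, 1.8 * (1.763 * 29.7 - 26.75), tolerance = 1e-9)
  expect_equal(fa$upper, 46.1, tolerance = 0.01)
  expect_true(all(eb$lower <= eb$upper + 1e-12))
  expect_true(all(eb$lower >= 0))
  # determinism: identical subjects give identical bounds
  expect_identical(assemble_subject_bounds(s), assemble_subject_bounds(s))
  # measured fat mass takes precedence over imputation
  s2 <- fixture_subject(fat_mass = 20)
  eb2 <- assemble_subject_bounds(s2)
  expect_equal(eb2$upper[eb2$metabolite == "fa"], 36)
  # VLDL secretion pinned to the measured rates
  tg <- eb[eb$metabolite == "vldl_tg", ]
  expect_equal(tg$lower, tg$upper)
  expect_equal(tg$lower, s$vldl_tg_secretion)
  # mandatory fields and sign checks
  s3 <- fixture_subject(); s3$weight <- NA
  expect_error(assemble_subject_bounds(s3), "missing mandatory")
  s4 <- fixture_subject(tg = -1)
  expect_error(assemble_subject_bounds(s4), "nonnegative")
})

test_that("AA mass balance closes: supply plus autophagy equals demand", {
  const <- physiology_constants()
  prof <- aa_profiles()
  for (s in list(fixture_subject(), fixture_subject(weight = 120, bmi = 36))) {
    eb <- assemble_subject_bounds(s, prof, const)
    aa_rows <- eb[eb$metabolite %in% prof$aa & eb$direction == "uptake", ]
    total_g <- sum(aa_rows$upper *
                     prof$molar_mass[match(aa_rows$metabolite, prof$aa)]) *
      24 / 1000
    expect_equal(total_g, const$aa_demand_g_day, tolerance = 1e-6)
  }
})

test_that("input mode 'bound' opens the uptake lower bounds", {
  s <- fixture_subject()
  eb <- assemble_subject_bounds(s, input_mode = "bound")
  fa <- eb[eb$metabolite == "fa" & eb$direction == "uptake", ]
  expect_equal(fa$lower, 0)
  expect_gt(fa$upper, 0)
})

test_that("exchange bounds serialize to CSV and validate on read", {
  eb <- assemble_subject_bounds(fixture_subject())
  f <- tempfile(fileext = ".csv")
  write_exchange_bounds(eb, f)
  back <- read_exchange_bounds(f)
  attr(eb, "body") <- NULL   # derivation metadata is not serialized
  expect_equal(as.data.frame(back), as.data.frame(eb), tolerance = 1e-12)
  expect_error(exchange_bounds("fa", "uptake", 5, 3), "lower <= upper")
  expect_error(exchange_bounds(c("fa", "fa"), c("uptake", "uptake"),
                               c(0, 0), c(1, 1)), "once per direction")
})
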