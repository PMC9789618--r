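test_that("ramps interpolate linearly between endpoint values", {
  r <- ramp_spec(0.5, 1.0, 40)
  expect_equal(ramp_value(r, 20), 0.75)
  expect_equal(ramp_value(r, 0), 0.5)
  expect_equal(ramp_value(r, 40), 1.0)
  expect_equal(ramp_value(ramp_spec(20, 30, 40), 40), 30)  # implant lifespan ramp
  expect_warning(v <- ramp_value(r, 50), "clamped")
  expect_equal(v, 1.0)

  # compatibility form agrees with the standard one when v0 = 1
  rc <- ramp_spec(1, 2, 40, compat = TRUE)
  expect_equal(ramp_value(rc, 10), ramp_value(ramp_spec(1, 2, 40), 10))
  # ... but misses the stated endpoint when v0 != 1
  rc2 <- ramp_spec(0.5, 1, 40, compat = TRUE)
  expect_false(isTRUE(all.equal(ramp_value(rc2, 40), 1)))
})

test_that("scenario presets carry the documented overrides", {
  base <- build_scenario("baseline")
  expect_equal(base$willingness$mode, "uniform")
  expect_equal(base$willingness$value, 0.01)
  expect_equal(base$prevalence_threshold, 60)
  eff <- cidemand:::effective_schedules(base, make_stylized_country()$schedules,
                                        t = 1, s = 40)
  expect_true(all(eff$w_u[21:101] == 0.01))
  expect_true(all(eff$w_u[1:20] == 0))

  expect_equal(build_scenario("innovative_ci")$cost_set, "innovative")
  expect_equal(innovative_cost_set()$devices$l_i, 23)
  expect_equal(build_scenario("relaxed_indication")$prevalence_threshold, 40)

  mixed <- build_scenario("mixed_prognosis", 40)
  sched <- make_stylized_country()$schedules
  eff40 <- cidemand:::effective_schedules(mixed, sched, t = 40, s = 40)
  expect_equal(eff40$fe_u, pmin(2 * sched$fe_u, 1))  # doubled, capped at 1
  expect_equal(ramp_value(mixed$l_i, 40), 30)
  expect_equal(ramp_value(mixed$l_s, 40), 10)
  # mixed prognosis is the union of the two single-change ramp presets
  fw <- build_scenario("feasibility_willingness_increase", 40)
  ls <- build_scenario("lifespan_increase", 40)
  expect_equal(mixed$feasibility_ramp, fw$feasibility_ramp)
  expect_equal(mixed$willingness, fw$willingness)
  expect_equal(mixed$l_i, ls$l_i)
  expect_equal(mixed$l_s, ls$l_s)

  expect_error(build_scenario("nope"), "baseline")
})

test_that("identical inputs give bit-identical scenario runs", {
  inp <- stylized_inputs()
  a <- run_scenario("baseline", inp, short_config(5))
  b <- run_scenario("baseline", inp, short_config(5))
  expect_identical(a, b)
})

test_that("the innovative CI changes costs but not implantation or processor flows", {
  inp <- stylized_inputs(ci_uni_share = 0.04, ci_bi_share = 0.03)
  base <- run_scenario("baseline", inp, short_config(10))
  innov <- run_scenario("innovative_ci", inp, short_config(10))
  expect_equal(innov$ciu, base$ciu)
  expect_equal(innov$cib, base$cib)
  expect_equal(innov$sn, base$sn)
  expect_equal(innov$cin, base$cin * 20 / 23)
})

test_that("relaxing the indication threshold never reduces unilateral implantations", {
  inp <- stylized_inputs()
  base <- run_scenario("baseline", inp, short_config(10))
  relaxed <- run_scenario("relaxed_indication", inp, short_config(10))
  expect_true(all(relaxed$ciu >= base$ciu))
})

test_that("willingness ramp ends at the surveyed profile", {
  scn <- build_scenario("feasibility_willingness_increase", 10)
  sched <- make_stylized_country()$schedules
  eff <- cidemand:::effective_schedules(scn, sched, t = 10, s = 10)
  wt <- willingness_table()
  expect_equal(eff$w_u[25], wt$unilateral[wt$age_lower == 20])
  expect_equal(eff$w_b[95], wt$bilateral[wt$age_lower == 90])
  eff0 <- cidemand:::effective_schedules(scn, sched, t = 1, s = 10)
  expect_lt(eff0$w_u[25], eff$w_u[25])

  # the multiplicative compatibility ramp stays anchored near the start value
  scn$willingness$compat <- TRUE
  effc <- cidemand:::effective_schedules(scn, sched, t = 10, s = 10)
  expect_equal(effc$w_u[25], 0.01 * (1 + (wt$unilateral[1] - 0.01)))
  expect_lt(effc$w_u[25], 0.02)
})
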