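test_that("grouped schedules expand to per-age step functions", {
  fe <- feasibility_table()
  sched <- expand_age_groups(data.frame(age_lower = fe$age_lower,
                                        age_upper = fe$age_upper,
                                        value = fe$unilateral))
  expect_equal(sched[21:30], rep(0.7657, 10))   # 20-29 group
  expect_equal(sched[91:101], rep(0.2730, 11))  # open 90+ group through age 100
  expect_true(all(sched[1:20] == 0))

  one <- expand_age_groups(data.frame(age_lower = 20, age_upper = 100, value = 1))
  expect_true(all(one[21:101] == 1))

  expect_error(expand_age_groups(data.frame(age_lower = c(20, 35),
                                            age_upper = c(29, 100),
                                            value = c(0.5, 0.5))),
               "gap or overlap")
})

test_that("unilateral implantation moves hearing-loss patients at fe * w", {
  st <- state_at(25, 2, 1000)
  sup <- const_supply(fe_u = 0.7657, w_u = 0.01)
  res <- step_unilateral(st, sup, dt = 365)
  expect_equal(sum(res$flow), 7.657)
  expect_equal(res$state$counts[26, 3], 7.657)

  expect_equal(sum(step_unilateral(st, const_supply(fe_u = 0.7657, w_u = 0),
                                   365)$flow), 0)

  sat <- step_unilateral(st, const_supply(fe_u = 1, w_u = 1), dt = 365)
  expect_equal(sat$state$counts[26, 2], 0)
  expect_equal(sat$state$counts[26, 3], 1000)
})

test_that("bilateral implantation draws only on unilateral users", {
  empty <- state_at(40, 2, 100)  # nobody in stage 3
  expect_equal(sum(step_bilateral(empty, const_supply(fe_b = 1, w_b = 1),
                                  365)$flow), 0)

  st <- state_at(40, 3, 100)
  res <- step_bilateral(st, const_supply(fe_b = 0.7602, w_b = 0.01), dt = 365)
  expect_equal(sum(res$flow), 0.7602)

  # cumulative stage-4 inflow can never exceed cumulative stage-3 inflow
  set.seed(11)
  for (rep in 1:3) {
    adult <- as.numeric(AGES_ >= 20)
    sup <- supply_schedules(stats::runif(101) * adult, stats::runif(101) * adult,
                            stats::runif(101) * adult, stats::runif(101) * adult,
                            provenance = "scenario")
    cur <- state_at(c(50, 70), c(2, 2), c(500, 300))
    in3 <- 0; in4 <- 0
    for (d in 1:200) {
      u <- step_unilateral(cur, sup, 1); in3 <- in3 + sum(u$flow)
      b <- step_bilateral(u$state, sup, 1); in4 <- in4 + sum(b$flow)
      cur <- b$state
    }
    expect_lte(in4, in3)
  }
})

test_that("replacement flows are stock / lifespan and leave the state alone", {
  st <- state_at(c(60, 60), c(3, 4), c(100, 50))
  dev <- device_parameters(l_i = 20, l_s = 5)
  expect_equal(processor_exchanges(st, dev, 365), 40)  # (100 + 2*50)/5
  expect_equal(reimplantations(st, dev, 365), 10)      # 200/20

  expect_equal(processor_exchanges(state_at(60, 2, 100), dev, 365), 0)

  # exact inverse proportionality in the lifespans
  expect_equal(processor_exchanges(st, device_parameters(l_s = 2.5), 365), 80)
  r23 <- reimplantations(st, device_parameters(l_i = 23), 365)
  expect_equal(r23 / reimplantations(st, dev, 365), 20 / 23)

  expect_error(device_parameters(l_s = 0), "positive")
})

test_that("base-year CI stocks are seeded proportional to allocation weights", {
  st <- state_at(c(30, 40, 50), c(2, 2, 2), c(1000, 1000, 1000))
  sup <- const_supply(fe_u = 0.5, w_u = 0.2, fe_b = 0.5, w_b = 0.1)

  same <- initialize_ci_stocks(st, sup, c(0, 0))
  expect_equal(same$counts, st$counts)

  seeded <- initialize_ci_stocks(st, sup, c(900, 0))
  expect_equal(sum(seeded$counts[, 3]), 900, tolerance = 1e-9)
  # uniform stocks and weights: equal thirds
  expect_equal(unname(seeded$counts[c(31, 41, 51), 3]), rep(300, 3))
  # stages 2+3+4 total unchanged
  expect_equal(sum(seeded$counts[, 2:4]), sum(st$counts[, 2:4]))

  both <- initialize_ci_stocks(st, sup, c(600, 300))
  expect_equal(sum(both$counts[, 4]), 300, tolerance = 1e-9)

  expect_error(initialize_ci_stocks(st, sup, c(4000, 0)), "infeasible")
})

test_that("with zero willingness no implantation flow ever occurs", {
  inp <- stylized_inputs()
  scn <- scenario("no_willingness",
                  willingness = list(mode = "uniform", value = 0,
                                     table = willingness_table()))
  out <- run_scenario(scn, inp, short_config(5))
  expect_true(all(out$ciu == 0))
  expect_true(all(out$cib == 0))
  expect_true(all(out$sn == 0))  # nothing implanted, nothing to replace
})
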