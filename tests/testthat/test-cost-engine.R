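base_params <- function() baseline_cost_set()$costs
innov_params <- function() innovative_cost_set()$costs

flows_of <- function(ciu_total = 0, cib_total = 0, sn = 0, cin = 0, age = 60) {
  ciu <- numeric(101); cib <- numeric(101)
  ciu[age + 1] <- ciu_total; cib[age + 1] <- cib_total
  list(ciu = ciu, cib = cib, sn = sn, cin = cin)
}

test_that("first-year cost prices this year's implantation events", {
  st <- state_at(60, 3, 100)  # the 100 implanted this year, no older stock
  cb <- annual_costs(flows_of(ciu_total = 100), NULL, st, base_params(),
                     flat_rates())
  expect_equal(cb$first_year_uni, 100 * 33442.86)
  expect_equal(cb$total, 3344286)
  expect_equal(cb$second_year + cb$subsequent_years + cb$reimplant +
                 cb$processor + cb$first_year_bi, 0)
})

test_that("zero flows and zero implanted stock cost nothing", {
  cb <- annual_costs(flows_of(), NULL, state_at(60, 2, 100), base_params(),
                     flat_rates())
  expect_equal(cb$total, 0)
})

test_that("second-year cost attaches to last year's events net of survival", {
  st <- state_at(60, 3, 100)
  prev <- flows_of(ciu_total = 80)
  cb <- annual_costs(flows_of(), prev, st, base_params(),
                     flat_rates(mortality = 0.05))
  expect_equal(cb$second_year, 3369.96 * 80 * 0.95)
  # year-3+ follow-up covers the implanted stock minus recent events
  expect_equal(cb$subsequent_years, 620.73 * (100 - 80 * 0.95))
})

test_that("swapping in the innovative second-year unit cost moves that component by -1.76%", {
  st <- state_at(60, 3, 500)
  prev <- flows_of(ciu_total = 80, cib_total = 20)
  cb_b <- annual_costs(flows_of(), prev, st, base_params(), flat_rates())
  cb_i <- annual_costs(flows_of(), prev, st, innov_params(), flat_rates())
  expect_equal(cb_i$second_year / cb_b$second_year, 3310.69 / 3369.96)
  expect_equal(100 * (1 - cb_i$second_year / cb_b$second_year), 1.76,
               tolerance = 0.005)
})

test_that("each unit cost enters its component linearly and touches nothing else", {
  st <- state_at(c(60, 70), c(3, 4), c(300, 100))
  flows <- flows_of(ciu_total = 40, cib_total = 10, sn = 90, cin = 15)
  prev <- flows_of(ciu_total = 30, cib_total = 5)
  base <- annual_costs(flows, prev, st, base_params(), flat_rates())
  comp_of <- c(c_first_year = "first_year_uni", c_second_year = "second_year",
               c_subsequent = "subsequent_years", c_reimplant = "reimplant",
               c_processor = "processor")
  for (p in names(comp_of)) {
    scaled <- base_params()
    scaled[[p]] <- scaled[[p]] * 3
    cb <- annual_costs(flows, prev, st, scaled, flat_rates())
    comp <- comp_of[[p]]
    if (p == "c_first_year") {
      expect_equal(cb$first_year_uni, 3 * base$first_year_uni)
      expect_equal(cb$first_year_bi, 3 * base$first_year_bi)
      untouched <- setdiff(names(base), c("first_year_uni", "first_year_bi", "total"))
    } else {
      expect_equal(cb[[comp]], 3 * base[[comp]])
      untouched <- setdiff(names(base), c(comp, "total"))
    }
    for (u in untouched) expect_equal(cb[[u]], base[[u]])
    expect_equal(cb$total, sum(cb[names(cb) != "total"]))
  }
})

test_that("cumulation sums, averages and ranks components", {
  one_year <- annual_costs(flows_of(), NULL, state_at(60, 2, 1), base_params(),
                           flat_rates())
  flat <- do.call(rbind, replicate(40, {
    x <- one_year; x$total <- 1; x
  }, simplify = FALSE))
  cc <- cumulate_costs(flat)
  expect_equal(cc$total[["total"]], 40)
  expect_equal(cc$annual_mean[["total"]], 1)
  # all-equal components: ties broken by the fixed component order
  expect_equal(cc$ordering, c("first_year_uni", "first_year_bi", "second_year",
                              "subsequent_years", "reimplant", "processor"))
})
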