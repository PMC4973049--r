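test_that("stratum risks apply the signed log odds ratio on the odds scale", {
  r0 <- risk_by_stratum(0.001806, 0)
  expect_equal(r0$risk_safe, r0$risk_unsafe)
  r <- risk_by_stratum(0.001806, -0.604)
  expect_equal(round(r$risk_safe, 6), 0.000988)
  expect_equal(r$risk_unsafe, 0.001806)
  # harmful direction: safe storage riskier than unsafe
  rh <- risk_by_stratum(0.001204, 0.2614)
  expect_gt(rh$risk_safe, rh$risk_unsafe)
})

test_that("severity split partitions every ingestion event", {
  s <- severity_split(0.63, 0.0191, 0.0116)
  expect_equal(s$minor, 0.37)
  expect_equal(round(s$moderate, 3), 0.618)
  expect_equal(round(s$death, 6), round(0.63 * 0.0191 * 0.0116, 6))
  expect_equal(s$minor + s$moderate + s$severe_survive + s$death, 1)
  s1 <- severity_split(1, 1, 1)  # all events fatal
  expect_equal(s1$death, 1)
  set.seed(6)
  p <- matrix(runif(30), 10)
  ss <- severity_split(p[, 1], p[, 2], p[, 3])
  expect_equal(ss$minor + ss$moderate + ss$severe_survive + ss$death,
               rep(1, 10))
})

test_that("acute unit costs rebuild the printed 2012 figures", {
  d <- toy_draws()
  expect_equal(acute_event_cost("minor", d), 175.12)
  expect_equal(acute_event_cost("moderate", d), 795.12)
  expect_equal(acute_event_cost("severe", d), 2670.12)
  expect_equal(acute_event_cost("minor", d, gp = TRUE), 175.12 + 43)
  expect_equal(acute_event_cost("fatal", d), 2670.12 + 205.5)
  expect_equal(acute_event_cost("fatal", d, gp = TRUE), 2670.12 + 205.5)
  expect_equal(event_utility_decrement("minor", d), 0.03)
  expect_equal(event_utility_decrement("severe", d), 0.146)
  expect_equal(d$uSevere, d$uModerate + d$uChronic)  # point estimates
})

test_that("preschool model with no ingestion risk yields no cases or costs", {
  res <- run_preschool(0.8, toy_draws(pIngest = 0), med_cfg)
  expect_equal(res$cases, 0)
  expect_equal(res$cost_health, 0)
  expect_equal(res$exit$alive_chronic, 0)
  expect_gt(res$qalys, 0)
})

test_that("occupancy is conserved on fuzzed parameter sets", {
  set.seed(41)
  draws <- random_parameter_set(40)
  ps <- runif(40)
  res <- run_preschool(ps, draws, med_cfg)
  sums <- apply(res$trace$occupancy, c(1, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-12)
  # dead states never shrink
  dead <- res$trace$occupancy[, 5, ] + res$trace$occupancy[, 6, ]
  expect_true(all(apply(dead, 1, function(x) all(diff(x) >= 0))))
})

test_that("expected cases are monotone in safe-storage prevalence", {
  grid <- seq(0, 1, 0.1)
  protective <- vapply(grid, function(p)
    run_preschool(p, toy_draws(), med_cfg)$cases, 0)
  expect_true(all(diff(protective) < 0))
  harmful <- vapply(grid, function(p)
    run_preschool(p, toy_draws(logOrIngest = 0.2614), med_cfg)$cases, 0)
  expect_true(all(diff(harmful) > 0))
})

test_that("discounting: zero-rate totals equal un-discounted cycle sums", {
  cfg0 <- with_settings(med_cfg, discount_costs = 0,
                        discount_utilities = 0)
  d <- toy_draws()
  res <- run_preschool(0.85, d, med_cfg)
  res0 <- run_preschool(0.85, d, cfg0)
  undisc <- function(m, rate) as.numeric(
    m %*% (1 + rate)^(seq_len(ncol(m))))
  expect_equal(undisc(res$trace$cost, 0.035), res0$cost_health)
  expect_equal(undisc(res$trace$qalys, 0.035), res0$qalys)
  expect_lt(res$qalys, res0$qalys)
  lt <- run_longterm(res$exit, d, med_cfg)
  lt0 <- run_longterm(res0$exit, d, cfg0)
  expect_lt(lt$qalys, lt0$qalys)
})

test_that("long-term model limits: extinction, annuity closed form, chronic", {
  d <- toy_draws()
  dead <- run_longterm(list(alive_no_chronic = 0, alive_chronic = 0),
                       d, med_cfg)
  expect_equal(dead$cost, 0)
  expect_equal(dead$qalys, 0)
  expect_equal(dead$dead_final, 1)
  expect_error(run_longterm(list(alive_no_chronic = 0.7,
                                 alive_chronic = 0.4), d, med_cfg),
               "exceed 1")

  # flat survival, flat utility, constant discount: geometric annuity
  qx <- 0.02; u <- 0.9; dr <- 0.035
  cfg <- med_cfg
  cfg$lifetable <- data.frame(age = 0:99, qx = qx)
  cfg$upop <- rep(u, 100)
  cfg$settings$discount_costs <- dr; cfg$settings$discount_utilities <- dr
  res <- run_longterm(list(alive_no_chronic = 1, alive_chronic = 0),
                      toy_draws(), cfg)
  s <- (1 - qx) / (1 + dr)
  expect_equal(res$qalys, u * (1 + dr)^-5 * s * (1 - s^95) / (1 - s))
  expect_equal(res$cost, 0)

  # pure chronic cohort, no mortality or discounting
  cfg2 <- with_settings(cfg, discount_costs = 0, discount_utilities = 0)
  cfg2$lifetable$qx <- 0
  res2 <- run_longterm(list(alive_no_chronic = 0, alive_chronic = 1),
                       toy_draws(), cfg2)
  expect_equal(res2$cost, 95 * 386.42)
  expect_equal(res2$qalys, 95 * (u - 0.1))
  # lifetime QALYs decrease in the chronic decrement
  res3 <- run_longterm(list(alive_no_chronic = 0, alive_chronic = 1),
                       toy_draws(uChronic = 0.2), cfg2)
  expect_lt(res3$qalys, res2$qalys)
})

test_that("lifetime discounted QALYs per person fall in the expected band", {
  d <- point_parameters(med_cfg)
  ps <- run_preschool(0.858, d, med_cfg)
  lt <- run_longterm(ps$exit, d, med_cfg)
  total <- ps$qalys + lt$qalys
  expect_gt(total, 24); expect_lt(total, 26)
})

test_that("health consequences scale linearly with children per household", {
  cfg2 <- with_settings(med_cfg, children_per_household = 2)
  d <- toy_draws()
  base <- run_model_arm(med_cfg$arms[2, ], d, med_cfg)
  dbl <- run_model_arm(med_cfg$arms[2, ], d, cfg2)
  expect_equal(dbl$cases, 2 * base$cases)
  expect_equal(dbl$qalys, 2 * base$qalys)
  expect_equal(dbl$cost_intervention, base$cost_intervention)
  expect_equal(dbl$cost_cea - dbl$cost_intervention,
               2 * (base$cost_cea - base$cost_intervention))
})
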