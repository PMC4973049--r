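# shared small PSA runs (200 draws keep the suite fast)
psa_a <- run_psa(med_cfg, 200, seed = 123)
psa_b <- run_psa(med_cfg, 200, seed = 123)

test_that("a seeded PSA is bit-for-bit reproducible", {
  expect_identical(psa_a$cases, psa_b$cases)
  expect_identical(psa_a$cost_cua, psa_b$cost_cua)
  expect_identical(psa_a$qalys, psa_b$qalys)
  expect_identical(psa_a$draws, psa_b$draws)
  psa_c <- run_psa(med_cfg, 200, seed = 124)
  expect_false(identical(psa_a$cases, psa_c$cases))
})

test_that("point-estimate mode collapses to a single deterministic draw", {
  p1 <- run_psa(med_cfg, 1, seed = 1, point_estimate = TRUE)
  p2 <- run_psa(med_cfg, 1, seed = 99, point_estimate = TRUE)
  expect_identical(p1$cases, p2$cases)
  expect_equal(nrow(p1$cases), 1)
  # fixed parameters identical across stochastic draws too
  expect_equal(unique(psa_a$draws$pAccept), 0.9)
  expect_equal(unique(psa_a$draws$cFatal), 205.5)
  # a 1-draw stochastic run keeps matrix shapes
  p3 <- run_psa(med_cfg, 1, seed = 5)
  expect_equal(dim(p3$qalys), c(1, 7))
})

test_that("each scenario changes only its stated parameters", {
  base <- apply_scenario(med_cfg, "base")
  fields <- function(cfg) list(prob = cfg$prob, costs = cfg$costs,
                               arms = cfg$arms, dec = cfg$decrements,
                               set = cfg$settings, eff = cfg$effectiveness)
  changed <- function(sc) {
    cfg <- apply_scenario(med_cfg, sc)
    f <- fields(cfg); b <- fields(base)
    names(which(!vapply(names(f), function(nm)
      identical(f[[nm]], b[[nm]]), TRUE)))
  }
  expect_equal(changed("SA1"), "set")    # sigma inflation only
  expect_equal(changed("SA2"), "prob")
  expect_equal(changed("SA3"), "prob")
  expect_equal(changed("SA4"), "prob")
  expect_equal(changed("SA5"), "prob")
  expect_equal(changed("SA8"), "set")
  expect_equal(changed("SA11"), "set")
  expect_equal(changed("SA12"), "set")
  # equipment repricing touches only arm costs
  sa6 <- apply_scenario(med_cfg, "SA6")
  expect_equal(sa6$arms$offer_cost[3], 2 * 2.65)
  expect_equal(sa6$arms$offer_cost[2], 3.67)
  expect_identical(sa6$prob, med_cfg$prob)
  sa7 <- apply_scenario(med_cfg, "SA7")
  expect_equal(sa7$arms$offer_cost[3], 2 * 4.80)
  expect_error(apply_scenario(med_cfg, "SA99"), "unknown scenario")
})

test_that("scenario parameter values match their definitions", {
  expect_equal(dist_mean(apply_scenario(med_cfg, "SA2")$prob$pSafe), 0.93)
  expect_equal(dist_mean(apply_scenario(med_cfg, "SA3")$prob$pSafe), 0.50)
  expect_equal(dist_mean(apply_scenario(med_cfg, "SA4")$prob$pAccept), 0.50)
  sa5 <- apply_scenario(med_cfg, "SA5")$prob$pAdmit
  expect_equal(dist_mean(sa5), 0.833)
  cv <- function(sp) with(sp$params, sqrt((shape2 / shape1) /
                                            (shape1 + shape2 + 1)))
  expect_equal(cv(sa5), cv(med_cfg$prob$pAdmit))
  # incidence recomputation from 44.9 / 10,000 with the 0.6 share
  sa9 <- apply_scenario(med_cfg, "SA9")
  expect_equal(sa9$derived$numerator, round(round(44.9 * 3996400 / 1e4) * 0.6))
  expect_equal(dist_mean(sa9$prob$pIngest),
               sa9$derived$numerator / 3996400)
  expect_identical(sa9$prob$pAdmit, med_cfg$prob$pAdmit)
})

test_that("children-per-household multiplier scales per draw exactly", {
  sa8 <- run_psa(med_cfg, 200, seed = 123, scenario = "SA8")
  expect_equal(sa8$cases, 1.8 * psa_a$cases)
  expect_equal(sa8$qalys, 1.8 * psa_a$qalys)
  expect_identical(sa8$cost_intervention, psa_a$cost_intervention)
  expect_equal(sa8$cost_cea - sa8$cost_intervention,
               1.8 * (psa_a$cost_cea - psa_a$cost_intervention))
})

test_that("utility-decrement scenarios rescale the sampling SE", {
  set.seed(77)
  d11 <- sample_parameters(apply_scenario(med_cfg, "SA11"), 5000)
  set.seed(77)
  d0 <- sample_parameters(med_cfg, 5000)
  expect_equal(sd(d11$uMinor) / sd(d0$uMinor), 2, tolerance = 0.1)
  expect_equal(mean(d11$uMinor), mean(d0$uMinor), tolerance = 0.002)
})

test_that("common random numbers make paired increments tight", {
  d_paired <- psa_a$cases[, 1] - psa_a$cases[, 2]
  set.seed(8)
  d_unpaired <- psa_a$cases[, 1] - sample(psa_a$cases[, 2])
  expect_lt(sd(d_paired), 0.5 * sd(d_unpaired))
})

test_that("probabilities sampled in the PSA respect their support", {
  pcols <- c("pSafe", "pAccept", "pIngest", "pAdmit", "pSevere", "pFatal",
             paste0("pEff", 1:7))
  for (cn in pcols)
    expect_true(all(psa_a$draws[[cn]] >= 0 & psa_a$draws[[cn]] <= 1),
                info = cn)
  for (cn in c("cAmb", "cED1", "cED2", "cAdmit1", "cAdmit2", "cChro"))
    expect_true(all(psa_a$draws[[cn]] > 0), info = cn)
})
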