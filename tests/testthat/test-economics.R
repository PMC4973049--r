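test_that("discount factor is the standard present-value weight", {
  expect_equal(discount_factor(0.035, 0), 1)
  expect_equal(round(discount_factor(0.035, 1), 5), 0.96618)
  expect_equal(discount_factor(0, 17), 1)
  expect_error(discount_factor(-0.01, 1), "negative discount")
  expect_error(discount_factor(0.035, -1), "negative time")
})

test_that("incremental analysis reproduces ratio-of-means ICERs", {
  arms <- data.frame(arm = 1:2, label = c("UC", "E"),
                     effect = c(0, 0.453), cost = c(0, 1316))
  tab <- incremental_analysis(arms)
  expect_equal(round(tab$icer_ref[tab$label == "E"]), 2905)
  expect_equal(tab$dominance, c("", ""))
})

test_that("strict and extended dominance are classified correctly", {
  # equal effect, higher cost: strictly dominated
  arms <- data.frame(arm = 1:3, label = c("a", "b", "c"),
                     effect = c(0, 1, 1), cost = c(0, 10, 12))
  tab <- incremental_analysis(arms)
  expect_equal(tab$dominance[tab$label == "c"], "dominated")
  expect_true(is.na(tab$icer_ref[tab$label == "c"]))

  # convexity violation: middle arm extendedly dominated
  arms4 <- data.frame(arm = 1:4, label = letters[1:4],
                      effect = c(0, 1, 2, 3), cost = c(0, 10, 40, 45))
  tab4 <- incremental_analysis(arms4)
  expect_equal(tab4$dominance[tab4$label == "c"], "ext dominated")
  expect_equal(oracle_dominance(arms4$effect, arms4$cost)[3],
               "ext dominated")

  # frontier ICERs are non-decreasing
  front <- tab4[tab4$dominance == "", ]
  expect_true(all(diff(front$icer_frontier[-1]) >= 0 |
                    is.na(diff(front$icer_frontier[-1]))))

  # tie tolerance: near-equal effects, tie broken by lower cost
  armst <- data.frame(arm = 1:2, label = c("a", "b"),
                      effect = c(1, 1.0004), cost = c(5, 9))
  expect_equal(incremental_analysis(armst)$dominance, c("", ""))
  tt <- incremental_analysis(armst, effect_tol = 1e-3)
  expect_equal(tt$dominance[tt$label == "b"], "dominated")
})

test_that("dominance classification agrees with the frontier oracle", {
  set.seed(55)
  for (rep in 1:60) {
    k <- sample(3:6, 1)
    arms <- data.frame(arm = seq_len(k), label = letters[seq_len(k)],
                       effect = runif(k, 0, 10), cost = runif(k, 0, 100))
    tab <- incremental_analysis(arms)
    tab <- tab[order(tab$arm), ]
    expect_equal(tab$dominance,
                 oracle_dominance(arms$effect, arms$cost),
                 info = paste("rep", rep))
    front <- incremental_analysis(arms)
    icers <- front$icer_frontier[front$dominance == ""]
    expect_true(all(diff(icers[-1]) >= -1e-9 | is.na(diff(icers[-1]))))
  }
})

# small synthetic PSA with known structure for CEAC / plane checks
fake_psa <- function(n = 500, seed = 9) {
  set.seed(seed)
  arms <- data.frame(arm = 1:3, label = c("A", "B", "C"),
                     education = FALSE, equipment = FALSE,
                     inspection = FALSE, fitting = FALSE,
                     offer_cost = c(0, 1, 2))
  # arm C strictly maximises effect (fewest cases) in every draw
  a <- rnorm(n, 6, 0.3)
  cases <- cbind(a, a - runif(n, 0.1, 1), a - runif(n, 1.2, 2))
  cost <- cbind(rnorm(n, 100, 5), rnorm(n, 500, 5), rnorm(n, 2000, 5))
  structure(list(cases = cases, cost_cea = cost, cost_cua = cost + 50,
                 qalys = -cases, draws = NULL,
                 arms = arms, variant = "toy", scenario = "base",
                 seed = seed, n_draws = n, point_estimate = FALSE),
            class = "psa_results")
}

test_that("CEAC probabilities sum to one and obey threshold limits", {
  psa <- fake_psa()
  cc <- ceac(psa, thresholds = c(0, 100, 1e4, 1e9))
  sums <- tapply(cc$probability, cc$threshold, sum)
  expect_equal(as.numeric(sums), rep(1, 4))
  # lambda = 0: the cheapest arm wins every draw
  expect_equal(cc$probability[cc$threshold == 0 & cc$label == "A"], 1)
  # lambda -> Inf: the arm strictly maximising effect in every draw wins
  expect_equal(cc$probability[cc$threshold == 1e9 & cc$label == "C"], 1)
})

test_that("CEAC splits exact ties equally", {
  psa <- fake_psa(n = 4)
  psa$cases <- matrix(c(5, 5, 5, 5), 4, 3)
  psa$cost_cea <- matrix(10, 4, 3)
  cc <- ceac(psa, thresholds = 30000)
  expect_equal(cc$probability, rep(1 / 3, 3))
})

test_that("CE plane preserves draw pairing against the reference", {
  psa <- fake_psa()
  pl <- ce_plane(psa)
  self <- pl[pl$label == "A", ]
  expect_true(all(self$d_effect == 0 & self$d_cost == 0))
  b <- pl[pl$label == "B", ]
  expect_equal(b$d_effect, psa$cases[, 1] - psa$cases[, 2])
  expect_equal(b$d_cost, psa$cost_cea[, 2] - psa$cost_cea[, 1])
  expect_error(ce_plane(psa, reference = 99), "reference arm")
})

test_that("ICER credible interval restricts to positive increments", {
  set.seed(2)
  d_e <- rnorm(1000, 0.5, 0.3); d_c <- rnorm(1000, 1000, 100)
  ci <- icer_credible_interval(d_c, d_e)
  expect_lt(ci["lower"], ci["upper"])
  expect_equal(unname(ci["prop_used"]), mean(d_e > 0))
  empty <- icer_credible_interval(1, -1)
  expect_true(is.na(empty["lower"]))
})
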