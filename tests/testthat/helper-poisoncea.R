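# shared fixtures: configs are loaded once per test run
med_cfg <- load_model_config("medicinal")
nonmed_cfg <- load_model_config("nonmedicinal")

# single-row parameter draw with overridable values, for deterministic
# cohort-model checks
toy_draws <- function(...) {
  d <- data.frame(
    pSafe = 0.75, pAccept = 0.9, pIngest = 0.001806, logOrIngest = -0.604,
    pAmb = 0.242, pAdmit = 0.63, pSevere = 0.0191, pFatal = 0.0116,
    cFixed = 79529, cAccept = 0.4, cAmb = 263, cED1 = 112, cED2 = 146,
    cAdmit1 = 586, cAdmit2 = 2461, cChro = 386.42, cFatal = 205.5,
    cGP = 43, uMinor = 0.03, uModerate = 0.046, uSevere = 0.146,
    uChronic = 0.1)
  for (i in 1:7) d[[paste0("pEff", i)]] <- c(0.87, 0.90, 0.93, 0.94,
                                             0.90, 0.90, 0.93)[i]
  over <- list(...)
  for (nm in names(over)) d[[nm]] <- over[[nm]]
  class(d) <- c("parameter_draws", "data.frame")
  d
}

# a config clone with modified settings, for discounting/horizon checks
with_settings <- function(cfg, ...) {
  over <- list(...)
  for (nm in names(over)) cfg$settings[[nm]] <- over[[nm]]
  cfg
}

# independent frontier oracle: walk the efficient frontier by repeatedly
# taking the minimum cost-per-effect slope among strictly more effective
# strategies (exact convex-hull construction, a different algorithm from
# the iterative-removal implementation under test)
oracle_frontier <- function(effect, cost) {
  n <- length(effect)
  start <- which(cost == min(cost))
  start <- start[which.max(effect[start])]
  frontier <- start
  repeat {
    i <- frontier[length(frontier)]
    cand <- which(effect > effect[i])
    if (!length(cand)) break
    slopes <- (cost[cand] - cost[i]) / (effect[cand] - effect[i])
    nxt <- cand[slopes == min(slopes)]
    nxt <- nxt[which.max(effect[nxt])]
    frontier <- c(frontier, nxt)
  }
  frontier
}

# oracle classification: strictly dominated / extendedly dominated / frontier
oracle_dominance <- function(effect, cost) {
  n <- length(effect)
  strict <- vapply(seq_len(n), function(i)
    any(cost[-i] <= cost[i] & effect[-i] >= effect[i] &
          (cost[-i] < cost[i] | effect[-i] > effect[i])), TRUE)
  frontier <- oracle_frontier(effect, cost)
  out <- rep("ext dominated", n)
  out[strict] <- "dominated"
  out[frontier] <- ""
  out
}
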