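test_that("the generator is deterministic and leaves no RNG state behind", {
  cfg <- generator_config(seed = 11)
  b1 <- generate_basin(cfg)
  set.seed(999)           # unrelated global state must not leak in
  r_before <- .Random.seed
  b2 <- generate_basin(cfg)
  expect_identical(.Random.seed, r_before)
  expect_equal(b1$network$reaches, b2$network$reaches)
  expect_equal(b1$districts, b2$districts)
  expect_equal(b1$cities, b2$cities)
  # byte-identical instance files
  d1 <- file.path(tempdir(), "inst_a"); d2 <- file.path(tempdir(), "inst_b")
  write_basin(b1, d1); write_basin(b2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("generated instances respect the configured parameter ranges", {
  cfg <- generator_config(seed = 3, n_reaches = 20, n_districts = 6,
                          n_cities = 3)
  bas <- generate_basin(cfg)
  r <- bas$network$reaches
  expect_equal(nrow(r), 20)
  expect_true(all(r$beta < 0))
  expect_true(all(r$beta >= -16.39 - 1e-9 & r$beta <= -0.10 + 1e-9))
  expect_true(all(r$valuation_tier %in% c("low", "medium", "high")))
  expect_equal(sum(r$local_inflow), 14600)
  expect_equal(length(bas$districts), 6)
  expect_equal(length(bas$cities), 3)
  # baseline acreage fits endowments (constructor enforces; spot check)
  for (d in bas$districts) {
    expect_lte(sum(d$activities$water_req * d$activities$observed_acreage),
               d$water_endowment + 1e-9)
  }
  expect_error(generator_config(beta_range = c(-1, 1)), "negative")
  expect_error(generator_config(tier_probabilities = c(low = 1, high = 1)),
               "sum to 1")
})

test_that("generated instances stay feasible from normal weather to 0.4", {
  for (seed in c(4, 9, 21)) {
    bas <- generate_basin(generator_config(seed = seed))
    for (lev in c(0, 0.3, 0.4)) {
      st <- propagate_flows(apply_drought(bas$network, lev),
                            basinopt:::instance_diversions(bas,
                                                           scale = 1 - lev),
                            check = FALSE)
      expect_gte(min(st$wout), -1e-6)
      mouth <- st$wout[st$reach_id == bas$network$mouth]
      minf <- bas$network$reaches$min_env_flow[
        bas$network$reaches$reach_id == bas$network$mouth]
      expect_gte(mouth, minf - 1e-6)
    }
  }
})

test_that("calibrate-then-solve reproduces a generated baseline", {
  bas <- calibrate_basin(generate_basin(generator_config(seed = 7)))
  sol <- solve_policy(bas, "ic", 0)
  obs <- unlist(lapply(bas$districts, function(d)
    d$activities$observed_acreage))
  expect_equal(unname(unlist(sol$acreage)), unname(obs), tolerance = 1e-6)
})

test_that("synthetic WUA observations lie on the curve when noiseless", {
  obs <- generate_wua_observations(-9.65, n = 33, noise_sd = 0, seed = 5)
  expect_equal(nrow(obs), 33)
  expect_true(all(diff(obs$flow) > 0))
  expect_equal(obs$wua, 1 - exp(-9.65 * obs$flow), tolerance = 1e-12)
  expect_true(all(obs$wua >= 0.05 - 1e-9 & obs$wua <= 0.95 + 1e-9))
  noisy <- generate_wua_observations(-9.65, n = 33, noise_sd = 0.05,
                                     seed = 5)
  expect_true(all(noisy$wua >= 0 & noisy$wua <= 1))
  expect_equal(fit_beta(noisy)$beta, -9.65, tolerance = 0.2)
})

test_that("the toy fixture carries the study's printed anchors", {
  bas <- toy_ebro()
  r <- bas$network$reaches
  expect_equal(nrow(r), 14)
  want <- c(`202` = -9.65, `264` = -2.07, `274` = -1.42, `406` = -16.39,
            `418` = -1.89, `421` = -0.12, `426` = -0.52, `428` = -0.30,
            `433` = -0.10, `441` = -8.14, `446` = -1.96, `455` = -9.61,
            `463` = -0.23, `662` = -0.26)
  expect_equal(unname(want[r$reach_id]), r$beta)
  expect_equal(sum(r$local_inflow), 14600)
  expect_equal(sum(r$length_km), 8900)
  mouth <- r[r$reach_id == bas$network$mouth, ]
  expect_equal(mouth$min_env_flow, 3000)
  expect_equal(mouth$min_env_flow_drought, 3000)
  cp <- r[r$min_env_flow > 0, ]
  expect_setequal(cp$reach_id, c("264", "421", "428"))
  expect_equal(cp$min_env_flow[cp$reach_id == "264"], 300)
  expect_equal(cp$min_env_flow[cp$reach_id == "421"], 945)
  expect_equal(cp$min_env_flow_drought[cp$reach_id == "421"], 640)
  # urban withdrawals are 402 Mm3 and constant across policies
  bc <- calibrate_basin(bas)
  s1 <- solve_policy(bc, "ic", 0.4)
  s2 <- solve_policy(bc, "ewm", 0.4)
  expect_equal(sum(s1$urban$volume), 402, tolerance = 1e-9)
  expect_equal(s1$ledger$urban, s2$ledger$urban)
  expect_equal(s1$ledger$urban, 1857, tolerance = 1e-9)
})
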