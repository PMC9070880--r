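test_that("drought scaling reduces every inflow proportionally", {
  bas <- toy_ebro()
  expect_equal(sum(bas$network$reaches$local_inflow), 14600)
  expect_equal(sum(apply_drought(bas$network, 0.4)$reaches$local_inflow),
               8760)
  expect_equal(sum(apply_drought(bas$network, 0.3)$reaches$local_inflow),
               10220)
  expect_equal(apply_drought(bas$network, 0), bas$network)
  expect_equal(apply_drought(c(100, 50), 0.4), c(60, 30))
  expect_error(apply_drought(bas$network, 1), "reduction")
})

test_that("policy regimes assemble the right caps and objectives", {
  bas <- oracle_basin()   # coefficients supplied directly
  alloc <- baseline_allocations(bas)
  ic <- build_policy_constraints(bas, "ic", 0.4)
  caps <- ic$b[grepl("^cap\\.", rownames(ic$A))]
  expect_equal(unname(caps), unname(alloc * 0.6))
  wm <- build_policy_constraints(bas, "wm", 0.4)
  pooled <- wm$b[rownames(wm$A) == "cap.pooled"]
  expect_equal(unname(pooled), sum(alloc) * 0.6)
  expect_equal(sum(grepl("^cap\\.", rownames(wm$A))), 1)
  # environmental policies add the reach-benefit term to the objective
  x <- rep(5, ncol(ic$A))
  eic <- build_policy_constraints(bas, "eic", 0.4)
  expect_equal(eic$fn(x) - ic$fn(x), eic$env_value(x), tolerance = 1e-9)
  expect_gt(eic$env_value(x), 0)
  expect_false(ic$include_env)
  expect_error(build_policy_constraints(bas, "zz", 0.4), "unknown policy")
  # long policy names are accepted
  expect_equal(build_policy_constraints(bas, "water_markets", 0.4)$policy,
               "wm")
})

test_that("the optimizer matches a brute-force grid on a small basin", {
  bas <- oracle_basin()   # one activity per district, coefficients given
  sol <- solve_policy(bas, "wm", 0.4)
  # hand-derived program: maximize
  #   (10 - 2)x1 - 0.08 x1^2 + (8 - 1)x2 - 0.12 x2^2
  # subject to (flows worked out from the chain by hand):
  #   pooled cap      1.5 x1 + x2 <= 0.6 (1.5*30 + 25) = 42
  #   node d1         1.5 x1 <= Win_r1 = 0.6*120 = 72
  #   node d2         x2 <= Win_r2 = (72 - 1.5 x1) + 0.2*1.5 x1 + 12
  #   outflows        Wout_r2 = Win_r2 - x2 >= 0 etc.
  obj <- function(x1, x2) 8 * x1 - 0.08 * x1^2 + 7 * x2 - 0.12 * x2^2
  feasible <- function(x1, x2) {
    win2 <- 84 - 1.2 * x1
    1.5 * x1 + x2 <= 42 & 1.5 * x1 <= 72 & x2 <= win2 & win2 - x2 >= 0
  }
  best <- grid_optimum_2d(obj, feasible, upper = c(30, 42), step = 0.02)
  fine <- grid_optimum_2d(obj, feasible,
                          lower = pmax(best$x - 0.05, 0),
                          upper = best$x + 0.05, step = 1e-3)
  oracle <- max(best$value, fine$value)
  expect_equal(sol$objective, oracle, tolerance = 1e-3)
  expect_gte(sol$objective, oracle - 1e-6)
  # the market exchange equals the gap between caps and chosen withdrawals
  ex <- compute_exchanges(sol)
  expect_equal(sum(ex$volume), sum(pmax(sol$caps - sol$withdrawals, 0)),
               tolerance = 1e-5)
})

test_that("zero drought under institutional cooperation is a fixed point", {
  bas <- calibrate_basin(toy_ebro())
  sol <- solve_policy(bas, "ic", 0)
  obs <- unlist(lapply(bas$districts, function(d)
    d$activities$observed_acreage))
  expect_equal(unname(unlist(sol$acreage)), unname(obs), tolerance = 1e-6)
  expect_equal(sol$ledger$irrigation_crop, 629, tolerance = 1e-6)
  expect_equal(sol$ledger$urban, 1857, tolerance = 1e-6)
  mouth <- sol$flows$wout[sol$flows$reach_id == bas$network$mouth]
  expect_equal(mouth, 8895, tolerance = 1e-4)
})

test_that("welfare orderings follow the nested feasible sets", {
  for (seed in 1:12) {
    bas <- calibrate_basin(generate_basin(generator_config(seed = seed)))
    sic <- solve_policy(bas, "ic", 0.4)
    seic <- solve_policy(bas, "eic", 0.4)
    swm <- solve_policy(bas, "wm", 0.4)
    sewm <- solve_policy(bas, "ewm", 0.4)
    expect_gte(seic$ledger$social, sic$ledger$social - 1e-5)
    expect_gte(sewm$ledger$social, swm$ledger$social - 1e-5)
    expect_gte(swm$ledger$private, sic$ledger$private - 1e-5)
    # urban supply is guaranteed: identical urban ledger in all policies
    urb <- vapply(list(sic, seic, swm, sewm), function(s)
      s$ledger$urban, numeric(1))
    expect_equal(max(urb) - min(urb), 0, tolerance = 1e-9)
    # feasibility of every returned solution
    for (s in list(sic, seic, swm, sewm)) {
      expect_equal(nrow(check_min_flows(s$flows, bas$network,
                                        drought = TRUE)), 0)
      expect_true(all(s$flows$wout >= 0))
    }
  }
})

test_that("social benefits weakly decrease with drought severity", {
  bas <- calibrate_basin(generate_basin(generator_config(seed = 1)))
  soc <- vapply(c(0, 0.2, 0.3, 0.4), function(r)
    solve_policy(bas, "ic", r)$ledger$social, numeric(1))
  expect_true(all(diff(soc) <= 1e-6))
})

test_that("exchange bookkeeping balances sellers, buyers and payments", {
  bas <- calibrate_basin(toy_ebro())
  sic <- solve_policy(bas, "ic", 0.4)
  expect_equal(nrow(compute_exchanges(sic)), 0)
  swm <- solve_policy(bas, "wm", 0.4)
  ex <- compute_exchanges(swm)
  net_pos <- swm$caps - swm$withdrawals
  sold <- tapply(ex$volume, ex$seller, sum)
  bought <- tapply(ex$volume, ex$buyer, sum)
  for (id in names(sold))
    expect_equal(unname(sold[id]), unname(net_pos[id]), tolerance = 1e-4)
  for (id in setdiff(names(bought), "environment"))
    expect_equal(unname(bought[id]), unname(-net_pos[id]), tolerance = 1e-4)
  expect_equal(sum(ex$volume[ex$buyer != "environment"]),
               sum(sold) - sum(ex$volume[ex$buyer == "environment"]),
               tolerance = 1e-6)
  # pooled trades clear at one scarcity price
  expect_equal(length(unique(ex$price)), 1)
  expect_gt(ex$price[1], 0)
  # transfers are neutral for social benefit
  sewm <- solve_policy(bas, "ewm", 0.4)
  l <- sewm$ledger
  expect_equal(l$social, l$irrigation_crop + l$urban + l$environmental,
               tolerance = 1e-9)
  expect_equal(l$irrigation_total - l$irrigation_crop,
               l$public_expenditure, tolerance = 1e-9)
  # market exchanges equal the withdrawal gap to the per-district solution
  gap <- sum(pmax(swm$caps - swm$withdrawals, 0))
  expect_equal(sum(ex$volume), gap, tolerance = 1e-4)
})

test_that("environmental purchases are priced at marginal water values", {
  bas <- calibrate_basin(toy_ebro())
  seic <- solve_policy(bas, "eic", 0.4)
  ex <- compute_exchanges(seic)
  expect_gt(nrow(ex), 0)
  expect_true(all(ex$buyer == "environment"))
  for (i in seq_len(nrow(ex))) {
    d <- bas$districts[[ex$seller[i]]]
    marg <- district_optimize(
      d, water_available = seic$withdrawals[[ex$seller[i]]])$duals["water"]
    expect_equal(ex$price[i], unname(marg), tolerance = 1e-6)
  }
  expect_equal(seic$ledger$public_expenditure, sum(ex$payment),
               tolerance = 1e-9)
})

test_that("a dry basin yields the all-zero plan instead of an error", {
  net <- chain_net(n = 2, inflow = c(0, 0))
  d <- simple_district(observed = 5, water_req = 2, withdraw = "r1",
                       ret = "r2")
  bas <- basin(net, list(d))
  sol <- solve_policy(bas, "ic", 0)
  expect_equal(unname(unlist(sol$acreage)), 0, tolerance = 1e-6)
  expect_equal(sol$ledger$social, 0, tolerance = 1e-6)
})
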