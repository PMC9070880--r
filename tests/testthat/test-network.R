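test_that("reach mass balance subtracts losses and diversions", {
  expect_equal(mass_balance_outflow(100, loss = 5, div_ir = 60,
                                    div_urb = 10), 25)
  expect_equal(mass_balance_outflow(50), 50)
  expect_error(mass_balance_outflow(20, loss = 5, div_ir = 30,
                                    reach_id = "r7"),
               "infeasible.*r7")
})

test_that("flow continuity routes outflow, returns and tributary inflow", {
  net <- two_reach_net(r_ir = 0.25, ro2 = 10)
  div <- data.frame(unit_id = "d1", unit_type = "district",
                    withdraw_reach = "r1", return_reach = "r2",
                    volume = 40, stringsAsFactors = FALSE)
  st <- propagate_flows(net, div)
  # Wout_1 = 100 - 40 = 60; Win_2 = 60 + 0.25*40 + 10 = 80
  expect_equal(st$win[st$reach_id == "r2"], 80)
  # no diversions: mouth outflow = total inflow - total losses
  st0 <- propagate_flows(net)
  expect_equal(st0$wout[st0$reach_id == "r2"], 110)
  # zero return coefficient: Win_{d+1} = Wout_d + RO_{d+1}
  net0 <- two_reach_net(r_ir = 0, ro2 = 10)
  st1 <- propagate_flows(net0, div)
  expect_equal(st1$win[st1$reach_id == "r2"], 70)
  expect_error(propagate_flows(net, transform(div, withdraw_reach = "zz")),
               "unknown reach")
})

test_that("basin-scale conservation holds for generated instances", {
  for (seed in 1:5) {
    bas <- generate_basin(generator_config(seed = seed, n_districts = 4))
    div <- basinopt:::instance_diversions(bas)
    st <- propagate_flows(bas$network, div)
    r <- bas$network$reaches
    consumptive <- sum((1 - r$r_ir[match(div$withdraw_reach[
      div$unit_type == "district"], r$reach_id)]) *
        div$volume[div$unit_type == "district"]) +
      sum((1 - r$r_urb[match(div$withdraw_reach[div$unit_type == "city"],
                             r$reach_id)]) *
            div$volume[div$unit_type == "city"])
    mouth <- st$wout[st$reach_id == bas$network$mouth]
    expect_equal(mouth, sum(r$local_inflow) - sum(r$loss) - consumptive,
                 tolerance = 1e-9)
    # idempotence: re-propagating the same diversions reproduces the state
    expect_equal(propagate_flows(bas$network, div), st)
  }
})

test_that("minimum-flow checks report each violated control point", {
  net <- chain_net(n = 2, inflow = c(8895, 0),
                   min_env_flow = c(0, 3000))
  st <- propagate_flows(net)
  expect_equal(nrow(check_min_flows(st, net)), 0)
  net2 <- chain_net(n = 2, inflow = c(2999, 0), min_env_flow = c(0, 3000))
  v <- check_min_flows(propagate_flows(net2), net2)
  expect_equal(v$reach_id, "r2")
  expect_equal(v$deficit, 1)
  # several control points: one row per shortfall
  net3 <- chain_net(n = 3, inflow = c(500, 100, 50),
                    min_env_flow = c(300, 640, 3000))
  v3 <- check_min_flows(propagate_flows(net3), net3)
  expect_equal(v3$reach_id, c("r2", "r3"))
})

test_that("closure calibration reproduces gauges with minimal-norm terms", {
  net <- chain_net(n = 3, inflow = c(100, 50, 20))
  # already calibrated: zero closures
  st <- propagate_flows(net)
  cal0 <- calibrate_closure(net, data.frame(reach_id = c("r1", "r3"),
                                            wout = st$wout[c(1, 3)]))
  expect_equal(cal0$reaches$closure, rep(0, 3), tolerance = 1e-9)
  # headwater gauge 10 above the model: one unknown on the path
  cal1 <- calibrate_closure(net, data.frame(reach_id = "r1",
                                            wout = st$wout[1] + 10))
  expect_equal(cal1$reaches$closure[cal1$reaches$reach_id == "r1"], 10,
               tolerance = 1e-9)
  st1 <- propagate_flows(cal1)
  expect_equal(st1$wout[1], st$wout[1] + 10, tolerance = 1e-9)
  # two gauges on one chain: compare with the explicit least-norm solution
  obs <- data.frame(reach_id = c("r2", "r3"),
                    wout = st$wout[2:3] + c(8, -5))
  cal2 <- calibrate_closure(net, obs)
  M <- rbind(c(1, 1, 0), c(1, 1, 1))     # reach at-or-upstream of gauge
  resid <- c(8, -5)
  oracle <- drop(t(M) %*% solve(M %*% t(M), resid))
  expect_equal(cal2$reaches$closure, oracle, tolerance = 1e-8)
  st2 <- propagate_flows(cal2)
  expect_equal(st2$wout[2:3], obs$wout, tolerance = 1e-8)
})

test_that("network validation rejects cycles and malformed trees", {
  bad <- data.frame(reach_id = c("a", "b"), downstream_id = c("b", "a"),
                    length_km = 1, local_inflow = 1, loss = 0, r_ir = 0.2,
                    r_urb = 0.8, min_env_flow = 0, beta = -1,
                    valuation_tier = "low", stringsAsFactors = FALSE)
  expect_error(river_network(bad), "mouth|cycle")
  two_mouths <- data.frame(reach_id = c("a", "b"),
                           downstream_id = c(NA, NA), length_km = 1,
                           local_inflow = 1, loss = 0, r_ir = 0.2,
                           r_urb = 0.8, min_env_flow = 0, beta = -1,
                           valuation_tier = "low", stringsAsFactors = FALSE)
  expect_error(river_network(two_mouths), "exactly one")
  pos_beta <- two_mouths
  pos_beta$downstream_id <- c("b", NA)
  pos_beta$beta <- c(0.5, -1)
  expect_error(river_network(pos_beta), "negative")
})
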