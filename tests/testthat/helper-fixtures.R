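# Shared fixtures: small networks, districts and basins built in code, plus
# brute-force oracles used to cross-check the optimizer.

two_reach_net <- function(r_ir = 0.25, ro2 = 10) {
  river_network(data.frame(
    reach_id = c("r1", "r2"), downstream_id = c("r2", NA),
    length_km = c(10, 10), local_inflow = c(100, ro2), loss = c(0, 0),
    r_ir = r_ir, r_urb = 0.8, min_env_flow = 0, beta = -1,
    valuation_tier = "low", stringsAsFactors = FALSE))
}

chain_net <- function(n = 4, inflow = rep(100, n), loss = rep(0, n),
                      min_env_flow = rep(0, n)) {
  river_network(data.frame(
    reach_id = paste0("r", seq_len(n)),
    downstream_id = c(paste0("r", seq_len(n)[-1]), NA),
    length_km = 10, local_inflow = inflow, loss = loss,
    r_ir = 0.2, r_urb = 0.8, min_env_flow = min_env_flow,
    beta = -0.5, valuation_tier = "low", stringsAsFactors = FALSE))
}

# one-activity district with given calibrated yield coefficients
simple_district <- function(id = "d1", price = 1, cost = 2, b0 = 10,
                            b1 = -0.5, water_req = 1, labor_req = 0,
                            observed = 8, land = 1000, water = 1000,
                            labor = 1000, withdraw = "r1", ret = "r2") {
  irrigation_district(
    id, data.frame(crop_id = "c", tech = "flood", price = price,
                   cost = cost, water_req = water_req,
                   labor_req = labor_req, observed_acreage = observed,
                   yield_intercept = b0, yield_slope = b1,
                   stringsAsFactors = FALSE),
    land_by_tech = list(flood = land), water_endowment = water,
    labor_endowment = labor, withdraw_reach = withdraw, return_reach = ret)
}

# random PMP-calibratable district: positive margins, slack endowments
random_district <- function(id, seed, withdraw = "r1", ret = "r2") {
  set.seed(seed)
  n <- sample(2:4, 1)
  tech <- sample(c("flood", "sprinkler", "drip"), n, replace = TRUE)
  a <- data.frame(
    crop_id = paste0("c", seq_len(n)), tech = tech,
    price = runif(n, 0.1, 0.6), cost = runif(n, 0.3, 2),
    water_req = runif(n, 4, 14), labor_req = runif(n, 1, 30),
    observed_acreage = runif(n, 5, 80), stringsAsFactors = FALSE)
  a$avg_yield <- (a$cost + runif(n, 0.3, 3)) / a$price  # margin > 0
  land <- tapply(a$observed_acreage, a$tech, sum) * runif(1, 1.2, 1.5)
  irrigation_district(
    id, a, land_by_tech = as.list(land),
    water_endowment = sum(a$water_req * a$observed_acreage) * 1.2,
    labor_endowment = sum(a$labor_req * a$observed_acreage) * 1.2,
    withdraw_reach = withdraw, return_reach = ret)
}

# brute-force 1-D maximizer of district profit for a single activity
grid_optimum_1d <- function(price, cost, b0, b1, upper, step = 1e-3) {
  x <- seq(0, upper, by = step)
  f <- (price * (b0 + b1 * x) - cost) * x
  i <- which.max(f)
  list(x = x[i], value = f[i])
}

# brute-force maximizer over a 2-D acreage grid; obj and feasible are
# vectorized over (x1, x2)
grid_optimum_2d <- function(obj, feasible, lower = c(0, 0), upper, step) {
  g <- expand.grid(x1 = seq(lower[1], upper[1], by = step),
                   x2 = seq(lower[2], upper[2], by = step))
  ok <- feasible(g$x1, g$x2)
  v <- ifelse(ok, obj(g$x1, g$x2), -Inf)
  i <- which.max(v)
  list(x = c(g$x1[i], g$x2[i]), value = v[i])
}

# small two-district basin used for solver-vs-grid comparisons
oracle_basin <- function() {
  net <- chain_net(n = 3, inflow = c(120, 20, 10))
  d1 <- simple_district("d1", price = 1, cost = 2, b0 = 10, b1 = -0.08,
                        water_req = 1.5, observed = 30, withdraw = "r1",
                        ret = "r2")
  d2 <- simple_district("d2", price = 1, cost = 1, b0 = 8, b1 = -0.12,
                        water_req = 1.0, observed = 25, withdraw = "r2",
                        ret = "r3")
  basin(net, list(d1, d2))
}
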