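test_that("net income per hectare follows the declining linear yield", {
  a <- list(price = 1, cost = 2, yield_intercept = 10, yield_slope = -0.1)
  expect_equal(net_income_per_ha(a, 40), 4)   # 1*(10-4) - 2
  flat <- list(price = 1, cost = 2, yield_intercept = 10, yield_slope = 0)
  expect_equal(net_income_per_ha(flat, 0), 8)
  expect_equal(net_income_per_ha(flat, 500), 8)
  expect_equal(net_income_per_ha(a, 0), 8)    # first-hectare margin
  expect_error(net_income_per_ha(a, -1), ">= 0")
})

test_that("district optimum matches the closed form and a grid search", {
  d <- simple_district(price = 1, cost = 2, b0 = 10, b1 = -0.5)
  o <- district_optimize(d)
  # interior optimum of (P*b0 - CP)x + P*b1*x^2: x* = 8, profit 32
  expect_equal(unname(o$acreage), 8, tolerance = 1e-6)
  expect_equal(o$profit, 32, tolerance = 1e-8)
  g <- grid_optimum_1d(1, 2, 10, -0.5, upper = 20)
  expect_equal(o$profit, g$value, tolerance = 1e-6)
  # no water: all water-using acreage shut down
  o0 <- district_optimize(d, water_available = 0)
  expect_equal(unname(o0$acreage), 0, tolerance = 1e-8)
  expect_equal(o0$profit, 0, tolerance = 1e-8)
})

test_that("competing activities equalize marginal profit per unit water", {
  d <- irrigation_district(
    "d2", data.frame(crop_id = c("a", "b"), tech = "flood",
                     price = c(1, 1), cost = c(1, 2),
                     water_req = c(2, 1), labor_req = 0,
                     observed_acreage = c(5, 10),
                     yield_intercept = c(9, 10), yield_slope = c(-0.2, -0.3),
                     stringsAsFactors = FALSE),
    land_by_tech = list(flood = 100), water_endowment = 25,
    labor_endowment = 100, withdraw_reach = "r1")
  o <- district_optimize(d)
  # brute force over the same feasible set
  obj <- function(x1, x2) (1 * (9 - 0.2 * x1) - 1) * x1 +
    (1 * (10 - 0.3 * x2) - 2) * x2
  g <- grid_optimum_2d(obj, function(x1, x2) 2 * x1 + x2 <= 25,
                       upper = c(12.5, 25), step = 0.005)
  expect_equal(o$profit, g$value, tolerance = 1e-3)
  expect_equal(sum(c(2, 1) * o$acreage), 25, tolerance = 1e-5) # cap binds
  # KKT: marginal profit per unit of water equal across active crops
  marg <- (c(1, 1) * (c(9, 10) + 2 * c(-0.2, -0.3) * o$acreage) -
             c(1, 2)) / c(2, 1)
  expect_equal(unname(marg[1]), unname(marg[2]), tolerance = 1e-4)
  expect_equal(unname(marg[1]), unname(o$duals["water"]), tolerance = 1e-4)
})

test_that("PMP calibration solves the worked two-condition example", {
  d <- irrigation_district(
    "d3", data.frame(crop_id = "c", tech = "flood", price = 1, cost = 2,
                     water_req = 1, labor_req = 1, observed_acreage = 40,
                     avg_yield = 6, stringsAsFactors = FALSE),
    land_by_tech = list(flood = 100), water_endowment = 100,
    labor_endowment = 100, withdraw_reach = "r1")
  dc <- pmp_calibrate(d)
  # no binding resource duals: mu = margin = 4; slope -mu/(P*X) = -0.1
  expect_equal(dc$activities$yield_slope, -0.1, tolerance = 1e-8)
  expect_equal(dc$activities$yield_intercept, 10, tolerance = 1e-7)
  expect_equal(unname(district_optimize(dc)$acreage), 40, tolerance = 1e-6)
})

test_that("a binding land constraint calibrates through the dual alone", {
  d <- irrigation_district(
    "d4", data.frame(crop_id = "c", tech = "flood", price = 1, cost = 2,
                     water_req = 1, labor_req = 1, observed_acreage = 40,
                     avg_yield = 6, stringsAsFactors = FALSE),
    land_by_tech = list(flood = 40), water_endowment = 100,
    labor_endowment = 100, withdraw_reach = "r1")
  dc <- pmp_calibrate(d)
  expect_equal(dc$activities$yield_slope, 0, tolerance = 1e-6)
  expect_true("c" %in% attr(dc, "pmp")$constraint_calibrated)
  expect_equal(unname(district_optimize(dc)$acreage), 40, tolerance = 1e-6)
})

test_that("calibration reproduces observed acreage on random districts", {
  worst <- 0
  for (s in 1:100) {
    d <- random_district(sprintf("rd%03d", s), seed = 5000 + s)
    dc <- pmp_calibrate(d)
    got <- district_optimize(dc)$acreage
    rel <- max(abs(got - d$activities$observed_acreage) /
                 d$activities$observed_acreage)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-6)
})

test_that("profit rises and the water dual falls with water availability", {
  d <- simple_district(price = 1, cost = 0.5, b0 = 8, b1 = -0.05,
                       water_req = 2)
  levels <- c(20, 60, 100, 140, 200)
  res <- lapply(levels, function(w) district_optimize(d, w))
  profits <- vapply(res, `[[`, numeric(1), "profit")
  duals <- vapply(res, function(r) unname(r$duals["water"]), numeric(1))
  expect_true(all(diff(profits) >= -1e-8))
  expect_true(all(diff(duals) <= 1e-6))
  # concavity: local optimum is global (matches 1-D grid at each level)
  g <- grid_optimum_1d(1, 0.5, 8, -0.05, upper = 10)  # water 20 -> x <= 10
  expect_equal(res[[1]]$profit, g$value, tolerance = 1e-5)
})
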