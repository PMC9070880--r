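#' Basin instances
#'
#' A basin bundles the river network, the irrigation districts, the cities
#' and the basin-wide water availability into one object that the policy
#' solver consumes.
#'
#' @param network a \code{\link{river_network}}.
#' @param districts list of \code{\link{irrigation_district}} objects.
#' @param cities list of \code{\link{city}} objects.
#' @param availability basin water availability (Mm3/yr) under normal
#'   weather; defaults to the total local inflow of the network.
#' @return object of class \code{basin}.
#' @export
basin <- function(network, districts, cities = list(), availability = NULL) {
  stopifnot(inherits(network, "river_network"))
  ids <- network$reaches$reach_id
  for (d in districts) {
    stopifnot(inherits(d, "irrigation_district"))
    if (!d$withdraw_reach %in% ids)
      stop("district ", d$id, " withdraws from unknown reach ",
           d$withdraw_reach)
    if (!is.na(d$return_reach) && !d$return_reach %in% ids)
      stop("district ", d$id, " returns to unknown reach ", d$return_reach)
  }
  for (u in cities) {
    stopifnot(inherits(u, "city"))
    if (!u$withdraw_reach %in% ids)
      stop("city ", u$id, " withdraws from unknown reach ", u$withdraw_reach)
  }
  if (is.null(availability))
    availability <- sum(network$reaches$local_inflow)
  names(districts) <- vapply(districts, `[[`, character(1), "id")
  names(cities) <- vapply(cities, `[[`, character(1), "id")
  structure(list(network = network, districts = districts, cities = cities,
                 availability = availability),
            class = "basin")
}

#' @export
print.basin <- function(x, ...) {
  cat("Basin:", nrow(x$network$reaches), "reaches,",
      length(x$districts), "districts,", length(x$cities), "cities\n")
  cat("  availability:", format(round(x$availability), big.mark = ","),
      "Mm3/yr\n")
  invisible(x)
}

#' Calibrate every district of a basin
#'
#' Runs \code{\link{pmp_calibrate}} on each irrigation district.
#'
#' @param basin a \code{basin}.
#' @param ... passed to \code{\link{pmp_calibrate}}.
#' @return the basin with calibrated districts.
#' @export
calibrate_basin <- function(basin, ...) {
  basin$districts <- lapply(basin$districts, pmp_calibrate, ...)
  basin
}

#' Scale inflows for a drought scenario
#'
#' Every local (tributary) inflow is scaled by \code{1 - reduction}; 0.4
#' corresponds to a severe drought and 0.3 to a moderate one.
#'
#' @param x a \code{river_network}, or a numeric vector of inflows.
#' @param reduction fraction in [0, 1).
#' @return object of the same type with scaled inflows.
#' @export
apply_drought <- function(x, reduction) {
  if (reduction < 0 || reduction >= 1)
    stop("reduction must lie in [0, 1)")
  if (inherits(x, "river_network")) {
    x$reaches$local_inflow <- x$reaches$local_inflow * (1 - reduction)
    x
  } else x * (1 - reduction)
}

#' Baseline irrigation allocations
#'
#' The water allocation of a district under normal weather: the water its
#' observed baseline acreage requires.
#'
#' @param basin a \code{basin}.
#' @return named vector of allocations (Mm3/yr).
#' @export
baseline_allocations <- function(basin) {
  vapply(basin$districts, function(d)
    sum(d$activities$water_req * d$activities$observed_acreage), numeric(1))
}

policy_codes <- c(ic = "institutional_cooperation",
                  eic = "environmental_institutional_cooperation",
                  wm = "water_markets",
                  ewm = "environmental_water_markets")

normalize_policy <- function(policy) {
  if (policy %in% names(policy_codes)) return(policy)
  hit <- names(policy_codes)[policy_codes == policy]
  if (length(hit) != 1L)
    stop("unknown policy '", policy, "'; use one of ",
         paste(names(policy_codes), collapse = ", "))
  hit
}

#' Assemble the constraint set and objective of a policy scenario
#'
#' Builds the concave program of a policy run: decision variables are the
#' district acreages, district withdrawals equal their crop water
#' requirements, and flows are affine in the withdrawals. Constraints are
#' equipped land and labor per district; the policy's water caps
#' (per-district caps equal to the drought-reduced baseline allocation under
#' the institutional policies, one pooled cap summing them under the market
#' policies); node feasibility (each withdrawal no larger than the inflow of
#' its reach); nonnegative reach outflows; minimum environmental flows at
#' the control points; and basin availability. The objective is private
#' benefit (crop profit plus the fixed urban surplus); the environmental
#' policies add the monetized reach benefits, which turns forgone
#' withdrawals into environmental purchases.
#'
#' @param basin a calibrated \code{basin}.
#' @param policy one of \code{"ic"}, \code{"eic"}, \code{"wm"},
#'   \code{"ewm"} (or the long policy names).
#' @param drought inflow reduction fraction in [0, 1).
#' @param tiers valuation tier values (M-euro/km).
#' @return list with the objective \code{fn}/\code{gr}, constraints
#'   \code{A}, \code{b} (named rows), variable metadata, the affine flow
#'   map and the fixed urban block; consumed by \code{\link{solve_policy}}.
#' @export
build_policy_constraints <- function(basin, policy, drought = 0,
                                     tiers = valuation_tiers()) {
  policy <- normalize_policy(policy)
  net <- apply_drought(basin$network, drought)
  reaches <- net$reaches
  n_reach <- nrow(reaches)
  districts <- basin$districts
  for (d in districts)
    if (!all(c("yield_intercept", "yield_slope") %in% names(d$activities)))
      stop("district ", d$id, " is not calibrated; run calibrate_basin first")

  # guaranteed urban block: priority supply fixed at the city optimum
  urban <- lapply(basin$cities, urban_optimize)
  urban_div <- if (length(basin$cities))
    data.frame(unit_id = names(basin$cities), unit_type = "city",
               withdraw_reach = vapply(basin$cities, `[[`, character(1),
                                       "withdraw_reach"),
               return_reach = vapply(basin$cities, function(u)
                 as.character(u$return_reach), character(1)),
               volume = vapply(urban, `[[`, numeric(1), "q"),
               stringsAsFactors = FALSE)
  else NULL
  urban_surplus_total <- sum(vapply(urban, `[[`, numeric(1), "surplus"))

  units <- data.frame(
    unit_id = names(districts), unit_type = "district",
    withdraw_reach = vapply(districts, `[[`, character(1), "withdraw_reach"),
    return_reach = vapply(districts, function(d)
      as.character(d$return_reach), character(1)),
    stringsAsFactors = FALSE)
  fmap <- flow_affine_map(net, units, fixed = urban_div)

  # variable layout: acreages of all districts, in district order
  sizes <- vapply(districts, function(d) nrow(d$activities), integer(1))
  n_x <- sum(sizes)
  offs <- cumsum(c(0L, sizes[-length(sizes)]))
  names(offs) <- names(districts)
  # withdrawal map: Div = G x
  G <- matrix(0, length(districts), n_x,
              dimnames = list(names(districts), NULL))
  lin <- quad <- numeric(n_x)
  for (i in seq_along(districts)) {
    d <- districts[[i]]
    j <- offs[i] + seq_len(sizes[i])
    G[i, j] <- d$activities$water_req
    tr <- district_profit_terms(d$activities)
    lin[j] <- tr$lin
    quad[j] <- tr$quad
  }
  WinX <- fmap$Dwin %*% G     # d win / d x
  WoutX <- fmap$Dwout %*% G   # d wout / d x

  A <- matrix(0, 0, n_x)
  b <- numeric(0)
  rn <- character(0)
  add_row <- function(row, rhs, name) {
    A <<- rbind(A, row); b <<- c(b, rhs); rn <<- c(rn, name)
  }
  # land and labor per district
  for (i in seq_along(districts)) {
    d <- districts[[i]]
    j <- offs[i] + seq_len(sizes[i])
    for (tech in intersect(c("flood", "sprinkler", "drip"),
                           unique(d$activities$tech))) {
      row <- numeric(n_x)
      row[j] <- as.numeric(d$activities$tech == tech)
      add_row(row, d$land_by_tech[[tech]],
              paste0("land.", d$id, ".", tech))
    }
    row <- numeric(n_x)
    row[j] <- d$activities$labor_req
    add_row(row, d$labor_endowment, paste0("labor.", d$id))
  }
  # policy water caps
  alloc <- baseline_allocations(basin)
  caps <- alloc * (1 - drought)
  if (policy %in% c("ic", "eic")) {
    for (i in seq_along(districts))
      add_row(G[i, ], caps[i], paste0("cap.", names(districts)[i]))
  } else {
    add_row(colSums(G), sum(caps), "cap.pooled")
  }
  # node feasibility: withdrawals cannot exceed reach inflow
  ridx <- stats::setNames(seq_len(n_reach), fmap$reach_id)
  for (i in seq_along(districts)) {
    w <- ridx[[units$withdraw_reach[i]]]
    add_row(G[i, ] - WinX[w, ], fmap$win0[w],
            paste0("node.", names(districts)[i]))
  }
  if (!is.null(urban_div)) for (i in seq_len(nrow(urban_div))) {
    w <- ridx[[urban_div$withdraw_reach[i]]]
    add_row(-WinX[w, ], fmap$win0[w] - urban_div$volume[i],
            paste0("node.", urban_div$unit_id[i]))
  }
  # nonnegative outflows everywhere; minimum flows at control points
  minf <- if (drought > 0) reaches$min_env_flow_drought
          else reaches$min_env_flow
  for (s in seq_len(n_reach)) {
    add_row(-WoutX[s, ], fmap$wout0[s], paste0("flow.", fmap$reach_id[s]))
    if (minf[s] > 0)
      add_row(-WoutX[s, ], fmap$wout0[s] - minf[s],
              paste0("minflow.", fmap$reach_id[s]))
  }
  # basin availability
  urban_q <- if (is.null(urban_div)) 0 else sum(urban_div$volume)
  add_row(colSums(G), basin$availability * (1 - drought) - urban_q,
          "availability")
  rownames(A) <- rn

  # environmental benefit term: concave in the outflows, affine in x
  vl <- unname(tiers[as.character(reaches$valuation_tier)]) *
    reaches$length_km
  ks <- reaches$beta * reaches$flow_scale
  # below zero flow (transiently visited by infeasible iterates; excluded by
  # the flow constraints at the optimum) the response is extended by its
  # tangent at zero, keeping the term concave and C1 everywhere
  env_value <- function(x) {
    wout <- fmap$wout0 + drop(WoutX %*% x)
    sum(vl * ifelse(wout >= 0, 1 - exp(ks * wout), -ks * wout))
  }
  env_grad <- function(x) {
    wout <- fmap$wout0 + drop(WoutX %*% x)
    f <- ifelse(wout >= 0, -vl * ks * exp(ks * wout), -vl * ks)
    drop(crossprod(WoutX, f))
  }
  include_env <- policy %in% c("eic", "ewm")
  fn <- function(x) {
    v <- sum(lin * x + quad * x^2)
    if (include_env) v <- v + env_value(x)
    v
  }
  gr <- function(x) {
    g <- lin + 2 * quad * x
    if (include_env) g <- g + env_grad(x)
    g
  }

  list(policy = policy, drought = drought, network = net,
       A = A, b = b, fn = fn, gr = gr,
       env_value = env_value, include_env = include_env,
       sizes = sizes, offsets = offs, G = G,
       fmap = fmap, WoutX = WoutX,
       allocations = alloc, caps = caps,
       urban_div = urban_div, urban_surplus = urban_surplus_total,
       tiers = tiers)
}

#' Solve a policy scenario
#'
#' Maximizes basin welfare under the chosen policy regime and drought level
#' (see \code{\link{build_policy_constraints}}) and returns the full
#' solution: the acreage plan, withdrawals, the propagated flow state, the
#' water exchanges and the benefit ledger. Payments for traded or purchased
#' water are transfers: they are reported in the ledger (trading income,
#' public expenditure) but social benefit is crop profit + urban surplus +
#' environmental benefit, which is invariant to the transfers. The start
#' point is the drought-scaled baseline acreage, so the solve is
#' deterministic.
#'
#' @param basin a calibrated \code{basin}.
#' @param policy \code{"ic"}, \code{"eic"}, \code{"wm"} or \code{"ewm"}.
#' @param drought inflow reduction fraction in [0, 1).
#' @param tiers valuation tier values (M-euro/km).
#' @param control solver control overrides (see \code{\link{al_maximize}}).
#' @return object of class \code{basin_solution}.
#' @export
solve_policy <- function(basin, policy = "ic", drought = 0,
                         tiers = valuation_tiers(), control = list()) {
  prob <- build_policy_constraints(basin, policy, drought, tiers)
  districts <- basin$districts

  # pre-flight: the guaranteed urban block and the mouth minimum must be
  # jointly satisfiable with irrigation shut off
  state0 <- propagate_flows(prob$network, prob$urban_div, check = FALSE)
  minf <- if (drought > 0) prob$network$reaches$min_env_flow_drought
          else prob$network$reaches$min_env_flow
  if (min(state0$wout) < -1e-6 ||
      any(state0$wout < minf - 1e-6))
    stop("infeasible scenario: urban priority and minimum flows cannot ",
         "be met even with zero irrigation withdrawals")

  x0 <- unlist(lapply(districts, function(d)
    d$activities$observed_acreage * (1 - drought)), use.names = FALSE)
  ctrl <- utils::modifyList(list(tol_feas = 1e-7, tol_x = 1e-8), control)
  sol <- al_maximize(prob$fn, prob$gr, prob$A, prob$b, x0 = x0,
                     lower = 0, control = ctrl)
  if (sol$max_violation > 1e-4) {
    worst <- which.max(drop(prob$A %*% sol$par) - prob$b)
    stop("solver failed to reach feasibility (violation ",
         signif(sol$max_violation, 4), " at constraint '",
         rownames(prob$A)[worst], "'); the scenario is likely infeasible")
  }
  duals <- stats::setNames(sol$duals, rownames(prob$A))

  # unpack the plan
  x <- sol$par
  acreage <- vector("list", length(districts))
  names(acreage) <- names(districts)
  crop_profit <- numeric(length(districts))
  for (i in seq_along(districts)) {
    d <- districts[[i]]
    j <- prob$offsets[i] + seq_len(prob$sizes[i])
    acreage[[i]] <- stats::setNames(
      x[j], paste(d$activities$crop_id, d$activities$tech, sep = "."))
    tr <- district_profit_terms(d$activities)
    crop_profit[i] <- sum(tr$lin * x[j] + tr$quad * x[j]^2)
  }
  names(crop_profit) <- names(districts)
  area_by_group <- local({
    acc <- numeric(0)
    for (i in seq_along(districts)) {
      a <- districts[[i]]$activities
      j <- prob$offsets[i] + seq_len(prob$sizes[i])
      g <- if ("group" %in% names(a)) as.character(a$group)
           else rep("all", nrow(a))
      for (k in seq_along(j))
        acc[g[k]] <- (if (g[k] %in% names(acc)) acc[[g[k]]] else 0) + x[j[k]]
    }
    acc
  })
  withdrawals <- drop(prob$G %*% x)
  names(withdrawals) <- names(districts)

  div <- data.frame(unit_id = names(districts), unit_type = "district",
                    withdraw_reach = vapply(districts, `[[`, character(1),
                                            "withdraw_reach"),
                    return_reach = vapply(districts, function(d)
                      as.character(d$return_reach), character(1)),
                    volume = pmax(withdrawals, 0),
                    stringsAsFactors = FALSE)
  all_div <- rbind(div, prob$urban_div)
  flows <- propagate_flows(prob$network, all_div, check = FALSE)
  flows$wout <- pmax(flows$wout, 0)  # clip solver-tolerance negatives

  env_by_reach <- vapply(seq_len(nrow(prob$network$reaches)), function(s)
    env_benefit(prob$network$reaches[s, ],
                flows$wout[match(prob$network$reaches$reach_id[s],
                                 flows$reach_id)], tiers),
    numeric(1))
  names(env_by_reach) <- prob$network$reaches$reach_id

  exchanges <- exchange_table(prob, districts, withdrawals, duals, control)
  env_sales <- sum(exchanges$payment[exchanges$buyer == "environment"])
  market_sales <- sum(exchanges$payment[exchanges$buyer != "environment"])

  ledger <- list(
    irrigation_crop = sum(crop_profit),
    irrigation_env_sales = env_sales,
    irrigation_market_sales = market_sales,
    irrigation_total = sum(crop_profit) + env_sales,
    urban = prob$urban_surplus,
    environmental = sum(env_by_reach),
    public_expenditure = env_sales)
  ledger$private <- ledger$irrigation_total + ledger$urban
  ledger$social <- ledger$irrigation_crop + ledger$urban +
    ledger$environmental

  structure(list(
    policy = prob$policy, drought = drought,
    acreage = acreage, area_by_group = area_by_group,
    crop_profit = crop_profit,
    withdrawals = withdrawals,
    allocations = prob$allocations, caps = prob$caps,
    urban = prob$urban_div, flows = flows,
    env_by_reach = env_by_reach, exchanges = exchanges,
    ledger = ledger, duals = duals,
    objective = sol$value,
    status = if (sol$converged) "optimal" else "not_converged",
    iterations = sol$iterations,
    network = prob$network),
    class = "basin_solution")
}

# Build the exchange table of a solved scenario. Sellers are districts
# withdrawing less than their cap, buyers withdraw more (market policies) or
# the environment absorbs the difference (environmental policies). Market
# trades are priced at the pooled water constraint's dual; environmental
# purchases under institutional cooperation at the seller's marginal profit
# of water. Sellers are matched to buyers in upstream-first (table) order,
# a reporting convention only.
exchange_table <- function(prob, districts, withdrawals, duals, control) {
  empty <- data.frame(seller = character(0), buyer = character(0),
                      volume = numeric(0), price = numeric(0),
                      payment = numeric(0), stringsAsFactors = FALSE)
  tol <- 1e-5
  net_pos <- prob$caps - withdrawals  # positive: seller
  if (prob$policy == "ic") return(empty)
  rows <- empty
  if (prob$policy == "eic") {
    price_of <- function(id) {
      d <- districts[[id]]
      use <- withdrawals[[id]]
      district_optimize(d, water_available = use,
                        control = control)$duals[["water"]]
    }
    for (id in names(districts)) {
      v <- net_pos[[id]]
      if (v > tol) {
        p <- price_of(id)
        rows <- rbind(rows, data.frame(
          seller = id, buyer = "environment", volume = v, price = p,
          payment = p * v, stringsAsFactors = FALSE))
      }
    }
    return(rows)
  }
  # market policies: scarcity price of entitlements when the pooled cap
  # binds; otherwise (environmental purchases leave entitlements slack) the
  # competitive price is the sellers' marginal profit of water, which the
  # optimum equalizes with the environmental marginal benefit
  price <- unname(duals[["cap.pooled"]])
  if (price <= tol) {
    sellers0 <- names(districts)[net_pos > tol]
    if (length(sellers0)) {
      marg <- vapply(sellers0, function(id)
        district_optimize(districts[[id]],
                          water_available = withdrawals[[id]],
                          control = control)$duals[["water"]],
        numeric(1))
      price <- mean(marg)
    }
  }
  sellers <- names(districts)[net_pos > tol]
  buyers <- names(districts)[net_pos < -tol]
  supply <- net_pos[sellers]
  demand <- -net_pos[buyers]
  if (prob$policy == "ewm") {
    env_vol <- max(0, sum(net_pos))
    buyers <- c(buyers, "environment")
    demand <- c(demand, environment = env_vol)
  }
  si <- 1L
  for (bi in seq_along(buyers)) {
    need <- demand[bi]
    while (need > tol && si <= length(sellers)) {
      take <- min(need, supply[si])
      if (take > tol)
        rows <- rbind(rows, data.frame(
          seller = sellers[si], buyer = buyers[bi], volume = take,
          price = price, payment = price * take, stringsAsFactors = FALSE))
      supply[si] <- supply[si] - take
      need <- need - take
      if (supply[si] <= tol) si <- si + 1L
    }
  }
  rows
}

#' Water exchanges of a solved scenario
#'
#' Per-trade bookkeeping of the reallocation relative to the policy caps:
#' sellers withdraw below their (reduced) allocation, buyers above it, and
#' under the environmental policies the basin authority buys the unused
#' allocation for the river. The payments are transfers; the sum of sales
#' equals the sum of purchases by construction.
#'
#' @param solution a \code{basin_solution}.
#' @return data.frame with columns \code{seller}, \code{buyer},
#'   \code{volume} (Mm3), \code{price} (M-euro/Mm3, i.e. euro/m3),
#'   \code{payment} (M-euro); empty under pure institutional cooperation.
#' @export
compute_exchanges <- function(solution) {
  stopifnot(inherits(solution, "basin_solution"))
  solution$exchanges
}

#' @export
print.basin_solution <- function(x, ...) {
  cat("Policy solution:", policy_codes[[x$policy]],
      sprintf("(drought reduction %.0f%%)\n", 100 * x$drought))
  cat(sprintf("  irrigation withdrawals: %.0f Mm3; urban: %.0f Mm3\n",
              sum(x$withdrawals),
              if (is.null(x$urban)) 0 else sum(x$urban$volume)))
  mouth <- x$flows$wout[match(x$network$mouth, x$flows$reach_id)]
  cat(sprintf("  flow at mouth: %.0f Mm3\n", mouth))
  l <- x$ledger
  cat(sprintf(
    "  benefits (M-euro): irrigation %.0f, urban %.0f, environmental %.0f, social %.0f\n",
    l$irrigation_total, l$urban, l$environmental, l$social))
  if (nrow(x$exchanges))
    cat(sprintf("  water exchanged: %.0f Mm3 (%.0f to the environment)\n",
                sum(x$exchanges$volume),
                sum(x$exchanges$volume[x$exchanges$buyer == "environment"])))
  cat("  status:", x$status, "\n")
  invisible(x)
}

#' Comparative welfare report across policies
#'
#' Summarizes one or more policy solutions of the same basin into the
#' standard comparative table: water use by sector, exchanged volumes, flow
#' at the mouth, irrigated area (total and by crop group when the
#' activities carry a \code{group} column), and the benefit ledger. Columns
#' follow the canonical order baseline, ic, eic, wm, ewm when the names
#' match.
#'
#' @param solutions named list of \code{basin_solution} objects; names
#'   become column names.
#' @return data.frame with one row per indicator and one column per
#'   solution.
#' @export
welfare_report <- function(solutions) {
  if (inherits(solutions, "basin_solution"))
    solutions <- list(solution = solutions)
  stopifnot(length(solutions) >= 1)
  if (is.null(names(solutions)))
    names(solutions) <- vapply(solutions, `[[`, character(1), "policy")
  canon <- c("baseline", "ic", "eic", "wm", "ewm")
  if (all(names(solutions) %in% canon))
    solutions <- solutions[order(match(names(solutions), canon))]
  groups <- unique(unlist(lapply(solutions, function(s)
    names(s$area_by_group))))
  col <- function(s) {
    irr <- sum(s$withdrawals)
    urb <- if (is.null(s$urban)) 0 else sum(s$urban$volume)
    ex <- s$exchanges
    ex_env <- sum(ex$volume[ex$buyer == "environment"])
    ex_irr <- sum(ex$volume[ex$buyer != "environment"])
    mouth <- s$flows$wout[match(s$network$mouth, s$flows$reach_id)]
    area <- sum(unlist(s$acreage))
    by_group <- vapply(groups, function(g)
      if (g %in% names(s$area_by_group)) s$area_by_group[[g]] else 0,
      numeric(1))
    names(by_group) <- paste0("surface_area_", groups)
    l <- s$ledger
    c(water_use = irr + urb, water_use_irrigation = irr,
      water_use_urban = urb,
      exchanges = ex_irr + ex_env,
      exchanges_between_irrigators = ex_irr,
      exchanges_with_environment = ex_env,
      flow_at_mouth = mouth,
      surface_area = area,
      by_group,
      private_benefits = l$private,
      irrigation_benefits = l$irrigation_total,
      urban_benefits = l$urban,
      environmental_benefits = l$environmental,
      social_benefits = l$social,
      public_expenditure = l$public_expenditure)
  }
  out <- vapply(solutions, col, col(solutions[[1]]))
  as.data.frame(out)
}
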