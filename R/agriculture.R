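#' Irrigation districts
#'
#' An irrigation district holds a set of crop-by-technology activities and
#' its resource endowments. Units keep all coefficients O(1): acreage in
#' thousand hectares (1,000 ha), money in millions of euros (so prices are
#' k-euro/t and costs k-euro/ha), water in Mm3 (water requirements in Mm3 per
#' 1,000 ha, i.e. thousands of m3/ha) and labor in thousand person-days.
#' Crop yields decline linearly in planted area (Ricardian rent: the best
#' land enters production first), \code{yield = yield_intercept +
#' yield_slope * acreage} with \code{yield_slope <= 0}.
#'
#' @param id district identifier.
#' @param activities data.frame with columns \code{crop_id}, \code{tech}
#'   (one of \code{"flood"}, \code{"sprinkler"}, \code{"drip"}),
#'   \code{price} (k-euro/t), \code{cost} (k-euro/ha), \code{water_req}
#'   (Mm3 per 1,000 ha), \code{labor_req} (thousand person-days per 1,000
#'   ha), \code{observed_acreage} (1,000 ha); optional \code{avg_yield}
#'   (t/ha, used by PMP calibration) and calibrated \code{yield_intercept},
#'   \code{yield_slope}.
#' @param land_by_tech named numeric: available equipped land per technology
#'   (1,000 ha).
#' @param water_endowment,labor_endowment resource endowments (Mm3, thousand
#'   person-days).
#' @param withdraw_reach,return_reach reach ids where the district takes and
#'   returns water.
#' @return object of class \code{irrigation_district}.
#' @export
irrigation_district <- function(id, activities, land_by_tech,
                                water_endowment, labor_endowment,
                                withdraw_reach, return_reach = NA) {
  a <- as.data.frame(activities, stringsAsFactors = FALSE)
  need <- c("crop_id", "tech", "price", "cost", "water_req", "labor_req",
            "observed_acreage")
  miss <- setdiff(need, names(a))
  if (length(miss))
    stop("activities table is missing columns: ", paste(miss, collapse = ", "))
  if (!all(a$tech %in% c("flood", "sprinkler", "drip")))
    stop("tech must be flood, sprinkler or drip")
  if (any(a$price < 0 | a$cost < 0 | a$water_req < 0 | a$labor_req < 0))
    stop("prices, costs and input requirements must be nonnegative")
  if (any(a$observed_acreage < 0)) stop("observed_acreage must be >= 0")
  if ("yield_slope" %in% names(a) && any(a$yield_slope > 0, na.rm = TRUE))
    stop("yield_slope must be <= 0")
  if (water_endowment < 0 || labor_endowment < 0 || any(land_by_tech < 0))
    stop("endowments must be nonnegative")
  d <- structure(list(id = id, activities = a,
                      land_by_tech = land_by_tech,
                      water_endowment = water_endowment,
                      labor_endowment = labor_endowment,
                      withdraw_reach = withdraw_reach,
                      return_reach = return_reach),
                 class = "irrigation_district")
  # baseline acreage must fit the endowments
  for (tech in names(land_by_tech)) {
    used <- sum(a$observed_acreage[a$tech == tech])
    if (used > land_by_tech[[tech]] + 1e-9)
      stop("district ", id, ": observed acreage exceeds ", tech,
           " land endowment")
  }
  if (sum(a$water_req * a$observed_acreage) > water_endowment + 1e-9)
    stop("district ", id, ": observed water use exceeds water endowment")
  if (sum(a$labor_req * a$observed_acreage) > labor_endowment + 1e-9)
    stop("district ", id, ": observed labor use exceeds labor endowment")
  d
}

#' @export
print.irrigation_district <- function(x, ...) {
  cat("Irrigation district", x$id, "-", nrow(x$activities), "activities\n")
  cat("  observed acreage:", round(sum(x$activities$observed_acreage), 3),
      "thousand ha; water endowment:", round(x$water_endowment, 1), "Mm3\n")
  if (all(c("yield_intercept", "yield_slope") %in% names(x$activities)))
    cat("  yield coefficients calibrated\n")
  invisible(x)
}

#' Net income per hectare of an activity
#'
#' \code{price * (yield_intercept + yield_slope * acreage) - cost}, the
#' margin of the marginal hectare when the activity occupies \code{acreage}.
#'
#' @param activity one-row data.frame (or list) with \code{price},
#'   \code{cost}, \code{yield_intercept}, \code{yield_slope}.
#' @param acreage planted area (1,000 ha), >= 0.
#' @return net income (k-euro/ha, equivalently M-euro per 1,000 ha).
#' @export
net_income_per_ha <- function(activity, acreage) {
  if (any(acreage < 0)) stop("acreage must be >= 0")
  with(activity, price * (yield_intercept + yield_slope * acreage) - cost)
}

# Resource constraint rows (A x <= b) of a district: one land row per
# technology present, one water row, one labor row.
district_constraints <- function(district, water_available = NULL) {
  a <- district$activities
  n <- nrow(a)
  techs <- intersect(c("flood", "sprinkler", "drip"), unique(a$tech))
  A <- matrix(0, 0, n)
  b <- numeric(0)
  rn <- character(0)
  for (tech in techs) {
    A <- rbind(A, as.numeric(a$tech == tech))
    b <- c(b, district$land_by_tech[[tech]])
    rn <- c(rn, paste0("land_", tech))
  }
  A <- rbind(A, a$water_req, a$labor_req)
  b <- c(b, if (is.null(water_available)) district$water_endowment
         else water_available,
         district$labor_endowment)
  rn <- c(rn, "water", "labor")
  rownames(A) <- rn
  list(A = A, b = b)
}

# Quadratic profit of a district: sum over activities of
#   (price*(b0 + b1*x) - cost) * x  [M-euro]
district_profit_terms <- function(a) {
  list(lin = a$price * a$yield_intercept - a$cost,
       quad = a$price * a$yield_slope)
}

#' Optimize a district's cropping plan
#'
#' Maximizes district profit \code{sum((price * yield(x) - cost) * x)}
#' subject to equipped-land-per-technology, water and labor constraints and
#' nonnegative acreage. With \code{yield_slope <= 0} the profit is concave
#' and the optimum global. The duals of the resource constraints are
#' returned; the water dual is the marginal value of water in the district
#' (M-euro per Mm3).
#'
#' @param district a calibrated \code{irrigation_district} (columns
#'   \code{yield_intercept}, \code{yield_slope} present).
#' @param water_available water cap (Mm3); defaults to the district
#'   endowment.
#' @param control solver control list passed to \code{\link{al_maximize}}.
#' @return list: \code{acreage} (named by crop_id.tech), \code{profit}
#'   (M-euro), \code{water_use} (Mm3), \code{duals} (named; includes
#'   \code{water}), \code{status}.
#' @export
district_optimize <- function(district, water_available = NULL,
                              control = list()) {
  a <- district$activities
  if (!all(c("yield_intercept", "yield_slope") %in% names(a)))
    stop("district ", district$id,
         " has no calibrated yield coefficients; run pmp_calibrate first")
  if (!is.null(water_available) && water_available < 0)
    stop("water_available must be >= 0")
  con <- district_constraints(district, water_available)
  tr <- district_profit_terms(a)
  fn <- function(x) sum(tr$lin * x + tr$quad * x^2)
  gr <- function(x) tr$lin + 2 * tr$quad * x
  # deterministic start: baseline acreage, shrunk onto the water cap
  x0 <- a$observed_acreage
  wa <- if (is.null(water_available)) district$water_endowment
        else water_available
  use0 <- sum(a$water_req * x0)
  if (use0 > wa && use0 > 0) x0 <- x0 * (wa / use0)
  sol <- al_maximize(fn, gr, con$A, con$b, x0 = x0,
                     lower = 0, control = control)
  acreage <- stats::setNames(sol$par, paste(a$crop_id, a$tech, sep = "."))
  list(acreage = acreage,
       profit = sol$value,
       water_use = sum(a$water_req * sol$par),
       duals = stats::setNames(sol$duals, rownames(con$A)),
       status = if (sol$converged) "optimal" else "not_converged")
}

#' Calibrate yield coefficients by Positive Mathematical Programming
#'
#' Two-stage PMP with a linear declining yield. Stage 1 solves the linear
#' program with profit margins at the observed average yields, the resource
#' constraints, and calibration bounds \code{x <= observed * (1 + eps)}; its
#' resource duals give the opportunity cost of land, water and labor. Stage 2
#' sets, per activity, the yield coefficients from two conditions: the yield
#' at the observed acreage equals the observed average yield, and the
#' first-order condition of profit maximization holds at the observed acreage
#' given the stage-1 duals. Writing \code{mu} for the calibration-bound dual
#' (margin minus resource opportunity cost) this gives
#' \code{yield_slope = -mu / (price * observed)} and
#' \code{yield_intercept = avg_yield - yield_slope * observed}. Re-solving
#' the district at baseline endowments then reproduces the observed acreage.
#'
#' Activities with zero observed acreage are excluded from calibration and
#' kept at their linear margin (flat yield). Activities whose calibration
#' dual is zero (held by a binding resource constraint rather than by
#' declining yield) get \code{yield_slope = 0} and are flagged in the
#' \code{"pmp"} attribute.
#'
#' @param district an \code{irrigation_district} whose activities carry
#'   \code{avg_yield} (t/ha), or pass \code{avg_yields} explicitly.
#' @param avg_yields optional numeric vector of observed average yields
#'   (t/ha), one per activity.
#' @param eps relative headroom of the calibration bounds (default
#'   \code{1e-6}).
#' @param control solver control list.
#' @return the district with calibrated \code{yield_intercept},
#'   \code{yield_slope}; attribute \code{"pmp"} records stage-1 duals, the
#'   calibration duals \code{mu} and any constraint-calibrated activities.
#' @export
pmp_calibrate <- function(district, avg_yields = NULL, eps = 1e-6,
                          control = list()) {
  a <- district$activities
  if (is.null(avg_yields)) {
    if (!"avg_yield" %in% names(a))
      stop("no average yields: supply avg_yields or an avg_yield column")
    avg_yields <- a$avg_yield
  }
  if (length(avg_yields) != nrow(a))
    stop("avg_yields must have one value per activity")
  margin <- a$price * avg_yields - a$cost
  obs <- a$observed_acreage
  con <- district_constraints(district)
  # stage 1: LP with calibration bounds as box upper bounds
  upper <- ifelse(obs > 0, obs * (1 + eps), 0)
  fn <- function(x) sum(margin * x)
  gr <- function(x) margin
  sol <- al_maximize(fn, gr, con$A, con$b, x0 = pmin(obs, upper),
                     lower = 0, upper = upper, control = control)
  duals <- stats::setNames(sol$duals, rownames(con$A))
  # opportunity cost of the resources each activity uses
  land_dual <- vapply(a$tech, function(t) {
    nm <- paste0("land_", t)
    if (nm %in% names(duals)) duals[[nm]] else 0
  }, numeric(1))
  opp <- land_dual + a$water_req * duals[["water"]] +
    a$labor_req * duals[["labor"]]
  mu <- pmax(0, margin - opp)
  slope <- ifelse(obs > 0 & a$price > 0, -mu / (a$price * pmax(obs, 1e-12)), 0)
  intercept <- avg_yields - slope * obs
  a$avg_yield <- avg_yields
  a$yield_slope <- slope
  a$yield_intercept <- intercept
  district$activities <- a
  corner <- which(obs > 0 & mu <= 1e-9)
  attr(district, "pmp") <- list(
    resource_duals = duals, mu = stats::setNames(mu, a$crop_id),
    constraint_calibrated = a$crop_id[corner])
  district
}
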