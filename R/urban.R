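#' Urban water economics
#'
#' Each city is described by a linear inverse demand curve (intercept
#' \code{a_d}, slope \code{b_d} > 0, written with a negative sign in the
#' surplus) and a linear marginal supply-cost curve (\code{a_s},
#' \code{b_s} >= 0). The economic surplus of serving demand \code{q_d} from
#' supply \code{q_s} is consumer plus producer surplus,
#' \code{a_d*q_d - b_d*q_d^2/2 - a_s*q_s - b_s*q_s^2/2}, and supply must
#' cover demand. Money is in M-euro and volumes in Mm3, so intercepts are in
#' M-euro/Mm3 (equivalently euro/m3).
#'
#' @param id city identifier.
#' @param a_d,b_d inverse-demand intercept (M-euro/Mm3) and slope
#'   (M-euro/Mm3 per Mm3), \code{b_d > 0}.
#' @param a_s,b_s supply-cost intercept and slope, \code{b_s >= 0}; gains
#'   from trade require \code{a_d > a_s}.
#' @param withdraw_reach,return_reach reach ids for the city's withdrawal
#'   and return flow.
#' @return object of class \code{city}.
#' @export
city <- function(id, a_d, b_d, a_s, b_s, withdraw_reach, return_reach = NA) {
  if (b_d <= 0) stop("demand slope b_d must be > 0")
  if (b_s < 0) stop("supply slope b_s must be >= 0")
  if (a_d <= a_s) stop("a_d must exceed a_s (positive gains from trade)")
  structure(list(id = id, a_d = a_d, b_d = b_d, a_s = a_s, b_s = b_s,
                 withdraw_reach = withdraw_reach,
                 return_reach = return_reach),
            class = "city")
}

#' Urban surplus at given demand and supply
#'
#' @param city a \code{city}.
#' @param q_demand,q_supply quantities (Mm3); supply must be at least demand.
#' @return surplus (M-euro).
#' @export
urban_surplus <- function(city, q_demand, q_supply = q_demand) {
  if (q_demand < 0 || q_supply < 0) stop("quantities must be >= 0")
  if (q_supply < q_demand - 1e-12)
    stop("city ", city$id, ": supply (", q_supply,
         ") cannot be below demand (", q_demand, ")")
  city$a_d * q_demand - 0.5 * city$b_d * q_demand^2 -
    city$a_s * q_supply - 0.5 * city$b_s * q_supply^2
}

#' Optimal urban withdrawal
#'
#' With supply equal to demand (excess supply only loses surplus) the
#' surplus is \code{(a_d - a_s) q - (b_d + b_s) q^2 / 2}, maximized at
#' \code{q* = (a_d - a_s) / (b_d + b_s)} unless the water cap binds first.
#'
#' @param city a \code{city}.
#' @param water_cap maximum withdrawal (Mm3), default unbounded.
#' @return list \code{q} (Mm3) and \code{surplus} (M-euro).
#' @export
urban_optimize <- function(city, water_cap = Inf) {
  q_star <- max(0, (city$a_d - city$a_s) / (city$b_d + city$b_s))
  q <- min(q_star, water_cap)
  list(q = q, surplus = urban_surplus(city, q, q))
}
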