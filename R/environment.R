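#' Ecological response of reaches to stream flow
#'
#' Habitat potential is summarized by the weighted usable area (WUA), an
#' index in [0, 1) of a reach's capacity to host its representative fish
#' species at a given flow. The response follows the saturating exponential
#' \code{WUA(x) = 1 - exp(beta * x)} with \code{beta < 0}: zero habitat at
#' zero flow, strictly increasing and concave in flow, approaching one as
#' flow rises. The ecosystem health status of a reach is identified with its
#' WUA, and the monetary environmental benefit of a reach is the per-km
#' value of its ecosystem services times reach length times health.
#'
#' @name ecological-response
NULL

#' Default valuation tiers for ecosystem services
#'
#' Per-kilometer values of riverine ecosystem services (M-euro/km):
#' \code{low} 0.072 for moderate-value main-stem sections, \code{medium}
#' 0.180 for non-mountain tributaries (the basin-average value), and
#' \code{high} 0.450 for mountain reaches and the delta.
#'
#' @return named numeric vector of tier values.
#' @export
valuation_tiers <- function() {
  c(low = 0.072, medium = 0.180, high = 0.450)
}

#' Weighted usable area at a given flow
#'
#' @param beta response parameter, strictly negative (per flow unit).
#' @param flow nonnegative flow, in the units \code{beta} was fitted in.
#' @return WUA fraction in [0, 1).
#' @export
wua <- function(beta, flow) {
  if (any(beta >= 0)) stop("beta must be negative")
  if (any(flow < 0)) stop("flow must be >= 0")
  1 - exp(beta * flow)
}

#' Ecosystem health status of a reach
#'
#' Health status equals the reach WUA evaluated at the effective flow.
#' Because the fitted \code{beta} values are tied to the (unstated) flow
#' units of the underlying habitat studies, each reach carries a
#' \code{flow_scale} factor converting the model's annual flow (Mm3/yr) into
#' the effective flow entering the response; a dry-season emphasis can be
#' expressed through the same factor.
#'
#' @param reach one row of a network's \code{reaches} table (needs
#'   \code{beta} and optionally \code{flow_scale}).
#' @param flow annual reach flow (Mm3/yr).
#' @return health fraction in [0, 1).
#' @export
ecosystem_health <- function(reach, flow) {
  scale <- if (!is.null(reach$flow_scale)) reach$flow_scale else 1
  wua(reach$beta, scale * flow)
}

#' Environmental benefit of a reach
#'
#' \code{value_per_km(tier) * length_km * health(flow)}, in M-euro.
#'
#' @param reach one row of a network's \code{reaches} table (needs
#'   \code{beta}, \code{length_km}, \code{valuation_tier}).
#' @param flow annual reach flow (Mm3/yr).
#' @param tiers named vector of tier values (M-euro/km), defaulting to
#'   \code{\link{valuation_tiers}}.
#' @return benefit (M-euro).
#' @export
env_benefit <- function(reach, flow, tiers = valuation_tiers()) {
  tier <- as.character(reach$valuation_tier)
  if (!tier %in% names(tiers))
    stop("reach ", reach$reach_id, " has unknown valuation tier '", tier, "'")
  unname(tiers[tier]) * reach$length_km * ecosystem_health(reach, flow)
}

#' Fit the WUA response parameter by nonlinear least squares
#'
#' Fits \code{wua = 1 - exp(beta * flow)} to (flow, WUA) observations,
#' constraining \code{beta < 0}. Returns the estimate with its asymptotic
#' standard error and t statistic, as habitat studies report them.
#'
#' @param observations data.frame with columns \code{flow} and \code{wua};
#'   at least three observations with distinct flows.
#' @return list: \code{beta} (estimate), \code{se}, \code{t}
#'   (\code{beta/se}), \code{n}, and the underlying \code{fit} object.
#' @export
fit_beta <- function(observations) {
  obs <- as.data.frame(observations)
  if (!all(c("flow", "wua") %in% names(obs)))
    stop("observations need columns flow and wua")
  obs <- obs[stats::complete.cases(obs[, c("flow", "wua")]), ]
  if (nrow(obs) < 3) stop("at least 3 observations are required")
  if (length(unique(obs$flow)) < 2)
    stop("degenerate data: all flows are equal")
  # starting value from the linearization log(1 - wua) = beta * flow
  ok <- obs$wua < 1 & obs$flow > 0
  b0 <- if (any(ok)) mean(log(1 - obs$wua[ok]) / obs$flow[ok]) else -1
  if (!is.finite(b0) || b0 >= 0) b0 <- -1
  fit <- tryCatch(
    minpack.lm::nlsLM(wua ~ 1 - exp(beta * flow), data = obs,
                      start = list(beta = b0),
                      lower = c(beta = -Inf), upper = c(beta = -1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("WUA regression did not converge: ",
                             conditionMessage(e)))
  co <- summary(fit)$coefficients
  list(beta = unname(co["beta", "Estimate"]),
       se = unname(co["beta", "Std. Error"]),
       t = unname(co["beta", "Estimate"] / co["beta", "Std. Error"]),
       n = nrow(obs), fit = fit)
}

#' Convert a per-hectare ecosystem value to a per-kilometer value
#'
#' Valuation studies report euros per hectare of riverbed covered by water;
#' dividing the total valued water area by the total river length converts
#' this to the per-kilometer value used in reach benefits.
#'
#' @param value_per_ha ecosystem-service value (euro/ha), > 0.
#' @param water_area_ha area covered by water (ha), > 0.
#' @param river_length_km total river length (km), > 0.
#' @return value in M-euro/km.
#' @export
value_per_km <- function(value_per_ha, water_area_ha, river_length_km) {
  if (value_per_ha <= 0 || water_area_ha <= 0)
    stop("value and area must be > 0")
  if (river_length_km <= 0) stop("river length must be > 0")
  value_per_ha * water_area_ha / river_length_km / 1e6
}

#' Environmental damage of water extractions
#'
#' Benefit-transfer cross-check: a unit damage cost per cubic meter applied
#' to an extracted (or remaining) annual volume. With the cost in euro/m3
#' and the volume in Mm3 the product is directly in M-euro.
#'
#' @param unit_cost_eur_m3 damage cost (euro/m3).
#' @param volume_mm3 annual volume (Mm3).
#' @return damages (M-euro).
#' @export
damage_cost <- function(unit_cost_eur_m3, volume_mm3) {
  if (unit_cost_eur_m3 < 0 || volume_mm3 < 0)
    stop("cost and volume must be >= 0")
  unit_cost_eur_m3 * volume_mm3
}
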