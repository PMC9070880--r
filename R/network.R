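#' River networks and reach mass balance
#'
#' A basin is represented as a directed tree of river reaches rooted at the
#' mouth: every reach drains to exactly one downstream reach (confluences are
#' reaches sharing a downstream neighbor) and exactly one reach, the mouth,
#' has no downstream neighbor. Each reach carries the reduced-form hydrology
#' parameters: tributary/local inflow (Mm3/yr), channel loss (Mm3/yr), return
#' coefficients for irrigation and urban diversions, minimum environmental
#' flows at control points, a signed closure term fitted against gauge data,
#' and the ecological response parameters (beta < 0, a flow-unit scale, a
#' valuation tier and the reach length in km).
#'
#' @param reaches data.frame with columns \code{reach_id},
#'   \code{downstream_id} (\code{NA} for the mouth), \code{length_km},
#'   \code{local_inflow}, \code{loss}, \code{r_ir}, \code{r_urb},
#'   \code{min_env_flow}, \code{beta}, \code{valuation_tier}; optional
#'   columns \code{min_env_flow_drought} (defaults to \code{min_env_flow}),
#'   \code{flow_scale} (defaults to 1) and \code{closure} (defaults to 0).
#' @param attachments optional data.frame mapping demand units to the
#'   network: columns \code{unit_id}, \code{unit_type} (\code{"district"} or
#'   \code{"city"}), \code{withdraw_reach}, \code{return_reach}.
#'
#' @return an object of class \code{river_network}: a list with the validated
#'   \code{reaches} table (ordered upstream to downstream), the
#'   \code{attachments} table and the topological order.
#' @export
river_network <- function(reaches, attachments = NULL) {
  reaches <- as.data.frame(reaches, stringsAsFactors = FALSE)
  need <- c("reach_id", "downstream_id", "length_km", "local_inflow",
            "loss", "r_ir", "r_urb", "min_env_flow", "beta",
            "valuation_tier")
  miss <- setdiff(need, names(reaches))
  if (length(miss))
    stop("network table is missing columns: ", paste(miss, collapse = ", "))
  reaches$reach_id <- as.character(reaches$reach_id)
  reaches$downstream_id <- as.character(reaches$downstream_id)
  reaches$downstream_id[reaches$downstream_id %in% c("", "NA", "none")] <- NA
  if (anyDuplicated(reaches$reach_id))
    stop("duplicated reach_id in network table")
  if (!"min_env_flow_drought" %in% names(reaches))
    reaches$min_env_flow_drought <- reaches$min_env_flow
  if (!"flow_scale" %in% names(reaches)) reaches$flow_scale <- 1
  if (!"closure" %in% names(reaches)) reaches$closure <- 0
  reaches$min_env_flow[is.na(reaches$min_env_flow)] <- 0
  reaches$min_env_flow_drought[is.na(reaches$min_env_flow_drought)] <-
    reaches$min_env_flow[is.na(reaches$min_env_flow_drought)]

  mouth <- reaches$reach_id[is.na(reaches$downstream_id)]
  if (length(mouth) != 1L)
    stop("exactly one reach must have no downstream reach (the mouth); found ",
         length(mouth))
  bad_ref <- setdiff(stats::na.omit(reaches$downstream_id), reaches$reach_id)
  if (length(bad_ref))
    stop("downstream_id refers to unknown reaches: ",
         paste(bad_ref, collapse = ", "))
  if (any(reaches$length_km <= 0)) stop("length_km must be > 0")
  if (any(reaches$loss < 0)) stop("loss must be >= 0")
  if (any(reaches$local_inflow < 0)) stop("local_inflow must be >= 0")
  if (any(reaches$r_ir < 0 | reaches$r_ir > 1 |
          reaches$r_urb < 0 | reaches$r_urb > 1))
    stop("return coefficients must lie in [0, 1]")
  if (any(is.na(reaches$beta)))
    stop("beta is required for every reach (missing for: ",
         paste(reaches$reach_id[is.na(reaches$beta)], collapse = ", "), ")")
  if (any(reaches$beta >= 0))
    stop("beta must be strictly negative (violated at: ",
         paste(reaches$reach_id[reaches$beta >= 0], collapse = ", "), ")")
  if (!all(reaches$valuation_tier %in% names(valuation_tiers())))
    stop("valuation_tier must be one of: ",
         paste(names(valuation_tiers()), collapse = ", "))

  order_ids <- topological_order(reaches)
  reaches <- reaches[match(order_ids, reaches$reach_id), , drop = FALSE]
  rownames(reaches) <- NULL

  if (!is.null(attachments)) {
    attachments <- as.data.frame(attachments, stringsAsFactors = FALSE)
    aneed <- c("unit_id", "unit_type", "withdraw_reach", "return_reach")
    amiss <- setdiff(aneed, names(attachments))
    if (length(amiss))
      stop("attachments table is missing columns: ",
           paste(amiss, collapse = ", "))
    dangling <- setdiff(
      c(attachments$withdraw_reach,
        stats::na.omit(attachments$return_reach)),
      reaches$reach_id)
    if (length(dangling))
      stop("attachments reference unknown reaches: ",
           paste(unique(dangling), collapse = ", "))
    if (!all(attachments$unit_type %in% c("district", "city")))
      stop("unit_type must be 'district' or 'city'")
  }

  structure(list(reaches = reaches, attachments = attachments,
                 mouth = mouth, order = order_ids),
            class = "river_network")
}

# Order reach ids so that every reach precedes its downstream neighbor.
# A cycle in the downstream pointers is reported with the reaches involved.
topological_order <- function(reaches) {
  ids <- reaches$reach_id
  down <- stats::setNames(reaches$downstream_id, ids)
  depth <- stats::setNames(integer(length(ids)), ids)
  for (id in ids) {
    cur <- id
    steps <- 0L
    path <- character(0)
    while (!is.na(cur)) {
      path <- c(path, cur)
      cur <- down[[cur]]
      steps <- steps + 1L
      if (steps > length(ids))
        stop("cycle detected in downstream links involving reaches: ",
             paste(unique(path), collapse = " -> "))
    }
    depth[[id]] <- steps
  }
  ids[order(-depth, ids)]
}

#' @export
print.river_network <- function(x, ...) {
  r <- x$reaches
  cat("River network:", nrow(r), "reaches, mouth at", x$mouth, "\n")
  cat("  total local inflow:", format(sum(r$local_inflow), big.mark = ","),
      "Mm3/yr; total loss:", format(sum(r$loss), big.mark = ","), "Mm3/yr\n")
  cp <- r[r$min_env_flow > 0, c("reach_id", "min_env_flow",
                                "min_env_flow_drought")]
  if (nrow(cp)) {
    cat("  control points (min flow normal/drought, Mm3/yr):\n")
    for (i in seq_len(nrow(cp)))
      cat("    ", cp$reach_id[i], ": ", cp$min_env_flow[i], " / ",
          cp$min_env_flow_drought[i], "\n", sep = "")
  }
  invisible(x)
}

#' Mass balance of a single reach
#'
#' Outflow of a reach equals inflow minus channel loss and the irrigation and
#' urban diversions taken in the reach, plus the (signed) calibration closure
#' term.
#'
#' @param inflow,loss,div_ir,div_urb nonnegative volumes (Mm3/yr).
#' @param closure signed closure adjustment (Mm3/yr), default 0.
#' @param reach_id identifier used in error messages.
#' @param check when \code{TRUE} (default) a negative outflow raises an
#'   infeasibility error naming the reach; \code{check = FALSE} returns the
#'   raw linear expression (used when building the affine flow map).
#' @return outflow volume (Mm3/yr).
#' @export
mass_balance_outflow <- function(inflow, loss = 0, div_ir = 0, div_urb = 0,
                                 closure = 0, reach_id = NULL, check = TRUE) {
  if (check && (inflow < 0 || loss < 0 || div_ir < 0 || div_urb < 0))
    stop("flows and diversions must be nonnegative")
  out <- inflow - loss - div_ir - div_urb + closure
  if (check && out < -1e-9)
    stop("infeasible mass balance", if (!is.null(reach_id))
      paste0(" at reach ", reach_id), ": outflow would be ",
      signif(out, 6), " Mm3/yr")
  out
}

#' Propagate flows through the network
#'
#' Computes the complete flow state in topological order: the inflow of a
#' reach is its local (tributary) inflow plus the outflows of its upstream
#' neighbors plus the return flows routed to it; the outflow follows the reach
#' mass balance. Return flows are the reach return coefficient (irrigation or
#' urban, by unit type) times the diversion, entering the inflow of the unit's
#' return reach.
#'
#' @param network a \code{river_network}.
#' @param diversions data.frame with columns \code{unit_id},
#'   \code{unit_type}, \code{withdraw_reach}, \code{return_reach},
#'   \code{volume}; or \code{NULL} for no diversions.
#' @param check enforce nonnegative outflows (see
#'   \code{\link{mass_balance_outflow}}).
#' @param use_closure include the calibration closure terms (default
#'   \code{TRUE}).
#' @return a \code{flow_state}: data.frame with columns \code{reach_id},
#'   \code{win}, \code{wout}, \code{div_ir}, \code{div_urb} in topological
#'   order.
#' @export
propagate_flows <- function(network, diversions = NULL, check = TRUE,
                            use_closure = TRUE) {
  stopifnot(inherits(network, "river_network"))
  r <- network$reaches
  n <- nrow(r)
  idx <- stats::setNames(seq_len(n), r$reach_id)
  div_ir <- div_urb <- ret <- numeric(n)
  if (!is.null(diversions) && nrow(diversions)) {
    d <- as.data.frame(diversions, stringsAsFactors = FALSE)
    bad <- setdiff(c(d$withdraw_reach, stats::na.omit(d$return_reach)),
                   r$reach_id)
    if (length(bad))
      stop("diversion attached to unknown reach(es): ",
           paste(unique(bad), collapse = ", "))
    for (i in seq_len(nrow(d))) {
      w <- idx[[d$withdraw_reach[i]]]
      v <- d$volume[i]
      if (check && v < 0) stop("diversion volumes must be nonnegative")
      if (identical(d$unit_type[i], "city")) {
        div_urb[w] <- div_urb[w] + v
        rc <- r$r_urb[w]
      } else {
        div_ir[w] <- div_ir[w] + v
        rc <- r$r_ir[w]
      }
      if (!is.na(d$return_reach[i])) {
        rr <- idx[[d$return_reach[i]]]
        ret[rr] <- ret[rr] + rc * v
      }
    }
  }
  win <- wout <- numeric(n)
  closure <- if (use_closure) r$closure else rep(0, n)
  for (i in seq_len(n)) {
    ups <- which(!is.na(r$downstream_id) & r$downstream_id == r$reach_id[i])
    win[i] <- r$local_inflow[i] + sum(wout[ups]) + ret[i]
    wout[i] <- mass_balance_outflow(win[i], r$loss[i], div_ir[i], div_urb[i],
                                    closure[i], reach_id = r$reach_id[i],
                                    check = check)
  }
  structure(data.frame(reach_id = r$reach_id, win = win, wout = wout,
                       div_ir = div_ir, div_urb = div_urb,
                       stringsAsFactors = FALSE),
            class = c("flow_state", "data.frame"))
}

#' Check minimum environmental flows at control points
#'
#' @param state a \code{flow_state} from \code{\link{propagate_flows}}.
#' @param network the \code{river_network} the state belongs to.
#' @param drought use the drought minimum flows (\code{min_env_flow_drought})
#'   instead of the normal-year minimums.
#' @param tol numerical slack (Mm3/yr) below which a shortfall is ignored.
#' @return data.frame with one row per violated control point
#'   (\code{reach_id}, \code{flow}, \code{min_flow}, \code{deficit}); zero
#'   rows for a feasible state.
#' @export
check_min_flows <- function(state, network, drought = FALSE, tol = 1e-6) {
  r <- network$reaches
  minf <- if (drought) r$min_env_flow_drought else r$min_env_flow
  flow <- state$wout[match(r$reach_id, state$reach_id)]
  short <- which(minf > 0 & flow < minf - tol)
  data.frame(reach_id = r$reach_id[short], flow = flow[short],
             min_flow = minf[short], deficit = minf[short] - flow[short],
             stringsAsFactors = FALSE)
}

# TRUE if reach `a` lies at or upstream of reach `g` (walking downstream
# pointers from `a` reaches `g`).
at_or_upstream <- function(network, a, g) {
  down <- stats::setNames(network$reaches$downstream_id,
                          network$reaches$reach_id)
  cur <- a
  while (!is.na(cur)) {
    if (cur == g) return(TRUE)
    cur <- down[[cur]]
  }
  FALSE
}

#' Calibrate closure terms against gauged flows
#'
#' The reduced-form mass balance omits non-observed exchanges (groundwater,
#' evaporation, unmeasured returns). Calibration fixes one signed closure term
#' per reach so that propagated outflows match the gauged flows exactly,
#' choosing the solution of minimal squared magnitude among the exact
#' solutions (minimum-norm least squares on the gauge incidence matrix). When
#' the observations are inconsistent the gauge residuals are reported via a
#' warning and the \code{"residuals"} attribute instead of failing silently.
#'
#' @param network a \code{river_network}; any existing closure terms are
#'   discarded before fitting.
#' @param observed_flows data.frame with columns \code{reach_id},
#'   \code{wout}: outflow observed at each gauged reach (Mm3/yr).
#' @param baseline_diversions diversions held fixed during calibration (same
#'   format as in \code{\link{propagate_flows}}).
#' @return the network with calibrated \code{closure} terms; attribute
#'   \code{"residuals"} holds the post-fit gauge residuals.
#' @export
calibrate_closure <- function(network, observed_flows,
                              baseline_diversions = NULL) {
  stopifnot(inherits(network, "river_network"))
  obs <- as.data.frame(observed_flows, stringsAsFactors = FALSE)
  if (!all(c("reach_id", "wout") %in% names(obs)))
    stop("observed_flows needs columns reach_id, wout")
  unknown <- setdiff(obs$reach_id, network$reaches$reach_id)
  if (length(unknown))
    stop("observed flows at unknown reaches: ",
         paste(unknown, collapse = ", "))
  base <- propagate_flows(network, baseline_diversions, check = FALSE,
                          use_closure = FALSE)
  model <- base$wout[match(obs$reach_id, base$reach_id)]
  resid <- obs$wout - model
  ids <- network$reaches$reach_id
  # incidence: closure at reach d shifts the outflow of every gauge at or
  # downstream of d by one unit
  M <- t(vapply(obs$reach_id, function(g)
    as.numeric(vapply(ids, at_or_upstream, logical(1),
                      network = network, g = g)),
    numeric(length(ids))))
  closure <- drop(MASS::ginv(M) %*% resid)
  network$reaches$closure <- closure
  fit <- propagate_flows(network, baseline_diversions, check = FALSE)
  res <- obs$wout - fit$wout[match(obs$reach_id, fit$reach_id)]
  if (max(abs(res)) > 1e-6)
    warning("gauge observations are inconsistent; residuals up to ",
            signif(max(abs(res)), 4), " Mm3/yr remain")
  attr(network, "residuals") <- stats::setNames(res, obs$reach_id)
  network
}

# Affine map from unit diversion volumes to the flow state:
#   win = win0 + Dwin %*% q,  wout = wout0 + Dwout %*% q
# where q are the diversion volumes of `units` (data.frame unit_id,
# unit_type, withdraw_reach, return_reach) and win0/wout0 already include the
# fixed diversions in `fixed` (e.g. guaranteed urban withdrawals).
flow_affine_map <- function(network, units, fixed = NULL) {
  base <- propagate_flows(network, fixed, check = FALSE)
  n <- nrow(network$reaches)
  k <- if (is.null(units)) 0L else nrow(units)
  Dwin <- matrix(0, n, k)
  Dwout <- matrix(0, n, k)
  if (k > 0L) {
    # zero every source term so a unit diversion maps to its pure sensitivity
    net0 <- network
    net0$reaches$local_inflow <- 0
    net0$reaches$loss <- 0
    net0$reaches$closure <- 0
    for (j in seq_len(k)) {
      dj <- data.frame(unit_id = units$unit_id[j],
                       unit_type = units$unit_type[j],
                       withdraw_reach = units$withdraw_reach[j],
                       return_reach = units$return_reach[j],
                       volume = 1, stringsAsFactors = FALSE)
      s <- propagate_flows(net0, dj, check = FALSE)
      Dwin[, j] <- s$win
      Dwout[, j] <- s$wout
    }
  }
  list(reach_id = base$reach_id, win0 = base$win, wout0 = base$wout,
       Dwin = Dwin, Dwout = Dwout)
}
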