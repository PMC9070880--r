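#' Configuration of the synthetic basin generator
#'
#' Defaults encode the study conditions the model targets: annual renewable
#' inflows of 14,600 Mm3, WUA response parameters spanning the fitted range
#' [-16.39, -0.10], the three valuation tiers, and severe (0.4) and moderate
#' (0.3) drought levels.
#'
#' @param n_reaches,n_districts,n_cities instance sizes (>= 1 reach).
#' @param seed integer seed; the generator has no hidden random state (the
#'   global RNG is restored on exit).
#' @param inflow_total annual basin inflow (Mm3).
#' @param beta_range strictly negative interval the WUA parameters are
#'   drawn from (log-uniform in magnitude).
#' @param tier_probabilities sampling weights of the valuation tiers; must
#'   sum to 1.
#' @param noise_sd Gaussian noise of synthetic WUA observations.
#' @param drought_levels drought reductions the instance must stay feasible
#'   under.
#' @return list of class \code{generator_config}.
#' @export
generator_config <- function(n_reaches = 14, n_districts = 5, n_cities = 2,
                             seed = 1, inflow_total = 14600,
                             beta_range = c(-16.39, -0.10),
                             tier_probabilities = c(low = 0.4, medium = 0.35,
                                                    high = 0.25),
                             noise_sd = 0.05,
                             drought_levels = c(0.3, 0.4)) {
  stopifnot(n_reaches >= 1, n_districts >= 1, n_cities >= 0)
  if (any(beta_range >= 0)) stop("beta_range must be strictly negative")
  if (abs(sum(tier_probabilities) - 1) > 1e-9)
    stop("tier_probabilities must sum to 1")
  if (any(drought_levels < 0 | drought_levels >= 1))
    stop("drought_levels must lie in [0, 1)")
  structure(list(n_reaches = n_reaches, n_districts = n_districts,
                 n_cities = n_cities, seed = seed,
                 inflow_total = inflow_total, beta_range = beta_range,
                 tier_probabilities = tier_probabilities,
                 noise_sd = noise_sd, drought_levels = drought_levels),
            class = "generator_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# crop catalog: margins (price * base_yield - cost) are strictly positive so
# every baseline activity is held by its declining yield, not by a corner
crop_catalog <- function() {
  data.frame(
    crop_id = c("barley", "wheat", "corn", "alfalfa",
                "fruit", "fruit", "vegetables"),
    group = c("field", "field", "field", "field",
              "fruit", "fruit", "vegetables"),
    tech = c("flood", "flood", "sprinkler", "flood",
             "drip", "flood", "drip"),
    price = c(0.18, 0.19, 0.19, 0.165, 0.55, 0.55, 0.35),
    base_yield = c(5.5, 6.2, 11, 13.5, 21, 19, 30),
    cost = c(0.54, 0.678, 1.39, 1.6275, 8.75, 8.25, 5.792),
    water_req = c(11, 12, 9.5, 14, 7, 12, 6),
    labor_req = c(2, 2.5, 6, 5, 25, 30, 40),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic basin instance
#'
#' Draws a directed-tree river network (a mainstem plus tributaries), PMP-
#' calibratable irrigation districts whose observed acreages are consistent
#' with their endowments and with the flow available at their withdrawal
#' reach, cities with linear demand/supply parameters, per-reach WUA
#' parameters within the configured range, and valuation tiers. Instances
#' are deterministic given the seed and are checked to be feasible at zero
#' drought and at every configured drought level (urban priority and
#' minimum flows satisfiable) before being returned.
#'
#' @param config a \code{\link{generator_config}}.
#' @return a \code{\link{basin}}; WUA observation sets for each reach are
#'   attached as attribute \code{"wua_observations"}.
#' @export
generate_basin <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    n <- config$n_reaches
    n_main <- max(1L, ceiling(0.6 * n))
    main_ids <- sprintf("M%02d", seq_len(n_main))
    trib_ids <- if (n > n_main) sprintf("T%02d", seq_len(n - n_main))
                else character(0)
    down <- c(if (n_main > 1) main_ids[-1] else character(0), NA)
    trib_to <- if (length(trib_ids))
      main_ids[sample.int(n_main, length(trib_ids), replace = TRUE)]
    else character(0)
    ids <- c(main_ids, trib_ids)
    downstream <- c(down, trib_to)

    w <- stats::rgamma(n, shape = 2)
    inflow <- config$inflow_total * w / sum(w)
    loss <- stats::runif(n, 0.01, 0.05) * inflow
    lb <- log(-config$beta_range)  # magnitudes
    beta <- -exp(stats::runif(n, min(lb), max(lb)))
    reaches <- data.frame(
      reach_id = ids, downstream_id = downstream,
      length_km = stats::runif(n, 20, 200),
      local_inflow = inflow, loss = loss,
      r_ir = stats::runif(n, 0.15, 0.3),
      r_urb = stats::runif(n, 0.7, 0.9),
      min_env_flow = 0, min_env_flow_drought = 0,
      beta = beta, flow_scale = 1,
      valuation_tier = sample(names(config$tier_probabilities), n,
                              replace = TRUE,
                              prob = config$tier_probabilities),
      closure = 0, stringsAsFactors = FALSE)
    net <- river_network(reaches)

    # undepleted flows, used to size demands conservatively
    free <- propagate_flows(net)
    win_free <- stats::setNames(free$win, free$reach_id)
    down_of <- stats::setNames(net$reaches$downstream_id,
                               net$reaches$reach_id)
    non_mouth <- setdiff(ids, net$mouth)

    catalog <- crop_catalog()
    worst <- 1 - max(config$drought_levels, 0)
    districts <- vector("list", config$n_districts)
    for (k in seq_len(config$n_districts)) {
      wr <- sample(non_mouth, 1,
                   prob = win_free[non_mouth] / sum(win_free[non_mouth]))
      acts <- catalog[sample.int(nrow(catalog),
                                 sample(3:5, 1)), , drop = FALSE]
      raw <- stats::runif(nrow(acts), 20, 120)
      # size total water use to a conservative share of the undepleted
      # inflow so the instance stays feasible under the worst drought
      target <- stats::runif(1, 0.08, 0.2) * worst * win_free[[wr]]
      raw <- raw * target / sum(acts$water_req * raw)
      acts$observed_acreage <- raw
      acts$avg_yield <- acts$base_yield * stats::runif(nrow(acts), 0.9, 1.1)
      land <- tapply(acts$observed_acreage, acts$tech, sum)
      districts[[k]] <- irrigation_district(
        id = sprintf("d%02d", k),
        activities = acts[, c("crop_id", "group", "tech", "price", "cost",
                              "water_req", "labor_req", "observed_acreage",
                              "avg_yield")],
        land_by_tech = as.list(land * 1.25),
        water_endowment = 1.15 * sum(acts$water_req * acts$observed_acreage),
        labor_endowment = 1.2 * sum(acts$labor_req * acts$observed_acreage),
        withdraw_reach = wr, return_reach = down_of[[wr]])
    }

    cities <- vector("list", config$n_cities)
    if (config$n_cities > 0) for (u in seq_len(config$n_cities)) {
      wr <- sample(non_mouth, 1,
                   prob = win_free[non_mouth] / sum(win_free[non_mouth]))
      delta <- stats::runif(1, 6, 11)
      q <- stats::runif(1, 0.01, 0.04) * worst * win_free[[wr]]
      a_s <- stats::runif(1, 0.2, 0.6)
      cities[[u]] <- city(sprintf("c%02d", u),
                          a_d = a_s + delta, b_d = 0.7 * delta / q,
                          a_s = a_s, b_s = 0.3 * delta / q,
                          withdraw_reach = wr, return_reach = down_of[[wr]])
    }

    bas <- basin(net, districts, cities)

    # baseline flows fix the WUA flow scale (health in (0.5, 0.95) at
    # baseline) and the mouth minimum flow (satisfiable under the worst
    # drought by construction)
    base_div <- instance_diversions(bas, scale = 1)
    state <- propagate_flows(net, base_div, check = TRUE)
    h <- stats::runif(n, 0.55, 0.9)
    wout <- pmax(state$wout[match(ids, state$reach_id)], 1e-6)
    bas$network$reaches$flow_scale <- log(1 - h) /
      (bas$network$reaches$beta * wout)
    worst_div <- instance_diversions(bas, scale = worst)
    worst_net <- apply_drought(bas$network, max(config$drought_levels, 0))
    worst_state <- propagate_flows(worst_net, worst_div, check = FALSE)
    mouth_worst <- worst_state$wout[match(bas$network$mouth,
                                          worst_state$reach_id)]
    if (min(worst_state$wout) < -1e-6 || mouth_worst <= 0)
      stop("generated instance is infeasible under the worst drought; ",
           "use a different seed or smaller demands")
    i_mouth <- match(bas$network$mouth, bas$network$reaches$reach_id)
    bas$network$reaches$min_env_flow[i_mouth] <- 0.5 * mouth_worst
    bas$network$reaches$min_env_flow_drought[i_mouth] <- 0.5 * mouth_worst

    for (lev in c(0, config$drought_levels)) {
      s <- propagate_flows(apply_drought(bas$network, lev),
                           instance_diversions(bas, scale = 1 - lev),
                           check = FALSE)
      stopifnot(min(s$wout) > -1e-6)
    }

    obs <- do.call(rbind, lapply(seq_len(n), function(s)
      cbind(reach_id = ids[s],
            generate_wua_observations(
              beta = bas$network$reaches$beta[s],
              n = sample(20:46, 1), noise_sd = config$noise_sd,
              seed = config$seed * 1000L + s))))
    attr(bas, "wua_observations") <- obs
    attr(bas, "config") <- config
    bas
  })
}

# diversions of all demand units at (scaled) baseline volumes
instance_diversions <- function(basin, scale = 1) {
  d_rows <- lapply(basin$districts, function(d) data.frame(
    unit_id = d$id, unit_type = "district",
    withdraw_reach = d$withdraw_reach,
    return_reach = as.character(d$return_reach),
    volume = scale * sum(d$activities$water_req *
                           d$activities$observed_acreage),
    stringsAsFactors = FALSE))
  c_rows <- lapply(basin$cities, function(u) data.frame(
    unit_id = u$id, unit_type = "city",
    withdraw_reach = u$withdraw_reach,
    return_reach = as.character(u$return_reach),
    volume = urban_optimize(u)$q, stringsAsFactors = FALSE))
  do.call(rbind, c(d_rows, c_rows))
}

#' Generate synthetic WUA observations
#'
#' Flows are spread over the range where the response curve traverses
#' (0.05, 0.95); observed WUA is the curve value plus Gaussian noise,
#' clamped to [0, 1].
#'
#' @param beta negative response parameter.
#' @param n number of observations (>= 3).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return data.frame with columns \code{flow}, \code{wua}.
#' @export
generate_wua_observations <- function(beta, n, noise_sd = 0.05, seed = 1) {
  if (beta >= 0) stop("beta must be negative")
  if (n < 3) stop("n must be >= 3")
  with_seed(seed, {
    flow <- seq(log(1 - 0.05), log(1 - 0.95), length.out = n) / beta
    wua_clean <- 1 - exp(beta * flow)
    wua <- pmin(pmax(wua_clean + stats::rnorm(n, 0, noise_sd), 0), 1)
    data.frame(flow = flow, wua = wua)
  })
}

#' The fixed toy Ebro fixture
#'
#' A 14-reach mainstem-plus-tributaries basin using the 14 fitted WUA
#' response parameters of the Ebro habitat study, the three regulated
#' control-point minimum flows (300 Mm3 at the Mendavia analogue; 945 Mm3
#' normal / 640 Mm3 drought at the Zaragoza analogue; 3,000 Mm3 at the
#' mouth), total annual inflow of 14,600 Mm3, baseline urban withdrawals of
#' 402 Mm3 and irrigation withdrawals of 5,380 Mm3, and the three valuation
#' tiers. The fixture is shipped as plain-text data files with a checksum
#' manifest and is read, never regenerated.
#'
#' @return an (uncalibrated) \code{\link{basin}}; run
#'   \code{\link{calibrate_basin}} before solving policies.
#' @export
toy_ebro <- function() {
  dir <- system.file("extdata", "toy_ebro", package = "basinopt")
  if (!nzchar(dir)) stop("toy fixture not found; is basinopt installed?")
  manifest <- file.path(dir, "manifest.txt")
  if (file.exists(manifest)) {
    want <- utils::read.table(manifest, header = FALSE,
                              col.names = c("md5", "file"),
                              stringsAsFactors = FALSE)
    got <- tools::md5sum(file.path(dir, want$file))
    bad <- want$file[unname(got) != want$md5]
    if (length(bad))
      warning("toy fixture files differ from the manifest: ",
              paste(bad, collapse = ", "))
  }
  read_basin(dir)
}
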