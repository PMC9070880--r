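#' Read a basin instance from a directory of plain-text files
#'
#' Expects the schema the package writes: \code{network.csv} (reach table),
#' \code{districts.csv} (one row per crop-technology activity),
#' \code{endowments.csv} (one row per district), \code{cities.csv}, and an
#' optional \code{config.json} holding the basin availability and valuation
#' tier overrides. All cross-references are validated: downstream links must
#' form a tree, and every withdrawal or return reach must exist.
#'
#' @param dir directory containing the files.
#' @return a \code{\link{basin}}.
#' @export
read_basin <- function(dir) {
  path <- function(f) file.path(dir, f)
  for (f in c("network.csv", "districts.csv", "endowments.csv"))
    if (!file.exists(path(f))) stop("missing file: ", path(f))
  reaches <- utils::read.csv(path("network.csv"), stringsAsFactors = FALSE)
  acts <- utils::read.csv(path("districts.csv"), stringsAsFactors = FALSE)
  endow <- utils::read.csv(path("endowments.csv"), stringsAsFactors = FALSE)
  cities_df <- if (file.exists(path("cities.csv")))
    utils::read.csv(path("cities.csv"), stringsAsFactors = FALSE)
  else NULL
  cfg <- if (file.exists(path("config.json")))
    jsonlite::read_json(path("config.json"), simplifyVector = TRUE)
  else list()

  districts <- lapply(seq_len(nrow(endow)), function(i) {
    e <- endow[i, ]
    a <- acts[acts$district_id == e$district_id, , drop = FALSE]
    if (!nrow(a))
      stop("district ", e$district_id, " has no activities")
    land <- list()
    for (tech in c("flood", "sprinkler", "drip")) {
      col <- paste0("tland_", tech)
      if (col %in% names(e) && !is.na(e[[col]]) && e[[col]] > 0)
        land[[tech]] <- e[[col]]
    }
    irrigation_district(
      id = as.character(e$district_id),
      activities = a[, setdiff(names(a), "district_id"), drop = FALSE],
      land_by_tech = land,
      water_endowment = e$twater, labor_endowment = e$tlabor,
      withdraw_reach = as.character(e$withdraw_reach),
      return_reach = as.character(e$return_reach))
  })
  cities <- if (is.null(cities_df)) list()
  else lapply(seq_len(nrow(cities_df)), function(i) {
    u <- cities_df[i, ]
    city(as.character(u$city_id), u$a_d, u$b_d, u$a_s, u$b_s,
         as.character(u$withdraw_reach), as.character(u$return_reach))
  })
  att <- data.frame(
    unit_id = c(endow$district_id,
                if (!is.null(cities_df)) cities_df$city_id),
    unit_type = c(rep("district", nrow(endow)),
                  if (!is.null(cities_df)) rep("city", nrow(cities_df))),
    withdraw_reach = c(endow$withdraw_reach,
                       if (!is.null(cities_df)) cities_df$withdraw_reach),
    return_reach = c(endow$return_reach,
                     if (!is.null(cities_df)) cities_df$return_reach),
    stringsAsFactors = FALSE)
  net <- river_network(reaches, attachments = att)
  basin(net, districts, cities,
        availability = if (!is.null(cfg$availability)) cfg$availability
        else NULL)
}

#' Write a basin instance to a directory of plain-text files
#'
#' Inverse of \code{\link{read_basin}}; writers are deterministic (stable
#' row order, no thousands separators, UTF-8, '.' decimal point), so
#' re-writing the same instance is byte-identical.
#'
#' @param basin a \code{\link{basin}}.
#' @param dir target directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_basin <- function(basin, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, f)
    utils::write.csv(df, file.path(dir, f), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  wcsv(basin$network$reaches, "network.csv")
  acts <- do.call(rbind, lapply(basin$districts, function(d)
    cbind(district_id = d$id, d$activities)))
  rownames(acts) <- NULL
  wcsv(acts, "districts.csv")
  endow <- do.call(rbind, lapply(basin$districts, function(d) {
    land <- function(t) if (t %in% names(d$land_by_tech))
      d$land_by_tech[[t]] else 0
    data.frame(district_id = d$id, tland_flood = land("flood"),
               tland_sprinkler = land("sprinkler"),
               tland_drip = land("drip"),
               twater = d$water_endowment, tlabor = d$labor_endowment,
               withdraw_reach = d$withdraw_reach,
               return_reach = as.character(d$return_reach),
               stringsAsFactors = FALSE)
  }))
  rownames(endow) <- NULL
  wcsv(endow, "endowments.csv")
  if (length(basin$cities)) {
    cit <- do.call(rbind, lapply(basin$cities, function(u)
      data.frame(city_id = u$id, a_d = u$a_d, b_d = u$b_d, a_s = u$a_s,
                 b_s = u$b_s, withdraw_reach = u$withdraw_reach,
                 return_reach = as.character(u$return_reach),
                 stringsAsFactors = FALSE)))
    rownames(cit) <- NULL
    wcsv(cit, "cities.csv")
  }
  jsonlite::write_json(list(availability = basin$availability),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Export a flow state to CSV
#'
#' @param state a \code{flow_state}.
#' @param file target CSV path.
#' @return \code{file}, invisibly.
#' @export
write_flow_state <- function(state, file) {
  out <- as.data.frame(state)
  out[-1] <- lapply(out[-1], round, 3)
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write the result files of a set of policy solutions
#'
#' Emits the comparative welfare table (\code{comparative.csv}, columns in
#' baseline/ic/eic/wm/ewm order, volumes and money rounded to whole units
#' as in standard basin-study reporting), per-reach flows by policy
#' (\code{flows.csv}), the stacked exchange ledger (\code{exchanges.csv})
#' and a JSON run manifest recording the configuration, seed, solver
#' status and package version. Writers are deterministic.
#'
#' @param solutions named list of \code{basin_solution} objects.
#' @param dir output directory (created if needed).
#' @param config optional list stored in the manifest (e.g. the run
#'   configuration including the seed).
#' @return \code{dir}, invisibly.
#' @export
write_results <- function(solutions, dir, config = list()) {
  stopifnot(length(solutions) >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep <- welfare_report(solutions)
  comp <- cbind(indicator = rownames(rep), round(rep))
  utils::write.csv(comp, file.path(dir, "comparative.csv"),
                   row.names = FALSE, quote = FALSE)
  first <- solutions[[1]]
  flows <- data.frame(reach_id = first$flows$reach_id,
                      stringsAsFactors = FALSE)
  for (nm in colnames(rep))
    flows[[nm]] <- round(solutions[[nm]]$flows$wout[
      match(flows$reach_id, solutions[[nm]]$flows$reach_id)], 3)
  utils::write.csv(flows, file.path(dir, "flows.csv"),
                   row.names = FALSE, quote = FALSE)
  ex <- do.call(rbind, lapply(colnames(rep), function(nm) {
    e <- solutions[[nm]]$exchanges
    if (nrow(e)) cbind(scenario = nm, round_df(e, 4)) else NULL
  }))
  if (is.null(ex))
    ex <- data.frame(scenario = character(0), seller = character(0),
                     buyer = character(0), volume = numeric(0),
                     price = numeric(0), payment = numeric(0))
  utils::write.csv(ex, file.path(dir, "exchanges.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- list(
    config = config,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("basinopt")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    scenarios = lapply(solutions, function(s)
      list(policy = s$policy, drought = s$drought, status = s$status,
           iterations = s$iterations)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  df
}

#' Reported Ebro policy ledger (reference values)
#'
#' The published comparative results for the Ebro basin under normal
#' weather and severe drought: water use, exchanged volumes, mouth flows,
#' irrigated area by crop group and the benefit ledger for the baseline and
#' the four drought policies. Shipped as a plain-text file; used by the
#' arithmetic cross-checks (ledger identities and drought-decline rates)
#' since the underlying basin calibration dataset is not public.
#'
#' @return data.frame with an \code{indicator} column and columns
#'   \code{baseline}, \code{ic}, \code{eic}, \code{wm}, \code{ewm}.
#' @export
ebro_reference_ledger <- function() {
  f <- system.file("extdata", "ebro_reference_ledger.csv",
                   package = "basinopt")
  if (!nzchar(f)) stop("reference ledger not found; is basinopt installed?")
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Percent change of a ledger indicator between two scenarios
#'
#' @param ledger data.frame in the shape of
#'   \code{\link{ebro_reference_ledger}} (or a \code{\link{welfare_report}}
#'   with an added indicator column).
#' @param indicator row name of the indicator.
#' @param from,to column names of the scenarios compared.
#' @return percent change from \code{from} to \code{to} (negative for a
#'   decline).
#' @export
ledger_change_pct <- function(ledger, indicator, from, to) {
  row <- ledger[ledger$indicator == indicator, , drop = FALSE]
  if (nrow(row) != 1L) stop("indicator '", indicator, "' not found")
  100 * (row[[to]] - row[[from]]) / row[[from]]
}
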