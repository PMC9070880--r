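# Builds the fixed toy Ebro fixture under inst/extdata/toy_ebro.
# Run from the package root: Rscript tools/make_toy_ebro.R
# The fixture is committed; this script documents its construction.

devtools::load_all(".", quiet = TRUE)

out <- file.path("inst", "extdata", "toy_ebro")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# 14 reaches named after the habitat-study segments whose fitted WUA
# parameters they carry; a mainstem 202-264-274-406-418-421-426-428 (mouth)
# with six tributaries.
beta <- c(`202` = -9.65, `264` = -2.07, `274` = -1.42, `406` = -16.39,
          `418` = -1.89, `421` = -0.12, `426` = -0.52, `428` = -0.30,
          `433` = -0.10, `441` = -8.14, `446` = -1.96, `455` = -9.61,
          `463` = -0.23, `662` = -0.26)
reaches <- data.frame(
  reach_id  = c("202", "433", "264", "441", "274", "446", "406",
                "455", "418", "463", "421", "662", "426", "428"),
  downstream_id = c("264", "264", "274", "274", "406", "406", "418",
                    "418", "421", "421", "426", "426", "428", NA),
  # reach lengths are aggregated river-section lengths; the network totals
  # 8,900 km of valued river
  length_km = c(350, 1300, 400, 600, 400, 500, 450, 900, 500, 1300, 600,
                800, 580, 220),
  # tributaries carry most of the water, as in the basin the fixture mimics
  local_inflow = c(1700, 1600, 200, 1200, 150, 3600, 200, 3400, 150,
                   1200, 200, 900, 80, 20),
  min_env_flow = c(0, 0, 300, 0, 0, 0, 0, 0, 0, 0, 945, 0, 0, 3000),
  min_env_flow_drought = c(0, 0, 300, 0, 0, 0, 0, 0, 0, 0, 640, 0, 0, 3000),
  valuation_tier = c("high", "medium", "low", "high", "low", "high",
                     "low", "high", "low", "medium", "low", "medium",
                     "low", "high"),
  stringsAsFactors = FALSE)
reaches$beta <- unname(beta[reaches$reach_id])
reaches$r_ir <- 0.2
reaches$r_urb <- 0.8
# losses close the annual balance at a mouth flow of 8,895 Mm3 given the
# baseline withdrawals (5,380 irrigation, 402 urban) and return coefficients
total_loss <- 14600 - 8895 - (1 - 0.2) * 5380 - (1 - 0.8) * 402
reaches$loss <- total_loss * reaches$local_inflow / sum(reaches$local_inflow)
reaches$flow_scale <- 1   # fitted below from the baseline flows
reaches$closure <- 0

cat("total inflow:", sum(reaches$local_inflow),
    " total loss:", round(total_loss, 1), "\n")

# districts: crop parameters from the generator's catalog; the vegetable
# water requirement closes irrigation withdrawals at 5,380 Mm3 and the
# vegetable cost closes baseline irrigation profit at 629 M-euro
cat_df <- basinopt:::crop_catalog()
act <- function(crop, tech, acreage) {
  r <- cat_df[cat_df$crop_id == crop & cat_df$tech == tech, ]
  data.frame(crop_id = crop, group = r$group, tech = tech, price = r$price,
             cost = r$cost, water_req = r$water_req, labor_req = r$labor_req,
             observed_acreage = acreage, avg_yield = r$base_yield,
             stringsAsFactors = FALSE)
}
a_raa <- rbind(act("barley", "flood", 110), act("corn", "sprinkler", 90),
               act("alfalfa", "flood", 60))
a_bar <- rbind(act("corn", "sprinkler", 80), act("wheat", "flood", 60))
a_jal <- rbind(act("fruit", "drip", 60), act("fruit", "flood", 24))
a_lod <- rbind(act("fruit", "drip", 20), act("vegetables", "drip", 25))
rest_water <- sum(a_raa$water_req * a_raa$observed_acreage) +
  sum(a_bar$water_req * a_bar$observed_acreage) +
  sum(a_jal$water_req * a_jal$observed_acreage) + 7 * 20
a_lod$water_req[a_lod$crop_id == "vegetables"] <- (5380 - rest_water) / 25
stopifnot(abs(a_lod$water_req[2] - 5.88) < 1e-9)

mkd <- function(id, acts, wr, rr) {
  land <- tapply(acts$observed_acreage, acts$tech, sum) * 1.25
  irrigation_district(
    id, acts, land_by_tech = as.list(land),
    water_endowment = 1.15 * sum(acts$water_req * acts$observed_acreage),
    labor_endowment = 1.25 * sum(acts$labor_req * acts$observed_acreage),
    withdraw_reach = wr, return_reach = rr)
}
# districts withdraw from the tributaries they sit on; returns re-enter the
# mainstem reach below the confluence
districts <- list(mkd("alto_aragon", a_raa, "446", "406"),
                  mkd("bardenas", a_bar, "455", "418"),
                  mkd("jalon", a_jal, "463", "421"),
                  mkd("lodosa", a_lod, "433", "264"))

# cities: identical demand-supply gap delta sized so total baseline urban
# surplus is 1,857 M-euro over 402 Mm3 of withdrawals
delta <- 2 * 1857 / 402
mkc <- function(id, q, wr, rr)
  city(id, a_d = 0.4 + delta, b_d = 0.7 * delta / q,
       a_s = 0.4, b_s = 0.3 * delta / q, withdraw_reach = wr,
       return_reach = rr)
cities <- list(mkc("zaragoza", 200, "421", "426"),
               mkc("logrono", 134, "274", "406"),
               mkc("tortosa_urban", 68, "426", "428"))

net <- river_network(reaches)
bas <- basin(net, districts, cities)

# flow scales: baseline health targets per reach. Reaches depleted by
# withdrawals sit lower on their response curve (steeper marginal habitat
# response), undepleted mountain reaches near saturation.
div <- basinopt:::instance_diversions(bas)
state <- propagate_flows(net, div)
h <- c(`202` = 0.85, `264` = 0.75, `274` = 0.75, `406` = 0.72,
       `418` = 0.72, `421` = 0.75, `426` = 0.75, `428` = 0.80,
       `433` = 0.70, `441` = 0.80, `446` = 0.55, `455` = 0.75,
       `463` = 0.60, `662` = 0.70)
ord <- bas$network$reaches$reach_id
wout <- state$wout[match(ord, state$reach_id)]
bas$network$reaches$flow_scale <-
  log(1 - unname(h[ord])) / (bas$network$reaches$beta * wout)

cat("baseline irrigation withdrawals:",
    sum(vapply(districts, function(d)
      sum(d$activities$water_req * d$activities$observed_acreage),
      numeric(1))), "\n")
cat("baseline mouth flow:", wout[ord == "428"], "\n")
stopifnot(abs(wout[ord == "428"] - 8895) < 1e-6)

write_basin(bas, out)
files <- c("network.csv", "districts.csv", "endowments.csv", "cities.csv",
           "config.json")
md5 <- tools::md5sum(file.path(out, files))
writeLines(paste(unname(md5), files), file.path(out, "manifest.txt"))
cat("fixture written to", out, "\n")
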