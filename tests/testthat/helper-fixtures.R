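# Shared fixtures, all built in code at test time.

# small curated panel from the generator (fast default for model tests)
small_panel <- function(n_regions = 12, n_months = 12, seed = 7, ...) {
  sim <- simulate_mgsr_data(generator_config(
    n_regions = n_regions, n_months = n_months, seed = seed, ...))
  curate(sim$raw)$panel
}

# hand-crafted 3-region, 3-month raw input set with one merger pair
# (R1 + R2 -> M1) and known arithmetic throughout
tiny_raw <- function() {
  months <- c("2018-01", "2018-02", "2018-03")
  regions <- data.frame(
    region_id = c("R1", "R2", "R3"), year = 2018,
    population = c(100000, 300000, 200000),
    population_over_65 = c(19000, 60000, 50000),
    people = c(96, 104, 100), places = c(99, 101, 100),
    lives = c(98, 102, 100),
    merger_group = c("M1", "M1", ""))
  providers <- expand.grid(provider_id = c("P1", "P2", "P3", "P4"),
                           month = months, stringsAsFactors = FALSE)
  providers$region_id <- c(P1 = "R1", P2 = "R1", P3 = "R2",
                           P4 = "R3")[providers$provider_id]
  providers$count <- c(P1 = 400, P2 = 600, P3 = 3000, P4 = 2000)[
    providers$provider_id]
  gp <- expand.grid(region_id = c("R1", "R2", "R3"), month = months,
                    stringsAsFactors = FALSE)
  gp$count <- c(R1 = 40000, R2 = 120000, R3 = 90000)[gp$region_id]
  contracts <- rbind(
    data.frame(contract_id = "C111", month = months, count = 300,
               service = "111"),
    data.frame(contract_id = "CAMB", month = months, count = 600,
               service = "ambulance"))
  contract_map <- data.frame(
    contract_id = c("C111", "C111", "C111", "CAMB", "CAMB", "CAMB"),
    region_id = c("R1", "R2", "R3", "R1", "R2", "R3"))
  list(providers = providers, contracts = contracts,
       contract_map = contract_map, regions = regions, gp = gp)
}

# stub level-0 model that "predicts" a stored column of newdata, used to
# verify the combiner against exact linear systems
make_stub <- function(col) structure(list(col = col), class = "stub_model")
predict.stub_model <- function(object, newdata, ...) newdata[[object$col]]
registerS3method("predict", "stub_model", predict.stub_model)

# independent single-pass metric oracles
r2_oracle <- function(truth, pred) {
  1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2)
}
mape_oracle <- function(truth, pred) sum(abs(truth - pred) / truth) / length(truth)
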