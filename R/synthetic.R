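#' Configuration for the synthetic raw-data generator
#'
#' Defaults emulate the curated study panel: 76 regions observed for 24
#' months, capacity rates calibrated to the cohort's descriptive
#' statistics (GP appointments ~4382, 111 calls ~354, ambulance calls
#' ~352 per 10,000 per month), populations with median ~500,000, health
#' indices around base 100, and a winter-peaking seasonal term in the
#' attendance rate.
#'
#' @param n_regions Number of regions.
#' @param n_months Number of consecutive months.
#' @param start First month ("YYYY-MM").
#' @param seed Integer seed; one seed drives a hierarchical generator
#'   (region-level draws first, then an independent monthly stream per
#'   region), so changing `n_months` does not reshuffle region draws.
#' @param capacity_effect_weight,health_effect_weight Weights `w_c`, `w_h`
#'   on the two latent signal components of the attendance rate.
#' @param noise_sd Standard deviation of the Gaussian observation noise
#'   on the monthly attendance rate (per 10,000).
#' @param seasonal_amplitude Amplitude of the sinusoidal seasonal term,
#'   peaking in January (per 10,000).
#' @param missing_counts Named list mapping a variable
#'   (`health_index`, `capacity_111`, `ambulance_capacity`,
#'   `gp_capacity`, `ed_attendances`) to the exact number of panel rows
#'   to blank in the raw files. Each variable is blanked at its native
#'   granularity (region-years for the health index, contract-months for
#'   111/ambulance, region-months otherwise); an unrepresentable count
#'   is an error.
#' @param capacity_means Target marginal means of the three capacity
#'   rates (per 10,000).
#' @param population_range Clipping range for region populations
#'   (persons).
#' @param index_sd Between-region standard deviations of the People,
#'   Places and Lives indices.
#' @param contract_regions_111 Optional explicit partition of regions
#'   into 111 contracts (list of character vectors); default groups of 8.
#' @param annual_drift If `TRUE` (default), populations grow ~0.7%/yr
#'   and age structure and health indices drift slowly between years;
#'   `FALSE` freezes all annual covariates (a stationary world, used for
#'   year-ahead stationarity checks).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_regions = 76L, n_months = 24L,
                             start = "2018-01", seed = 0L,
                             capacity_effect_weight = 1,
                             health_effect_weight = 1,
                             noise_sd = 25,
                             seasonal_amplitude = 15,
                             missing_counts = list(),
                             capacity_means = c(gp = 4382, c111 = 354,
                                                amb = 352),
                             population_range = c(1e5, 3.4e6),
                             index_sd = c(people = 6, places = 2, lives = 6),
                             contract_regions_111 = NULL,
                             annual_drift = TRUE) {
  stopifnot(n_regions >= 1, n_months >= 1,
            capacity_effect_weight >= 0, health_effect_weight >= 0,
            noise_sd >= 0, seasonal_amplitude >= 0)
  check_month(start)
  bad <- setdiff(names(missing_counts),
                 c("health_index", "capacity_111", "ambulance_capacity",
                   "gp_capacity", "ed_attendances"))
  if (length(bad)) stop("unknown missing_counts variable(s): ",
                        paste(bad, collapse = ", "))
  if (any(unlist(missing_counts) > n_regions * n_months)) {
    stop("missing counts exceed panel size")
  }
  structure(list(
    n_regions = as.integer(n_regions), n_months = as.integer(n_months),
    start = start, seed = as.integer(seed),
    w_c = capacity_effect_weight, w_h = health_effect_weight,
    noise_sd = noise_sd, seasonal_amplitude = seasonal_amplitude,
    missing_counts = missing_counts,
    capacity_means = capacity_means,
    population_range = population_range,
    index_sd = index_sd,
    contract_regions_111 = contract_regions_111,
    annual_drift = isTRUE(annual_drift)),
    class = "generator_config")
}

#' Latent capacity component of the attendance rate
#'
#' Documented fixed form: linear in the three capacity rates plus one
#' saturating ambulance term, so the signal is smooth and non-linear but
#' recoverable. Ambulance capacity carries most of the variance, GP
#' capacity the least.
#'
#' @param gp,c111,amb Capacity rates per 10,000.
#' @return Numeric component of the monthly attendance rate.
#' @export
capacity_signal <- function(gp, c111, amb) {
  0.04 * gp + 0.18 * c111 + 0.28 * amb + 40 * tanh((amb - 350) / 300)
}

#' Latent population-health component of the attendance rate
#'
#' Documented fixed form: linear in population and age structure, linear
#' and *decreasing* in each Health-Index domain (healthier regions attend
#' less), plus one saturating population term. Population is the dominant
#' driver.
#'
#' @param pop_scaled Population / 10,000.
#' @param pct65 Percentage of population over 65.
#' @param people,places,lives Health-Index domain values (base 100).
#' @return Numeric component of the monthly attendance rate.
#' @export
health_signal <- function(pop_scaled, pct65, people, places, lives) {
  2.0 * pop_scaled + 4.0 * pct65 +
    0.8 * (100 - people) + 0.5 * (100 - places) + 1.6 * (100 - lives) +
    30 * tanh((pop_scaled - 60) / 50)
}

#' Seasonal term of the attendance rate
#'
#' Sinusoid over the calendar year peaking in January, so December to
#' February sit near the maximum (the winter pressure months).
#'
#' @param month "YYYY-MM" labels.
#' @param amplitude Peak deviation from the annual mean (per 10,000).
#' @return Numeric seasonal offsets.
#' @export
seasonal_term <- function(month, amplitude) {
  amplitude * cos(2 * pi * (month_num(month) - 1) / 12)
}

# child seed for region r's monthly stream; kept below 2^31
derive_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(r) * 7919 + 1) %%
               2147483647)
}

#' Generate a raw multi-source input set with ground truth
#'
#' Draws region-level characteristics, monthly capacity rates, and the
#' latent attendance rate `y = w_h * f_h + w_c * f_c + seasonal + noise`,
#' then decomposes everything into the raw file schema the curation
#' pipeline consumes: provider-level ED counts, contract-level 111 and
#' ambulance counts, region-level GP counts and an annual region
#' registry. The ground truth records, row for row, the signal
#' components of the panel that curation reconstructs.
#'
#' @param config A [generator_config()].
#' @return List with `raw` (data frames `providers`, `contracts`,
#'   `contract_map`, `regions`, `gp`), `truth` (one row per region-month
#'   with covariates, components and `y`) and `config`.
#' @export
simulate_mgsr_data <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_regions
  months <- month_seq(config$start, config$n_months)
  years <- sort(unique(month_year(months)))
  region_ids <- sprintf("R%02d", seq_len(n))

  ## ---- region-level draws (fixed count, independent of n_months) ----
  set.seed(config$seed)
  pop1 <- rlnorm(n, meanlog = log(5e5), sdlog = 0.65)
  pop1 <- pmin(pmax(pop1, config$population_range[1]), config$population_range[2])
  drift_on <- as.numeric(config$annual_drift)
  pop_growth <- 0.007 * (1 + 0.3 * rnorm(n)) * drift_on   # ~0.7%/yr
  pct65_1 <- pmin(pmax(rnorm(n, 19, 4), 5), 35)
  pct65_drift <- rnorm(n, 0.1, 0.05) * drift_on
  people1 <- rnorm(n, 99, config$index_sd[["people"]])
  places1 <- rnorm(n, 100, config$index_sd[["places"]])
  lives1 <- rnorm(n, 100, config$index_sd[["lives"]])
  index_drift <- matrix(rnorm(3 * n, 0, 0.5), ncol = 3) * drift_on
  # region-level multiplicative bases of the capacity rates; the meanlog
  # correction keeps the marginal mean at the configured target
  sdl_r <- c(gp = 0.17, c111 = 0.45, amb = 0.75)
  sdl_m <- 0.06
  cap_base <- sapply(c("gp", "c111", "amb"), function(v) {
    rlnorm(n, meanlog = log(config$capacity_means[[v]]) -
             (sdl_r[[v]]^2 + sdl_m^2) / 2, sdlog = sdl_r[[v]])
  })
  provider_share <- runif(n, 0.3, 0.7)               # split across 2 providers

  ## ---- registry (one row per region-year) ----
  registry <- do.call(rbind, lapply(seq_along(years), function(k) {
    yfac <- (1 + pop_growth)^(k - 1)
    data.frame(region_id = region_ids, year = years[k],
               population = pop1 * yfac,
               population_over_65 =
                 pop1 * yfac * pmin(pct65_1 + pct65_drift * (k - 1), 99) / 100,
               people = people1 + index_drift[, 1] * (k - 1),
               places = places1 + index_drift[, 2] * (k - 1),
               lives = lives1 + index_drift[, 3] * (k - 1),
               merger_group = "")
  }))

  ## ---- monthly streams (one seeded stream per region) ----
  grid <- expand.grid(region_id = region_ids, month = months,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$region_id, grid$month), , drop = FALSE]
  rownames(grid) <- NULL
  innov_list <- lapply(seq_len(n), function(r) {
    set.seed(derive_seed(config$seed, r))
    # 4 draws per month, month-major, so extending n_months extends the
    # stream without reshuffling earlier months
    draws <- matrix(rnorm(4 * config$n_months), ncol = 4, byrow = TRUE)
    list(innov = draws[, 1:3, drop = FALSE] * sdl_m,
         noise = draws[, 4] * config$noise_sd)
  })

  ridx <- match(grid$region_id, region_ids)
  midx <- month_index(grid$month, config$start) + 1L
  gp_rate <- cap_base[ridx, "gp"] *
    exp(vapply(seq_len(nrow(grid)),
               function(i) innov_list[[ridx[i]]]$innov[midx[i], 1], 0.0))
  c111_region <- cap_base[ridx, "c111"] *
    exp(vapply(seq_len(nrow(grid)),
               function(i) innov_list[[ridx[i]]]$innov[midx[i], 2], 0.0))
  amb_region <- cap_base[ridx, "amb"] *
    exp(vapply(seq_len(nrow(grid)),
               function(i) innov_list[[ridx[i]]]$innov[midx[i], 3], 0.0))
  eps <- vapply(seq_len(nrow(grid)),
                function(i) innov_list[[ridx[i]]]$noise[midx[i]], 0.0)

  yr <- month_year(grid$month)
  pop <- registry_lookup(registry, grid$region_id, yr, "population")

  ## ---- contract structure and stratified capacity covariates ----
  contracts_111 <- config$contract_regions_111 %||%
    split(region_ids, ceiling(seq_len(n) / 8))
  contracts_amb <- split(region_ids, ceiling(seq_len(n) / ceiling(n / 11)))
  cmap <- rbind(
    contract_table(contracts_111, "N111"),
    contract_table(contracts_amb, "AMB"))

  c111_raw <- c111_region * pop / 10000
  amb_raw <- amb_region * pop / 10000
  contract_counts <- rbind(
    contract_counts_from(grid, c111_raw, contracts_111, "N111", "111"),
    contract_counts_from(grid, amb_raw, contracts_amb, "AMB", "ambulance"))

  # the covariates downstream models see are the post-stratification
  # rates; recompute them with the curation operation itself
  alloc_111 <- stratify_by_population(
    contract_counts[contract_counts$service == "111",
                    c("contract_id", "month", "count")], cmap, registry)
  alloc_amb <- stratify_by_population(
    contract_counts[contract_counts$service == "ambulance",
                    c("contract_id", "month", "count")], cmap, registry)
  k111 <- match(paste(grid$region_id, grid$month),
                paste(alloc_111$region_id, alloc_111$month))
  kamb <- match(paste(grid$region_id, grid$month),
                paste(alloc_amb$region_id, alloc_amb$month))
  c111_rate <- scale_per_10k(alloc_111$count[k111], pop)
  amb_rate <- scale_per_10k(alloc_amb$count[kamb], pop)

  ## ---- latent attendance rate ----
  pop_scaled <- pop / 10000
  pct65 <- registry_lookup(registry, grid$region_id, yr, "population_over_65") /
    pop * 100
  people <- registry_lookup(registry, grid$region_id, yr, "people")
  places <- registry_lookup(registry, grid$region_id, yr, "places")
  lives <- registry_lookup(registry, grid$region_id, yr, "lives")

  f_c <- capacity_signal(gp_rate, c111_rate, amb_rate)
  f_h <- health_signal(pop_scaled, pct65, people, places, lives)
  seas <- seasonal_term(grid$month, config$seasonal_amplitude)
  y <- config$w_c * f_c + config$w_h * f_h + seas + eps
  ed_raw <- pmax(y, 0) * pop / 10000
  y <- scale_per_10k(ed_raw, pop)          # keep truth exactly curation's value

  truth <- data.frame(grid,
                      gp_capacity = gp_rate, capacity_111 = c111_rate,
                      ambulance_capacity = amb_rate,
                      population_scaled = pop_scaled, pct_over_65 = pct65,
                      people_index = people, places_index = places,
                      lives_index = lives,
                      capacity_component = config$w_c * f_c,
                      health_component = config$w_h * f_h,
                      seasonal = seas, noise = eps,
                      ed_attendances = y)

  ## ---- raw files ----
  providers <- rbind(
    data.frame(provider_id = paste0(grid$region_id, "-a"),
               region_id = grid$region_id, month = grid$month,
               count = ed_raw * provider_share[ridx]),
    data.frame(provider_id = paste0(grid$region_id, "-b"),
               region_id = grid$region_id, month = grid$month,
               count = ed_raw * (1 - provider_share[ridx])))
  gp <- data.frame(region_id = grid$region_id, month = grid$month,
                   count = gp_rate * pop / 10000)
  raw <- list(providers = providers, contracts = contract_counts,
              contract_map = cmap, regions = registry, gp = gp)

  raw <- inject_missing(raw, config, months, contracts_111, contracts_amb,
                        region_ids)
  list(raw = raw, truth = truth, config = config)
}

contract_table <- function(groups, prefix) {
  do.call(rbind, lapply(seq_along(groups), function(g) {
    data.frame(contract_id = sprintf("%s%02d", prefix, g),
               region_id = groups[[g]])
  }))
}

contract_counts_from <- function(grid, raw_counts, groups, prefix, service) {
  region_to_contract <- stats::setNames(
    rep(sprintf("%s%02d", prefix, seq_along(groups)), lengths(groups)),
    unlist(groups))
  df <- data.frame(contract_id = region_to_contract[grid$region_id],
                   month = grid$month, count = raw_counts)
  out <- group_sum(df, c("contract_id", "month"), "count")
  out$service <- service
  out
}

# Blank exactly the configured number of panel rows per variable, at each
# variable's native granularity. Selection order is deterministic given
# the config seed.
inject_missing <- function(raw, config, months, contracts_111, contracts_amb,
                           region_ids) {
  mc <- config$missing_counts
  if (!length(mc)) return(raw)
  set.seed(derive_seed(config$seed, 999983L))

  pick_units <- function(units, footprints, k, what) {
    ord <- sample(length(units))
    chosen <- integer(0)
    left <- k
    for (i in ord) {
      if (left >= footprints[i]) {
        chosen <- c(chosen, i)
        left <- left - footprints[i]
      }
      if (left == 0) break
    }
    if (left != 0) {
      stop("infeasible missing count for ", what, ": ", k,
           " rows cannot be composed from the native record footprints")
    }
    chosen
  }

  if (!is.null(mc$health_index)) {
    units <- unique(raw$regions[c("region_id", "year")])
    foot <- vapply(seq_len(nrow(units)), function(i) {
      sum(month_year(months) == units$year[i])
    }, 0L)
    ch <- pick_units(seq_len(nrow(units)), foot, mc$health_index, "health_index")
    hit <- paste(raw$regions$region_id, raw$regions$year) %in%
      paste(units$region_id[ch], units$year[ch])
    raw$regions[hit, c("people", "places", "lives")] <- NA
  }
  for (svc in c("111", "ambulance")) {
    var <- if (svc == "111") "capacity_111" else "ambulance_capacity"
    if (is.null(mc[[var]])) next
    rows <- which(raw$contracts$service == svc)
    members <- table(raw$contract_map$contract_id)
    foot <- as.integer(members[raw$contracts$contract_id[rows]])
    ch <- pick_units(rows, foot, mc[[var]], var)
    raw$contracts$count[rows[ch]] <- NA
  }
  if (!is.null(mc$gp_capacity)) {
    ch <- pick_units(seq_len(nrow(raw$gp)), rep(1L, nrow(raw$gp)),
                     mc$gp_capacity, "gp_capacity")
    raw$gp$count[ch] <- NA
  }
  if (!is.null(mc$ed_attendances)) {
    first <- raw$providers$provider_id == paste0(raw$providers$region_id, "-a")
    idx <- which(first)
    ch <- pick_units(idx, rep(1L, length(idx)), mc$ed_attendances,
                     "ed_attendances")
    raw$providers$count[idx[ch]] <- NA
  }
  raw
}

#' Write a raw input set to CSV files
#'
#' @param raw The `raw` element of [simulate_mgsr_data()], or a
#'   compatible named list of data frames.
#' @param dir Output directory (created if needed).
#' @param truth Optional ground-truth data frame, written as
#'   `ground_truth.csv`.
#' @return Invisibly, the directory.
#' @export
write_raw_dir <- function(raw, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(raw)) {
    write.csv(raw[[nm]], file.path(dir, paste0(nm, ".csv")), row.names = FALSE,
              na = "")
  }
  if (!is.null(truth)) {
    write.csv(truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Raw input set shaped like the study's curation accounting
#'
#' A deterministic 81-region, 24-month raw data set in which 5 regions
#' have incomplete ED attendance data (so curation drops them), exactly
#' 48 rows are missing the health indices (two retained regions, both
#' years) and exactly 158 rows are missing 111 capacity (a 7-region
#' contract blanked for 22 months plus a single-region contract blanked
#' for 4), the two sets disjoint. Curation therefore yields 76 retained
#' regions, 1824 potential records, 1618 final records and 74 regions
#' represented in the final panel.
#'
#' @return A raw input list as in [simulate_mgsr_data()]`$raw`.
#' @export
paper_shaped_fixture <- function() {
  n <- 81L
  ids <- sprintf("R%02d", seq_len(n))
  part <- c(list(ids[3:9], ids[10]),
            split(ids[-(3:10)], ceiling(seq_along(ids[-(3:10)]) / 8)))
  cfg <- generator_config(n_regions = n, n_months = 24L, seed = 20180101L,
                          contract_regions_111 = part)
  sim <- simulate_mgsr_data(cfg)
  raw <- sim$raw
  months <- month_seq(cfg$start, cfg$n_months)

  # 5 regions with incomplete ED data: blank one provider-month each
  ed_miss <- ids[77:81]
  hit <- raw$providers$region_id %in% ed_miss &
    raw$providers$month == months[3] &
    raw$providers$provider_id == paste0(raw$providers$region_id, "-a")
  raw$providers$count[hit] <- NA

  # 48 health-index rows: two retained regions, all months of both years
  raw$regions[raw$regions$region_id %in% ids[1:2],
              c("people", "places", "lives")] <- NA

  # 158 111-capacity rows: 7-region contract x 22 months + 1-region x 4
  c7 <- raw$contract_map$contract_id[match(ids[3], raw$contract_map$region_id)]
  c1 <- raw$contract_map$contract_id[match(ids[10], raw$contract_map$region_id)]
  raw$contracts$count[raw$contracts$service == "111" &
                        ((raw$contracts$contract_id == c7 &
                            raw$contracts$month %in% months[1:22]) |
                           (raw$contracts$contract_id == c1 &
                              raw$contracts$month %in% months[1:4]))] <- NA
  raw
}
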