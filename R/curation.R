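#' Aggregate provider-level monthly counts to regions
#'
#' Provider-level totals (e.g. ED attendances reported per hospital trust)
#' are summed over the providers mapped to each region, month by month.
#'
#' @param counts Data frame with columns `provider_id`, `month`, `count`
#'   (a `region_id` column, if present, is ignored in favour of `mapping`).
#' @param mapping Data frame with columns `provider_id`, `region_id`.
#' @return Data frame `region_id`, `month`, `count` with one row per
#'   region-month observed in `counts`.
#' @export
aggregate_providers <- function(counts, mapping) {
  check_columns(counts, c("provider_id", "month", "count"), "provider counts")
  check_columns(mapping, c("provider_id", "region_id"), "provider mapping")
  check_month(counts$month)
  if (any(counts$count < 0, na.rm = TRUE)) stop("negative provider counts")
  idx <- match(counts$provider_id, mapping$provider_id)
  if (anyNA(idx)) {
    stop("unmapped provider_id(s): ",
         paste(unique(counts$provider_id[is.na(idx)]), collapse = ", "))
  }
  counts$region_id <- mapping$region_id[idx]
  group_sum(counts, c("region_id", "month"), "count")
}

#' Apportion contract-level counts to regions by population share
#'
#' Services commissioned per contract (111 calls offered, ambulance calls
#' answered) cover sets of regions. Each contract-month count is split
#' across its member regions in proportion to their population in the
#' calendar year of the record, so allocations over a contract always sum
#' back to the contract count.
#'
#' @param counts Data frame `contract_id`, `month`, `count`.
#' @param mapping Data frame `contract_id`, `region_id` (one row per
#'   member region).
#' @param registry Region registry: data frame `region_id`, `year`,
#'   `population` (other columns allowed).
#' @return Data frame `region_id`, `month`, `count` of allocations.
#' @export
stratify_by_population <- function(counts, mapping, registry) {
  check_columns(counts, c("contract_id", "month", "count"), "contract counts")
  check_columns(mapping, c("contract_id", "region_id"), "contract mapping")
  check_columns(registry, c("region_id", "year"), "region registry")
  check_month(counts$month)

  members <- split(mapping$region_id, mapping$contract_id)
  absent <- setdiff(unique(counts$contract_id), names(members))
  if (length(absent)) {
    stop("contract(s) with empty region set: ", paste(absent, collapse = ", "))
  }

  pieces <- lapply(seq_len(nrow(counts)), function(i) {
    regions <- members[[as.character(counts$contract_id[i])]]
    yr <- month_year(counts$month[i])
    pop <- registry_lookup(registry, regions, yr, "population")
    total <- sum(pop)
    if (!is.finite(total) || total <= 0) {
      stop("contract ", counts$contract_id[i], ", month ", counts$month[i],
           ": total population is not positive")
    }
    data.frame(region_id = regions, month = counts$month[i],
               count = counts$count[i] * pop / total)
  })
  alloc <- do.call(rbind, pieces)
  # a region can belong to several contracts: sum its allocations
  group_sum(alloc, c("region_id", "month"), "count")
}

#' Scale a raw count to a rate per 10,000 people
#'
#' @param raw_value Raw count(s).
#' @param population Population of the same unit; must be positive.
#' @return `raw_value * 10000 / population`.
#' @export
scale_per_10k <- function(raw_value, population) {
  if (any(!is.finite(population) | population <= 0)) {
    stop("population must be positive to scale per 10,000")
  }
  raw_value * 10000 / population
}

#' Percentage of a region's population over age 65
#'
#' @param registry Region registry with `region_id`, `year`, `population`,
#'   `population_over_65`.
#' @param region Region identifier(s).
#' @param year Calendar year(s), recycled against `region`.
#' @return Percentage(s) in (0, 100].
#' @export
derive_pct_over_65 <- function(registry, region, year) {
  pop <- registry_lookup(registry, region, year, "population")
  over <- registry_lookup(registry, region, year, "population_over_65")
  if (any(over > pop)) stop("population_over_65 exceeds population")
  100 * over / pop
}

registry_lookup <- function(registry, region, year, field) {
  check_columns(registry, c("region_id", "year", field), "region registry")
  key <- paste(registry$region_id, registry$year)
  idx <- match(paste(region, year), key)
  if (anyNA(idx)) {
    miss <- unique(paste(region, year)[is.na(idx)])
    stop("region registry has no entry for: ", paste(miss, collapse = "; "))
  }
  registry[[field]][idx]
}

#' Aggregate merged regions in a raw (pre-scaling) panel
#'
#' Regions that merged during or after the study window are combined so
#' the panel is stable over the forecasting horizon: count-type columns
#' and populations are summed within a merger group; unit-free index
#' columns (People/Places/Lives) are combined as population-weighted means
#' -- summing an index with base 100 would be meaningless.
#'
#' @param rows Raw panel: one row per region-month with columns
#'   `region_id`, `month`, count columns (`ed_raw`, `gp_raw`, `c111_raw`,
#'   `amb_raw` as present), `population`, `population_over_65`,
#'   `people_index`, `places_index`, `lives_index`.
#' @param registry Registry with `region_id` and `merger_group` (blank or
#'   `NA` merger_group means the region stands alone).
#' @return Panel with one row per merged region per month; `region_id`
#'   becomes the merger-group identifier for grouped regions.
#' @export
merge_regions <- function(rows, registry) {
  check_columns(rows, c("region_id", "month", "population"), "raw panel")
  grp <- merger_group_of(registry)
  bad <- setdiff(unique(rows$region_id), names(grp))
  if (length(bad)) stop("regions absent from registry: ", paste(bad, collapse = ", "))
  rows$.group <- unname(grp[rows$region_id])

  count_cols <- intersect(
    c("ed_raw", "gp_raw", "c111_raw", "amb_raw",
      "population", "population_over_65"), names(rows))
  index_cols <- intersect(
    c("people_index", "places_index", "lives_index"), names(rows))

  key <- paste(rows$.group, rows$month)
  split_rows <- split(rows, factor(key, levels = unique(key[order(rows$.group, rows$month)])))
  out <- lapply(split_rows, function(g) {
    res <- data.frame(region_id = g$.group[1], month = g$month[1])
    for (cc in count_cols) res[[cc]] <- sum(g[[cc]])
    w <- g$population / sum(g$population)
    for (ic in index_cols) res[[ic]] <- sum(w * g[[ic]])
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

merger_group_of <- function(registry) {
  check_columns(registry, "region_id", "region registry")
  reg <- registry[!duplicated(registry$region_id), ]
  grp <- if ("merger_group" %in% names(reg)) as.character(reg$merger_group) else NA
  grp <- ifelse(is.na(grp) | grp == "", as.character(reg$region_id), grp)
  # a region's merger group must be constant across registry years
  if ("merger_group" %in% names(registry)) {
    chk <- tapply(as.character(registry$merger_group), registry$region_id,
                  function(v) length(unique(v[!is.na(v) & v != ""])))
    if (any(chk > 1, na.rm = TRUE)) {
      stop("conflicting merger_group definitions for: ",
           paste(names(chk)[which(chk > 1)], collapse = ", "))
    }
  }
  stats::setNames(grp, reg$region_id)
}

# Fixed attribution order for missing-record accounting: a row missing
# several variables is counted once, under the first group in this order.
MISSING_ORDER <- list(
  health_index = c("people_index", "places_index", "lives_index"),
  capacity_111 = "capacity_111",
  ambulance_capacity = "ambulance_capacity",
  gp_capacity = "gp_capacity",
  ed_attendances = "ed_attendances",
  population = c("population_scaled", "pct_over_65")
)

#' Remove incomplete panel rows, with accounting
#'
#' A region-month survives only if every field is present. Each dropped
#' row is attributed to the first missing variable group in the fixed
#' order health indices, 111, ambulance, GP, attendances, population, so
#' drop counts are disjoint and sum exactly to the number of rows removed.
#'
#' @param rows Scaled panel rows (possibly with `NA` fields).
#' @return List with `panel` (complete rows) and `log` (a `curation_log`:
#'   `n_potential_records`, `n_dropped_by_variable`, `n_final_records`).
#' @export
drop_missing <- function(rows) {
  n_potential <- nrow(rows)
  remaining <- rep(TRUE, n_potential)
  dropped <- stats::setNames(integer(length(MISSING_ORDER)), names(MISSING_ORDER))
  for (grp_name in names(MISSING_ORDER)) {
    cols <- intersect(MISSING_ORDER[[grp_name]], names(rows))
    if (!length(cols)) next
    miss <- remaining & Reduce(`|`, lapply(rows[cols], is.na))
    dropped[grp_name] <- sum(miss)
    remaining <- remaining & !miss
  }
  log <- structure(
    list(n_potential_records = n_potential,
         n_dropped_by_variable = as.list(dropped),
         n_final_records = sum(remaining)),
    class = "curation_log")
  stopifnot(log$n_final_records == n_potential - sum(dropped))
  list(panel = rows[remaining, , drop = FALSE], log = log)
}

#' @export
print.curation_log <- function(x, ...) {
  cat("Curation log\n")
  if (!is.null(x$n_regions_initial)) {
    cat("  regions:", x$n_regions_initial, "initial,",
        x$n_regions_dropped, "dropped (incomplete ED data)\n")
  }
  cat("  potential records:", x$n_potential_records, "\n")
  drops <- unlist(x$n_dropped_by_variable)
  for (v in names(drops)[drops > 0]) cat("  dropped [", v, "]:", drops[v], "\n")
  cat("  final records:", x$n_final_records, "\n")
  invisible(x)
}

#' Annual mean of the monthly ED attendance rate
#'
#' The population-health model's dependent variable: the arithmetic mean
#' of the monthly attendance rate over a region-year's surviving months.
#'
#' @param rows Curated panel rows (complete cases).
#' @return Data frame with one row per region-year: `region_id`, `year`,
#'   the five annual health covariates, `n_months` used, and
#'   `annual_mean_attendances`.
#' @export
annual_mean_target <- function(rows) {
  check_columns(rows, c("region_id", "month", TARGET_VAR), "curated panel")
  yr <- month_year(rows$month)
  key <- paste(rows$region_id, yr, sep = "\r")
  ord <- !duplicated(key)
  out <- data.frame(region_id = rows$region_id[ord], year = yr[ord])
  for (v in intersect(HEALTH_VARS, names(rows))) out[[v]] <- rows[[v]][ord]
  out$n_months <- as.integer(tapply(rows[[TARGET_VAR]], key, length)[key[ord]])
  out$annual_mean_attendances <-
    as.numeric(tapply(rows[[TARGET_VAR]], key, mean)[key[ord]])
  rownames(out) <- NULL
  out[order(out$region_id, out$year), , drop = FALSE]
}

#' Curate raw multi-source inputs into the modelling panel
#'
#' Runs the full processing pipeline: provider aggregation (ED
#' attendances), population-share stratification (111 and ambulance
#' contracts), merger-group aggregation, removal of regions with
#' incomplete ED coverage, per-10,000 scaling, `%>65` derivation, and
#' missing-record removal with accounting.
#'
#' @param raw Either a directory containing the raw CSVs
#'   (`providers.csv`, `contracts.csv`, `contract_map.csv`, `regions.csv`,
#'   `gp.csv`) or a named list of the corresponding data frames
#'   (`providers`, `contracts`, `contract_map`, `regions`, `gp`).
#' @param months Study window as a character vector of "YYYY-MM" labels;
#'   default: every month present in the provider file.
#' @return List with `panel` (one complete row per region-month, columns
#'   `region_id`, `month`, the 8 model covariates and `ed_attendances`)
#'   and `log` (a `curation_log`).
#' @export
curate <- function(raw, months = NULL) {
  if (is.character(raw)) raw <- read_raw_dir(raw)
  for (nm in c("providers", "contracts", "contract_map", "regions", "gp")) {
    if (is.null(raw[[nm]])) stop("raw input is missing '", nm, "'")
  }
  providers <- raw$providers
  registry <- raw$regions
  if (is.null(months)) months <- sort(unique(providers$month))
  check_month(months)

  prov_map <- providers[!duplicated(providers$provider_id),
                        c("provider_id", "region_id")]
  ed <- aggregate_providers(providers[c("provider_id", "month", "count")],
                            prov_map)
  gp <- raw$gp
  check_columns(gp, c("region_id", "month", "count"), "gp counts")
  contracts <- raw$contracts
  check_columns(contracts, c("contract_id", "month", "count", "service"),
                "contracts")
  c111 <- stratify_by_population(
    contracts[contracts$service == "111", c("contract_id", "month", "count")],
    raw$contract_map, registry)
  amb <- stratify_by_population(
    contracts[contracts$service == "ambulance",
              c("contract_id", "month", "count")],
    raw$contract_map, registry)

  # full region x month grid at the unmerged level; absent rows become NA
  grid <- expand.grid(region_id = unique(registry$region_id), month = months,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  put <- function(grid, src, name) {
    idx <- match(paste(grid$region_id, grid$month),
                 paste(src$region_id, src$month))
    grid[[name]] <- src$count[idx]
    grid
  }
  grid <- put(grid, ed, "ed_raw")
  grid <- put(grid, gp, "gp_raw")
  grid <- put(grid, c111, "c111_raw")
  grid <- put(grid, amb, "amb_raw")
  yr <- month_year(grid$month)
  key <- match(paste(grid$region_id, yr), paste(registry$region_id, registry$year))
  for (v in c("population", "population_over_65", "people", "places", "lives")) {
    if (!v %in% names(registry)) stop("region registry is missing '", v, "'")
  }
  grid$population <- registry$population[key]
  grid$population_over_65 <- registry$population_over_65[key]
  grid$people_index <- registry$people[key]
  grid$places_index <- registry$places[key]
  grid$lives_index <- registry$lives[key]

  merged <- merge_regions(grid, registry)

  # regions with incomplete ED attendance series never enter the panel
  ed_complete <- tapply(!is.na(merged$ed_raw), merged$region_id, all)
  keep_regions <- names(ed_complete)[ed_complete]
  n_initial <- length(ed_complete)
  merged <- merged[merged$region_id %in% keep_regions, , drop = FALSE]

  panel <- data.frame(region_id = merged$region_id, month = merged$month)
  panel$gp_capacity <- scale_per_10k(merged$gp_raw, merged$population)
  panel$capacity_111 <- scale_per_10k(merged$c111_raw, merged$population)
  panel$ambulance_capacity <- scale_per_10k(merged$amb_raw, merged$population)
  panel$ed_attendances <- scale_per_10k(merged$ed_raw, merged$population)
  panel$population_scaled <- merged$population / 10000
  panel$pct_over_65 <- 100 * merged$population_over_65 / merged$population
  panel$people_index <- merged$people_index
  panel$places_index <- merged$places_index
  panel$lives_index <- merged$lives_index
  panel <- panel[order(panel$region_id, panel$month), , drop = FALSE]
  rownames(panel) <- NULL

  res <- drop_missing(panel)
  res$log$n_regions_initial <- n_initial
  res$log$n_regions_dropped <- n_initial - length(keep_regions)
  res
}

#' Read the raw input CSVs from a directory
#'
#' @param dir Directory containing `providers.csv`, `contracts.csv`,
#'   `contract_map.csv`, `regions.csv`, `gp.csv` (UTF-8, header row,
#'   months as "YYYY-MM").
#' @return Named list of data frames.
#' @export
read_raw_dir <- function(dir) {
  files <- c(providers = "providers.csv", contracts = "contracts.csv",
             contract_map = "contract_map.csv", regions = "regions.csv",
             gp = "gp.csv")
  out <- lapply(files, function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing raw input file: ", path)
    read.csv(path, stringsAsFactors = FALSE, colClasses = NA)
  })
  names(out) <- names(files)
  out
}

#' Write a curated panel and its log
#'
#' @param curated Result of [curate()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_curated <- function(curated, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  panel_path <- file.path(dir, "panel.csv")
  log_path <- file.path(dir, "curation_log.json")
  write.csv(curated$panel, panel_path, row.names = FALSE)
  jsonlite::write_json(unclass(curated$log), log_path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(panel = panel_path, log = log_path))
}
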