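test_that("provider aggregation sums counts within region-month", {
  counts <- data.frame(provider_id = c("A", "B", "C"),
                       month = "2018-01", count = c(100, 200, 0))
  mapping <- data.frame(provider_id = c("A", "B", "C"),
                        region_id = c("R1", "R1", "R2"))
  out <- aggregate_providers(counts, mapping)
  expect_equal(out$count[out$region_id == "R1"], 300)
  expect_equal(out$count[out$region_id == "R2"], 0)

  counts$provider_id[1] <- "ZZ"
  expect_error(aggregate_providers(counts, mapping), "ZZ")
})

test_that("provider aggregation equals a brute-force group-and-sum", {
  set.seed(11)
  counts <- data.frame(
    provider_id = sprintf("P%02d", sample(10, 60, replace = TRUE)),
    month = sample(month_seq("2018-01", 3), 60, replace = TRUE),
    count = rpois(60, 50))
  mapping <- data.frame(provider_id = sprintf("P%02d", 1:10),
                        region_id = sprintf("R%d", rep(1:3, length.out = 10)))
  out <- aggregate_providers(counts, mapping)
  oracle <- tapply(counts$count,
                   paste(mapping$region_id[match(counts$provider_id,
                                                 mapping$provider_id)],
                         counts$month), sum)
  expect_equal(out$count, as.numeric(oracle[paste(out$region_id, out$month)]))
  expect_equal(sum(out$count), sum(counts$count))  # additivity
})

test_that("population-share stratification is proportional and conservative", {
  registry <- data.frame(region_id = c("R1", "R2", "R3"), year = 2018,
                         population = c(10000, 20000, 30000))
  mapping <- data.frame(contract_id = "C1", region_id = c("R1", "R2", "R3"))
  counts <- data.frame(contract_id = "C1", month = "2018-05", count = 300)
  out <- stratify_by_population(counts, mapping, registry)
  expect_equal(out$count[match(c("R1", "R2", "R3"), out$region_id)],
               c(50, 100, 150))

  one <- stratify_by_population(
    data.frame(contract_id = "C2", month = "2018-05", count = 42),
    data.frame(contract_id = "C2", region_id = "R2"), registry)
  expect_equal(one$count, 42)

  expect_error(stratify_by_population(
    data.frame(contract_id = "CX", month = "2018-05", count = 1),
    mapping, registry), "empty region set")
  registry0 <- transform(registry, population = 0)
  expect_error(stratify_by_population(counts, mapping, registry0),
               "not positive")
})

test_that("stratification conserves contract totals on random structures", {
  set.seed(21)
  for (trial in 1:5) {
    n_r <- sample(5:12, 1)
    registry <- data.frame(region_id = sprintf("R%02d", 1:n_r),
                           year = rep(2018:2019, each = n_r),
                           population = runif(2 * n_r, 5e4, 9e5))
    sizes <- diff(sort(c(0, sample(n_r - 1, sample(1:3, 1)), n_r)))
    mapping <- data.frame(
      contract_id = rep(sprintf("C%d", seq_along(sizes)), sizes),
      region_id = sprintf("R%02d", 1:n_r))
    counts <- expand.grid(contract_id = unique(mapping$contract_id),
                          month = c("2018-03", "2019-11"),
                          stringsAsFactors = FALSE)
    counts$count <- runif(nrow(counts), 100, 1e5)
    out <- stratify_by_population(counts, mapping, registry)
    for (i in seq_len(nrow(counts))) {
      members <- mapping$region_id[mapping$contract_id == counts$contract_id[i]]
      got <- sum(out$count[out$region_id %in% members &
                             out$month == counts$month[i]])
      expect_equal(got, counts$count[i], tolerance = 1e-9)
    }
  }
})

test_that("per-10k scaling round-trips and rejects bad populations", {
  expect_equal(scale_per_10k(5000, 250000), 200)
  expect_equal(scale_per_10k(0, 1000), 0)
  set.seed(3)
  raw <- runif(50, 0, 1e5); pop <- runif(50, 1e4, 1e6)
  expect_equal(scale_per_10k(raw, pop) * pop / 10000, raw, tolerance = 1e-9)
  expect_error(scale_per_10k(10, 0), "positive")
  expect_error(scale_per_10k(10, -5), "positive")
})

test_that("percent over 65 matches the direct formula", {
  registry <- data.frame(region_id = c("R1", "R1", "R2"),
                         year = c(2018, 2019, 2018),
                         population = c(100000, 101000, 50000),
                         population_over_65 = c(19000, 20000, 50000))
  expect_equal(derive_pct_over_65(registry, "R1", 2018), 19)
  expect_equal(derive_pct_over_65(registry, "R2", 2018), 100)
  expect_equal(derive_pct_over_65(registry, c("R1", "R1"), c(2018, 2019)),
               c(19, 100 * 20000 / 101000))
  expect_error(derive_pct_over_65(registry, "R2", 2019), "no entry")
})

test_that("merger aggregation sums counts and population-weights indices", {
  raw <- tiny_raw()
  months <- unique(raw$providers$month)
  grid <- data.frame(region_id = rep(c("R1", "R2", "R3"), length(months)),
                     month = rep(months, each = 3))
  grid$ed_raw <- c(R1 = 1000, R2 = 3000, R3 = 2000)[grid$region_id]
  key <- match(grid$region_id, raw$regions$region_id)
  grid$population <- raw$regions$population[key]
  grid$people_index <- raw$regions$people[key]
  merged <- merge_regions(grid, raw$regions)
  m1 <- merged[merged$region_id == "M1", ]
  expect_equal(nrow(merged), 2 * length(months))
  expect_equal(unique(m1$ed_raw), 4000)          # 1000 + 3000
  expect_equal(unique(m1$population), 400000)
  expect_equal(unique(m1$people_index), 102)     # 0.25*96 + 0.75*104
  r3 <- merged[merged$region_id == "R3", ]       # singleton unchanged
  expect_equal(unique(r3$ed_raw), 2000)
  expect_equal(unique(r3$people_index), 100)

  bad <- raw$regions; bad$merger_group[2] <- "M9"
  bad <- rbind(raw$regions, bad)
  expect_error(merge_regions(grid, bad), "conflicting")
})

test_that("drop_missing attributes each row once, in the fixed order", {
  panel <- data.frame(region_id = "R1", month = "2018-01",
                      gp_capacity = c(1, NA, 1, NA),
                      capacity_111 = c(1, 1, NA, NA),
                      ambulance_capacity = 1, ed_attendances = 1,
                      population_scaled = 1, pct_over_65 = 10,
                      people_index = c(100, 100, 100, NA),
                      places_index = 100, lives_index = 100)
  res <- drop_missing(panel)
  d <- unlist(res$log$n_dropped_by_variable)
  # row 2: gp only; row 3: 111 only; row 4: health first in the order
  expect_equal(unname(d[c("health_index", "capacity_111", "gp_capacity")]),
               c(1L, 1L, 1L))
  expect_equal(res$log$n_final_records, 1L)
  expect_equal(res$log$n_potential_records,
               res$log$n_final_records + sum(d))

  clean <- drop_missing(panel[1, ])
  expect_equal(sum(unlist(clean$log$n_dropped_by_variable)), 0L)
  expect_equal(nrow(clean$panel), 1L)
})

test_that("annual mean target equals a brute-force group mean", {
  panel <- small_panel(n_regions = 6, n_months = 24, seed = 5)
  ann <- annual_mean_target(panel)
  expect_equal(nrow(ann), 12)                    # 6 regions x 2 years
  oracle <- tapply(panel$ed_attendances,
                   paste(panel$region_id, month_year(panel$month)), mean)
  expect_equal(ann$annual_mean_attendances,
               as.numeric(oracle[paste(ann$region_id, ann$year)]))
  # constant and two-month cases
  p2 <- data.frame(region_id = "R1", month = c("2018-01", "2018-02"),
                   ed_attendances = c(90, 110))
  expect_equal(annual_mean_target(p2)$annual_mean_attendances, 100)
})

test_that("full curation of the hand-crafted raw set matches hand arithmetic", {
  cur <- curate(tiny_raw())
  expect_equal(cur$log$n_regions_initial, 2L)    # after merging: M1, R3
  expect_equal(cur$log$n_final_records, 6L)      # 2 regions x 3 months
  m1 <- cur$panel[cur$panel$region_id == "M1", ]
  # ED: (400 + 600 + 3000) * 1e4 / 400000
  expect_equal(unique(m1$ed_attendances), 100)
  # 111: contract 300 split 50/150/100 by population; M1 gets 200
  expect_equal(unique(m1$capacity_111), 200 * 1e4 / 400000)
  expect_equal(unique(m1$pct_over_65), 100 * 79000 / 400000)
  expect_equal(unique(m1$people_index), 102)
  r3 <- cur$panel[cur$panel$region_id == "R3", ]
  expect_equal(unique(r3$capacity_111), 100 * 1e4 / 200000)
  expect_equal(unique(r3$gp_capacity), 90000 * 1e4 / 200000)
})

test_that("curation is deterministic and survives the CSV round trip", {
  raw <- tiny_raw()
  dir <- withr::local_tempdir()
  write_raw_dir(raw, dir)
  a <- curate(raw)
  b <- curate(dir)
  expect_identical(a$panel, b$panel)
  expect_identical(unclass(a$log), unclass(b$log))
})
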