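test_that("read_lpd parses the wide dialect, skipping blank cells", {
  path <- toy_lpd_csv()
  pops <- read_lpd(path)
  expect_equal(nrow(pops), 3)
  expect_true(all(purrr::map_int(pops$data, nrow) <= 11))
  # p2 has observations only in 2000, 2003, 2005, 2010
  expect_equal(pops$data[[2]]$year, c(2000, 2003, 2005, 2010))
  expect_equal(pops$data[[2]]$abundance, c(5, 4, 3, 2))
  # threat flags parse to a set
  expect_setequal(pops$threats[[1]], c("disease", "exploitation"))
  expect_equal(pops$threats[[2]], character(0))
  expect_false(pops$threat_status_known[3])
})

test_that("read_lpd errors name the offending column or record", {
  path <- toy_lpd_csv()
  raw <- readLines(path)
  # drop a mandatory column
  broken <- tempfile(fileext = ".csv")
  writeLines(sub("latitude,", "lat_broken,", raw), broken)
  expect_error(read_lpd(broken), "latitude")
  # unparseable abundance names the row
  broken2 <- tempfile(fileext = ".csv")
  writeLines(sub(",12,", ",twelve,", raw), broken2)
  expect_error(read_lpd(broken2), "p1")
  expect_error(read_lpd(tempfile()), "not found")
})

test_that("wide round trip write_lpd -> read_lpd preserves observations", {
  sim <- small_sim()
  path <- tempfile(fileext = ".csv")
  write_lpd(sim$populations, path)
  back <- read_lpd(path)
  expect_equal(nrow(back), nrow(sim$populations))
  for (i in c(1, 5, nrow(back))) {
    expect_equal(back$data[[i]]$year, sim$populations$data[[i]]$year)
    expect_equal(back$data[[i]]$abundance,
                 sim$populations$data[[i]]$abundance, tolerance = 1e-12)
    expect_setequal(back$threats[[i]], sim$populations$threats[[i]])
  }
})

test_that("filter_series applies the span, point-count and status rules", {
  mk <- function(id, years, known = TRUE) {
    tibble::tibble(
      population_id = id, species_id = "sp", latitude = 0, longitude = 0,
      system = "marine", taxon = "fish", threats = list(character(0)),
      threat_status_known = known,
      data = list(tibble::tibble(year = years,
                                 abundance = seq_along(years) + 1))
    )
  }
  pops <- dplyr::bind_rows(
    mk("span10_pts5", c(1990, 1992, 1995, 1997, 1999)),   # span 10, 5 pts
    mk("span9_pts9", 1991:1999),                          # span 9: dropped
    mk("span15_pts4", c(2000, 2004, 2009, 2014)),         # 4 pts: dropped
    mk("unknown", c(1990, 1992, 1995, 1997, 1999), known = FALSE)
  )
  kept <- filter_series(pops)
  expect_equal(kept$population_id, "span10_pts5")
  # unknown status retained when not required
  kept2 <- filter_series(pops, require_threat_status = FALSE)
  expect_setequal(kept2$population_id, c("span10_pts5", "unknown"))
  # idempotent
  expect_identical(filter_series(kept), kept)
  # thresholds are parameters
  expect_equal(nrow(filter_series(pops, min_span_years = 9,
                                  min_points = 4,
                                  require_threat_status = FALSE)), 4)
})

test_that("prepare_series centres log abundance and year exactly", {
  pops <- tibble::tibble(
    population_id = c("const", "lin"), species_id = "sp",
    latitude = 10.65, longitude = -3.2, system = "marine", taxon = "fish",
    threats = list(character(0), "exploitation"),
    threat_status_known = TRUE,
    data = list(tibble::tibble(year = 2000:2002, abundance = c(10, 10, 10)),
                tibble::tibble(year = 2000:2004,
                               abundance = exp(1:5)))
  )
  prep <- prepare_series(pops)
  cst <- prep[prep$population_id == "const", ]
  expect_equal(cst$centered_log_abundance, c(0, 0, 0))
  lin <- prep[prep$population_id == "lin", ]
  expect_equal(lin$centered_year, c(-2, -1, 0, 1, 2))
  expect_equal(lin$centered_log_abundance, (1:5) - 3)
  # centring removes the mean to numerical precision
  for (id in unique(prep$population_id)) {
    expect_lt(abs(mean(prep$centered_log_abundance[
      prep$population_id == id])), 1e-10)
    expect_lt(abs(mean(prep$centered_year[prep$population_id == id])),
              1e-10)
  }
  # no observation invented or lost
  expect_equal(nrow(prep), sum(purrr::map_int(pops$data, nrow)))
  # site id from integer-rounded coordinates (10.65 -> 11)
  expect_true(all(prep$site_id == "s+011-0003"))
})

test_that("zero abundances get the 1%-of-mean offset", {
  pops <- tibble::tibble(
    population_id = "z", species_id = "sp", latitude = 0, longitude = 0,
    system = "marine", taxon = "fish", threats = list(character(0)),
    threat_status_known = TRUE,
    data = list(tibble::tibble(year = 2000:2002, abundance = c(0, 4, 8)))
  )
  prep <- prepare_series(pops)
  expect_equal(unique(prep$offset_applied), 0.04)
  logs <- log(c(0.04, 4.04, 8.04))
  expect_equal(prep$centered_log_abundance, logs - mean(logs))
  # alternative policies
  expect_equal(unique(prepare_series(pops,
                                     zero_policy = "add_one")$offset_applied),
               1)
  expect_error(prepare_series(pops, zero_policy = "error"), "zero")
})

test_that("prepare_series rejects unusable series", {
  mk <- function(ab) {
    tibble::tibble(
      population_id = "x", species_id = "sp", latitude = 0, longitude = 0,
      system = "marine", taxon = "fish", threats = list(character(0)),
      threat_status_known = TRUE,
      data = list(tibble::tibble(year = seq_along(ab) + 1999,
                                 abundance = ab))
    )
  }
  expect_error(prepare_series(mk(c(0, 0, 0))), "all-zero")
  expect_error(prepare_series(mk(c(1, -2, 3))), "negative")
  expect_error(prepare_series(mk(5)), "fewer than 2")
})
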