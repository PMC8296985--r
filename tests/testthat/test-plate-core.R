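make_plate <- function(trt_signals, veh = 10000, kill = 2000,
                       n_ctrl = 2, concs = NULL) {
  n <- length(trt_signals)
  if (is.null(concs)) concs <- 10^seq(-7, -4, length.out = n)
  dplyr::bind_rows(
    tibble::tibble(well = sprintf("T%02d", 1:n), compound = "cmpd",
                   conc = concs, role = "treatment", signal = trt_signals,
                   replicate = 1L),
    tibble::tibble(well = sprintf("V%02d", 1:n_ctrl), compound = "vehicle",
                   conc = 0, role = "vehicle", signal = rep(veh, n_ctrl),
                   replicate = 1L),
    tibble::tibble(well = sprintf("K%02d", 1:n_ctrl), compound = "kill",
                   conc = 0, role = "kill_control",
                   signal = rep(kill, n_ctrl), replicate = 1L))
}

test_that("plate CSV round-trips with unit conversion to molar", {
  plate <- make_plate(c(9000, 6000, 3000, 2500))
  path <- withr::local_tempfile(fileext = ".csv")

  um <- dplyr::mutate(plate, conc = conc * 1e6)
  readr::write_csv(um, path)
  rd <- read_plate_table(path, conc_unit = "uM")
  expect_s3_class(rd, "plate_table")
  expect_equal(nrow(rd), nrow(plate))
  expect_equal(sort(rd$conc[rd$role == "treatment"]),
               sort(plate$conc[plate$role == "treatment"]), tolerance = 1e-12)

  readr::write_csv(plate, path)
  expect_equal(read_plate_table(path, conc_unit = "M")$conc, plate$conc)
})

test_that("schema violations are rejected with the offending row named", {
  plate <- make_plate(c(9000, 6000, 3000, 2500))
  path <- withr::local_tempfile(fileext = ".csv")

  readr::write_csv(dplyr::select(plate, -role), path)
  expect_error(read_plate_table(path), "role")

  bad <- plate; bad$role[3] <- "mystery"
  readr::write_csv(bad, path)
  expect_error(read_plate_table(path), "mystery")

  bad <- plate; bad$signal[2] <- -5
  readr::write_csv(bad, path)
  expect_error(read_plate_table(path), "non-negative")

  bad <- plate; bad$conc[1] <- 0
  readr::write_csv(bad, path)
  expect_error(read_plate_table(path), "concentration > 0")

  # extra roles can be declared via config
  ok <- plate; ok$role[1] <- "edge"
  readr::write_csv(ok, path)
  expect_error(read_plate_table(path), "edge")
  expect_silent(read_plate_table(path, config = list(roles = "edge")))
})

test_that("viability normalization anchors vehicle at 100 and kill at 0", {
  plate <- make_plate(c(6000, 10000, 2000, 4000), veh = 10000, kill = 2000)
  nv <- normalize_viability(plate, average = FALSE)
  expect_equal(nv$value[nv$compound == "vehicle"], rep(100, 2),
               tolerance = 1e-9)
  expect_equal(nv$value[nv$compound == "kill"], rep(0, 2), tolerance = 1e-9)
  expect_equal(nv$value[nv$compound == "cmpd"][1], 50)  # linear midpoint
  expect_true(all(nv$mode == "viability"))

  # without kill wells the floor is zero signal
  nofloor <- dplyr::filter(plate, role != "kill_control")
  nv0 <- normalize_viability(nofloor, average = FALSE)
  expect_equal(nv0$value[nv0$compound == "cmpd"][1], 100 * 6000 / 10000)

  expect_error(normalize_viability(make_plate(1000, veh = 100, kill = 2000)),
               "Degenerate")
  expect_error(
    normalize_viability(dplyr::filter(plate, role != "vehicle")), "vehicle")
})

test_that("toxicity normalization anchors vehicle at 0 and max-lysis at 100", {
  plate <- make_plate(c(1500, 500, 2500), veh = 500, kill = 2500)
  tx <- normalize_toxicity(plate, average = FALSE)
  expect_equal(tx$value[tx$compound == "vehicle"], rep(0, 2), tolerance = 1e-9)
  expect_equal(tx$value[tx$compound == "kill"], rep(100, 2), tolerance = 1e-9)
  expect_equal(tx$value[tx$compound == "cmpd"][1], 50)

  # no lysis anchor: rescaled by the plate maximum
  nolysis <- dplyr::filter(plate, role != "kill_control")
  tx0 <- normalize_toxicity(nolysis, average = FALSE)
  expect_equal(max(tx0$value), 100, tolerance = 1e-9)
  expect_equal(tx0$value[tx0$compound == "vehicle"], rep(0, 2),
               tolerance = 1e-9)
})

test_that("percent inhibition is the complement of viability and an involution", {
  plate <- make_plate(c(6000, 9000, 5000))
  nv <- normalize_viability(plate)
  inh <- percent_inhibition(nv)
  expect_equal(inh$value, 100 - nv$value)
  expect_true(all(inh$mode == "inhibition"))
  back <- percent_inhibition(inh)
  expect_equal(back$value, nv$value)
  expect_true(all(back$mode == "viability"))

  spot <- tibble::tibble(compound = "x", conc = 1e-6, value = 37.5,
                         mode = "viability")
  expect_equal(percent_inhibition(spot)$value, 62.5)
  expect_error(percent_inhibition(dplyr::mutate(spot, mode = "toxicity")),
               "mode")
})

test_that("normalization is affine and preserves within-plate signal ranking", {
  set.seed(101)
  for (i in 1:20) {
    sig <- runif(8, 1000, 12000)
    plate <- make_plate(sig, veh = 13000, kill = 500)
    nv <- normalize_viability(plate, average = FALSE)
    v <- nv$value[nv$compound == "cmpd"]
    expect_equal(order(v), order(sig))
    # affine: normalized values are a linear map of signals
    cf <- lm(v ~ sig)
    expect_lt(max(abs(resid(cf))), 1e-9)
  }
})

test_that("replicates are averaged per concentration after normalization", {
  plate <- dplyr::bind_rows(
    make_plate(c(6000, 8000), concs = c(1e-6, 1e-6)),
    tibble::tibble(well = "T99", compound = "cmpd", conc = 2e-6,
                   role = "treatment", signal = 4000, replicate = 2L))
  nv <- normalize_viability(plate)
  expect_equal(nrow(nv[nv$compound == "cmpd", ]), 2)
  expect_equal(nv$value[nv$compound == "cmpd" & nv$conc == 1e-6],
               mean(100 * (c(6000, 8000) - 2000) / 8000))
})
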