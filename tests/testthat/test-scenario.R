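# Configuration parsing, validation, presets, round trips.

test_that("empty configuration file yields the base-case defaults", {
  tf <- tempfile(fileext = ".yaml")
  writeLines("", tf)
  scn <- load_scenario(tf)
  expect_equal(scn$geometry$R0, 0.01)
  expect_equal(scn$geometry$L_vessel, 0.07)
  expect_equal(scn$geometry$L0, 0.02824)
  expect_equal(scn$geometry$delta, 0.005)               # 50% blockage
  expect_equal(scn$geometry$d + scn$geometry$L0 / 2, 0.02)  # throat at 2 cm
  expect_equal(scn$fluid$sigma, 0.8)
  expect_equal(scn$fluid$rho, 1050)
  expect_equal(scn$fluid$cp, 3490)
  expect_equal(scn$fluid$carreau$mu1, 0.056)
  expect_equal(scn$magnetics$B0, 0)
  expect_equal(scn$solver$T_inlet, 310)
  unlink(tf)
})

test_that("unit suffixes are converted to SI at load", {
  tf <- tempfile(fileext = ".yaml")
  writeLines(c("geometry:",
               "  L0: 2.824 cm",
               "  R0: 10 mm",
               "pressure:",
               "  Pm: 0.3 mmHg",
               "solver:",
               "  T_inlet: 37 C"), tf)
  scn <- load_scenario(tf)
  expect_equal(scn$geometry$L0, 0.02824)
  expect_equal(scn$geometry$R0, 0.01)
  expect_equal(scn$pressure$Pm, 0.3 * 133.322387415)
  expect_equal(scn$solver$T_inlet, 310.15)
  unlink(tf)
})

test_that("validation rejects bad physics and unknown keys together", {
  expect_error(scenario(geometry = list(blockage_fraction = 1.2)),
               "blockage_fraction")
  expect_error(scenario(magnetics = list(B0 = 1, Ha = 1)), "exactly one")
  expect_error(scenario(pressure = list(eps = 1.5)), "eps")
  expect_error(scenario(geometry = list(R00 = 1)), "unknown key")
  # multiple problems reported in one message
  err <- tryCatch(scenario(geometry = list(blockage_fraction = 1.2),
                           pressure = list(eps = 1.5)),
                  error = conditionMessage)
  expect_match(err, "blockage_fraction")
  expect_match(err, "eps")
  # unknown top-level key
  tf <- tempfile(fileext = ".yaml")
  writeLines("geometrry:\n  R0: 0.01", tf)
  expect_error(load_scenario(tf), "top-level")
  unlink(tf)
})

test_that("every preset round-trips through save/load losslessly", {
  scns <- c(list(preset("paper_case_50pct"), preset("joule_60pct_lowdp")),
            preset("ha_sweep"), preset("blockage_sweep"))
  for (scn in scns) {
    tf <- tempfile(fileext = ".yaml")
    save_scenario(scn, tf)
    expect_true(isTRUE(all.equal(scn, load_scenario(tf))), label = scn$name)
    expect_equal(scenario_hash(scn), scenario_hash(load_scenario(tf)))
    unlink(tf)
  }
})

test_that("presets mirror the study cases", {
  hs <- preset("ha_sweep")
  expect_length(hs, 3)
  expect_equal(sapply(hs, function(s) s$magnetics$Ha), c(Ha0 = 0,
                                                         Ha0.1 = 0.1,
                                                         Ha1 = 1))
  # scenarios differ only in the magnetics block
  a <- hs[[1]]; b <- hs[[3]]
  a$magnetics <- b$magnetics; a$name <- b$name
  expect_true(isTRUE(all.equal(a, b)))

  bs <- preset("blockage_sweep")
  expect_length(bs, 7)
  blks <- sapply(bs, function(s) s$geometry$delta / s$geometry$R0)
  expect_equal(unname(blks), c(0.2, 0.4, 0.5, 0.6, 0.7, 0.8, 0.85))
  expect_true(all(sapply(bs, function(s) s$geometry$L_vessel) == 0.06))

  low <- preset("joule_60pct_lowdp")
  expect_equal(low$magnetics$Ha, 1)
  expect_true(low$solver$cooled_wall)
  expect_equal(low$pressure$Pm,
               0.75 * preset("paper_case_50pct")$pressure$Pm)
  expect_error(preset("nope"), "unknown preset")
})

test_that("mean driving pressure is calibrated to Re of about 100", {
  scn <- preset("paper_case_50pct")
  # reconstruct the mean velocity of the unobstructed Newtonian tube
  mu <- scn$fluid$carreau$mu_inf
  u_bar <- scn$pressure$Pm * scn$geometry$R0^2 /
    (8 * mu * scn$geometry$L_vessel)
  Re <- scn$fluid$rho * u_bar * 2 * scn$geometry$R0 / mu
  expect_equal(Re, 100, tolerance = 1e-10)
})
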