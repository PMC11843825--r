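test_that("packaged chromophore library satisfies its invariants", {
  expect_s4_class(.lib, "ChromophoreLibrary")
  expect_equal(.lib@wavelengths, seq(450, 1000, by = 5))
  expect_length(.lib@wavelengths, 111L)
  for (curve in list(.lib@eps_hbo2, .lib@eps_hb, .lib@mu_melanin,
                     .lib@mu_water, .lib@mu_fat, .lib@mus_reduced)) {
    expect_true(all(is.finite(curve) & curve >= 0))
  }
  # an isosbestic point exists in 500-600 nm and the curves agree there
  w <- isosbesticWavelength(.lib, c(500, 600))
  expect_gte(w, 500); expect_lte(w, 600)
  lib2 <- loadChromophores(grid = sort(c(seq(450, 1000, 5), w)))
  i <- which.min(abs(lib2@wavelengths - w))
  expect_lt(abs(lib2@eps_hbo2[i] - lib2@eps_hb[i]), 1e-9)
})

test_that("malformed chromophore tables are rejected with location info", {
  tab <- utils::read.csv(system.file("extdata", "chromophores_synthetic.csv",
                                     package = "burndyn"))
  p1 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab[, 1:3], p1, row.names = FALSE)
  expect_error(loadChromophores(p1), "missing columns")

  tab2 <- tab; tab2$eps_hb[20] <- NA
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab2, p2, row.names = FALSE)
  expect_error(loadChromophores(p2), as.character(tab$wavelength_nm[20]))

  expect_error(loadChromophores("/nonexistent/file.csv"), "not found")
})

test_that("layer absorption: baseline, isosbestic equality, linearity in vHb", {
  zero <- perfusionProfile(rep(0, 6), rep(0.5, 6))
  base1 <- layerAbsorption(zero, 1, .lib, .model)
  expect_equal(base1, .model@water * .lib@mu_water + .model@fat * .lib@mu_fat +
                 .model@melanin * .lib@mu_melanin)
  base3 <- layerAbsorption(zero, 3, .lib, .model)
  expect_equal(base3, .model@water * .lib@mu_water + .model@fat * .lib@mu_fat)

  # oxy and deoxy absorption differ at 560 nm but agree at an isosbestic band
  w <- isosbesticWavelength(.lib, c(500, 600))
  lib2 <- loadChromophores(grid = sort(c(seq(450, 1000, 5), w)))
  oxy <- perfusionProfile(rep(0.5, 6), rep(1, 6))
  deoxy <- perfusionProfile(rep(0.5, 6), rep(0, 6))
  mo <- layerAbsorption(oxy, 2, lib2, .model)
  md <- layerAbsorption(deoxy, 2, lib2, .model)
  i560 <- which(lib2@wavelengths == 560)
  iiso <- which.min(abs(lib2@wavelengths - w))
  expect_gt(abs(mo[i560] - md[i560]), 1e-3)
  expect_lt(abs(mo[iiso] - md[iiso]), 1e-9)

  # hemoglobin term is linear in vHb
  p1 <- perfusionProfile(c(0.2, rep(0, 5)), rep(0.6, 6))
  p2 <- perfusionProfile(c(0.4, rep(0, 5)), rep(0.6, 6))
  expect_equal(layerAbsorption(p2, 1, .lib, .model) - base1,
               2 * (layerAbsorption(p1, 1, .lib, .model) - base1))
})

test_that("rendered remission: zero-blood baseline and saturation invariance", {
  base <- renderSpectrum(perfusionProfile(rep(0, 6), rep(0, 6)), .lib, .model)
  expect_true(all(base@remission >= 0 & base@remission <= 1))
  # with no blood the spectrum cannot depend on any saturation value
  for (x in c(0, 0.5, 1)) {
    sp <- renderSpectrum(perfusionProfile(rep(0, 6), rep(x, 6)), .lib, .model)
    expect_identical(sp@remission, base@remission)
  }
  # saturation of a bloodless layer is irrelevant even with blood elsewhere
  pa <- perfusionProfile(c(0.5, 0, 0.3, 0.3, 0.2, 0.2), c(0.7, 0.1, rep(0.5, 4)))
  pb <- perfusionProfile(c(0.5, 0, 0.3, 0.3, 0.2, 0.2), c(0.7, 0.9, rep(0.5, 4)))
  expect_identical(renderSpectrum(pa, .lib, .model)@remission,
                   renderSpectrum(pb, .lib, .model)@remission)
})

test_that("remission decreases monotonically in vHb at an absorbing band", {
  i560 <- which(.lib@wavelengths == 560)
  vals <- sapply(seq(0, 1, 0.1), function(v) {
    p <- perfusionProfile(c(v, rep(0.2, 5)), rep(0.5, 6))
    renderSpectrum(p, .lib, .model)@remission[i560]
  })
  expect_true(all(diff(vals) < 0))
  # per-layer monotonicity at the hemoglobin band
  for (layer in 1:6) {
    v <- rep(0.2, 6)
    lo <- perfusionProfile(v, rep(0.5, 6))
    v[layer] <- 0.6
    hi <- perfusionProfile(v, rep(0.5, 6))
    expect_lte(renderSpectrum(hi, .lib, .model)@remission[i560],
               renderSpectrum(lo, .lib, .model)@remission[i560])
  }
})

test_that("a superficial vHb increment perturbs the spectrum at least as much as a deep one", {
  v0 <- rep(0.2, 6)
  ref <- renderSpectrum(perfusionProfile(v0, rep(0.5, 6)), .lib, .model)@remission
  l2 <- sapply(c(1L, 6L), function(layer) {
    v <- v0; v[layer] <- v[layer] + 0.3
    sqrt(sum((renderSpectrum(perfusionProfile(v, rep(0.5, 6)), .lib,
                             .model)@remission - ref)^2))
  })
  expect_gte(l2[1], l2[2])
})

test_that("rendering is deterministic and bounded", {
  set.seed(11)
  for (k in 1:5) {
    p <- randGroupProfile()
    a <- renderSpectrum(p, .lib, .model)
    b <- renderSpectrum(p, .lib, .model)
    expect_identical(a@remission, b@remission)
    expect_true(all(a@remission >= 0 & a@remission <= 1))
  }
})

test_that("spectrum CSV writer and reader round-trip", {
  sp <- renderSpectrum(perfusionProfile(rep(0.3, 6), rep(0.6, 6)), .lib, .model)
  p <- withr::local_tempfile(fileext = ".csv")
  writeSpectrumCsv(sp, p)
  rt <- readSpectrumCsv(p)
  expect_equal(rt@wavelengths, sp@wavelengths)
  expect_equal(rt@remission, sp@remission)
})
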