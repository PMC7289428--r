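test_that("von Kries coefficient is the reciprocal background catch and is linear", {
  g <- toy_grid
  S <- spectral_function(g, c(1, 1, 1))
  D <- spectral_function(g, c(1, 1, 1))
  # background catch = sum(values) * step = (0.01 + 0.005 + 0.005) * 100 = 2
  IB <- spectral_function(g, c(0.010, 0.005, 0.005))
  expect_equal(von_kries_coefficient(S, IB, D), 0.5)
  # scaling the illuminant by k scales R by 1/k
  Dk <- spectral_function(g, 3 * D$value)
  expect_equal(von_kries_coefficient(S, IB, Dk),
               von_kries_coefficient(S, IB, D) / 3)
  expect_error(von_kries_coefficient(S, spectral_function(g, rep(0, 3)), D),
               "degenerate")
})

test_that("10 nm Riemann catch agrees with a trapezoid-rule oracle", {
  S <- bee_receptors()$B
  IB <- make_leaf_background()
  D <- make_illuminant()
  riemann <- 1 / von_kries_coefficient(S, IB, D)
  prod_v <- S$value * IB$value * D$value
  trap <- trapz(S$wavelength, prod_v)
  # the two quadrature rules differ only by the half-weighted end points
  expect_equal(riemann, trap, tolerance = 0.02)
  expect_equal(riemann, sum(prod_v) * 10, tolerance = 1e-12)
})

test_that("photon capture is 1 for the background, 0 for black, linear in reflectance", {
  recs <- bee_receptors()
  IB <- make_leaf_background()
  D <- make_illuminant()
  black <- spectral_function(model_grid(), rep(0, 36))
  doubled <- spectral_function(model_grid(), 2 * IB$value)
  for (S in recs) {
    R <- von_kries_coefficient(S, IB, D)
    expect_equal(photon_capture(S, IB, D, R), 1)
    expect_equal(photon_capture(S, black, D, R), 0)
    expect_equal(photon_capture(S, doubled, D, R), 2)
  }
})

test_that("excitation saturates as P/(P+1)", {
  expect_equal(excitation(1), 0.5)
  expect_equal(excitation(0), 0)
  expect_equal(excitation(3), 0.75)
  expect_true(all(excitation(10^(0:6)) < 1))
  expect_error(excitation(-0.1), "non-negative")
})

test_that("hexagon coordinates place background at centre and vertices at distance 1", {
  expect_equal(hexagon_coords(0.5, 0.5, 0.5), c(x = 0, y = 0))
  expect_equal(hexagon_coords(0, 1, 0), c(x = 0, y = 1))
  expect_equal(hexagon_coords(0, 0, 1), c(x = sqrt(3) / 2, y = -0.5))
  expect_equal(hexagon_coords(1, 0, 0), c(x = -sqrt(3) / 2, y = -0.5))
  for (E in list(c(0, 1, 0), c(1, 0, 0), c(0, 0, 1))) {
    xy <- hexagon_coords(E[1], E[2], E[3])
    expect_equal(sqrt(sum(xy^2)), 1, tolerance = 1e-12)
  }
  expect_error(hexagon_coords(-0.1, 0.5, 0.5), "0, 1")
})

test_that("hue is measured counter-clockwise from BG with blue at 90 degrees", {
  expect_equal(hue_and_contrast(0, 1), list(hue_deg = 90, contrast = 1))
  pol <- hue_and_contrast(sqrt(3) / 2, -0.5)
  expect_equal(pol$hue_deg, 330)
  expect_equal(pol$contrast, 1)
  origin <- hue_and_contrast(0, 0)
  expect_true(is.na(origin$hue_deg))
  expect_equal(origin$contrast, 0)
})

test_that("sector classification partitions the hue circle into six 60-degree bins", {
  expect_equal(as.character(classify_sector(90)), "B")
  expect_equal(as.character(classify_sector(0)), "BG")
  expect_equal(as.character(classify_sector(60)), "B")   # boundary goes up
  expect_equal(as.character(classify_sector(330)), "G")
  expect_error(classify_sector(NA_real_), "achromatic")
  hues <- seq(0, 359.75, by = 0.25)
  sec <- classify_sector(hues)
  expect_false(anyNA(sec))
  expect_setequal(levels(sec), hexagon_sectors())
  # each sector's preimage is a single contiguous 60-degree arc
  expect_equal(as.vector(table(sec)[unique(as.character(sec))]),
               rep(240L, 6))
  expect_equal(sum(table(sec)), length(hues))
})

test_that("any background maps to the hexagon origin under its own adaptation", {
  set.seed(42)
  for (i in 1:10) {
    bg <- spectral_function(model_grid(), runif(36, 0.01, 0.9))
    loc <- spectrum_to_locus(bg, background = bg)
    expect_lt(abs(loc$x), 1e-12)
    expect_lt(abs(loc$y), 1e-12)
    expect_true(is.na(loc$hue_deg))
  }
})

test_that("loci are scale-invariant to the illuminant and bounded by the hexagon", {
  set.seed(43)
  bg <- make_leaf_background()
  D <- make_illuminant()
  for (i in 1:10) {
    stim <- spectral_function(model_grid(), runif(36, 0, 2))
    loc1 <- spectrum_to_locus(stim, bg, D)
    Dk <- spectral_function(D$wavelength, D$value * runif(1, 0.1, 10))
    loc2 <- spectrum_to_locus(stim, bg, Dk)
    expect_equal(c(loc1$x, loc1$y), c(loc2$x, loc2$y), tolerance = 1e-12)
    expect_lte(loc1$contrast, 1 + 1e-12)
  }
})

test_that("extra reflectance seen only by the blue receptor moves loci toward larger y", {
  recs <- toy_receptors()
  # restrict the blue receptor's support to 500 nm for a clean manipulation
  recs$B <- spectral_function(toy_grid, c(0, 1, 0))
  bg <- toy_background(); D <- toy_illuminant()
  stim <- spectral_function(toy_grid, c(0.3, 0.2, 0.5))
  y_at <- function(mid) {
    s <- spectral_function(toy_grid, c(0.3, mid, 0.5))
    spectrum_to_locus(s, bg, D, recs)$y
  }
  ys <- vapply(seq(0.2, 1, by = 0.2), y_at, numeric(1))
  expect_true(all(diff(ys) > 0))
})

test_that("full pipeline matches a hand-computed oracle on the 3-wavelength toy grid", {
  recs <- toy_receptors(); bg <- toy_background(); D <- toy_illuminant()
  stim <- spectral_function(toy_grid, c(0.5, 0.1, 0.9))
  # hand computation, written out term by term (step = 100 nm)
  E_hand <- numeric(3)
  sens <- list(c(1.0, 0.2, 0.0), c(0.1, 1.0, 0.1), c(0.0, 0.3, 1.0))
  for (k in 1:3) {
    s <- sens[[k]]
    catch_bg <- (s[1] * 0.2 * 1.0 + s[2] * 0.3 * 0.8 + s[3] * 0.4 * 0.6) * 100
    catch_st <- (s[1] * 0.5 * 1.0 + s[2] * 0.1 * 0.8 + s[3] * 0.9 * 0.6) * 100
    P <- catch_st / catch_bg
    E_hand[k] <- P / (P + 1)
  }
  x_hand <- sin(pi / 3) * (E_hand[3] - E_hand[1])
  y_hand <- E_hand[2] - 0.5 * (E_hand[3] + E_hand[1])
  loc <- spectrum_to_locus(stim, bg, D, recs)
  expect_equal(c(loc$E_UV, loc$E_B, loc$E_G), E_hand, tolerance = 1e-12)
  expect_equal(loc$x, x_hand, tolerance = 1e-12)
  expect_equal(loc$y, y_hand, tolerance = 1e-12)
  expect_equal(loc$contrast, sqrt(x_hand^2 + y_hand^2), tolerance = 1e-12)
})

test_that("a flat bright reflector excites all receptors above the background", {
  white <- spectral_function(model_grid(), rep(1, 36))
  loc <- spectrum_to_locus(white)
  expect_true(all(c(loc$E_UV, loc$E_B, loc$E_G) > 0.5))
})

test_that("the UV-absorbing-white archetype lands in the BLUE-GREEN sector", {
  arch <- flower_archetypes()$uv_absorbing_white
  loc <- spectrum_to_locus(make_flower_spectrum(arch, jitter = 0))
  expect_equal(loc$sector, "BG")
})
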