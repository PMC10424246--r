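# Frozen expected values below were hand-evaluated from the defining
# formulas (Oh = eta/sqrt(gamma*rho*L), We = rho U^2 L/gamma,
# Re = rho U L/eta, Fr = U/sqrt(gL), Bo = rho g L^2/gamma,
# K_sp = sqrt(We sqrt(Re))) for the water-like medium with a 250 um
# nozzle at U = 2 m/s.

test_that("dimensionless numbers match hand-evaluated values for the water-like medium", {
  s <- water_spec()
  expect_equal(ohnesorge(s), 0.007419916797, tolerance = 1e-9)
  expect_equal(1 / ohnesorge(s), 134.7724007, tolerance = 1e-9)
  expect_equal(reynolds(s), 499.0, tolerance = 1e-12)
  expect_equal(weber(s), 13.70879121, tolerance = 1e-9)
  expect_equal(froude(s), 40.38550219, tolerance = 1e-9)
  expect_equal(bond(s), 0.00840520261, tolerance = 1e-9)
  expect_equal(splashing_parameter(s), 17.49946282, tolerance = 1e-9)
})

test_that("numbers scale as their formulas dictate", {
  s <- water_spec()
  s2 <- fluid_jet_spec(2e-3, 0.0728, 998, 250e-6, 2)
  expect_equal(ohnesorge(s2), 2 * ohnesorge(s))
  s4g <- fluid_jet_spec(1e-3, 4 * 0.0728, 998, 250e-6, 2)
  expect_equal(ohnesorge(s4g), ohnesorge(s) / 2)
  # Bo quadratic in L; independent of U and viscosity
  sL <- fluid_jet_spec(1e-3, 0.0728, 998, 2.5e-3, 2)
  expect_equal(bond(sL), 100 * bond(s))
  expect_equal(bond(sL), 0.840520261, tolerance = 1e-9)
  expect_true(bond(sL) < 1)
  for (U in c(0, 1, 5)) {
    sU <- water_spec(U)
    expect_equal(bond(sU), bond(s))
  }
  sEta <- fluid_jet_spec(5e-2, 0.0728, 998, 250e-6, 2)
  expect_equal(bond(sEta), bond(s))
})

test_that("zero-velocity configurations give zero inertial numbers", {
  s0 <- water_spec(0)
  expect_equal(weber(s0), 0)
  expect_equal(reynolds(s0), 0)
  expect_equal(froude(s0), 0)
  expect_equal(splashing_parameter(s0), 0)
  expect_false(is_splashing(splashing_parameter(s0)))
  # Oh does not depend on U
  expect_equal(ohnesorge(s0), ohnesorge(water_spec(2)))
})

test_that("Oh via fluid properties equals sqrt(We)/Re over random specs", {
  set.seed(11)
  for (i in 1:1000) {
    s <- random_spec()
    oh1 <- ohnesorge(s)
    oh2 <- sqrt(weber(s)) / reynolds(s)
    expect_equal(oh1, oh2, tolerance = 1e-9)
    expect_equal(oh1 * (1 / oh1), 1)
  }
})

test_that("splashing classification boundary sits exactly at 57.7", {
  eps <- 1e-6
  expect_false(is_splashing(57.7 - eps))
  expect_true(is_splashing(57.7 + eps))
  expect_true(is_splashing(57.7))
  expect_false(is_splashing(5.1))   # reported configuration: no splashing
  expect_error(is_splashing(-1), "non-negative")
})

test_that("K_sp increases monotonically with droplet velocity", {
  U <- seq(0.1, 10, length.out = 25)
  k <- vapply(U, function(u) splashing_parameter(water_spec(u)), numeric(1))
  expect_true(all(diff(k) > 0))
})

test_that("profile aggregates all numbers with consistent flags", {
  p <- printability_profile(water_spec())
  expect_s3_class(p, "printability_profile")
  expect_equal(p$Oh, ohnesorge(water_spec()))
  expect_equal(p$Z * p$Oh, 1)
  expect_equal(p$K_sp, 17.49946282, tolerance = 1e-9)
  expect_true(p$gravity_negligible)
  expect_false(p$splashing)
  expect_true(all(unlist(p[c("Oh", "We", "Re", "Fr", "Bo", "Z", "K_sp")]) >= 0))

  p0 <- printability_profile(water_spec(0))
  expect_equal(p0$We, 0)
  expect_equal(p0$Re, 0)
  expect_equal(p0$Fr, 0)
  expect_equal(p0$K_sp, 0)
  expect_gt(p0$Oh, 0)
  expect_gt(p0$Bo, 0)
})

test_that("invalid fluid specs are rejected", {
  expect_error(fluid_jet_spec(0, 0.07, 998, 250e-6), "viscosity")
  expect_error(fluid_jet_spec(1e-3, -0.07, 998, 250e-6), "surface_tension")
  expect_error(fluid_jet_spec(1e-3, 0.07, 998, 0), "orifice_diameter")
  expect_error(fluid_jet_spec(1e-3, 0.07, 998, 250e-6, -1), "droplet_velocity")
  expect_error(ohnesorge(list(viscosity = 1)), "fluid_jet_spec")
})

test_that("gravimetric droplet volume and equivalent diameter are exact", {
  # 1e-5 kg over 1000 droplets of a 1000 kg/m3 fluid: 10 nl, ~267 um
  dv <- droplet_volume(1.0e-5, 1000, 1000)
  expect_equal(dv$volume, 1e-11)
  expect_equal(dv$diameter, 0.0002673009235, tolerance = 1e-9)
  # identity: one droplet of mass rho*V has volume V
  V <- 3.7e-11
  expect_equal(droplet_volume(1050 * V, 1, 1050)$volume, V)
  expect_error(droplet_volume(0, 1000, 1000), "total_mass")
  expect_error(droplet_volume(1e-5, 0, 1000), "droplet_count")
})

test_that("droplet velocity is the least-squares displacement slope", {
  expect_equal(droplet_velocity(c(0, 2e-3, 4e-3), 1e-3), 2)
  expect_equal(droplet_velocity(rep(5e-3, 10), 1e-3), 0)
  set.seed(4)
  t <- (0:49) * 1e-3
  pos <- 1.7 * t + rnorm(50, sd = 2e-5)
  v <- droplet_velocity(pos, 1e-3)
  se <- 2e-5 / sqrt(sum((t - mean(t))^2))
  expect_lt(abs(v - 1.7), 4 * se)
  expect_error(droplet_velocity(1e-3, 1e-3), "at least 2")
})

test_that("fluid spec files in lab units are converted to SI", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c(
    "viscosity: {value: 1.0, unit: mPa.s}",
    "surface_tension: {value: 72.8, unit: mN/m}",
    "density: {value: 0.998, unit: g/ml}",
    "orifice_diameter: {value: 250, unit: um}",
    "droplet_velocity: 2"), yml)
  s <- read_fluid_spec(yml)
  expect_equal(s$viscosity, 1e-3)
  expect_equal(s$surface_tension, 0.0728)
  expect_equal(s$density, 998)
  expect_equal(s$orifice_diameter, 250e-6)
  expect_equal(reynolds(s), 499)

  jsn <- tempfile(fileext = ".json")
  writeLines(paste0('{"viscosity": 1e-3, "surface_tension": 0.0728,',
                    '"density": 998, "orifice_diameter": 250e-6}'), jsn)
  s2 <- read_fluid_spec(jsn)
  expect_equal(ohnesorge(s2), ohnesorge(s))

  bad <- tempfile(fileext = ".yaml")
  writeLines("viscosity: 1.0e-3", bad)
  expect_error(read_fluid_spec(bad), "missing required")
})
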