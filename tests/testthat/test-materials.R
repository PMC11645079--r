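# Dispersion tables, slab mode solver, V parameter, grating relation, taper.

test_that("refractive_index interpolates tables and refuses extrapolation", {
  vac <- material_table("vacuum")
  expect_equal(refractive_index(vac, 600), 1.0)
  # water near 500 nm: standard 20 C value ~1.335
  expect_equal(refractive_index(material_table("water"), 500), 1.335,
               tolerance = 0.002)
  # packaged SiN vs the independent Luke dispersion model: same film family,
  # different fit -- agreement to ~2%
  sin_tab <- material_table("SiN")
  expect_gt(refractive_index(sin_tab, 500), 2.0)
  expect_lt(refractive_index(sin_tab, 500), 2.07)
  for (wl in c(450, 500, 600, 700, 800)) {
    expect_equal(refractive_index(sin_tab, wl), oracle_n_sin_luke(wl / 1000),
                 tolerance = 0.02)
  }
  expect_error(refractive_index(vac, 300), "outside")
  expect_error(material_dispersion("x", c(500, 400, 600), c(1, 1, 1)),
               "increasing")
  expect_error(material_dispersion("x", c(400, 900), c(0.9, 1)), ">= 1")
})

test_that("slab solver reaches the bulk limit and has no TE0 cutoff", {
  # very thick core: n_eff -> n_core
  ne <- slab_effective_index(500, 10000, 2.0, 1.46, 1.46)
  expect_equal(ne, 2.0, tolerance = 1e-3)
  # symmetric slab at the TE1 cutoff thickness: TE0 still guided
  # (d_c = lambda / (2 sqrt(n1^2 - n2^2)) for the first higher mode)
  d_c <- 500 / (2 * sqrt(2.0^2 - 1.46^2))
  ne <- slab_effective_index(500, d_c, 2.0, 1.46, 1.46)
  expect_gt(ne, 1.46)
  expect_lt(ne, 2.0)
  # thin SiN layer between SOG claddings: effective index between the two
  nc <- refractive_index(material_table("SiN"), 500)
  ns <- refractive_index(material_table("SOG"), 500)
  ne <- slab_effective_index(500, 100, nc, ns, ns)
  expect_gt(ne, ns)
  expect_lt(ne, nc)
  # strongly asymmetric ultrathin slab has a genuine cutoff
  expect_error(slab_effective_index(500, 5, 1.6, 1.46, 1.0),
               class = "slab_cutoff")
})

test_that("slab solver agrees with a brute-force dense-grid scan", {
  set.seed(42)
  for (i in 1:20) {
    n_clad <- runif(1, 1.3, 1.5)
    n_sub <- n_clad + runif(1, 0, 0.1)
    n_core <- n_sub + runif(1, 0.3, 0.8)
    d <- runif(1, 80, 400)
    wl <- runif(1, 450, 800)
    ref <- oracle_slab_neff(wl, d, n_core, n_sub, n_clad)
    if (is.na(ref)) next  # below cutoff for this draw
    expect_equal(slab_effective_index(wl, d, n_core, n_sub, n_clad), ref,
                 tolerance = 1e-6)
  }
})

test_that("V parameter scales as 1/lambda at fixed indices and vanishes at zero contrast", {
  flat <- function(n) material_dispersion("flat", c(400, 6000), c(n, n))
  ws <- waveguide_spec(core = flat(2.0), substrate = flat(1.46),
                       cladding = flat(1.46))
  # material-index reading isolates the explicit 1/lambda factor
  expect_equal(v_parameter(5000, ws, n_wg = "material") * 10,
               v_parameter(500, ws, n_wg = "material"), tolerance = 1e-12)
  ws0 <- waveguide_spec(core = flat(1.46 + 1e-9), substrate = flat(1.46),
                        cladding = flat(1.46))
  expect_equal(v_parameter(500, ws0, n_wg = "material"), 0, tolerance = 1e-3)
})

test_that("V parameter is decreasing in wavelength and single-mode from 600 nm", {
  ws <- waveguide_spec()
  v <- vapply(c(500, 550, 600, 650, 700, 780), v_parameter, numeric(1),
              spec = ws)
  expect_true(all(diff(v) < 0))
  expect_true(all(v[v < v[1]] > 0))
  # the single-mode bound holds across the 600-780 nm design range
  expect_true(all(v[3:6] < 2.4))
})

test_that("grating relation and outcoupling angle are mutual inverses", {
  g <- grating_model(365, n_top = 1.46)
  # vertical outcoupling: beta = 2 pi / Lambda
  expect_equal(propagation_constant(500, g, 0), 2 * pi / 365,
               tolerance = 1e-15)
  # grazing limit: theta = pi/2
  b_graze <- 2 * pi / 365 + 2 * pi * 1.46 / 500
  expect_equal(outcoupling_angle(b_graze, 500, g), pi / 2, tolerance = 1e-6)
  # round trip at random angles
  set.seed(1)
  for (th in runif(10, -1.4, 1.4)) {
    b <- propagation_constant(633, g, th)
    expect_equal(outcoupling_angle(b, 633, g), th, tolerance = 1e-12)
  }
  expect_error(outcoupling_angle(b_graze * 1.2, 500, g),
               class = "evanescent_order")
})

test_that("slab-derived beta gives near-vertical outcoupling with the 365 nm grating", {
  ws <- waveguide_spec()
  g <- grating_model(365, refractive_index(material_table("SOG"), 500))
  th <- outcoupling_angle(beta_slab(500, ws), 500, g)
  expect_lt(abs(th), 20 * pi / 180)
})

test_that("taper profile matches its endpoints exactly and is monotone", {
  ws <- waveguide_spec()  # w1 = 0.6 um, w2 = 20 um, L = 40 um, m = 1.15
  expect_equal(taper_half_width(20, ws), 10)        # wide end: w2/2
  expect_equal(taper_half_width(-20, ws), 0.3)      # narrow end: w1/2
  mid <- taper_half_width(0, ws)
  expect_gt(mid, 0.3); expect_lt(mid, 10)
  y <- taper_half_width(seq(-20, 20, length.out = 2000), ws)
  expect_true(all(diff(y) > 0))
  expect_error(taper_half_width(21, ws), "outside")
})

test_that("material tables round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- material_table("water")
  utils::write.csv(data.frame(wavelength_nm = tab$wavelength_nm, n = tab$n),
                   path, row.names = FALSE)
  back <- read_material_csv(path)
  expect_equal(refractive_index(back, 555), refractive_index(tab, 555))
})
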