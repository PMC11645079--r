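# Lens phase, NA/F relations, segmentation and phase-matched placement.

test_that("lens phase is zero at center, radially symmetric and matches direct arithmetic", {
  sp <- lens_phase_spec(20, 500, 660, na = 1.1)
  expect_equal(lens_phase(0, 0, 500, sp), 0)
  set.seed(3)
  x <- runif(20, -1e4, 1e4); y <- runif(20, -1e4, 1e4)
  expect_equal(lens_phase(x, y, 500, sp), lens_phase(-x, -y, 500, sp))
  # independent evaluation of (2 pi n / lambda)(F - sqrt(F^2 + r^2))
  n_w <- refractive_index(material_table("water"), 500)
  F_nm <- sp$F_um * 1000
  expect_equal(lens_phase(x, y, 500, sp),
               2 * pi * n_w / 500 * (F_nm - sqrt(F_nm^2 + x^2 + y^2)),
               tolerance = 1e-12)
  expect_true(all(lens_phase(x, y, 660, sp) <= 0))
})

test_that("NA and focal length invert each other and match the headline design", {
  # 45-degree marginal ray: F = D/2
  n <- 1.33
  expect_equal(focal_length_from_na(n * sin(pi / 4), 10, n), 5,
               tolerance = 1e-12)
  # D = 20 um, F = 7 um in water reproduces NA ~ 1.1 (two significant figures)
  expect_equal(signif(na_from_focal(7, 20, 1.33), 2), 1.1)
  # and NA = 1.1 puts the focus near 7 um
  F7 <- focal_length_from_na(1.1, 20, 1.33)
  expect_gt(F7, 6.5); expect_lt(F7, 7.2)
  expect_equal(na_from_focal(F7, 20, 1.33), 1.1, tolerance = 1e-12)
  expect_error(focal_length_from_na(1.4, 20, 1.33), "unphysical")
})

test_that("lens spec keeps D, F, NA mutually consistent through both constructors", {
  a <- lens_phase_spec(20, 500, 660, na = 1.1)
  b <- lens_phase_spec(20, 500, 660, F_um = a$F_um)
  expect_equal(a$na, b$na, tolerance = 1e-9)
  expect_equal(a$F_um, b$F_um)
})

test_that("waveguide phase is beta*x plus the input model and periodic in 2 pi / beta", {
  none <- input_phase_model("none")
  expect_equal(waveguide_phase(0, 1234, 0.02, none), 0)
  expect_equal(waveguide_phase(2 * pi / 0.02, 0, 0.02, none), 2 * pi)
  cyl <- input_phase_model("cylindrical", R_um = 40)
  expect_equal(waveguide_phase(0, 0, 0.02, cyl), 0)  # on-axis reference
  expect_gt(waveguide_phase(0, 5000, 0.02, cyl), 0)
  # even in y
  expect_equal(waveguide_phase(0, 3000, 0.02, cyl),
               waveguide_phase(0, -3000, 0.02, cyl))
})

test_that("segment selector tiles the aperture with complementary half-open stripes", {
  lay <- segment_layout(20, 5)
  y <- seq(-1e4, 1e4, by = 111)
  expect_true(all(segment_selector(y, lay, 1) + segment_selector(y, lay, 2) == 1))
  # stripe_width = 2 um: y = 0.5 um lies in the stripe [0, 2) um
  fam_center <- segment_selector(500, lay, 1)
  # boundary belongs to the +y stripe: y = 0 is in the same stripe as 0.5 um
  expect_equal(segment_selector(0, lay, 1), fam_center)
  expect_equal(segment_selector(0, lay, 2), 1L - fam_center)
  # y just below a boundary is in the other family
  expect_equal(segment_selector(-1, lay, 1), 1L - fam_center)
  expect_error(segment_selector(1.1e4, lay, 1), "outside")
})

test_that("placed atoms satisfy phase matching and local spacing near center is the guided period", {
  des <- cached_design(500, 660)
  a <- des$atoms
  expect_gt(nrow(a), 1000)
  # residuals are asserted at construction; re-check explicitly for family 1
  sel <- a$family == 1
  b1 <- des$beta_fun(500)
  res <- wrap_phase(waveguide_phase(a$x_nm[sel], a$y_nm[sel], b1, des$ipm) -
                      lens_phase(a$x_nm[sel], a$y_nm[sel], 500, des$lens))
  expect_lt(max(abs(res)), 1e-3)
  # consecutive roots near x = 0 are ~ 2 pi / beta apart
  row_y <- a$y_nm[which.min(abs(a$y_nm))]
  xs <- sort(a$x_nm[a$y_nm == row_y])
  near0 <- which(abs(xs) < 2000)
  gaps <- diff(xs[near0])
  lam_seg <- a$segment_lambda_nm[a$y_nm == row_y][1]
  expect_equal(mean(gaps), 2 * pi / des$beta_fun(lam_seg), tolerance = 0.05)
  # all atoms respect the minimum center spacing within a row
  for (yy in unique(a$y_nm[seq(1, nrow(a), by = 571)])) {
    expect_true(all(diff(sort(a$x_nm[a$y_nm == yy])) >= a$diameter_nm[1]))
  }
})

test_that("root-finding placement reproduces the dense-scan oracle on a toy aperture", {
  lens <- lens_phase_spec(5, 500, 660, na = 1.1)
  lay <- segment_layout(5, 2)
  ws <- waveguide_spec()
  b1 <- beta_slab(500, ws); b2 <- beta_slab(660, ws)
  ipm <- input_phase_model("cylindrical", R_um = 40)
  atoms <- place_meta_atoms(lens, lay, b1, b2, ipm, row_pitch_nm = 500)
  expect_gt(nrow(atoms), 50)
  for (yy in unique(atoms$y_nm)) {
    sub <- atoms[atoms$y_nm == yy, ]
    lam <- sub$segment_lambda_nm[1]
    bet <- if (sub$family[1] == 1) b1 else b2
    ref <- oracle_scan_atoms(yy, lam, bet, lens, ipm, 5000, 200)
    expect_equal(length(ref), nrow(sub))
    expect_lt(max(abs(sort(sub$x_nm) - sort(ref))), 1)
  }
})

test_that("atom columns bend symmetrically in y for an even input phase", {
  # single-family design: +-y rows share the wavelength, so the even
  # cylindrical input phase must give mirror-identical atom columns
  des <- metalens_design(500, 660, D_um = 5, segmented = FALSE,
                         row_pitch_nm = 500)
  atoms <- des$atoms
  ys <- sort(unique(atoms$y_nm))
  checked <- 0
  for (yy in ys[ys > 0]) {
    sub_p <- sort(atoms$x_nm[atoms$y_nm == yy])
    sub_m <- sort(atoms$x_nm[abs(atoms$y_nm + yy) < 1e-6])
    expect_equal(sub_p, sub_m, tolerance = 1e-6)
    checked <- checked + 1
  }
  expect_gt(checked, 2)
})

test_that("degenerate designs (beta below the lens-phase slope) are rejected", {
  lens <- lens_phase_spec(20, 500, 660, na = 1.1)
  lay <- segment_layout(20, 5)
  b_low <- 2 * pi * 1.05 / 500  # effective index below the NA
  expect_error(place_meta_atoms(lens, lay, b_low, b_low), "degenerate")
})

test_that("layout CSV export round-trips, including the empty design", {
  path <- withr::local_tempfile(fileext = ".csv")
  toy <- data.frame(x_nm = c(-500, 0, 500), y_nm = c(0, 0, 0),
                    diameter_nm = 200, height_nm = 500,
                    segment_lambda_nm = 500)
  export_layout(toy, path)
  back <- read_layout(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$x_nm, toy$x_nm)
  expect_equal(names(back), c("x_nm", "y_nm", "diameter_nm", "height_nm",
                              "segment_lambda_nm"))
  empty <- toy[0, ]
  export_layout(empty, path)
  expect_equal(nrow(read_layout(path)), 0)
})
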