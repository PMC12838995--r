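test_that("background field matches both calibrated endpoints", {
  expect_equal(background_field(0, dev0), 9e-3, tolerance = 1e-12)
  expect_equal(background_field(27e-3, dev0), 35e-3, tolerance = 1e-12)
  # independent re-derivation of the exponent: solve the two-point fit
  p_closed <- background_exponent(dev0)
  f <- function(p) 35e-3 * ((45e-3 - 27e-3) / 45e-3)^p - 9e-3
  p_solved <- uniroot(f, c(0.1, 10), tol = 1e-12)$root
  expect_equal(p_closed, p_solved, tolerance = 1e-9)
  expect_equal(p_closed, log(35 / 9) / log(45 / 18), tolerance = 1e-12)
  # closed form at mid-array agrees with the solved-exponent evaluation
  expect_equal(background_field(13.5e-3, dev0),
               35e-3 * (18 / 31.5)^p_solved, tolerance = 1e-9)
  # monotone increasing toward the magnet
  xs <- seq(0, 27e-3, length.out = 50)
  expect_true(all(diff(background_field(xs, dev0)) > 0))
  expect_error(background_field(-1e-3, dev0), "sorting zone")
  expect_error(background_field(28e-3, dev0), "sorting zone")
})

test_that("strip magnetization is continuous, monotone and saturates", {
  m <- mat0
  Ms <- m$saturation_polarization / mu0
  expect_equal(strip_magnetization(0, m), 0)
  # without shape correction the operating fields saturate the strips
  expect_equal(strip_magnetization(35e-3, m, demag_N = 0), Ms)
  expect_equal(strip_magnetization(9e-3, m, demag_N = 0), Ms)
  # with it, magnetization tracks the background linearly below saturation
  N <- demag_factor(dev0$geometry)
  M9 <- strip_magnetization(9e-3, m, demag_N = N)
  M18 <- strip_magnetization(18e-3, m, demag_N = N)
  expect_lt(M9, Ms)
  expect_equal(M18 / M9, 2, tolerance = 1e-9)
  # monotone non-decreasing
  Ms_seq <- strip_magnetization(seq(0, 0.2, length.out = 100), m, demag_N = N)
  expect_true(all(diff(Ms_seq) >= 0))
  # default device: only the high-field end reaches saturation
  src <- strip_sources(dev0)
  expect_equal(max(src$magnetization), Ms)
  expect_lt(src$magnetization[1], 0.3 * Ms)
})

test_that("single-strip field matches a brute-force quadrature oracle", {
  src <- strip_sources(dev0)[27, ]
  # dense numerical integration over the two edge charge sheets
  oracle <- function(x, z) {
    kern <- function(a, sig) {
      Hx <- integrate(function(zp) (x - a) / ((x - a)^2 + (z - zp)^2),
                      src$z_bottom, src$z_top, rel.tol = 1e-12)$value
      Hz <- integrate(function(zp) (z - zp) / ((x - a)^2 + (z - zp)^2),
                      src$z_bottom, src$z_top, rel.tol = 1e-12)$value
      sig / (2 * pi) * c(Hx, Hz)
    }
    mu0 * (kern(src$x_right, src$magnetization) +
             kern(src$x_left, -src$magnetization))
  }
  pts <- list(c(src$x_right, src$z_top + 50e-6),
              c(src$x_left - 30e-6, src$z_top + 10e-6),
              c((src$x_left + src$x_right) / 2, src$z_top + 120e-6))
  for (p in pts) {
    B <- as.numeric(strip_field(src, p[1], p[2]))
    Bq <- oracle(p[1], p[2])
    expect_lt(sqrt(sum((B - Bq)^2)) / sqrt(sum(Bq^2)), 1e-3)
  }
})

test_that("an isolated strip has 2D-dipole far-field decay and mirror symmetry", {
  src <- strip_sources(dev0)[14, ]
  xc <- (src$x_left + src$x_right) / 2
  # 1/r^2 decay along a diagonal well outside the strip
  r <- 10e-3
  B1 <- sqrt(sum(strip_field(src, xc + r, src$z_top + r)^2))
  B2 <- sqrt(sum(strip_field(src, xc + 2 * r, src$z_top + 2 * r)^2))
  expect_equal(B2 / B1, 1 / 4, tolerance = 0.02)
  # Bx even, Bz odd in (x - center) at fixed height
  dx <- c(0.1e-3, 0.4e-3, 1.2e-3)
  fp <- strip_field(src, xc + dx, rep(src$z_top + 40e-6, 3))
  fm <- strip_field(src, xc - dx, rep(src$z_top + 40e-6, 3))
  expect_equal(fp[, "Bx"], fm[, "Bx"], tolerance = 1e-12)
  expect_equal(fp[, "Bz"], -fm[, "Bz"], tolerance = 1e-12)
  expect_error(strip_field(src, xc, src$z_top - 1e-6), "inside")
})

test_that("superposition over strips is exact", {
  src <- strip_sources(dev0)
  x <- src$x_right[3] + 120e-6; z <- 20e-6
  two <- magsort:::cpp_field(x, z, magsort:::.strip_matrix(src[3:4, ]),
                             0, 1, 1, 0.5)
  single <- magsort:::cpp_field(x, z, magsort:::.strip_matrix(src[3, ]),
                                0, 1, 1, 0.5) +
    magsort:::cpp_field(x, z, magsort:::.strip_matrix(src[4, ]),
                        0, 1, 1, 0.5)
  expect_equal(as.numeric(two), as.numeric(single), tolerance = 1e-14)
})

test_that("with unmagnetized strips the field reduces to the background", {
  dev <- dev0
  dev$materials$saturation_polarization <- 1e-30 # forces M ~ 0
  xs <- c(1e-3, 9e-3, 20e-3)
  f <- total_field(xs, rep(30e-6, 3), dev)
  expect_equal(f$Bx, background_field(xs, dev), tolerance = 1e-9)
  expect_equal(f$Bz, rep(0, 3), tolerance = 1e-20)
  # force factor reduces to the background's own gradient term
  p <- background_exponent(dev)
  H <- background_field(xs, dev) / mu0
  expect_equal(f$ffx, H * p * H / (45e-3 - xs), tolerance = 1e-6)
})

test_that("curl-free identity: advective and energy-gradient force factors agree", {
  # independent code paths: FD Jacobian advection vs analytic grad(|H|^2)/2
  xs <- as.vector(outer(c(3e-3, 9e-3, 15e-3, 21e-3, 26e-3),
                        c(-180e-6, 0, 230e-6), `+`))
  zs <- rep(c(5e-6, 30e-6, 80e-6), each = 5)
  f <- total_field(xs, zs, dev0)
  rel <- vapply(seq_along(xs), function(i) {
    J <- fd_jacobian_H(dev0, xs[i], zs[i])
    adv <- as.numeric(J %*% H_at(dev0, xs[i], zs[i]))
    en <- c(f$ffx[i], f$ffz[i])
    sqrt(sum((adv - en)^2)) / sqrt(sum(en^2))
  }, numeric(1))
  expect_lt(max(rel), 1e-6)
})

test_that("strip fields are divergence-free on a test grid", {
  # FD divergence of total B minus the (non-solenoidal) background envelope
  hs <- 2e-8
  xs <- c(2e-3, 13e-3, 25e-3) + 230e-6
  zs <- c(5e-6, 40e-6, 90e-6)
  p <- background_exponent(dev0)
  for (i in seq_along(xs)) {
    x <- xs[i]; z <- zs[i]
    dbx <- (total_field(x + hs, z, dev0)$Bx -
              total_field(x - hs, z, dev0)$Bx) / (2 * hs)
    dbz <- (total_field(x, z + hs, dev0)$Bz -
              total_field(x, z - hs, dev0)$Bz) / (2 * hs)
    bg_div <- p * background_field(x, dev0) / (45e-3 - x)
    f <- total_field(x, z, dev0)
    scale <- sqrt(f$dBdx^2 + f$dBdz^2)
    expect_lt(abs(dbx + dbz - bg_div) / scale, 1e-5)
  }
})

test_that("the sculpted profile oscillates with a local maximum per strip", {
  xs <- seq(5e-5, 27e-3 - 5e-5, by = 1e-5)
  B <- total_field(xs, rep(0, length(xs)), dev0)$B
  imax <- which(diff(sign(diff(B))) < 0) + 1
  period <- findInterval(xs, seq(0, 27e-3, by = 1e-3))
  # every one of the 27 periods contains at least one local maximum
  expect_setequal(unique(period[imax]), 1:27)
  # and the per-period peak grows monotonically toward the magnet
  expect_true(all(diff(tapply(B, period, max)) > 0))
})

test_that("gradients are strongest near the strips and decay with height", {
  g10 <- line_gradient_scan(dev0, strip_index = 20, height = 10e-6)$max_grad
  g50 <- line_gradient_scan(dev0, strip_index = 20, height = 50e-6)$max_grad
  expect_gt(g10, g50)
  # monotone decay with height above a strip edge across the channel
  edge <- strip_sources(dev0)$x_right[20]
  zs <- seq(10e-6, 100e-6, by = 5e-6)
  f <- total_field(rep(edge, length(zs)), zs, dev0)
  expect_true(all(diff(sqrt(f$dBdx^2 + f$dBdz^2)) <= 0))
})

test_that("field maps evaluate deterministic finite samples on a valid lattice", {
  ext <- magsort:::.strip_extent(dev0$geometry, 5)
  fm <- field_map(dev0, xlim = c(ext[1] - 250e-6, ext[2] + 250e-6),
                  zlim = c(0, 100e-6), nx = 3, nz = 3)
  expect_equal(nrow(fm), 9)
  expect_true(all(is.finite(as.matrix(fm))))
  expect_true(all(diff(attr(fm, "x_grid")) > 0))
  expect_true(all(diff(attr(fm, "z_grid")) > 0))
  expect_error(field_map(dev0, nx = 1), "resolution")
  expect_error(total_field(ext[1] + 10e-6, -60e-6, dev0), "inside")
})
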