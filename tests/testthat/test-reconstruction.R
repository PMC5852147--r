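slice_src <- function(sigma_j = 1) slab_source(50, 300, sigma_j = sigma_j)

fft_k_for_test <- function(M, L) 2 * pi * c(0:(M / 2), -(M / 2 - 1):-1)[1:M] / L
fftshift2_for_test <- function(x) {
  M <- nrow(x)
  i <- c((floor(M / 2) + 1):M, 1:floor(M / 2))
  x[i, i]
}

test_that("transfer function limits, symmetry and monotonicity", {
  src <- slice_src()
  # k -> 0 limit: a1 mu0 d / 2
  expect_equal(transfer_function(0, src), ms_constants$mu0 * 300 / 2)
  expect_equal(transfer_function(1e-9, src), transfer_function(0, src),
               tolerance = 1e-6)

  # with a rational correction the k -> 0 limit picks up the log term
  src2 <- slab_source(50, 300, volume_correction(0.5, 30, 10))
  expected <- 0.5 * ms_constants$mu0 * 150 +
    30 * ms_constants$mu0 / 2 * log((50 + 10 + 300) / (50 + 10))
  expect_equal(transfer_function(0, src2), expected)
  expect_equal(transfer_function(1e-7, src2), expected, tolerance = 1e-4)

  # strictly positive, strictly decreasing in k
  k <- seq(0, pi / 2, length.out = 400)
  f <- transfer_function(k, src)
  expect_true(all(f > 0))
  expect_true(all(diff(f) < 0))

  # radial symmetry is structural (depends on |k| only): same k, same value
  expect_equal(transfer_function(matrix(0.02, 2, 2), src)[1, 1],
               transfer_function(0.02, src))

  # cut-off decreases with standoff and with slab depth
  khalf <- function(z0, d) {
    s <- slab_source(z0, d)
    f0 <- transfer_function(0, s)
    stats::uniroot(function(k) transfer_function(k, s) - f0 / 2,
                   c(1e-6, 10))$root
  }
  expect_gt(khalf(25, 300), khalf(50, 300))
  expect_gt(khalf(50, 150), khalf(50, 300))

  expect_error(transfer_function(-0.1, src), "non-negative")
})

test_that("transfer function matches the brute-force Fourier oracle", {
  z0 <- 50
  d <- 300
  # oracle 1: closed-form depth-integrated spatial kernel of the slab
  # field, discretised on a padded domain, Fourier transformed by plain
  # DFT. Accuracy is limited by truncating the 1/rho^3 kernel tail at the
  # domain edge (error scales as 1/L_pad).
  Lpad <- 8000
  M <- 1024
  delta <- Lpad / M
  x <- ((0:(M - 1)) - M / 2) * delta
  R2 <- outer(x^2, x^2, "+")
  g <- ms_constants$mu0_4pi * (1 / sqrt(R2 + z0^2) - 1 / sqrt(R2 + (z0 + d)^2))
  Gk <- Re(fft(fftshift2_for_test(g))) * delta^2
  k1 <- fft_k_for_test(M, Lpad)
  K <- sqrt(outer(k1^2, k1^2, "+"))
  f_analytic <- transfer_function(K, slice_src())
  f0 <- transfer_function(0, slice_src())
  usable <- f_analytic > 1e-3 * f0 & K <= pi / 2
  rel <- abs(Gk[usable] - f_analytic[usable]) / f_analytic[usable]
  expect_lt(max(rel), 0.05)

  # oracle 2: radial Fourier (Hankel) quadrature of the same kernel,
  # free of domain truncation; this pins the analytic form to < 1%
  hankel <- function(k) {
    integrate(function(r) {
      2 * pi * r * besselJ(k * r, 0) * ms_constants$mu0_4pi *
        (1 / sqrt(r^2 + z0^2) - 1 / sqrt(r^2 + (z0 + d)^2))
    }, 0, 2e4, subdivisions = 2000L, rel.tol = 1e-10)$value
  }
  ks <- c(0.002, 0.005, 0.01, 0.02, 0.05, 0.09)
  f_or <- vapply(ks, hankel, numeric(1))
  expect_lt(max(abs(f_or - transfer_function(ks, slice_src())) / f_or), 0.01)
})

test_that("Wiener filter limits and pixel-size independence", {
  src <- slice_src(sigma_j = 100)
  k <- seq(0, 0.1, length.out = 50)
  f <- transfer_function(k, src)

  # noiseless limit: exact inverse
  fI0 <- wiener_filter(f, noise_spec(0), 100)
  expect_equal(fI0 * f, rep(1, length(f)))

  # strong-noise limit: matched filter, vanishing
  fIinf <- wiener_filter(f, noise_spec(1e6), 100)
  expect_equal(fIinf, f * 100^2 / (1e12 * 1e6), tolerance = 1e-6)

  # joint scaling invariance of (sigma_j, eta)
  fI1 <- wiener_filter(f, noise_spec(10), 100)
  fI2 <- wiener_filter(f, noise_spec(20), 200)
  expect_equal(fI1, fI2)

  # the filter depends on k only, not on the pixel size: the k-grid of a
  # 64-pixel sensor is a subset of the 128-pixel one over the same FoV, and
  # the filter values on the shared modes coincide exactly
  L <- 1000
  K64 <- abs(outer(fft_k_for_test(64, L)^2, fft_k_for_test(64, L)^2, "+"))^0.5
  K128 <- abs(outer(fft_k_for_test(128, L)^2, fft_k_for_test(128, L)^2, "+"))^0.5
  fI64 <- wiener_filter(transfer_function(K64, src), noise_spec(10), 100)
  fI128 <- wiener_filter(transfer_function(K128, src), noise_spec(10), 100)
  half <- c(1:33, 98:128) # modes of the 128 grid that exist on the 64 grid
  expect_equal(fI128[half, half], fI64, tolerance = 1e-14)
})

test_that("source calibration hits the analytic peak and scales linearly", {
  src <- slice_src()
  s1 <- calibrate_source_strength(src, 1.5)
  s2 <- calibrate_source_strength(src, 3.0)
  expect_equal(s2, 2 * s1)

  # identity correction: closed-form peak (mu0/4pi)(1/z0 - 1/(z0+d))
  expect_equal(s1, 1.5 / (0.1 * (1 / 50 - 1 / 350)), tolerance = 1e-8)

  # rendered pixel-averaged map peaks slightly below the calibration target
  srcp <- slab_source(1, 2)
  srcp$sigma_j <- calibrate_source_strength(srcp, 2.5)
  bx <- render_slab_field(srcp, noise_spec(0), 1000 / 512)
  expect_lt(max(bx), 2.5)
  expect_gt(max(bx), 1.5)
  # while the smooth slice field peak stays close to the target (the small
  # excess comes from periodic wrap-around of the slowly decaying field on
  # the 1 mm rendering domain)
  srcs <- slice_src()
  srcs$sigma_j <- s1
  bxs <- render_slab_field(srcs, noise_spec(0), 1000 / 128)
  expect_equal(max(bxs), 1.5, tolerance = 0.05)
})

test_that("PSF limits: band-limited delta at low noise, monotone in eta", {
  src <- slice_src()
  src$sigma_j <- calibrate_source_strength(src, 1.5)
  delta <- 1000 / 128

  # zero noise: the PSF is the band-limited delta. On the native sampling
  # grid its profile is the discrete delta (the sinc zeros fall exactly on
  # the samples), so the interpolated FWHM estimate is delta, the grid
  # limit of the continuum sinc main-lobe width 1.21 delta.
  rec0 <- psf_reconstruction(src, noise_spec(0), delta)
  expect_equal(rec0$fwhm_um, delta)
  # exactly zero noise: perfect band-limited inverse, infinite pSNR
  expect_equal(psf_reconstruction(src, noise_spec(0), delta)$psnr, Inf)
  expect_equal(psnr(src, noise_spec(0), delta, "monte_carlo"), Inf)

  etas <- c(0.1, 1, 3, 10, 30)
  recs <- lapply(etas, function(e) psf_reconstruction(src, noise_spec(e), delta))
  fwhm <- vapply(recs, `[[`, numeric(1), "fwhm_um")
  ps <- vapply(recs, `[[`, numeric(1), "psnr")
  expect_true(all(diff(fwhm) >= 0))
  expect_true(all(diff(ps) < 0))

  # pSNR invariant under joint scaling of source strength and noise
  src2 <- src
  src2$sigma_j <- 3 * src$sigma_j
  expect_equal(psf_reconstruction(src2, noise_spec(30), delta)$psnr,
               psf_reconstruction(src, noise_spec(10), delta)$psnr)

  # PSF peak sits at the source location (grid centre)
  pk <- which(recs[[4]]$psf == max(recs[[4]]$psf), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(65, 65))

  # axis-cut and azimuthally averaged FWHM agree for this radial PSF
  rec_r <- psf_reconstruction(src, noise_spec(10), delta, profile = "radial")
  expect_equal(rec_r$fwhm_um, recs[[4]]$fwhm_um, tolerance = 0.1)

  expect_error(psf_reconstruction(src, noise_spec(10), 7.9), "divide")
})

test_that("analytic noise propagation matches seeded Monte Carlo", {
  src <- slice_src()
  src$sigma_j <- calibrate_source_strength(src, 1.5)
  delta <- 1000 / 128
  pa <- psnr(src, noise_spec(10), delta, "analytic")
  pm <- psnr(src, noise_spec(10), delta, "monte_carlo",
             n_realizations = 500, seed = 99)
  expect_lt(abs(pa - pm) / pa, 0.05)
  expect_error(psnr(src, noise_spec(10), delta, "bogus"))
})

test_that("map deconvolution is consistent with the PSF operator", {
  src <- slice_src()
  src$sigma_j <- calibrate_source_strength(src, 1.5)
  delta <- 1000 / 128
  noise <- noise_spec(10)

  # noiseless field of the centred point source reconstructs to the PSF
  bx <- render_slab_field(src, noise, delta, pixel_averaged = FALSE)
  jhat <- reconstruct_map(bx, src, noise, delta)
  rec <- psf_reconstruction(src, noise, delta)
  expect_equal(jhat, rec$psf, tolerance = 1e-8)

  # two well-separated sources reconstruct to two maxima at the truth
  M <- 128
  L <- M * delta
  k1 <- fft_k_for_test(M, L)
  f <- transfer_function(sqrt(outer(k1^2, k1^2, "+")), src)
  shift <- function(n) exp(2i * pi * (0:(M - 1)) * n / M)
  two_k <- src$sigma_j * f * (outer(shift(-20), shift(0)) + outer(shift(20), shift(0)))
  bx2 <- Re(fft(two_k, inverse = TRUE)) / L^2
  jhat2 <- reconstruct_map(bx2, src, noise, delta)
  top <- order(jhat2, decreasing = TRUE)[1:2]
  rows <- sort(((top - 1) %% M) + 1)
  expect_equal(rows, c(21, 109)) # delta at 0-based rows 20 and -20 (= 108)

  expect_error(reconstruct_map(matrix(0, 4, 5), src, noise, delta), "square")
})

test_that("resolution scan reproduces the plateau and linear regimes", {
  # slice scenario: resolution plateaus for small pixels
  scan_s <- resolution_scan(slice_src(), delta_grid = c(1000 / 500, 1000 / 100),
                            eta_grid = 10, target_peak_b = 1.5)
  expect_lte(scan_s$fwhm_um[2], 1.1 * scan_s$fwhm_um[1])

  # planar scenario: resolution tracks the pixel size for coarse pixels
  scan_p <- resolution_scan(slab_source(1, 2),
                            delta_grid = c(1000 / 200, 1000 / 100, 1000 / 50),
                            eta_grid = 0.4, target_peak_b = 2.5)
  ratio <- scan_p$fwhm_um / scan_p$delta_um
  expect_lt(diff(range(ratio)) / mean(ratio), 0.35)
  expect_true(all(diff(scan_p$fwhm_um) > 0))

  # scan rows match direct calls
  src <- slice_src()
  src$sigma_j <- calibrate_source_strength(src, 1.5)
  direct <- psf_reconstruction(src, noise_spec(10), 1000 / 100)
  row <- scan_s[scan_s$delta_um == 1000 / 100, ]
  expect_equal(row$fwhm_um, direct$fwhm_um)
  expect_equal(row$psnr, direct$psnr)
})

test_that("reduced active depth degrades resolution at equal noise", {
  # thin control source: same peak-field convention is NOT applied; the
  # total strength drops to ~1/6 when only 50 um of depth is active
  full <- slice_src()
  full$sigma_j <- calibrate_source_strength(full, 1.5)
  thin <- slab_source(50, 50)
  thin$sigma_j <- full$sigma_j / 6
  delta <- 1000 / 128
  f_full <- psf_reconstruction(full, noise_spec(10), delta)
  f_thin <- psf_reconstruction(thin, noise_spec(10), delta)
  expect_gte(f_thin$fwhm_um, f_full$fwhm_um)
})

test_that("noise threshold search brackets the target pSNR", {
  src <- slice_src()
  src$sigma_j <- calibrate_source_strength(src, 1.5)
  delta <- 1000 / 128
  eta_star <- eta_for_psnr(src, delta, target_psnr = 10)
  p_lo <- psf_reconstruction(src, noise_spec(eta_star * 0.98), delta)$psnr
  p_hi <- psf_reconstruction(src, noise_spec(eta_star * 1.02), delta)$psnr
  expect_gt(p_lo, 10 * 0.99)
  expect_lt(p_hi, 10 * 1.01)
})

# local copies of internal grid helpers (kept independent of the package
# internals on purpose)
fft_k_for_test <- function(M, L) 2 * pi * c(0:(M / 2), -(M / 2 - 1):-1)[1:M] / L
fftshift2_for_test <- function(x) {
  M <- nrow(x)
  i <- c((floor(M / 2) + 1):M, 1:floor(M / 2))
  x[i, i]
}
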