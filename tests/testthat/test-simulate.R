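# Phantom generation, parallel-beam projection, count-domain noise, FBP.

test_that("phantoms are deterministic, clipped and honour degenerate specs", {
  sp <- phantom_spec(size = 64, n_ellipses = 5, rng_seed = 3)
  p1 <- generate_phantom(sp)
  p2 <- generate_phantom(sp)
  expect_identical(p1$pixels, p2$pixels)
  p3 <- generate_phantom(phantom_spec(size = 64, n_ellipses = 5, rng_seed = 4))
  expect_false(identical(p1$pixels, p3$pixels))
  expect_true(all(p1$pixels >= -1024 & p1$pixels <= 3071))
  # no ellipses: a uniform body disk on air
  pd <- generate_phantom(phantom_spec(size = 64, n_ellipses = 0, rng_seed = 1))
  expect_setequal(unique(as.vector(pd$pixels)), c(-1000, 0))
  expect_error(phantom_spec(size = 16), ">= 32")
})

test_that("forward projection is linear and matches the disk chord oracle", {
  g <- ct_geometry(32, 96)
  z <- forward_project(matrix(0, 64, 64), g)
  expect_equal(dim(z), c(32, 96))
  expect_true(all(z == 0))
  set.seed(21)
  a <- matrix(runif(64 * 64, 0, 0.02), 64)
  b <- matrix(runif(64 * 64, 0, 0.02), 64)
  pa <- forward_project(a, g)
  pb <- forward_project(b, g)
  expect_equal(forward_project(a + b, g), pa + pb, tolerance = 1e-10)
  # analytic chord length for a centred uniform disk: 2 mu sqrt(r^2 - t^2)
  s <- 128
  g2 <- ct_geometry(16, 200)
  img <- matrix(0, s, s)
  c0 <- (s - 1) / 2
  r <- 40
  mu <- 0.02
  for (i in 1:s) for (j in 1:s)
    if ((i - 1 - c0)^2 + (j - 1 - c0)^2 <= r^2) img[i, j] <- mu
  sino <- forward_project(img, g2)
  tt <- (0:199) - 99.5
  chord <- ifelse(abs(tt) < r, 2 * mu * sqrt(pmax(r^2 - tt^2, 0)), 0)
  for (a_i in c(1, 5, 12))
    expect_lt(max(abs(sino[a_i, abs(tt) < 0.9 * r] - chord[abs(tt) < 0.9 * r])),
              0.05 * max(chord))
  expect_error(forward_project(matrix(0, 64, 64), ct_geometry(32, 50)), "diagonal")
})

test_that("count-domain noise follows the delta-method variance", {
  prof <- source_profile("t", I0 = 1e4, sigma_e = 0)
  # p = 0: var(p_hat) ~ 1/I0
  ph <- inject_low_dose_noise(matrix(0, 1000, 100), prof, rng_seed = 2)
  expect_lt(abs(var(as.vector(ph)) * prof$I0 - 1), 0.05)
  expect_lt(abs(mean(ph)), 3 / sqrt(1e5 * 1e-4))  # mean ~ 0
  # p in 1..3: var ~ e^p / I0 within 10%
  for (p in 1:3) {
    ph <- inject_low_dose_noise(matrix(p, 1000, 100), prof, rng_seed = 2 + p)
    expect_lt(abs(var(as.vector(ph)) / (exp(p) / prof$I0) - 1), 0.1)
  }
  # electronic noise adds sigma_e^2 e^{2p} / I0^2
  prof2 <- source_profile("t", I0 = 1e4, sigma_e = 8)
  ph <- inject_low_dose_noise(matrix(2, 1000, 100), prof2, rng_seed = 9)
  pred <- exp(2) / 1e4 + 64 * exp(4) / 1e8
  expect_lt(abs(var(as.vector(ph)) / pred - 1), 0.1)
  # determinism and near-exactness at enormous dose
  s1 <- inject_low_dose_noise(matrix(1, 10, 10), prof, rng_seed = 5)
  s2 <- inject_low_dose_noise(matrix(1, 10, 10), prof, rng_seed = 5)
  expect_identical(s1, s2)
  hi <- source_profile("h", I0 = 1e12, sigma_e = 0)
  p_grid <- matrix(seq(0, 5, length.out = 100), 10)
  ph <- inject_low_dose_noise(p_grid, hi, rng_seed = 6)
  expect_lt(max(abs(ph - p_grid)), 1e-3)
  expect_error(source_profile("x", I0 = 0), "positive")
  expect_error(inject_low_dose_noise(matrix(-1, 2, 2), prof), "nonnegative")
})

test_that("FBP reconstructs a noiseless projection within 5% NRMSE", {
  ph <- generate_phantom(phantom_spec(size = 256, n_ellipses = 5, rng_seed = 7))
  g <- ct_geometry(180, as.integer(ceiling(sqrt(2) * 256)) + 2)
  sino <- forward_project(ph, g)
  rec <- fbp_reconstruct(sino, g, "ram-lak", 256)
  c0 <- (256 - 1) / 2
  xs <- matrix(rep(0:255 - c0, each = 256), 256)
  ys <- matrix(rep(0:255 - c0, times = 256), 256)
  body <- (xs^2 + ys^2) <= (0.8 * 128)^2
  nrmse <- sqrt(mean((rec$pixels[body] - ph$pixels[body])^2)) /
    diff(range(ph$pixels[body]))
  expect_lt(nrmse, 0.05)
  # zero sinogram reconstructs to (numerically) zero attenuation
  z <- fbp_reconstruct(matrix(0, 180, g$n_detectors), g, "ram-lak", 64,
                       as_hu = FALSE)
  expect_equal(max(abs(z)), 0)
  expect_error(fbp_reconstruct(sino, g, "cosine", 256), "'arg'")
})

test_that("apodised filters damp high frequencies relative to ram-lak", {
  ph <- generate_phantom(phantom_spec(size = 64, n_ellipses = 4, rng_seed = 8))
  prof <- source_profile("t", I0 = 2000, sigma_e = 0,
                         geometry = ct_geometry(90, 93))
  sino <- forward_project(ph, prof$geometry)
  noisy <- inject_low_dose_noise(sino, prof, rng_seed = 3)
  hf_energy <- function(filter) {
    rec <- fbp_reconstruct(noisy, prof$geometry, filter, 64, as_hu = FALSE)
    d <- diff(rec)  # vertical first differences as a high-pass probe
    mean(d^2)
  }
  expect_lt(hf_energy("hann"), hf_energy("shepp-logan"))
  expect_lt(hf_energy("shepp-logan"), hf_energy("ram-lak"))
})

test_that("paired simulation is dose-monotone and profile-sensitive", {
  g <- ct_geometry(90, 93)
  seeds <- 1:4
  mean_psnr <- function(I0) {
    prof <- source_profile("d", I0 = I0, sigma_e = 2, filter = "hann", geometry = g)
    mean(sapply(seeds, function(k) {
      ph <- generate_phantom(phantom_spec(size = 64, n_ellipses = 5, rng_seed = k))
      ph$source_id <- "d"
      pr <- simulate_pair(ph, prof, rng_seed = 50 + k)
      psnr(hu_to_normalized(pr$ndct), hu_to_normalized(pr$ldct))
    }))
  }
  doses <- c(5e2, 5e3, 5e4)
  curves <- sapply(doses, mean_psnr)
  expect_true(all(diff(curves) > 0))
  # distinct profiles give distinct flat-region noise
  ph <- generate_phantom(phantom_spec(size = 64, n_ellipses = 0, rng_seed = 2))
  flat <- 25:40
  vars <- sapply(default_source_profiles(64), function(pr) {
    ph$source_id <- pr$source_id
    var(as.vector(simulate_pair(ph, pr, rng_seed = 77)$ldct$pixels[flat, flat]))
  })
  expect_equal(length(unique(round(vars, 6))), 3)
  expect_true(all(diff(vars) < 0))  # higher dose, less variance
})

test_that("corpus generation is a pure function of its seed", {
  d1 <- file.path(tempdir(), "corpA")
  d2 <- file.path(tempdir(), "corpB")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- build_multisource_corpus(d1, n_pairs_per_source = 2,
                                 profiles = default_source_profiles(64),
                                 phantom = phantom_spec(size = 64, n_ellipses = 3),
                                 rng_seed = 5)
  m2 <- build_multisource_corpus(d2, n_pairs_per_source = 2,
                                 profiles = default_source_profiles(64),
                                 phantom = phantom_spec(size = 64, n_ellipses = 3),
                                 rng_seed = 5)
  expect_equal(nrow(m1), 6)  # 3 sources x 2 pairs, one manifest row per pair
  expect_identical(readLines(file.path(d1, "manifest.tsv")),
                   readLines(file.path(d2, "manifest.tsv")))
  p1 <- load_manifest_pair(m1[1, , drop = FALSE], d1)
  p2 <- load_manifest_pair(m2[1, , drop = FALSE], d2)
  expect_identical(p1$ldct$pixels, p2$ldct$pixels)
  expect_equal(sort(unique(m1$source_id)), c("A", "B", "C"))
  expect_true(file.exists(file.path(d1, "profiles.json")))
})
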