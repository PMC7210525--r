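test_that("region means use the binary Heaviside with phi = 0 as interior", {
  img <- matrix(0.7, 4, 4)
  phi <- matrix(c(-1, 1), 4, 4)
  rm <- region_means(img, phi)
  expect_equal(rm$c1, 0.7)
  expect_equal(rm$c2, 0.7)

  img2 <- matrix(c(0, 0, 1, 1), 2, 2)   # columns (0,0) and (1,1)
  phi2 <- matrix(c(-1, -1, 0, 2), 2, 2) # interior = column 2 (phi >= 0)
  rm2 <- region_means(img2, phi2)
  expect_equal(rm2$c1, 1)
  expect_equal(rm2$c2, 0)

  expect_error(region_means(img, matrix(1, 4, 4)),
               class = "octdme_empty_region_error")
  expect_error(region_means(img, matrix(-1, 4, 4)),
               class = "octdme_empty_region_error")
})

test_that("region means agree with the brute-force oracle on random fields", {
  for (s in 1:25) {
    withr::with_seed(s, {
      img <- matrix(stats::runif(256), 16, 16)
      phi <- matrix(stats::rnorm(256), 16, 16)
    })
    got <- region_means(img, phi)
    ref <- bf_region_means(img, phi)
    expect_equal(got$c1, ref$c1, tolerance = 1e-12)
    expect_equal(got$c2, ref$c2, tolerance = 1e-12)
  }
})

test_that("signed pressure force matches hand arithmetic and normalization", {
  img <- matrix(c(0.2, 0.5, 0.9), 1, 3)
  expect_equal(spf_conventional(img, 0.9, 0.1),
               matrix(c(-0.75, 0, 1), 1, 3), tolerance = 1e-12)
  img2 <- matrix(c(0.1, 0.4, 0.8), 1, 3)
  expect_equal(spf_modified(img2, 0.1, 0.7),
               matrix(c(-0.75, 0, 1), 1, 3), tolerance = 1e-12)

  # symmetric threshold on a binary image
  bin <- matrix(rep(c(0, 1), 8), 4, 4)
  expect_equal(spf_conventional(bin, 1, 0), bin * 2 - 1)
  expect_equal(spf_modified(bin, 0, 1), bin * 2 - 1)

  # zero-numerator branch
  expect_equal(spf_conventional(matrix(0.5, 3, 3), 0.6, 0.4),
               matrix(0, 3, 3))
})

test_that("substituting C = c2 reproduces the conventional force; max|spf| is 0 or 1", {
  withr::local_seed(7)
  for (k in 1:20) {
    img <- matrix(stats::runif(64), 8, 8)
    c1 <- stats::runif(1); c2 <- stats::runif(1)
    expect_identical(spf_modified(img, c1, c2), spf_conventional(img, c1, c2))
    m <- max(abs(spf_conventional(img, c1, c2)))
    expect_true(isTRUE(all.equal(m, 1)) || m == 0)
  }
})

test_that("gradient magnitude handles constants, ramps and borders", {
  expect_equal(gradient_magnitude(matrix(2.5, 5, 5)), matrix(0, 5, 5))
  ramp <- matrix(rep(1:6, each = 5), 5, 6)             # phi(r, c) = c
  expect_equal(gradient_magnitude(ramp)[2:4, 2:5],
               matrix(1, 3, 4))
  diag_ramp <- outer(1:5, 1:6, "+")                    # phi(r, c) = r + c
  expect_equal(gradient_magnitude(diag_ramp)[2:4, 2:5],
               matrix(sqrt(2), 3, 4))
  expect_error(gradient_magnitude(matrix(1, 2, 2)),
               class = "octdme_contract_error")
})

test_that("evolve_step is explicit Euler on the balloon force", {
  p <- evolution_params(alpha = 1, dt = 0.5, sigma = 0)
  phi <- matrix(rep(1:6, each = 5), 5, 6) * 1.0
  expect_equal(evolve_step(phi, matrix(0, 5, 6), p), phi)
  out <- evolve_step(phi, matrix(1, 5, 6), p)
  expect_equal(out[2:4, 2:5] - phi[2:4, 2:5], matrix(0.5, 3, 4))

  expect_error(evolution_params(alpha = 0), class = "octdme_contract_error")
  big <- evolution_params(alpha = 10, dt = 1, sigma = 0)
  huge <- matrix(rep(1:6, each = 5), 5, 6) * 1e308
  err <- expect_error(evolve_step(huge, matrix(1, 5, 6), big),
                      class = "octdme_numeric_blowup_error")
  expect_match(conditionMessage(err), "dt \\* alpha")
})

test_that("regularization is the sign map followed by truncated Gaussian smoothing", {
  expect_equal(regularize(matrix(c(-3.2, 0.5, 7.0), 1, 3), sigma = 0),
               matrix(c(-1, 1, 1), 1, 3))
  expect_equal(regularize(matrix(4, 6, 6), sigma = 2), matrix(1, 6, 6),
               tolerance = 1e-12)

  # one kernel placement by hand: 3x3 truncated kernel, sigma = 1
  phi <- matrix(-1, 9, 9); phi[5, 5] <- 1
  g <- stats::dnorm(-1:1)
  w_center <- (g[2] / sum(g))^2
  out <- regularize(phi, sigma = 1, radius = 1)
  expect_equal(out[5, 5], 2 * w_center - 1, tolerance = 1e-12)
  expect_true(all(out >= -1 & out <= 1))
})

test_that("DME initialization thresholds ROI pixels at (c_dark + C)/2", {
  mask <- matrix(FALSE, 6, 6); mask[2:5, 2:5] <- TRUE
  roi <- toy_roi(mask, C = 0.7, centers = c(0.1, 0.8))  # threshold 0.4
  img <- matrix(0.6, 6, 6)
  img[3:4, 3:4] <- 0.2                                  # dark pocket
  img[1, 1] <- 0.01                                     # dark but outside ROI
  phi <- initialize_dme_phi(img, roi)
  expected <- matrix(-1, 6, 6); expected[3:4, 3:4] <- 1
  expect_identical(phi, expected)

  # uniform ROI: single-pixel fallback at the first darkest in row-major order
  phi_u <- initialize_dme_phi(matrix(0.6, 6, 6), roi)
  expect_equal(sum(phi_u == 1), 1)
  expect_equal(phi_u[2, 2], 1)

  expect_error(initialize_dme_phi(img, toy_roi(matrix(FALSE, 6, 6), C = 0.7)),
               class = "octdme_empty_roi_error")
})

test_that("conventional engine recovers a bright disk and matches its threshold oracle", {
  img <- matrix(0.2, 24, 24)
  rows <- matrix(1:24, 24, 24); cols <- t(rows)
  disk <- (rows - 12)^2 + (cols - 12)^2 <= 49
  img[disk] <- 0.9
  init <- matrix(-1, 24, 24)
  init[disk & cols <= 12] <- 1                 # half of the disk
  res <- run_sbgfrls(img, init, evolution_params())
  expect_true(res$converged)
  oracle <- img > (res$c1 + res$c2) / 2
  expect_identical(res$mask, oracle)
  expect_identical(res$mask, disk)
})

test_that("a stationary field converges immediately at zero tolerance", {
  img <- matrix(0.5, 8, 8)                     # spf is identically zero
  init <- matrix(-1, 8, 8); init[3:5, 3:5] <- 1
  res <- run_sbgfrls(img, init,
                     evolution_params(conv_tol = 0, conv_window = 1))
  expect_true(res$converged)
  expect_equal(res$iterations, 1L)
  expect_identical(res$mask, init > 0)
  expect_identical(res$area_trace, 9L)
})

test_that("a vanished interior surfaces as an empty-region error with the iteration", {
  # a single-pixel seed on a zero-force image dies under the Gaussian
  # regularization, leaving the next iteration with an empty interior
  img <- matrix(0.5, 9, 9)
  init <- matrix(-1, 9, 9); init[5, 5] <- 1
  p <- evolution_params(alpha = 20, sigma = 1, conv_tol = 0, conv_window = 5)
  err <- expect_error(run_sbgfrls(img, init, p),
                      class = "octdme_empty_region_error")
  expect_match(conditionMessage(err), "iteration")
})

test_that("the interior area is non-decreasing under a pure positive balloon", {
  p <- evolution_params(alpha = 5, dt = 1, sigma = 0)
  spf <- matrix(1, 12, 12)
  withr::local_seed(13)
  for (k in 1:5) {
    phi <- matrix(sample(c(-1, 1), 144, replace = TRUE), 12, 12)
    areas <- integer(20)
    for (it in 1:20) {
      phi <- regularize(evolve_step(phi, spf, p), sigma = 0)
      areas[it] <- sum(phi > 0)
    }
    expect_true(all(diff(areas) >= 0))
  }
})
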