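test_that("kinetic_scheme builds the rate matrix with the outflow convention", {
  s <- sequential_scheme3()
  expect_equal(diag(s$K), -1 / c(A = 5, B = 60, C = 700))
  expect_equal(s$K["B", "A"], 1 / 5)
  expect_equal(sum(s$initial), 1)
  expect_equal(scheme_lifetimes(s), c(5, 60, 700))
  expect_error(kinetic_scheme("A", loss = c(A = -1)), "non-negative")
  expect_error(kinetic_scheme(c("A", "B"),
                              transfers = data.frame(from = "A", to = "Z",
                                                     rate = 1)),
               "unknown compartment")
})

test_that("single-compartment populations follow the closed form", {
  still <- kinetic_scheme("A")               # rate 0: constant population
  tt <- seq(0, 10, by = 0.5)
  cp <- concentration_profiles(still, tt)
  expect_equal(as.vector(cp), rep(1, length(tt)))

  k <- 1 / 7
  dec <- kinetic_scheme("A", loss = c(A = k))
  cp2 <- concentration_profiles(dec, tt)
  expect_equal(as.vector(cp2), exp(-k * tt), tolerance = 1e-12)
  expect_equal(unname(concentration_profiles(dec, 1 / k)[1, 1]), exp(-1),
               tolerance = 1e-12)
})

test_that("closed-form profiles match adaptive ODE integration to 1e-8", {
  s <- kinetic_scheme(c("A", "B"),
                      transfers = data.frame(from = "A", to = "B", rate = 1 / 5),
                      loss = c(B = 1 / 200))
  tt <- c(0, exp(seq(log(0.1), log(1000), length.out = 80)))
  closed <- concentration_profiles(s, tt)
  rhs <- function(t, y, p) list(drop(s$K %*% y))
  ode <- deSolve::ode(y = s$initial, times = tt, func = rhs, parms = NULL,
                      rtol = 1e-12, atol = 1e-14)[, -1]
  expect_lt(max(abs(closed - ode)), 1e-8)
})

test_that("IRF-convolved profiles converge to unconvolved ones as fwhm -> 0", {
  s <- sequential_scheme3()
  tt <- c(seq(-5, -0.5, by = 0.5), seq(0.01, 2000, length.out = 200))
  bare <- concentration_profiles(s, tt)
  conv <- concentration_profiles(s, tt, irf = irf_model(fwhm = 1e-4))
  expect_lt(max(abs(bare - conv)), 1e-6)
})

test_that("IRF convolution smooths through time zero and stays finite for slow rates", {
  irf <- irf_model(fwhm = 0.2, t0 = 0)
  tt <- seq(-1, 1, by = 0.01)
  y <- conv_exp(tt, rate = 1 / 2000, irf = irf)
  expect_true(all(is.finite(y)))
  expect_equal(y[tt == 0], 0.5, tolerance = 1e-3)   # half-risen at t0
  expect_lt(max(abs(diff(y))), 0.05)                # no jump
  # large rate x width regime uses the asymptotic branch and stays finite
  y2 <- conv_exp(seq(-10, 0, by = 0.1), rate = 50, irf = irf_model(fwhm = 2))
  expect_true(all(is.finite(y2)))
  expect_true(all(y2 >= 0))
})

test_that("svd_rank handles degenerate and synthetic-truth cases", {
  # rank-1 outer product
  m <- outer(exp(-(0:50) / 10), exp(-((1:20) - 10)^2))
  r1 <- svd_rank(m)
  expect_equal(r1$rank, 1L)
  expect_false(is.unsorted(rev(r1$singular_values)))
  # zero matrix: rank 0, no error
  expect_equal(svd_rank(matrix(0, 5, 5))$rank, 0L)
  # four well-separated components at 1% noise
  sch <- kinetic_scheme(c("A", "B", "C", "D"),
    transfers = data.frame(from = c("A", "B", "C"), to = c("B", "C", "D"),
                           rate = 1 / c(5, 50, 400)),
    loss = c(D = 1 / 2000))
  surf <- make_surface(sch,
                       times = c(seq(-1, 2, by = 0.1),
                                 exp(seq(log(2.4), log(6000), length.out = 70))),
                       wavelengths = seq(550, 700, by = 2),
                       band_centers = c(600, 630, 660, 690), band_widths = 12,
                       irf = irf_model(0.1), noise_sigma = 0.01, seed = 3)
  expect_equal(svd_rank(surf)$rank, 4L)
})
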