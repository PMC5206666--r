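test_that("propagation at zero distance is the identity", {
  set.seed(1)
  f <- wave_field(
    matrix(complex(real = rnorm(32^2), imaginary = rnorm(32^2)), 32, 32),
    pitch = 1.67, wavelength = 457.5
  )
  g <- propagate(f, 0)
  expect_identical(g$amplitude, f$amplitude)
  expect_identical(g$z_ref, f$z_ref)
})

test_that("forward then backward propagation is the identity on band-limited fields", {
  set.seed(2)
  f <- wave_field(
    matrix(complex(real = rnorm(64^2), imaginary = rnorm(64^2)), 64, 64),
    pitch = 1.67, wavelength = 457.5
  )
  f <- band_limit(f)
  g <- propagate(propagate(f, 350, pad = FALSE), -350, pad = FALSE)
  peak <- max(Mod(f$amplitude))
  expect_lt(max(Mod(g$amplitude - f$amplitude)) / peak, 1e-8)
})

test_that("a spatially constant field keeps unit modulus under propagation", {
  f <- wave_field(matrix(1 + 0i, 48, 48), pitch = 1.67, wavelength = 625)
  for (z in c(137, 1000, -420)) {
    g <- propagate(f, z, pad = FALSE)
    expect_lt(max(abs(Mod(g$amplitude) - 1)), 1e-10)
  }
})

test_that("energy is conserved by the band-limited periodic transform", {
  set.seed(3)
  f <- wave_field(
    matrix(complex(real = rnorm(256^2), imaginary = rnorm(256^2)), 256, 256),
    pitch = 1.67, wavelength = 457.5
  )
  f <- band_limit(f)
  e0 <- sum(Mod(f$amplitude)^2)
  g <- propagate(f, 777, pad = FALSE)
  expect_lt(abs(sum(Mod(g$amplitude)^2) - e0) / e0, 1e-9)
})

test_that("propagation is linear", {
  set.seed(4)
  mk <- function() {
    matrix(complex(real = rnorm(32^2), imaginary = rnorm(32^2)), 32, 32)
  }
  a <- 1.7 - 0.3i
  b <- -0.4 + 2.1i
  A <- mk()
  B <- mk()
  f <- function(M) propagate(wave_field(M, 1.67, 457.5), 200, pad = FALSE)$amplitude
  lhs <- f(a * A + b * B)
  rhs <- a * f(A) + b * f(B)
  expect_lt(max(Mod(lhs - rhs)) / max(Mod(rhs)), 1e-12)
})

test_that("angular spectrum agrees with a direct Rayleigh-Sommerfeld sum", {
  # smooth band-limited source (Gaussian spot): the sampled RS kernel is a
  # valid quadrature inside the cone where its fringes are resolved by the
  # grid, i.e. within ~ z * tan(asin(lambda / 2 pitch)) of the source
  n <- 64
  pitch <- 1.67
  wl_um <- 0.4575
  z <- 200
  ii <- matrix(1:n, n, n)
  jj <- t(ii)
  G <- exp(-(((ii - 28)^2 + (jj - 36)^2)) / (2 * 2.5^2)) + 0i
  P <- propagate(wave_field(G, pitch, wl_um * 1000), -z)$amplitude
  O <- rs_direct_sum(G, pitch, wl_um, -z)
  h <- 12 # comparison half-window, inside the resolved cone (~16 px)
  win <- function(M) M[(28 - h):(28 + h), (36 - h):(36 + h)]
  rel_rms <- sqrt(mean(Mod(win(P) - win(O))^2)) / sqrt(mean(Mod(win(O))^2))
  expect_lt(rel_rms, 0.01)
})

test_that("evanescent frequencies are removed", {
  # a field with energy beyond the propagating band loses exactly that part
  set.seed(5)
  f <- wave_field(
    matrix(complex(real = rnorm(64^2), imaginary = rnorm(64^2)), 64, 64),
    pitch = 0.2, wavelength = 625
  ) # pitch < lambda/2: much of the band is evanescent
  fb <- band_limit(f)
  g <- propagate(f, 50, pad = FALSE)
  gb <- propagate(fb, 50, pad = FALSE)
  expect_lt(max(Mod(g$amplitude - gb$amplitude)), 1e-10)
  expect_lt(sum(Mod(fb$amplitude)^2), sum(Mod(f$amplitude)^2))
})

test_that("invalid construction parameters are rejected", {
  expect_error(wave_field(matrix(1 + 0i, 4, 4), pitch = -1, wavelength = 500),
    class = "holocyte_invalid_parameter"
  )
  expect_error(wave_field(matrix(1 + 0i, 4, 4), pitch = 1.67, wavelength = 0),
    class = "holocyte_invalid_parameter"
  )
  f <- wave_field(matrix(1 + 0i, 4, 4), 1.67, 500)
  expect_error(propagate(f, Inf), class = "holocyte_invalid_parameter")
})
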