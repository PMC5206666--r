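test_that("a uniform hologram back-propagates to a uniform field", {
  h <- hologram(matrix(1000, 64, 64), wavelength = 457.5, channel = "blue")
  f <- backpropagate(h, 800)
  expect_lt(stats::sd(Mod(f$amplitude)), 1e-8)
  expect_equal(f$z_ref, 800)
  expect_error(backpropagate(h, -5), class = "holocyte_invalid_parameter")
})

test_that("an absorbing disk back-propagates to a dark centre at its true position", {
  cells <- one_cell_df(row = 70.0, col = 58.0, diam = 8, phase = 0, absorption = 0.5)
  sc <- manual_scene(cells)
  h <- simulate_hologram(sc, 457.5, noise = "none")
  f <- backpropagate(h, 1000)
  M <- Mod(f$amplitude)
  core <- M[20:109, 20:109] # avoid frame borders
  idx <- which(core == min(core), arr.ind = TRUE)
  expect_lte(abs(idx[1, 1] + 19 - 70), 1)
  expect_lte(abs(idx[1, 2] + 19 - 58), 1)
})

test_that("autofocus finds the object plane of absorbing cells and degrades off-plane", {
  pp <- phantom_params(frame_shape = c(128L, 128L), ery_phase = c(0, 0))
  sc <- sample_scene(0, 1, pp, seed = 11)
  h <- simulate_hologram(sc, 457.5, noise = "none")
  z0 <- autofocus(h, c(800, 1200), 20)
  expect_lt(abs(as.numeric(z0) - 1000), 20)
  tr <- attr(z0, "focus_trace")
  near <- tr$metric[which.min(abs(tr$z - 1000))]
  far <- tr$metric[which.min(abs(tr$z - 840))]
  expect_gt(near, far) # off-plane focus metric is strictly worse
  # two coplanar cells agree with the single-cell estimate
  sc2 <- sample_scene(0, 2, pp, seed = 11)
  h2 <- simulate_hologram(sc2, 457.5, noise = "none")
  expect_lt(abs(as.numeric(autofocus(h2, c(800, 1200), 20)) - as.numeric(z0)), 20)
})

test_that("a featureless hologram raises a no-focus error", {
  h <- hologram(matrix(5000, 96, 96), wavelength = 457.5, channel = "blue")
  expect_error(autofocus(h, c(800, 1200), 50), class = "holocyte_no_focus")
})

test_that("zero phase-retrieval iterations reproduce plain back-propagation", {
  sc <- sample_scene(0, 4, phantom_params(frame_shape = c(128L, 128L)), seed = 3)
  h <- simulate_hologram(sc, 457.5)
  pr0 <- phase_retrieval(h, 1000, iterations = 0)
  bp <- backpropagate(h, 1000)
  expect_lt(max(Mod(pr0$field$amplitude - bp$amplitude)), 1e-10)
  expect_equal(pr0$iterations, 0L)
})

test_that("the phase-retrieval loss trace is non-increasing and recorded", {
  sc <- sample_scene(1, 3, phantom_params(frame_shape = c(128L, 128L)), seed = 4)
  h <- simulate_hologram(sc, 457.5)
  pr <- phase_retrieval(h, 1000, iterations = 15)
  expect_true(all(diff(pr$loss_trace$loss) <= 1e-9))
  expect_equal(nrow(pr$loss_trace), pr$iterations + 1L)
  expect_s3_class(tidy(pr), "tbl_df")
  g <- glance(pr)
  expect_lt(g$final_loss, g$initial_loss)
})

test_that("phase retrieval beats back-propagation on phase recovery and twin energy", {
  cells <- one_cell_df(
    kind = "leukocyte", row = 64, col = 64, diam = 12,
    phase = 2.5, absorption = 0.1
  )
  sc <- manual_scene(cells)
  h <- simulate_hologram(sc, 625, noise = "none")
  pr <- phase_retrieval(h, 1000, iterations = 30)
  bp <- backpropagate(h, 1000)
  # peak phase within 10% of ground truth
  expect_lt(abs(Arg(pr$field$amplitude[64, 64]) - 2.5) / 2.5, 0.10)
  # twin-image energy (module variance outside the true support) halved
  ii <- matrix(1:128, 128, 128)
  jj <- t(ii)
  outside <- sqrt((ii - 64)^2 + (jj - 64)^2) > (6 / 1.67 + 4)
  tw_pr <- stats::var(Mod(pr$field$amplitude[outside]))
  tw_bp <- stats::var(Mod(bp$amplitude[outside]))
  expect_lt(tw_pr, 0.5 * tw_bp)
  # masked phase RMSE against ground truth improves too
  t_true <- render_transmittance(sc, 625)$amplitude
  inside <- !outside
  rmse <- function(A) sqrt(mean((Arg(A[inside]) - Arg(t_true[inside]))^2))
  expect_lt(rmse(pr$field$amplitude), rmse(bp$amplitude))
})

test_that("mismatched hologram geometries are rejected", {
  h1 <- hologram(matrix(100, 32, 32), wavelength = 457.5, channel = "blue")
  h2 <- hologram(matrix(100, 64, 64), wavelength = 625, channel = "red")
  expect_error(phase_retrieval(list(h1, h2), 1000),
    class = "holocyte_geometry_mismatch"
  )
})
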