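test_that("a blank image yields no detections", {
  expect_equal(nrow(detect_cells(matrix(1, 128, 128))), 0)
  expect_equal(nrow(detect_cells(matrix(0, 128, 128))), 0)
})

test_that("detection count is monotone non-increasing in the accumulator threshold", {
  sc <- sample_scene(2, 8, phantom_params(frame_shape = c(192L, 192L)), seed = 21)
  h <- simulate_hologram(sc, 457.5, snr_db = 30, seed = 121)
  recon <- phase_retrieval(h, 1000, iterations = 15)
  img <- detection_image(recon, 250)
  counts <- vapply(
    c(0.1, 0.2, 0.3, 0.5, 0.8),
    function(th) nrow(detect_cells(img, accumulator_threshold = th)),
    numeric(1)
  )
  expect_true(all(diff(counts) <= 0))
})

test_that("defocusing improves the ring contrast of a cell pattern", {
  cells <- one_cell_df(row = 96, col = 96, diam = 7, phase = 0.9, absorption = 0.45)
  sc <- manual_scene(cells, frame_shape = c(192L, 192L))
  h <- simulate_hologram(sc, 457.5, noise = "none")
  recon <- phase_retrieval(h, 1000, iterations = 15)
  ring_contrast <- function(M) {
    # peak-to-background ratio in an annulus around the cell
    th <- seq(0, 2 * pi, length.out = 64)[-64]
    ann <- vapply(4:12, function(rr) {
      max(M[cbind(round(96 + rr * cos(th)), round(96 + rr * sin(th)))])
    }, numeric(1))
    max(ann) / stats::median(M)
  }
  in_focus <- ring_contrast(detection_image(recon, 0))
  defocused <- ring_contrast(detection_image(recon, 250))
  expect_gte(defocused, in_focus)
  # both defocus signs produce a detectable pattern
  for (dz in c(250, -250)) {
    d <- detect_cells(detection_image(recon, dz), accumulator_threshold = 0.2)
    expect_gte(nrow(d), 1)
  }
})

test_that("a noiseless phantom with 10 cells yields exactly 10 detections at true centroids", {
  pp <- phantom_params(frame_shape = c(256L, 256L))
  sc <- sample_scene(2, 8, pp, seed = 31)
  hb <- simulate_hologram(sc, 457.5, noise = "none")
  hr <- simulate_hologram(sc, 625, noise = "none")
  rb <- phase_retrieval(hb, 1000, iterations = 30)
  rr <- phase_retrieval(hr, 1000, iterations = 30)
  raw <- detect_cells(detection_image(rb, 250), accumulator_threshold = 0.2)
  dets <- confirm_detections(raw, rb, rr)
  expect_equal(nrow(dets), 10)
  m <- match_detections(dets, sc$cells, tol_px = 1)
  expect_equal(m$tp, 10)
  # sorted by descending score
  expect_true(all(diff(dets$score) <= 1e-12))
})

test_that("two cells closer than the separation limit collapse to one detection", {
  cells <- rbind(
    one_cell_df(row = 96, col = 96),
    one_cell_df(row = 99, col = 97) # ~3 px apart, below min_separation_px
  )
  sc <- manual_scene(cells, frame_shape = c(192L, 192L))
  h <- simulate_hologram(sc, 457.5, noise = "none")
  recon <- phase_retrieval(h, 1000, iterations = 15)
  d <- detect_cells(detection_image(recon, 250),
    accumulator_threshold = 0.2,
    min_separation_px = 6
  )
  # the suppression contract: no two kept peaks within the separation limit
  if (nrow(d) > 1) {
    dd <- as.matrix(dist(cbind(d$row, d$col)))
    diag(dd) <- Inf
    expect_gt(min(dd), 6)
  }
  # after in-focus confirmation the pair resolves to a single cell
  dc <- confirm_detections(d, recon)
  expect_equal(nrow(dc), 1)
  expect_lt(sqrt((dc$row - 96)^2 + (dc$col - 96)^2), 4)
})

test_that("detected diameters are positive and in the plausible cell range", {
  sc <- sample_scene(1, 6, phantom_params(frame_shape = c(192L, 192L)), seed = 41)
  hb <- simulate_hologram(sc, 457.5, snr_db = 30, seed = 141)
  rb <- phase_retrieval(hb, 1000, iterations = 15)
  dets <- confirm_detections(
    detect_cells(detection_image(rb, 250), accumulator_threshold = 0.2), rb
  )
  expect_true(all(dets$diameter_um > 0))
  expect_true(all(dets$diameter_um < 45))
})
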