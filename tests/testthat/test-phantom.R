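small_params <- phantom_params(frame_shape = c(128L, 128L))

test_that("scene sampling is reproducible and respects counts", {
  s1 <- sample_scene(3, 11, small_params, seed = 42)
  s2 <- sample_scene(3, 11, small_params, seed = 42)
  expect_identical(s1$cells, s2$cells)
  expect_equal(sum(s1$cells$kind == "leukocyte"), 3)
  expect_equal(sum(s1$cells$kind == "erythrocyte"), 11)
  expect_true(all(s1$cells$diameter_um[s1$cells$kind == "erythrocyte"] >= 6))
  expect_true(all(s1$cells$diameter_um[s1$cells$kind == "erythrocyte"] <= 8))
  expect_true(all(s1$cells$diameter_um[s1$cells$kind == "leukocyte"] >= 7))
  # minimum separation honoured
  d <- as.matrix(dist(cbind(s1$cells$row_px, s1$cells$col_px))) * s1$pitch
  diag(d) <- Inf
  expect_gte(min(d), small_params$min_sep_um)
})

test_that("an empty scene renders to unit transmittance and uniform holograms", {
  sc <- sample_scene(0, 0, small_params, seed = 1)
  expect_equal(nrow(sc$cells), 0)
  t <- render_transmittance(sc, 457.5)
  expect_lt(max(Mod(t$amplitude - 1)), 1e-12)
  h <- simulate_hologram(sc, 457.5, noise = "none")
  expect_lt(stats::sd(h$intensity) / mean(h$intensity), 1e-6)
})

test_that("infeasible packing raises an error", {
  tiny <- phantom_params(frame_shape = c(64L, 64L), min_sep_um = 40)
  expect_error(sample_scene(0, 500, tiny, seed = 1), class = "holocyte_packing_error")
})

test_that("transmittance phase peaks at the cell centre and phases add", {
  sc <- manual_scene(one_cell_df(phase = 1.0, absorption = 0))
  t <- render_transmittance(sc, 625) # reference wavelength: no scaling
  expect_equal(max(Arg(t$amplitude)), 1.0, tolerance = 1e-6)
  expect_equal(
    which.max(Arg(t$amplitude)),
    (64 - 1) * 128 + 64 # column-major index of the centre pixel
  )
  expect_lt(max(abs(Mod(t$amplitude) - 1)), 1e-12)

  # coincident cells: thin-object phases add
  two <- rbind(
    one_cell_df(phase = 0.4, absorption = 0),
    one_cell_df(phase = 0.6, absorption = 0)
  )
  t2 <- render_transmittance(manual_scene(two), 625)
  expect_equal(max(Arg(t2$amplitude)), 1.0, tolerance = 1e-6)
})

test_that("a pure-phase scene conserves mean hologram intensity", {
  cells <- one_cell_df(kind = "leukocyte", diam = 12, phase = 2.0, absorption = 0)
  sc <- manual_scene(cells)
  h <- simulate_hologram(sc, 625, noise = "none", counts_scale = 10000)
  sc0 <- sample_scene(0, 0, small_params, seed = 1)
  h0 <- simulate_hologram(sc0, 625, noise = "none", counts_scale = 10000)
  # energy conservation of the unitary propagator: same mean as empty scene
  expect_lt(abs(mean(h$intensity) - mean(h0$intensity)) / mean(h0$intensity), 0.005)
})

test_that("simulated diffraction rings match the Rayleigh-Sommerfeld oracle", {
  # one 8 um erythrocyte-like disk; compare radial intensity minima of the
  # hologram against the direct-sum oracle, within the resolved cone
  # pure absorption: the same object in both channels, so ring geometry
  # differences reflect the wavelength alone
  cells <- one_cell_df(row = 64, col = 64, diam = 8, phase = 0, absorption = 0.5)
  first_min <- function(I, r0 = 64, c0 = 64, rmax = 30) {
    prof <- vapply(0:rmax, function(rr) {
      if (rr == 0) {
        return(I[r0, c0])
      }
      th <- seq(0, 2 * pi, length.out = 64)[-64]
      pr <- pmin(pmax(round(r0 + rr * cos(th)), 1), nrow(I))
      pc <- pmin(pmax(round(c0 + rr * sin(th)), 1), ncol(I))
      mean(I[cbind(pr, pc)])
    }, numeric(1))
    interior <- which(diff(sign(diff(prof))) > 0) + 1
    if (length(interior)) interior[1] - 1 else NA_integer_
  }
  radii <- sapply(c(457.5, 625), function(wl) {
    sc <- manual_scene(cells)
    h <- simulate_hologram(sc, wl, noise = "none")
    t <- render_transmittance(sc, wl)
    O <- rs_hologram_intensity(t$amplitude, 1.67, wl / 1000, sc$chamber_z)
    sim_min <- first_min(h$intensity / mean(h$intensity))
    orc_min <- first_min(O)
    expect_lte(abs(sim_min - orc_min), 1) # within one pixel of the oracle
    orc_min
  })
  # shorter wavelength -> tighter rings (blue first minimum inside red's)
  expect_lt(radii[1], radii[2])
})

test_that("the RGB acquisition is deterministic and channel-stamped", {
  sc <- sample_scene(1, 5, small_params, seed = 9)
  trip1 <- simulate_rgb_acquisition(sc)
  trip2 <- simulate_rgb_acquisition(sc)
  expect_identical(trip1$blue$intensity, trip2$blue$intensity)
  expect_identical(trip1$red$intensity, trip2$red$intensity)
  expect_equal(names(trip1), c("red", "green", "blue"))
  expect_equal(trip1$green$wavelength, 527.5)
  # independent noise draws per channel
  expect_false(identical(trip1$red$intensity, trip1$blue$intensity))
})

test_that("ground-truth concentrations follow count / (area x depth)", {
  full <- phantom_params(frame_shape = c(3840L, 2748L))
  sc <- sample_scene(100, 900, full, seed = 5)
  conc <- scene_concentrations(sc)
  expect_equal(conc$leuko_conc, 100 / 2.944, tolerance = 1e-12)
  expect_equal(conc$ery_conc, 900 / 2.944, tolerance = 1e-12)
})

test_that("holograms round-trip through 16-bit TIFF with sidecar", {
  sc <- sample_scene(0, 3, small_params, seed = 2)
  h <- simulate_hologram(sc, 457.5)
  path <- withr::local_tempfile(fileext = ".tif")
  write_hologram(h, path)
  h2 <- read_hologram(path)
  expect_equal(h2$intensity, h$intensity)
  expect_equal(h2$wavelength, h$wavelength)
  expect_equal(h2$channel, h$channel)
})
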