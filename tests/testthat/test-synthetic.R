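test_that("trajectory reduces to its closed forms", {
  parts <- default_parts()
  # zero force: the band never leaves the edge
  twin <- functionalized_bead(rel_permittivity = 78, bulk_conductivity = 0.01,
                              surface_conductance = 0)
  traj <- suppressWarnings(
    simulate_band_trajectory(twin, parts$medium, parts$field, 1e6))
  expect_equal(traj$position_um, rep(0, 401))
  expect_equal(length(traj$time_ms), floor(40 / 0.1) + 1)
  # near-uniform gradient: constant-velocity motion x(t) = v0 t
  flat <- electrode_field_model(grad_e2_at_edge = 1e18, decay_length = 1e6)
  traj <- simulate_band_trajectory(parts$bead, parts$medium, flat, 2e6)
  v0 <- traj$edge_speed_um_s
  expect_equal(traj$position_um, v0 * traj$time_ms * 1e-3,
               tolerance = 1e-9)
  # exponential decay: x(t) = lambda ln(1 + v0 t / lambda)
  traj <- simulate_band_trajectory(parts$bead, parts$medium, parts$field, 2e6)
  lambda_um <- parts$field$decay_length * 1e6
  closed <- lambda_um * log(1 + traj$edge_speed_um_s *
                              traj$time_ms * 1e-3 / lambda_um)
  expect_equal(traj$position_um[-1], closed[-1], tolerance = 1e-6)
})

test_that("trajectory integration is converged and monotone", {
  parts <- default_parts()
  t1 <- simulate_band_trajectory(parts$bead, parts$medium, parts$field, 2e6,
                                 dt_ms = 0.1)
  t2 <- simulate_band_trajectory(parts$bead, parts$medium, parts$field, 2e6,
                                 dt_ms = 0.05)
  x1 <- t1$position_um[length(t1$position_um)]
  x2 <- t2$position_um[length(t2$position_um)]
  expect_lt(abs(x1 - x2) / x2, 1e-6)
  expect_true(all(diff(t1$position_um) >= 0))
  # positive DEP warns and clips at the edge
  expect_warning(
    tp <- simulate_band_trajectory(parts$bead, parts$medium, parts$field,
                                   1e4),
    "positive DEP")
  expect_true(all(tp$position_um == 0))
})

test_that("40 ms displacement grows with |Re[K]| and with the edge gradient", {
  parts <- default_parts()
  final_x <- function(bead, field, f) {
    tr <- simulate_band_trajectory(bead, parts$medium, field, f)
    tr$position_um[length(tr$position_um)]
  }
  beads <- nucleotide_bead_table("last")
  for (f in c(5e5, 1.25e6, 2e6)) {
    k <- sapply(beads, function(b) {
      abs(Re(clausius_mossotti(b, parts$medium, f)))
    })
    x <- sapply(beads, final_x, field = parts$field, f = f)
    expect_equal(order(x), order(k))
  }
  grads <- c(1e17, 3e17, 1e18)
  xg <- sapply(grads, function(g) {
    final_x(parts$bead, electrode_field_model(grad_e2_at_edge = g), 1e6)
  })
  expect_true(all(diff(xg) > 0))
})

test_that("rendered frames are deterministic and faithful to ground truth", {
  parts <- default_parts()
  img <- small_imaging(seed = 123)
  fp1 <- simulate_frame_pair(parts$bead, parts$medium, parts$field, 5e5, img)
  fp2 <- simulate_frame_pair(parts$bead, parts$medium, parts$field, 5e5, img)
  expect_identical(fp1$frames, fp2$frames)  # same seed, same bits
  img2 <- small_imaging(seed = 124)
  fp3 <- simulate_frame_pair(parts$bead, parts$medium, parts$field, 5e5, img2)
  expect_false(identical(fp1$frames[[1]], fp3$frames[[1]]))
  # noiseless frame: column argmax sits at the band center pixel
  img0 <- small_imaging(noise_sigma = 0)
  fp <- simulate_frame_pair(parts$bead, parts$medium, parts$field, 5e5, img0)
  gt <- fp$metadata$ground_truth_x_um
  prof <- extract_profile(fp, 1)
  expect_lt(abs(prof$positions_um[which.max(prof$intensities)] - gt[1]),
            img0$pixel_size_um)
  # t0 band rests at the configured standoff from the edge
  expect_equal(gt[1], img0$band_offset_um)
})

test_that("noiseless localization recovers the band to sub-pixel accuracy", {
  parts <- default_parts()
  img0 <- small_imaging(noise_sigma = 0)
  px <- img0$pixel_size_um
  # at the symmetric resting phase recovery is essentially exact
  fp <- simulate_frame_pair(parts$bead, parts$medium, parts$field, 5e5, img0)
  loc0 <- locate_band(background_subtract(extract_profile(fp, 1)))
  expect_lt(abs(loc0$x_cm_um - fp$metadata$ground_truth_x_um[1]), 1e-6 * px)
  # across the sweep, displacement recovery is bounded by the intrinsic
  # pixel-phase quantization of the thresholded center of mass (< 0.38 px;
  # the hard two-thirds cut on a 1 px grid cannot do better in general)
  for (f in seq(5e5, 2e6, length.out = 6)) {
    fp <- simulate_frame_pair(parts$bead, parts$medium, parts$field, f, img0)
    locs <- lapply(1:2, function(j) {
      locate_band(background_subtract(extract_profile(fp, j)))
    })
    measured <- locs[[2]]$x_cm_um - locs[[1]]$x_cm_um
    truth <- diff(fp$metadata$ground_truth_x_um)
    expect_lt(abs(measured - truth) / px, 0.38)
  }
})

test_that("render_frames validates timestamps and frame bounds", {
  parts <- default_parts()
  img <- small_imaging()
  traj <- simulate_band_trajectory(parts$bead, parts$medium, parts$field, 5e5)
  expect_error(render_frames(traj, img, c(0, 80)), "span")
  # a band pushed beyond the frame edge is refused
  tiny <- imaging_config(frame_width = 60L, frame_height = 20L,
                         electrode_extent = 40L, seed = 1)
  big <- electrode_field_model(grad_e2_at_edge = 5e18)
  far <- simulate_band_trajectory(parts$bead, parts$medium, big, 2e6)
  expect_error(render_frames(far, tiny, c(0, 40)), "outside")
})

test_that("run_protocol writes the full labeled dataset with ground truth", {
  parts <- default_parts()
  out <- withr::local_tempdir()
  proto <- protocol_config(n_steps = 2, n_replicates = 1)
  beads <- nucleotide_bead_table("last")["A"]
  manifest <- run_protocol(proto, beads, parts$medium, parts$field,
                           small_imaging(), out)
  expect_equal(nrow(manifest), 2)  # 1 label x 2 steps x 1 replicate
  proto <- protocol_config(n_steps = 3, n_replicates = 2)
  beads <- nucleotide_bead_table("last")[c("A", "T")]
  manifest <- run_protocol(proto, beads, parts$medium, parts$field,
                           small_imaging(), out)
  expect_equal(nrow(manifest), 2 * 3 * 2)
  expect_true(all(file.exists(file.path(out, manifest$file))))
  expect_true(all(file.exists(file.path(out, manifest$sidecar))))
  expect_true(file.exists(file.path(out, "config.json")))
  # replicate seeds differ, trajectories (ground truth) shared
  a5 <- manifest[manifest$label == "A" &
                   manifest$frequency_hz == 5e5, ]
  expect_equal(length(unique(a5$seed)), 2)
  expect_equal(a5$gt_displacement_um[1], a5$gt_displacement_um[2])
  # default replication depth is six per frequency
  expect_equal(protocol_config()$n_replicates, 6L)
  # stronger-repulsion label displaces further at every frequency
  for (f in unique(manifest$frequency_hz)) {
    d <- manifest[manifest$frequency_hz == f & manifest$replicate == 1, ]
    expect_gt(d$gt_displacement_um[d$label == "A"],
              d$gt_displacement_um[d$label == "T"])
  }
})

test_that("frame sequences survive the TIFF + sidecar round trip", {
  parts <- default_parts()
  out <- withr::local_tempdir()
  fp <- simulate_frame_pair(parts$bead, parts$medium, parts$field, 1e6,
                            small_imaging(seed = 9))
  path <- file.path(out, "pair.tif")
  write_frame_sequence(fp, path)
  back <- read_frame_sequence(path)
  # 16-bit storage quantizes to ~0.004 counts on the 255-count scale
  expect_lt(max(abs(back$frames[[2]] - fp$frames[[2]])), 0.005)
  expect_equal(back$timestamps_ms, fp$timestamps_ms)
  expect_equal(back$metadata$ground_truth_x_um,
               fp$metadata$ground_truth_x_um)
  expect_equal(back$roi, fp$roi)
  expect_error(read_frame_sequence(file.path(out, "absent.tif")),
               "not found")
  file.remove(sub("\\.tif$", ".json", path))
  expect_error(read_frame_sequence(path), "sidecar")
})
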