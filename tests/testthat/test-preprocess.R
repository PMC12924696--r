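## independent oracle: squared magnitude of an analog Butterworth bandpass
## (one forward-backward pass), evaluated directly from the definition
butter2_oracle <- function(f, lo, hi, ord) {
  x <- (f^2 - lo * hi) / (f * (hi - lo))
  1 / (1 + x^(2 * ord))
}

sine_rec <- function(f, rate = 1000, dur = 36, channel = "Oz") {
  t <- (0:(rate * dur - 1)) / rate
  fpvs_recording(matrix(cos(2 * pi * f * t), 1,
                        dimnames = list(channel, NULL)), rate, channel)
}

peak_amp <- function(x) max(Mod(fft(x)) / length(x) * 2)

test_that("bandpass filter matches the Butterworth magnitude response", {
  ## DC is removed
  dc <- fpvs_recording(matrix(5, 1, 36000, dimnames = list("Oz", NULL)),
                       1000, "Oz")
  out <- bandpass_filter(dc)
  expect_lt(max(abs(out$data[1, 2000:34000])), 5e-3)
  ## mid-band and stop-band amplitudes against the oracle
  for (f in c(6, 40, 150)) {
    fr <- bandpass_filter(sine_rec(f))
    a <- peak_amp(fr$data[1, 5001:29000])
    expect_equal(a, butter2_oracle(f, 0.1, 100, 4), tolerance = 0.01)
  }
  fr6 <- bandpass_filter(sine_rec(6))
  expect_equal(peak_amp(fr6$data[1, 5001:29000]), 1, tolerance = 0.01)
  fr150 <- bandpass_filter(sine_rec(150))
  expect_lt(peak_amp(fr150$data[1, 5001:29000]), 0.3)
  expect_error(bandpass_filter(sine_rec(6), low_hz = 0.1, high_hz = 600),
               "band edges")
})

test_that("resampling preserves in-band content and suppresses out-of-band", {
  rec <- sine_rec(6)
  rs <- resample_recording(rec, 200)
  expect_equal(ncol(rs$data), 7200)
  expect_equal(rs$rate_hz, 200)
  expect_equal(peak_amp(rs$data[1, ]), 1, tolerance = 0.01)
  ## 99 Hz below the new Nyquist is retained, 150 Hz suppressed
  expect_gt(peak_amp(resample_recording(sine_rec(99), 200)$data[1, ]), 0.9)
  expect_lt(peak_amp(resample_recording(sine_rec(150), 200)$data[1, ]), 0.05)
  expect_error(resample_recording(rs, 400), "upsampling")
})

test_that("cropping yields one segment per event and drops overruns", {
  data <- matrix(rnorm(2 * 200 * 120), 2,
                 dimnames = list(c("Oz", "POz"), NULL))
  rec <- fpvs_recording(data, 200, c("Oz", "POz"),
                        events = data.frame(time_s = c(1, 40, 119),
                                            label = c("a", "b", "a")))
  expect_warning(segs <- crop_segments(rec, 36), "dropped")
  expect_length(segs, 2)
  expect_equal(ncol(segs[[1]]$data), 7200)
  expect_equal(segs[[2]]$condition_label, "b")
  expect_equal(segs[[1]]$data[, 1], data[, 201])
})

test_that("blink components are removed without harming posterior signal", {
  mon <- posterior_montage()
  sched <- build_sequence_schedule()
  comp <- list(steady_state_component(6, c(2, 1), topo_gaussian(mon, "Oz")))
  clean <- simulate_recording(sched, comp, noise_model(noise_scale = 3),
                              mon, 200, seed = 21)
  blinky <- simulate_recording(sched, comp,
                               noise_model(noise_scale = 3, blink_rate = 9,
                                           blink_amplitude = 400),
                               mon, 200, seed = 21)
  seg <- crop_segments(blinky$recording, 36)[[1]]
  res <- remove_blink_components(seg)
  expect_gte(res$report$n_removed, 1)
  expect_lte(res$report$n_removed, 5)
  frontal <- grepl("^(Fp|F)", rownames(seg$data))
  expect_lt(max(abs(res$segment$data[frontal, ])), 200)
  clean_seg <- crop_segments(clean$recording, 36)[[1]]
  for (ch in c("Oz", "O1", "PO8"))
    expect_gt(cor(res$segment$data[ch, ], clean_seg$data[ch, ]), 0.95)
})

test_that("blink-free segments pass through almost unchanged", {
  mon <- posterior_montage()
  sched <- build_sequence_schedule()
  comp <- list(steady_state_component(6, c(2, 1), topo_gaussian(mon, "Oz")))
  sim <- simulate_recording(sched, comp, noise_model(noise_scale = 3),
                            mon, 200, seed = 22)
  seg <- crop_segments(sim$recording, 36)[[1]]
  res <- remove_blink_components(seg)
  expect_equal(res$report$n_removed, 0)
  expect_gt(cor(as.vector(res$segment$data), as.vector(seg$data)), 0.999)
})

test_that("artifact blocking suppresses large events and leaves clean data", {
  mon <- posterior_montage()
  sched <- build_sequence_schedule()
  comp <- list(steady_state_component(6, c(2, 1), topo_gaussian(mon, "Oz")))
  sim <- simulate_recording(sched, comp, noise_model(noise_scale = 5),
                            mon, 200, seed = 31)
  seg <- crop_segments(sim$recording, 36)[[1]]
  ## clean segment passes through identically
  res0 <- artifact_block(seg)
  expect_identical(res0$segment$data, seg$data)
  expect_false(res0$report$unusable)
  ## inject a 0.5-s 800-uV artifact on one channel
  bad <- seg
  idx <- 2000:2099
  truth <- seg$data["P8", idx]
  bad$data["P8", idx] <- bad$data["P8", idx] + 800
  res <- artifact_block(bad)
  expect_lte(max(abs(res$segment$data)), 500)
  ## unmarked samples unchanged within 1 uV
  untouched <- res$segment$data[, -idx]
  expect_lt(max(abs(untouched - seg$data[, -idx])), 1)
  for (ch in c("Oz", "O1"))
    expect_gt(cor(res$segment$data[ch, ], seg$data[ch, ]), 0.95)
})

test_that("artifact blocking flags hopeless segments and zeros pass through", {
  z <- fpvs_segment(matrix(0, 3, 400,
                           dimnames = list(c("Oz", "O1", "O2"), NULL)), 200)
  res <- artifact_block(z)
  expect_identical(res$segment$data, z$data)
  big <- fpvs_segment(matrix(900, 3, 400,
                             dimnames = list(c("Oz", "O1", "O2"), NULL)), 200)
  res2 <- artifact_block(big)
  expect_true(res2$report$unusable)
})

test_that("channel interpolation recovers equidistant-neighbor means", {
  mon <- fpvs_montage(channels = c("Cz", "C1", "C2", "FCz", "CPz", "Oz"))
  d <- matrix(rnorm(6 * 100), 6,
              dimnames = list(mon$channel_names, NULL))
  ## Cz's 4 nearest neighbors (C1, C2, FCz, CPz) are equidistant by symmetry
  d["Cz", ] <- colMeans(d[c("C1", "C2", "FCz", "CPz"), ])
  seg <- fpvs_segment(d, 200)
  corrupted <- seg
  corrupted$data["Cz", ] <- 999
  fixed <- interpolate_channels(corrupted, "Cz", mon)
  expect_equal(fixed$data["Cz", ], d["Cz", ], tolerance = 1e-9)
  expect_identical(fixed$data["Oz", ], d["Oz", ])
  ## identity when no bad channels; error when too few good ones
  expect_identical(interpolate_channels(seg, character(0), mon), seg)
  expect_error(interpolate_channels(seg, mon$channel_names[1:4], mon),
               "good channels")
})

test_that("spatially smooth fields interpolate accurately", {
  mon <- fpvs_montage("adult_55")  # dense montage, symmetric neighbors
  ## linear potential field over the scalp
  field <- mon$positions %*% c(1.5, -0.8, 2)
  d <- field %*% t(rep(1, 50)) + 0
  rownames(d) <- mon$channel_names
  seg <- fpvs_segment(d, 200)
  seg$data["Pz", ] <- 0
  fixed <- interpolate_channels(seg, "Pz", mon)
  err <- sqrt(mean((fixed$data["Pz", ] - field[match("Pz", mon$channel_names)])^2))
  expect_lt(err / abs(field[match("Pz", mon$channel_names)]), 0.05)
})

test_that("symmetric average reference zeroes the reference set", {
  mon <- posterior_montage()
  d <- matrix(rnorm(length(mon$channel_names) * 60), length(mon$channel_names),
              dimnames = list(mon$channel_names, NULL))
  seg <- fpvs_segment(d, 200)
  ref <- rereference_symmetric_average(seg, mon)
  ref_chs <- intersect(
    c(mon$mirror_pairs$left, mon$mirror_pairs$right, mon$midline),
    rownames(d))
  expect_equal(colMeans(ref$data[ref_chs, ]), rep(0, 60), tolerance = 1e-12)
  ## idempotent
  ref2 <- rereference_symmetric_average(ref, mon)
  expect_equal(ref2$data, ref$data, tolerance = 1e-12)
  ## mirror-symmetric input stays mirror-symmetric
  sym <- d
  for (i in seq_len(nrow(mon$mirror_pairs)))
    sym[mon$mirror_pairs$right[i], ] <- sym[mon$mirror_pairs$left[i], ]
  rsym <- rereference_symmetric_average(fpvs_segment(sym, 200), mon)
  for (i in seq_len(nrow(mon$mirror_pairs)))
    expect_equal(rsym$data[mon$mirror_pairs$right[i], ],
                 rsym$data[mon$mirror_pairs$left[i], ], tolerance = 1e-12)
})

test_that("preprocessing operators preserve shape", {
  mon <- posterior_montage()
  d <- matrix(rnorm(length(mon$channel_names) * 7200),
              length(mon$channel_names),
              dimnames = list(mon$channel_names, NULL))
  seg <- fpvs_segment(d, 200)
  expect_equal(dim(bandpass_filter(seg, 0.1, 90)$data), dim(d))
  expect_equal(dim(remove_blink_components(seg)$segment$data), dim(d))
  expect_equal(dim(artifact_block(seg)$segment$data), dim(d))
  expect_equal(dim(rereference_symmetric_average(seg, mon)$data), dim(d))
})
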