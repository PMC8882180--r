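test_that("intensity to optical density matches its definition", {
  # constant intensity -> OD identically zero
  I <- matrix(5, 50, 3)
  expect_equal(intensity_to_od(I), matrix(0, 50, 3))

  # inverse construction: I = Ibar * exp(-x) recovers x
  set.seed(1)
  x <- matrix(rnorm(100, 0, 0.1), 50, 2)
  x <- sweep(x, 2, log(colMeans(exp(-x))), "+")  # make exp(-x) mean-1
  I <- exp(-x) * 3
  expect_equal(intensity_to_od(I), x, tolerance = 1e-12)

  # brute-force per-sample oracle
  set.seed(2)
  I <- matrix(runif(200, 0.5, 2), 100, 2)
  od <- intensity_to_od(I)
  oracle <- I
  for (j in 1:2) for (t in 1:100)
    oracle[t, j] <- -log(I[t, j] / mean(I[, j]))
  expect_equal(od, oracle, tolerance = 1e-12)

  Ibad <- I; Ibad[7, 2] <- 0
  expect_error(intensity_to_od(Ibad), "sample 7, channel 2")
})

test_that("MBLL inversion recovers known concentrations and is linear", {
  params <- mbll_params()
  z <- matrix(0, 10, 4)
  out0 <- od_to_hemoglobin(list(z, z), params)
  expect_equal(out0$hbo, z)
  expect_equal(out0$hbr, z)

  set.seed(3)
  hbo <- matrix(rnorm(80, 0, 0.5), 20, 4)
  hbr <- matrix(rnorm(80, 0, 0.2), 20, 4)
  od <- hemoglobin_to_od(hbo, hbr, params)
  rec <- od_to_hemoglobin(od, params)
  expect_equal(rec$hbo, hbo, tolerance = 1e-10)
  expect_equal(rec$hbr, hbr, tolerance = 1e-10)

  # linearity: doubling OD doubles concentrations
  twice <- od_to_hemoglobin(lapply(od, function(m) 2 * m), params)
  expect_equal(twice$hbo, 2 * rec$hbo, tolerance = 1e-10)

  # additivity on random matrices
  odB <- hemoglobin_to_od(hbr, hbo, params)
  sum_of <- od_to_hemoglobin(Map(`+`, od, odB), params)
  each <- Map(`+`, rec, od_to_hemoglobin(odB, params))
  expect_equal(sum_of$hbo, each$hbo, tolerance = 1e-10)

  expect_error(mbll_params(extinction = matrix(1, 2, 2)), "singular")
})

test_that("band-pass attenuates cardiac band and passes task band", {
  fs <- 7.81
  t <- (0:2810) / fs
  rms <- function(x) sqrt(mean(x^2))
  hi <- sin(2 * pi * 1.1 * t)
  lo <- sin(2 * pi * 0.05 * t)
  expect_lt(rms(bandpass_and_detrend(hi, fs)) / rms(hi), 0.05)
  expect_gt(rms(bandpass_and_detrend(lo, fs)) / rms(lo), 0.9)
  expect_lt(max(abs(bandpass_and_detrend(rep(3, 500), fs))), 1e-9)
  expect_error(bandpass_and_detrend(lo, fs, 0.5, 0.1), "low_hz")
})

test_that("epoching and block averaging follow the event structure", {
  fs <- 7.81
  spec <- quiet_spec()
  sc <- synth_scan_timeseries(0.7, spec)
  layout <- build_probe_layout()
  tcs <- epoch_and_block_average(sc, layout)
  expect_equal(length(tcs$MPFC$hbo), round(40 * fs) + 1)
  # final 2-back block (onset 330 s) lacks a full window and is dropped
  expect_equal(tcs$MPFC$n_blocks_averaged, 5L)
  expect_equal(tcs$MPFC$n_blocks_dropped, 1L)

  # identical response every block: average equals a single epoch
  ev <- sc$events[sc$events$condition == "2-back", ]
  o <- ev$onset_sample[2]
  rel <- 0:round(40 * fs)
  base <- mean(sc$series$hbo[o + ceiling(-2 * fs):(-1), 1])
  single <- sc$series$hbo[o + rel, 1] - base
  expect_equal(tcs$MPFC$hbo, single, tolerance = 0.02)

  # ROI whose channels all equal the same series reproduces that series
  expect_equal(tcs$MPFC$hbo, tcs$LVLPFC$hbo)
})

test_that("block average equals the hand-computed elementwise mean", {
  fs <- 10
  n <- 1000
  set.seed(8)
  base_sig <- rnorm(n)
  m <- matrix(base_sig, n, 20)
  ev <- data.frame(onset_sample = c(101L, 301L, 501L),
                   condition = "2-back", duration_s = 30)
  sc <- new_scan("p", "THC", 2, fs, "hemoglobin",
                 list(hbo = m, hbr = m), ev)
  tcs <- epoch_and_block_average(sc, build_probe_layout())
  rel <- 0:400
  brel <- -20:-1
  eps <- sapply(ev$onset_sample, function(o)
    base_sig[o + rel] - mean(base_sig[o + brel]))
  expect_equal(tcs$MPFC$hbo, rowMeans(eps), tolerance = 1e-12)
})

test_that("noise-free pipeline recovers the simulated response amplitude", {
  spec <- quiet_spec()
  for (beta in c(0.2, 0.5)) {
    sc <- synth_scan_timeseries(beta, spec)
    tcs <- epoch_and_block_average(sc)
    expect_equal(max(tcs$MPFC$hbo), beta, tolerance = 0.01 * beta)
  }
})

test_that("raw-intensity scans run through the full conversion chain", {
  spec <- quiet_spec(scan_duration_s = 75, n_blocks = 2)
  sc <- synth_scan_timeseries(0.5, spec)
  params <- mbll_params()
  od <- hemoglobin_to_od(sc$series$hbo, sc$series$hbr, params)
  # synthesize intensities around baseline 1 that produce these ODs
  raw <- lapply(od, function(m) {
    I <- exp(-m)
    sweep(I, 2, colMeans(I), "/")
  })
  raw_scan <- new_scan("p", "THC", 2, spec$fs, "raw_intensity",
                       raw, sc$events)
  tcs <- preprocess_scan(raw_scan, params = params)
  ref <- preprocess_scan(sc)
  expect_equal(tcs$MPFC$hbo, ref$MPFC$hbo, tolerance = 1e-6)
})
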