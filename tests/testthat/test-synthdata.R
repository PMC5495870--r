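# Fast configs: simulate directly at the analysis rate unless a test needs
# the decimation path.
fast_cfg <- function(...) {
  sim_config(fs_raw = 100, fs_out = 100, ...)
}

test_that("simulation is deterministic under a fixed seed", {
  cfg <- fast_cfg(n_subjects = 2, n_trials = 2, seed = 11)
  expect_identical(simulate_dataset(cfg)$data, simulate_dataset(cfg)$data)
})

test_that("different seeds give different data", {
  a <- simulate_dataset(fast_cfg(n_subjects = 1, n_trials = 1, seed = 1))
  b <- simulate_dataset(fast_cfg(n_subjects = 1, n_trials = 1, seed = 2))
  expect_false(identical(a$data, b$data))
})

test_that("pure-noise configuration yields unit-SD white channels", {
  cfg <- fast_cfg(n_subjects = 37, n_trials = 10, couplings = list(),
                  oscillators = list(), sway = NULL,
                  onset_impulse_amplitude = 0, alpha_drop = NULL,
                  noise_sd = 1, eog = NULL, seed = 4)
  rec <- simulate_dataset(cfg)
  sds <- apply(rec$data, 3, sd)
  expect_true(all(abs(sds - 1) < 0.05))
})

test_that("planted coupling raises the lagged cross-correlation after onset", {
  cfg <- fast_cfg(n_subjects = 1, n_trials = 10, oscillators = list(),
                  sway = NULL, onset_impulse_amplitude = 0, alpha_drop = NULL,
                  eog = NULL, seed = 21)
  rec <- simulate_dataset(cfg)
  si <- match("CPz", rec$channel_names); ti <- match("Cz", rec$channel_names)
  on <- rec$onset_sample; lag <- 2
  xc <- function(idx) {
    num <- den <- 0
    for (r in 1:10) {
      x <- rec$data[1, r, si, idx - lag]; y <- rec$data[1, r, ti, idx]
      num <- num + cor(x, y)
    }
    num / 10
  }
  n <- dim(rec$data)[4]
  pre <- (lag + 1):(on - 1)
  post <- (on + 20):n
  expect_gt(xc(post), xc(pre) + 0.1)
})

test_that("an unstable coupling configuration is rejected with a diagnostic", {
  cfg <- fast_cfg(n_subjects = 1, n_trials = 1,
                  couplings = list(coupling("CPz", "Cz", gain_post = 5),
                                   coupling("Cz", "CPz", gain_post = 5)))
  expect_error(simulate_dataset(cfg), "unstable AR system.*post")
})

test_that("oscillators concentrate power at their centre frequency at the stated amplitude", {
  cfg <- fast_cfg(n_subjects = 1, n_trials = 8, couplings = list(),
                  oscillators = list(oscillator("Oz", freq = 10,
                                                amplitude = 10)),
                  sway = NULL, onset_impulse_amplitude = 0, alpha_drop = NULL,
                  noise_sd = 0.1, eog = NULL, seed = 8)
  rec <- simulate_dataset(cfg)
  ci <- match("Oz", rec$channel_names)
  x <- rec$data[1, 1, ci, ]
  sp <- spec.pgram(ts(x, frequency = 100), plot = FALSE, taper = 0,
                   spans = c(5, 5))
  expect_lt(abs(sp$freq[which.max(sp$spec)] - 10), 1)
  rmss <- sapply(1:8, function(r) sqrt(mean(rec$data[1, r, ci, ]^2)))
  expect_lt(abs(mean(rmss) - 10 / sqrt(2)), 1)
})

test_that("oscillators are independent across channels (no planted cross-correlation)", {
  cfg <- fast_cfg(n_subjects = 1, n_trials = 10, couplings = list(),
                  oscillators = list(oscillator(c("O1", "Oz"), freq = 10,
                                                amplitude = 10)),
                  sway = NULL, onset_impulse_amplitude = 0, alpha_drop = NULL,
                  noise_sd = 0.1, eog = NULL, seed = 9)
  rec <- simulate_dataset(cfg)
  i1 <- match("O1", rec$channel_names); i2 <- match("Oz", rec$channel_names)
  cc <- sapply(1:10, function(r) cor(rec$data[1, r, i1, ], rec$data[1, r, i2, ]))
  expect_lt(mean(abs(cc)), 0.35)
})

test_that("phase-locked sway is identical across trials and absent before onset", {
  cfg <- fast_cfg(n_subjects = 1, n_trials = 3, couplings = list(),
                  oscillators = list(), sway = sway_spec(phase_locked = TRUE),
                  onset_impulse_amplitude = 0, alpha_drop = NULL,
                  noise_sd = 1e-8, eog = NULL, seed = 3)
  rec <- simulate_dataset(cfg)
  on <- rec$onset_sample
  post <- rec$data[1, , 1, (on + 25):dim(rec$data)[4]]
  expect_lt(max(abs(post[1, ] - post[2, ])), 1e-6)
  expect_lt(max(abs(rec$data[1, 1, 1, 1:(on - 1)])), 1e-6)
  expect_gt(sd(post[1, ]), 1)
})

test_that("sway carries a posterior-dominant topography", {
  g <- balancenet:::sway_gains(sway_spec(), channels_subset())
  names(g) <- channels_subset()
  expect_gt(g[["Oz"]], g[["Cz"]])
  expect_gt(diff(range(g)), 0.2)
})

test_that("alpha oscillation amplitude drops transiently after onset", {
  cfg <- fast_cfg(n_subjects = 1, n_trials = 6, couplings = list(),
                  oscillators = list(oscillator("Oz", freq = 10,
                                                amplitude = 10)),
                  sway = NULL, onset_impulse_amplitude = 0,
                  alpha_drop = c(0.6, 1), noise_sd = 0.1, eog = NULL,
                  seed = 12)
  rec <- simulate_dataset(cfg)
  ci <- match("Oz", rec$channel_names)
  tt <- rec_times(rec)
  rms_in <- function(lo, hi) {
    idx <- which(tt >= lo & tt < hi)
    mean(sapply(1:6, function(r) sqrt(mean(rec$data[1, r, ci, idx]^2))))
  }
  during <- rms_in(3.1, 3.9)
  after <- rms_in(5, 8)
  expect_lt(during / after, 0.65)   # nominal depth 0.6 -> ratio 0.4
})

test_that("onset impulse appears at the onset sample with the stated scale", {
  cfg <- fast_cfg(n_subjects = 1, n_trials = 1, couplings = list(),
                  oscillators = list(), sway = NULL,
                  onset_impulse_amplitude = 20, alpha_drop = NULL,
                  noise_sd = 1e-8, eog = NULL, seed = 5)
  rec <- simulate_dataset(cfg)
  x <- rec$data[1, 1, 1, ]
  peak_at <- which.max(abs(x))
  expect_true(peak_at >= rec$onset_sample &&
              peak_at <= rec$onset_sample + round(0.2 * rec$fs))
  expect_gt(max(abs(x)), 10)
  expect_lt(max(abs(x)), 21)
})

test_that("blinks ride on the EOG channel and propagate to scalp channels", {
  cfg <- fast_cfg(n_subjects = 1, n_trials = 10, couplings = list(),
                  oscillators = list(), sway = NULL,
                  onset_impulse_amplitude = 0, alpha_drop = NULL,
                  noise_sd = 0.5,
                  eog = eog_spec(blink_rate = 1, amplitude = 100,
                                 propagation = 0.2),
                  seed = 31)
  rec <- simulate_dataset(cfg)
  expect_identical(rec$eog_channel, "EOG")
  ei <- match("EOG", rec$channel_names)
  expect_gt(max(abs(rec$data[1, , ei, ])), 50)
  cc <- sapply(1:10, function(r)
    cor(rec$data[1, r, 1, ], rec$data[1, r, ei, ]))
  expect_gt(mean(cc), 0.5)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(fs_raw = 1000, fs_out = 300), "divisible")
  expect_error(sim_config(onset_time = 9), "inside the epoch")
  expect_error(sim_config(couplings = list(coupling("XX", "Cz"))),
               "unknown channel")
  expect_error(sim_config(oscillators = list(oscillator("XX", 10, 1))),
               "unknown channel")
})

test_that("platform trace marks the release and separates baseline from sway variance", {
  tr <- simulate_platform(fs = 1000, duration = 30, release_time = 10, seed = 2)
  expect_identical(tr$true_release_sample, 10000L)
  ratios <- sapply(1:20, function(s) {
    tr <- simulate_platform(fs = 200, duration = 30, release_time = 12, seed = s)
    base <- tr$displacement[1, 1:(tr$true_release_sample - 1)]
    post <- tr$displacement[1, (tr$true_release_sample + 1):(14 * 200)]
    var(base) / var(post)
  })
  expect_true(all(ratios < 1 / 25))
  expect_error(simulate_platform(duration = 10, release_time = 12),
               "inside the trace")
})
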