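test_that("zero weights never fire and empty networks are rejected", {
  net <- wta_network(3, seed = 1)
  net$weights[] <- 0
  pat <- spread_pattern()
  for (i in 1:50) {
    st <- run_frame(net, pat)
    net <- st$net
    expect_true(is.na(st$result$fired_neuron))
  }
  expect_error(wta_network(0), "neuron")
  expect_error(run_frame(net, c(1, 0)), "frame length")
})

test_that("integration to threshold follows the closed-form frame count", {
  for (theta in c(1000, 2500, 5000)) {
    net <- wta_network(1, theta0 = theta, d_theta = 1, theta_max = 1e6,
                       seed = 1)
    net$weights[] <- 255
    pat <- spread_pattern()
    k <- 0L
    repeat {
      k <- k + 1L
      st <- run_frame(net, pat); net <- st$net
      if (!is.na(st$result$fired_neuron)) break
    }
    expect_identical(k, as.integer(ceiling((theta + 1) / (4 * 255))))
  }
})

test_that("a fire resets every integrator and bumps only the winner's threshold", {
  net <- wta_network(4, theta0 = 100, d_theta = 10, seed = 2)
  pat <- spread_pattern()
  st <- run_frame(net, pat)
  expect_false(is.na(st$result$fired_neuron))
  expect_true(all(st$net$integrator == 0))
  w <- st$result$fired_neuron
  expect_identical(st$net$fire_threshold[w], 110)
  expect_identical(st$net$fire_threshold[-w], rep(100, 3))
})

test_that("falling-edge plasticity moves 4 weights up and 12 down, clipped", {
  row <- rep(128, 16)
  pat <- spread_pattern()
  upd <- apply_plasticity(row, pat, d_ltp = 16, d_ltd = 4)
  expect_identical(sum(upd - row == 16), 4L)
  expect_identical(sum(upd - row == -4), 12L)
  expect_identical(apply_plasticity(250, 1, 16, 4), 255)   # ceiling clip
  expect_identical(apply_plasticity(0, 0, 16, 4), 0)       # floor
})

test_that("synaptic counters stay within 0..255 under random fuzz", {
  set.seed(99)
  net <- wta_network(5, theta0 = 300, d_theta = 3, seed = 3)
  for (i in 1:5000) {
    frame <- as.integer(runif(16) < 0.3)
    st <- run_frame(net, frame,
                    kind = if (i %% 2) "pattern" else "noise")
    net <- st$net
    expect_true(all(net$weights >= 0 & net$weights <= 255))
  }
  expect_true(all(net$fire_threshold >= net$theta0))
})

test_that("fire thresholds are non-decreasing and saturate at the ceiling", {
  net <- wta_network(2, theta0 = 100, d_theta = 50, theta_max = 260,
                     seed = 4)
  pat <- spread_pattern()
  prev <- net$fire_threshold
  for (i in 1:200) {
    st <- run_frame(net, pat); net <- st$net
    expect_true(all(net$fire_threshold >= prev))
    prev <- net$fire_threshold
  }
  expect_true(all(net$fire_threshold <= 260))
})

test_that("the session schedule alternates pattern and noise 50/50", {
  net <- wta_network(2, seed = 5)
  ses <- run_session(net, list(spread_pattern()), lfsr_new(1),
                     n_frames = 10)
  expect_identical(sum(ses$trace$kind == "pattern"), 5L)
  expect_identical(sum(ses$trace$kind == "noise"), 5L)

  # all-none stream: only noise frames are actually presented
  ses2 <- run_session(wta_network(2, seed = 5), list(NULL), lfsr_new(1),
                      n_frames = 40)
  pat_rows <- ses2$trace$kind == "pattern"
  expect_true(all(is.na(ses2$trace$fired[pat_rows])))
  expect_error(run_session(net, list(NULL), lfsr_new(1), 0), ">= 1")
})

test_that("session replay under the same seeds is bitwise identical", {
  pats <- list(spread_pattern(), as.integer(rev(spread_pattern())))
  run <- function() {
    run_session(wta_network(4, seed = 7), pats, lfsr_new(9),
                n_frames = 400, record_weights = TRUE,
                snapshot_every = 50)
  }
  a <- run(); b <- run()
  expect_identical(a$trace, b$trace)
  expect_identical(a$net, b$net)
  expect_identical(a$snapshots, b$snapshots)
})

test_that("the synaptic window measures pattern/background separation", {
  pat <- spread_pattern()
  expect_identical(synaptic_window(rep(100, 16), pat), 0)
  w <- ifelse(pat == 1, 255, 0)
  expect_identical(synaptic_window(w, pat), 255)
  expect_error(synaptic_window(rep(1, 16), rep(1L, 16)), "ON and OFF")
  expect_error(synaptic_window(rep(1, 16), rep(0L, 16)), "ON and OFF")
})

test_that("training one pattern against noise opens the synaptic window", {
  pat <- spread_pattern()
  net <- wta_network(3, seed = 2)
  ses <- run_session(net, list(pat), lfsr_new(7), n_frames = 2000)
  best <- max(apply(coef(ses$net), 1, synaptic_window, pattern = pat))
  expect_gt(best, 128)
})

test_that("weight traces export one row per neuron per snapshot", {
  ses <- run_session(wta_network(2, seed = 1), list(spread_pattern()),
                     lfsr_new(2), n_frames = 100, record_weights = TRUE,
                     snapshot_every = 50)
  tr <- weight_trace(ses)
  expect_identical(nrow(tr), 2L * length(ses$snapshots))
  expect_identical(ncol(tr), 18L)
  f <- tempfile(fileext = ".csv")
  weight_trace(ses, f)
  expect_identical(nrow(utils::read.csv(f)), nrow(tr))
})
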