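make_series <- function(t, vm, ca) data.frame(t_ms = t, Vm_mV = vm, Cai_mM = ca)

test_that("a flat trace yields zero deltas and no event", {
  t <- 0:1200
  s <- make_series(t, rep(-84, length(t)), rep(7e-5, length(t)))
  e <- detect_events(s, rest_start = 0)
  expect_equal(e$delta_Vm, 0)
  expect_equal(e$delta_Ca, 0)
  expect_false(e$triggered)
  expect_equal(e$n_waves, 0)
})

test_that("a synthetic bump is measured at its amplitude and peak time", {
  t <- 0:1500
  vm <- -84 + 8 * exp(-(t - 350)^2 / (2 * 60^2))
  ca <- 7e-5 + 5e-5 * exp(-(t - 330)^2 / (2 * 50^2))
  e <- detect_events(make_series(t, vm, ca), rest_start = 0)
  expect_equal(e$delta_Vm, 8, tolerance = 0.02)
  expect_equal(e$T_peakVm, 350, tolerance = 0.02)
  expect_equal(e$delta_Ca, 5e-5, tolerance = 0.02)
  expect_equal(e$T_peakCa, 330, tolerance = 0.05)
  expect_false(e$triggered)  # 8 mV bump never nears the AP threshold
})

test_that("a fast suprathreshold upstroke is classified as triggered", {
  t <- 0:1000
  vm <- rep(-84, length(t))
  up <- t >= 600 & t <= 900
  vm[up] <- -84 + 104 * exp(-(t[up] - 650)^2 / (2 * 80^2))
  vm[t >= 600 & t <= 650] <- seq(-84, 20, length.out = 51)  # ~2 mV/ms mean,
  vm[t %in% 620:621] <- c(-60, 40)                          # 100 mV/ms jump
  e <- detect_events(make_series(t, vm, 7e-5 + 0 * t), rest_start = 0)
  expect_true(e$triggered)
})

test_that("the rest baseline is re-established after the last paced beat", {
  t <- 0:2000
  vm <- rep(-84, length(t))
  # paced AP: 0-300 ms plateau near 0 mV, repolarising to rest by ~400 ms
  vm[t <= 300] <- 0
  vm[t > 300 & t <= 420] <- seq(0, -84, length.out = 120)
  vm <- vm + 6 * exp(-(t - 1000)^2 / (2 * 50^2))  # DAD at 1000 ms
  e <- detect_events(make_series(t, vm, 7e-5 + 0 * t), rest_start = 300)
  expect_gt(e$t_rest_start, 300)
  expect_lt(e$t_rest_start, 450)
  expect_equal(e$delta_Vm, 6, tolerance = 0.05)
  expect_equal(e$T_peakVm + e$t_rest_start, 1000, tolerance = 0.01)
})

test_that("a window too short for a baseline is rejected", {
  t <- 0:120
  s <- make_series(t, rep(-84, length(t)), rep(7e-5, length(t)))
  expect_error(detect_events(s, rest_start = 0), "too short")
  expect_error(detect_events(s[, 1:2], rest_start = NULL), "rest_start")
})

test_that("ensemble statistics reproduce textbook mean, SEM and ANOVA", {
  df <- data.frame(
    n_rogue = rep(c(0, 1), each = 3),
    rep = rep(1:3, 2),
    delta_Ca = c(1, 2, 3, 1, 2, 3),
    delta_Vm = c(1, 2, 3, 10, 10, 10),
    T_peakCa = c(5, 5, 5, 4, 4, 4),
    T_peakVm = c(5, 5, 5, 5, 5, 5),
    triggered = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE)
  )
  st <- summarize_ensemble(df)
  m <- st$stats[st$stats$metric == "delta_Ca" & st$stats$n_rogue == 0, ]
  expect_equal(m$mean, 2)
  expect_equal(m$sem, 1 / sqrt(3))  # sd({1,2,3}) = 1
  expect_equal(m$n, 3L)
  # identical groups: F ~ 0, P ~ 1
  a_ca <- st$anova[st$anova$metric == "delta_Ca", ]
  expect_lt(a_ca$F, 1e-10)
  expect_gt(a_ca$P, 0.99)
  # fully separated groups: significant
  a_vm <- st$anova[st$anova$metric == "delta_Vm", ]
  expect_lt(a_vm$P, 0.05)
  expect_equal(st$triggered$fraction, c(0, 2 / 3))
  # undersized group is dropped with a warning
  expect_warning(st2 <- summarize_ensemble(df[-(4:5), ]), "dropped")
  expect_equal(unique(st2$stats$n_rogue), 0)
})

tiny_cfg <- function(...) {
  # reference (unloaded) store so the sheet stays quiescent
  scenario_config("heart_failure", pacing_n = 0, rest_ms = 300,
                  init_casr = 1.3,
                  grid = list(Lx = 20, Ly = 10, h = 0.5, dt = 0.02), ...)
}

test_that("runs are reproducible and the linescan has the contracted shape", {
  cfg <- tiny_cfg(n_rogue = 0.5)
  r1 <- run_protocol(cfg, seed = 21)
  r2 <- run_protocol(cfg, seed = 21)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$series, r2$series)
  r3 <- run_protocol(cfg, seed = 22)
  expect_false(identical(r3$series$Ca_field_mM, r1$series$Ca_field_mM))

  ls <- linescan(r1)
  expect_equal(dim(ls), c(20 / 0.5 + 1, 301))
  expect_equal(attr(ls, "x"), seq(0, 20, by = 0.5))
  # quiescent run stays near resting Ca along the whole scan
  expect_lt(max(abs(ls - 7e-5)), 5e-5)
  expect_error(linescan(r1, y = 50), "outside")
  expect_error(linescan(r1, y = 2), "mid-height")
  expect_silent(linescan(r1, y = 5))
})

test_that("a single forced spark appears at the right linescan location", {
  params <- make_params("control", grid = list(Lx = 20, Ly = 10, h = 0.5,
                                               dt = 0.02))
  lat <- ryr_lattice(0, params$grid, params$release, seed = 1)
  # cluster at x = 10, y = 5 (the recorded mid-height row)
  k <- which(lat$cluster_pos[, "x"] == 10 & lat$cluster_pos[, "y"] == 5)
  eng <- rogueryr:::engine_inputs(params, lat, 7e-5,
                                  force = list(kind = 0L, idx = k - 1L,
                                               on = 50, off = 60))
  numerics <- list(dt = 0.02, gating_every = 5L, rec_every = 50L,
                   linescan_row = as.integer(round(5 / 0.5)),
                   stochastic = FALSE)
  protocol <- list(stim_start = numeric(0), stim_dur = 1, stim_amp = 52,
                   t_end = 200, gna_zero_after = Inf)
  res <- rogueryr:::.engine_run(eng$grid, eng$release, eng$membrane,
                                eng$channels, cell_init(params$membrane),
                                protocol, numerics, 1)
  ls <- res$linescan   # 41 x-nodes x 201 samples (1 ms sampling)
  ix <- 10 / 0.5 + 1
  during <- 56:61      # samples at 55-60 ms
  before <- 1:45
  expect_gt(max(ls[ix, during]), 10 * max(ls[ix, before]))
  # localised: far end of the scan stays at rest while the spark burns
  expect_lt(max(ls[1, during]) / max(ls[ix, during]), 0.05)
})
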