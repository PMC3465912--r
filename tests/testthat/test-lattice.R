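grid_default <- grid_params()

test_that("cluster lattice has the expected interior positions and counts", {
  pos <- build_cluster_grid(grid_default)
  expect_equal(nrow(pos), 49 * 19)
  expect_equal(sort(unique(pos[, "x"])), 2 * (1:49))
  expect_equal(sort(unique(pos[, "y"])), 1 * (1:19))

  tiny <- grid_params(Lx = 4, Ly = 2)
  p1 <- build_cluster_grid(tiny)
  expect_equal(nrow(p1), 1L)
  expect_equal(unname(p1[1, ]), c(2, 1))

  expect_error(build_cluster_grid(grid_params(Lx = 2, Ly = 2)),
               "no interior")
  expect_error(build_cluster_grid(grid_params(Lx = 5, Ly = 2)),
               "divisible")
})

test_that("rogue placement has the right count, reproducibility and uniformity", {
  expect_equal(nrow(place_rogues(1.0, grid_default, 1)), 2000L)
  expect_equal(nrow(place_rogues(0, grid_default, 1)), 0L)
  expect_equal(nrow(place_rogues(0.25, grid_default, 1)), 500L)
  expect_error(place_rogues(-1, grid_default, 1), "non-negative")

  a <- place_rogues(1.0, grid_default, 7)
  b <- place_rogues(1.0, grid_default, 7)
  expect_identical(a, b)
  expect_false(identical(a, place_rogues(1.0, grid_default, 8)))
  expect_true(all(a[, "x"] >= 0 & a[, "x"] <= 100))
  expect_true(all(a[, "y"] >= 0 & a[, "y"] <= 20))

  # coarse uniformity: chi-square over a 10 x 2 binning
  bins <- table(cut(a[, "x"], seq(0, 100, by = 10)),
                cut(a[, "y"], seq(0, 20, by = 10)))
  p <- stats::chisq.test(as.vector(bins))$p.value
  expect_gt(p, 0.001)
})

test_that("luminal factor follows the saturating Hill form", {
  p <- release_params("control")
  expect_equal(luminal_factor(p$D_SR, p), p$k_max / 2)  # half-saturation
  expect_equal(luminal_factor(1e9, p), 2.0, tolerance = 1e-6)  # k_max limit
  expect_equal(luminal_factor(2.5, p), 0.4698745752, tolerance = 1e-8)
  expect_error(luminal_factor(-1, p), "positive")
  expect_error(luminal_factor(0, p), "positive")
})

test_that("firing probability matches the closed form at anchor points", {
  p <- release_params("control")
  # cytosolic and luminal half-saturation: P_max/2 * k_max/2 = 0.15 /ms
  expect_equal(firing_probability(p$K_m_cluster, p$D_SR, "cluster", p), 0.15)
  expect_equal(firing_probability(p$K_m_rogue, p$D_SR, "rogue", p), 0.15)
  # full saturation: P_max * k_max = 0.6 /ms
  expect_equal(firing_probability(1e6, 1e6, "cluster", p), 0.6,
               tolerance = 1e-6)
  # failing channels fire more readily at identical Ca
  ph <- firing_probability(0.002, 2.0, "cluster", release_params("heart_failure"))
  pc <- firing_probability(0.002, 2.0, "cluster", p)
  expect_equal(ph, 0.0173208589, tolerance = 1e-8)
  expect_equal(pc, 0.002322532431, tolerance = 1e-8)
  expect_gt(ph, pc)
  expect_error(firing_probability(-1, 2, "cluster", p), "positive")
})

test_that("gating functions are monotone in cytosolic and luminal Ca", {
  set.seed(11)
  for (rep in 1:20) {
    p <- release_params(sample(c("control", "heart_failure"), 1))
    ca <- sort(stats::runif(8, 1e-5, 0.05))
    casr <- sort(stats::runif(8, 0.3, 6))
    k <- luminal_factor(casr, p)
    expect_true(all(diff(k) > 0))
    expect_true(all(k > 0 & k < p$k_max))
    for (kind in c("cluster", "rogue")) {
      pj_ca <- firing_probability(ca, 2.0, kind, p)
      pj_sr <- firing_probability(0.001, casr, kind, p)
      expect_true(all(diff(pj_ca) > 0))
      expect_true(all(diff(pj_sr) > 0))
      expect_true(all(pj_ca >= 0 & pj_ca <= p$P_max * p$k_max))
    }
  }
})

test_that("stochastic state advance opens channels at the nominal rate", {
  grid <- grid_params(Lx = 20, Ly = 10)
  rel <- release_params("control")
  ca_clamp <- rel$K_m_cluster  # P = 0.15 /ms at luminal half-saturation
  nxy <- c(round(grid$Lx / grid$h) + 1, round(grid$Ly / grid$h) + 1)
  field <- matrix(ca_clamp, nxy[1], nxy[2])
  dt <- 0.1
  set.seed(5)
  total_open <- 0L; total_closed <- 0L
  for (rep in 1:40) {
    lat <- ryr_lattice(1.0, grid, rel, seed = rep)
    n <- nrow(lat$cluster_pos)
    lat2 <- advance_states(lat, field, rel$D_SR, dt)
    total_open <- total_open + length(attr(lat2, "opened")$clusters)
    total_closed <- total_closed + n
  }
  p_exp <- 0.15 * dt
  se <- sqrt(total_closed * p_exp * (1 - p_exp))
  expect_lt(abs(total_open - total_closed * p_exp), 3 * se)
})

test_that("state advance respects open/refractory dwell times and determinism", {
  grid <- grid_params(Lx = 8, Ly = 4)
  rel <- release_params("control")
  nxy <- c(round(grid$Lx / grid$h) + 1, round(grid$Ly / grid$h) + 1)
  # zero firing probability: vanishing cytosolic Ca
  field0 <- matrix(1e-12, nxy[1], nxy[2])
  lat <- ryr_lattice(0.5, grid, rel, seed = 3)
  set.seed(1)
  lat2 <- advance_states(lat, field0, 2.0, 0.1)
  expect_identical(lat2$cluster_state, lat$cluster_state)
  expect_identical(lat2$rogue_state, lat$rogue_state)
  expect_length(attr(lat2, "opened")$clusters, 0)

  # saturating Ca: everything opens, stays open t_open, then is refractory
  fieldS <- matrix(10, nxy[1], nxy[2])
  relfast <- release_params("control", t_open_cluster = 0.2,
                            t_open_rogue = 0.2, t_refractory = 0.3)
  lat <- ryr_lattice(0, grid, relfast, seed = 3)
  set.seed(2)
  lat <- advance_states(lat, fieldS, 100, 0.1)  # P*dt ~ 0.06: some open
  opened1 <- attr(lat, "opened")$clusters
  for (i in 1:2) { set.seed(10 + i); lat <- advance_states(lat, fieldS, 100, 0.1) }
  expect_true(all(lat$cluster_state[opened1] == 2L))  # now refractory
  for (i in 1:3) { set.seed(20 + i); lat <- advance_states(lat, fieldS, 100, 0.1) }
  # refractory period expired; channels may be closed or reopened
  expect_true(all(lat$cluster_state[opened1] %in% c(0L, 1L)))

  # identical RNG state implies identical opening sequence
  latA <- ryr_lattice(0.5, grid, rel, seed = 9)
  set.seed(77); a <- advance_states(latA, fieldS, 2.0, 0.1)
  set.seed(77); b <- advance_states(latA, fieldS, 2.0, 0.1)
  expect_identical(a$cluster_state, b$cluster_state)
  expect_identical(attr(a, "opened"), attr(b, "opened"))

  # a time step too coarse for the firing probability is rejected
  expect_error(advance_states(latA, fieldS, 2.0, 10), "smaller dt")
})
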