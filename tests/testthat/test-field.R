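test_that("cluster and rogue release fluxes follow the stated forms", {
  p <- release_params("control")
  expect_equal(p$V_cluster, 1.97e-8)
  expect_equal(p$J_rogue_amp, 3.3166e-9)
  expect_equal(cluster_flux(1.3, 1.3, p), 0)          # zero gradient
  expect_equal(cluster_flux(3.25, 1e-4, p), 6.402303e-8, tolerance = 1e-12)
  expect_equal(cluster_flux(1.0, 2.0, p), 0)          # reversed gradient clamps
  expect_equal(rogue_flux(FALSE, p), 0)
  expect_equal(rogue_flux(TRUE, p), 3.3166e-9)
})

test_that("point-flux to node-rate conversion survives dimensional analysis", {
  g <- grid_params()
  j <- 3.3166e-9                                    # pmol/ms
  # independent route: pmol -> mol, voxel um^3 -> litres, mol/L -> mM
  mol_per_ms <- j * 1e-12
  voxel_L <- g$h^2 * g$depth * 1e-15
  expected_mM_ms <- mol_per_ms / voxel_L * 1e3
  expect_equal(flux_to_node_rate(j, g), expected_mM_ms, tolerance = 1e-12)
  # linearity in the flux
  expect_equal(flux_to_node_rate(2 * j, g), 2 * flux_to_node_rate(j, g))
})

test_that("uniform resting field with pump balanced by leak is stationary", {
  g <- grid_params(Lx = 5, Ly = 3)
  f <- ca_field_init(g, ca0 = 7e-5)
  f2 <- f
  for (k in 1:200) f2 <- step_field(f2, leak = field_leak(g, 7e-5))
  expect_equal(f2$ca, f$ca, tolerance = 1e-9)
  expect_equal(f2$dye_b, f$dye_b, tolerance = 1e-9)
  expect_equal(f2$buf_b, f$buf_b, tolerance = 1e-9)
})

test_that("diffusion-only stepping conserves mass under zero-flux boundaries", {
  g <- grid_params(Lx = 5, Ly = 3, dye_total = 0, buf_total = 0,
                   pump_vmax = 0, leak = 0)
  f <- ca_field_init(g, ca0 = 7e-5)
  set.seed(4)
  f$ca <- matrix(stats::runif(f$nx * f$ny, 0, 1e-3), f$nx, f$ny)
  m0 <- sum(f$ca)
  for (k in 1:1000) f <- step_field(f, leak = 0)
  expect_equal(sum(f$ca), m0, tolerance = 1e-10)
  expect_true(all(f$ca >= 0))
})

test_that("total Ca balances the time-integrated sources, pump and leak", {
  g <- grid_params(Lx = 6, Ly = 3, h = 0.2, dt = 0.02)
  f <- ca_field_init(g, ca0 = 7e-5)
  leak <- field_leak(g, 7e-5)
  src <- matrix(0, f$nx, f$ny)
  src[round(f$nx / 2), round(f$ny / 2)] <- 0.2    # mM/ms point source
  influx <- 0
  n_steps <- 5000                                  # 100 ms
  for (k in seq_len(n_steps)) {
    pump_now <- sum(field_pump(f$ca, g))
    influx <- influx + g$dt * (sum(src) - pump_now + leak * f$nx * f$ny)
    f <- step_field(f, src = src, leak = leak)
  }
  total0 <- with(ca_field_init(g, ca0 = 7e-5), sum(ca + dye_b + buf_b))
  total1 <- sum(f$ca + f$dye_b + f$buf_b)
  expect_equal(total1 - total0, influx, tolerance = 1e-3)
  expect_true(all(f$ca >= 0))
})

test_that("an impulsive point source spreads as the anisotropic heat kernel", {
  g <- grid_params(Lx = 12, Ly = 6, dye_total = 0, buf_total = 0,
                   pump_vmax = 0, leak = 0)
  f <- ca_field_init(g, ca0 = 0.999e-12)
  f$ca[] <- 0
  ic <- round(f$nx / 2); jc <- round(f$ny / 2)
  amp <- 1  # mM in one voxel
  f$ca[ic, jc] <- amp
  t_diff <- 1  # ms
  for (k in seq_len(round(t_diff / g$dt))) f <- step_field(f, leak = 0)
  x <- (seq_len(f$nx) - ic) * g$h
  y <- (seq_len(f$ny) - jc) * g$h
  q <- amp * g$h^2
  exact <- q / (4 * pi * t_diff * sqrt(g$D_x * g$D_y)) *
    outer(x, y, function(xx, yy)
      exp(-(xx^2 / (4 * g$D_x * t_diff) + yy^2 / (4 * g$D_y * t_diff))))
  rms <- sqrt(mean((f$ca - exact)^2)) / max(exact)
  expect_lt(rms, 0.02)
})

test_that("release source map sums channels exactly and feeds the cell coupling", {
  g <- grid_params(Lx = 20, Ly = 10)
  rel <- release_params("heart_failure")
  mem <- membrane_params("heart_failure")
  lat <- ryr_lattice(1.0, g, rel, seed = 2)
  f <- ca_field_init(g, 7e-5)

  # no open channels
  fm0 <- source_map(lat, f, 2.0)
  expect_equal(fm0$J_total, 0)
  expect_true(all(fm0$src == 0))
  expect_equal(subrel_total(fm0, mem), 0)

  # two clusters with equal flux give exactly twice one
  lat1 <- lat; lat1$cluster_state[5] <- 1L
  lat2 <- lat; lat2$cluster_state[c(5, 50)] <- 1L
  f1 <- source_map(lat1, f, 2.0); f2 <- source_map(lat2, f, 2.0)
  expect_equal(f2$J_total, 2 * f1$J_total)
  expect_equal(sum(f2$src), 2 * sum(f1$src), tolerance = 1e-12)

  # random open set equals brute-force per-channel summation
  set.seed(9)
  oc <- sample(nrow(lat$cluster_pos), 40)
  oro <- sample(nrow(lat$rogue_pos), 25)
  lat$cluster_state[oc] <- 1L
  lat$rogue_state[oro] <- 1L
  fm <- source_map(lat, f, 2.0)
  brute <- sum(vapply(oc, function(k) {
    node <- lat$cluster_node[k, ]
    cluster_flux(2.0, f$ca[node[1], node[2]], rel)
  }, 0)) + length(oro) * rel$J_rogue_amp
  expect_equal(fm$J_total, brute, tolerance = 1e-12)
  # total source mass equals total flux through the voxel conversion
  expect_equal(sum(fm$src) * g$h^2 * g$depth / 1e6, fm$J_total,
               tolerance = 1e-9)
  # J_rel / J_sub_rel is the fixed cellular multiplier
  jsub <- subrel_total(fm, mem)
  expect_equal(couple_release(jsub, rel) / jsub, 22.25)
})

test_that("halving the mesh changes a deterministic spark peak by < 5%", {
  peaks <- vapply(c(0.2, 0.1), function(h) {
    g <- grid_params(Lx = 8, Ly = 4, h = h, dt = 0.01)
    rel <- release_params("control")
    f <- ca_field_init(g, 7e-5)
    ic <- round(4 / h) + 1; jc <- round(2 / h) + 1
    fp <- rogueryr:::footprint_offsets(g, rel$r_source)
    src <- matrix(0, f$nx, f$ny)
    j_spark <- cluster_flux(3.25, 7e-5, rel)
    for (k in seq_len(nrow(fp)))
      src[ic + fp$dx[k], jc + fp$dy[k]] <-
        src[ic + fp$dx[k], jc + fp$dy[k]] +
        flux_to_node_rate(j_spark * fp$w[k], g)
    for (s in seq_len(round(10 / g$dt))) f <- step_field(f, src = src)
    max(f$ca)
  }, 0)
  expect_lt(abs(peaks[2] - peaks[1]) / peaks[1], 0.05)
})
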