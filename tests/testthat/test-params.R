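test_that("condition-specific constants match the published parameter table", {
  ctl <- make_params("control")
  hf <- make_params("heart_failure")
  expect_equal(ctl$membrane$G_Na, 14.838)
  expect_equal(hf$membrane$G_Na, 8.902)
  expect_equal(ctl$membrane$V_max_pump, 0.006375)
  expect_equal(hf$membrane$V_max_pump, 0.0035)
  expect_equal(ctl$membrane$G_Ks, 0.392)
  expect_equal(hf$membrane$G_Ks, 0.196)
  expect_equal(ctl$membrane$G_K1, 5.405)
  expect_equal(hf$membrane$G_K1, 4.324)
  expect_equal(ctl$membrane$P_NaK, 2.724)
  expect_equal(hf$membrane$P_NaK, 1.57)
  expect_equal(ctl$membrane$G_bCa, 0.000592)
  expect_equal(hf$membrane$G_bCa, 0.0009045)
  expect_equal(ctl$release$K_m_cluster, 0.015)
  expect_equal(hf$release$K_m_cluster, 0.0075)
  expect_equal(ctl$release$D_SR, 3.25)
  expect_equal(hf$release$D_SR, 2.5)
})

test_that("failure-to-control ratios reflect the reported remodelling", {
  ctl <- make_params("control")
  hf <- make_params("heart_failure")
  # ~45% SERCA reduction
  expect_equal(hf$membrane$V_max_pump / ctl$membrane$V_max_pump,
               0.0035 / 0.006375, tolerance = 0.01)
  expect_lt(abs(hf$membrane$V_max_pump / ctl$membrane$V_max_pump - 0.549), 0.01)
  # I_to declines to ~64%
  expect_equal(hf$membrane$G_to / ctl$membrane$G_to, 0.63, tolerance = 0.01)
  # NCX upregulated by exactly 65%
  expect_identical(hf$membrane$k_NaCa / ctl$membrane$k_NaCa, 1.65)
  # I_K1 down 20%, I_Ks down 50%, I_NaK down 42%
  expect_equal(hf$membrane$G_K1 / ctl$membrane$G_K1, 0.8, tolerance = 1e-6)
  expect_equal(hf$membrane$G_Ks / ctl$membrane$G_Ks, 0.5, tolerance = 1e-6)
  expect_equal(hf$membrane$P_NaK / ctl$membrane$P_NaK, 0.58, tolerance = 0.01)
})

test_that("make_params is pure and HF differs in exactly the tabled entries", {
  a <- make_params("control")
  b <- make_params("control")
  expect_identical(a, b)
  ctl <- make_params("control")
  hf <- make_params("heart_failure")
  mem_fields <- setdiff(names(ctl$membrane), "condition")
  diff_mem <- mem_fields[vapply(mem_fields, function(f)
    !identical(ctl$membrane[[f]], hf$membrane[[f]]), TRUE)]
  expect_setequal(diff_mem, c("G_Na", "G_K1", "G_to", "G_Ks", "P_NaK",
                              "G_bCa", "k_NaCa", "V_max_pump"))
  rel_fields <- setdiff(names(ctl$release), "condition")
  diff_rel <- rel_fields[vapply(rel_fields, function(f)
    !identical(ctl$release[[f]], hf$release[[f]]), TRUE)]
  expect_setequal(diff_rel, c("K_m_cluster", "K_m_rogue", "D_SR"))
  expect_identical(unclass(ctl$grid), unclass(hf$grid))
  expect_error(make_params("dilated"), "unknown condition")
})

test_that("parameter invariants are enforced at construction", {
  expect_error(release_params("control", n_rogue = 2), "n_rogue")
  expect_error(release_params("control", P_max = -0.1), "positive")
  expect_error(membrane_params("control", G_Na = -1), ">= 0")
  expect_error(grid_params(dt = -1), "positive")
  # explicit stability bound checked at construction
  expect_error(grid_params(h = 0.1, dt = 0.05), "stability")
  expect_silent(validate_grid_params(grid_params(h = 0.1, dt = 0.01)))
  # rogue and cluster cytosolic sensitivities identical by default
  p <- release_params("heart_failure")
  expect_identical(p$K_m_rogue, p$K_m_cluster)
})

test_that("scenario config validates fields and round-trips through files", {
  expect_error(scenario_config("control", n_reps = 0), "n_reps")
  expect_error(scenario_config("control", grid = list(dt = -1)), "dt")
  expect_error(scenario_config("control", n_rogue = -0.5), "n_rogue")

  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("[scenario]", "condition = heart_failure"), path)
  expect_message(cfg <- load_config(path), "defaults applied")
  expect_identical(cfg$condition, "heart_failure")
  expect_identical(cfg$pacing_cl, 1000)  # default 1 Hz pacing
  expect_identical(cfg$n_rogue, 0)

  cfg2 <- scenario_config("heart_failure", n_rogue = 1.0, seed = 99L,
                          disable_ina_after_pacing = TRUE,
                          grid = list(h = 0.5, dt = 0.02))
  write_config(cfg2, path)
  suppressMessages(back <- load_config(path))
  expect_identical(back$n_rogue, 1.0)
  expect_identical(back$seed, 99L)
  expect_true(back$disable_ina_after_pacing)
  expect_identical(back$grid$h, 0.5)

  writeLines(c("[scenario]", "condition = control", "dtt = 0.01"), path)
  expect_error(load_config(path), "unknown")
  writeLines(c("[scenario]", "condition = control", "[grid]", "dt = -1"), path)
  expect_error(load_config(path), "dt")
  expect_error(load_config(file.path(tempdir(), "no-such-file.cfg")), "not found")
})
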