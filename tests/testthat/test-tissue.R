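test_that("classification follows the X > Y rule with ties to Y", {
  expect_equal(as.character(classify_expression(0.9, 0.1)), "X_STATE")
  expect_equal(as.character(classify_expression(0.1, 0.9)), "Y_STATE")
  expect_equal(as.character(classify_expression(0.5, 0.5)), "Y_STATE")
  expect_error(classify_expression(-1, 0), ">= 0")
})

test_that("sharpening index counts exactly the mixed columns", {
  # perfectly sorted grid: no mixed column
  lab <- cbind(matrix(1L, 4, 3), matrix(2L, 4, 3))
  expect_equal(sharpening_index(lab), 0L)
  # checkerboard: every column mixed
  cb <- outer(1:10, 1:10, function(i, j) 1L + (i + j) %% 2L)
  expect_equal(sharpening_index(cb), 10L)
  # two specific mixed columns on a 4 x 6 grid
  lab2 <- cbind(matrix(1L, 4, 2), rbind(matrix(1L, 2, 2), matrix(2L, 2, 2)),
                matrix(2L, 4, 2))
  expect_equal(sharpening_index(lab2), 2L)
  expect_error(sharpening_index(matrix(integer(0), 0, 0)), "non-empty")
})

test_that("tissue simulation is reproducible under a fixed seed", {
  p <- default_params("MRSA")
  fld <- parametric_gradient(linear_profile(), 0.06, 12, times = 0, seed = 5)
  cfg <- sde_config(d = 0.01, save_times = c(5, 10), seed = 42)
  a <- simulate_tissue(p, fld, cfg, n_rows = 4)
  b <- simulate_tissue(p, fld, cfg, n_rows = 4)
  expect_identical(a$X, b$X)
  expect_identical(a$labels, b$labels)
})

test_that("deterministic columns converge to the fate set by their morphogen", {
  p <- default_params("MRSA")
  ref <- reference_m_levels("MRSA")
  Ms <- c(ref[["low"]], ref[["high"]])
  fld <- morphogen_field(matrix(rep(Ms, each = 2), 2, 2), c(0, 400))
  cfg <- sde_config(d = 0, save_times = 400, seed = 1, s = 0)
  ts <- simulate_tissue(p, fld, cfg, n_rows = 3)
  # all rows of a column identical in the deterministic run
  expect_lt(max(apply(ts$X[1, , ], 2, stats::sd)), 1e-12)
  # low-M column keeps the X fate, high-M (monostable-Y) column flips
  expect_true(all(ts$labels[1, , 1] == 1L))
  expect_true(all(ts$labels[1, , 2] == 2L))
  # terminal states sit on fixed points of the drift
  for (j in 1:2) {
    d <- drift(p, ts$X[1, 1, j], ts$Y[1, 1, j], Ms[j])
    expect_lt(max(abs(c(d$fx, d$fy))), 1e-6)
  }
})

test_that("states remain non-negative and inside the trapping box", {
  p <- default_params("MRSA")
  fld <- parametric_gradient(linear_profile(), 0.1, 10, times = 0, seed = 2)
  cfg <- sde_config(d = 0.02, save_times = c(50, 100), seed = 3)
  ts <- simulate_tissue(p, fld, cfg, n_rows = 5)
  expect_true(all(ts$X >= 0) && all(ts$Y >= 0))
  # the stochastic cloud spreads around the deterministic trapping box by
  # the stationary fluctuation width; twice the box comfortably bounds it
  tb <- trapping_box(p)
  expect_true(all(ts$X <= tb[1] * 2))
  expect_true(all(ts$Y <= tb[2] * 2))
})

test_that("frozen deterministic dynamics give a constant SI trace", {
  p <- default_params("MRSA")
  fld <- parametric_gradient(linear_profile(), 0, 8, times = 0, seed = 1)
  cfg <- sde_config(d = 0, save_times = c(200, 300, 400), seed = 1)
  ts <- simulate_tissue(p, fld, cfg, n_rows = 4)
  tr <- si_trace(ts)
  # after deterministic convergence the labels cannot change
  expect_equal(tr$si[2], tr$si[3])
  expect_identical(ts$labels[2, , ], ts$labels[3, , ])
})

test_that("labels slot is consistent with the classification rule", {
  p <- default_params("MRSA")
  fld <- parametric_gradient(linear_profile(), 0.06, 10, times = 0, seed = 8)
  ts <- simulate_tissue(p, fld, sde_config(d = 0.01, save_times = 20, seed = 2),
                        n_rows = 4)
  expect_identical(ts$labels, array(ifelse(ts$X > ts$Y, 1L, 2L), dim = dim(ts$X)))
})

test_that("per-cell sensing splits rows; per-column realization does not", {
  p <- default_params("MRSA")
  # noiseless runs coincide between the two modes
  fld0 <- parametric_gradient(linear_profile(), 0, 10, times = 0, seed = 1)
  cfg <- sde_config(d = 0, save_times = 50, seed = 7)
  a <- simulate_tissue(p, fld0, cfg, n_rows = 4, morphogen_noise = "per_cell")
  b <- simulate_tissue(p, fld0, cfg, n_rows = 4, morphogen_noise = "per_column")
  expect_equal(a$X, b$X)
  # noisy per-column realization keeps rows identical at d = 0
  fld <- parametric_gradient(linear_profile(), 0.1, 10, times = 0:50, seed = 1)
  cfg <- sde_config(d = 0, save_times = 50, seed = 7, s = 0)
  pc <- simulate_tissue(p, fld, cfg, n_rows = 4, morphogen_noise = "per_column")
  expect_lt(max(apply(pc$X[1, , ], 2, stats::sd)), 1e-12)
  # per-cell sensing decorrelates rows
  pcell <- simulate_tissue(p, fld, cfg, n_rows = 4, morphogen_noise = "per_cell")
  expect_gt(max(apply(pcell$X[1, , ], 2, stats::sd)), 1e-6)
})

test_that("simulate_tissue validates field/model pairing", {
  p <- default_params("MRSA")
  pc <- default_params("MRSA_CROSS")
  fld <- parametric_gradient(linear_profile(), 0, 6, times = 0)
  expect_error(simulate_tissue(pc, fld, sde_config(save_times = 1)), "two morphogen")
  expect_error(simulate_tissue(p, fld, sde_config(save_times = 1), field2 = fld),
               "single morphogen")
})

test_that("init modes start near the intended corner", {
  p <- default_params("MRSA")
  fld <- parametric_gradient(linear_profile(), 0, 6, times = 0)
  cfg <- sde_config(d = 0, save_times = 0.01, seed = 3, init_mode = "Y_HIGH")
  ts <- simulate_tissue(p, fld, cfg, n_rows = 4)
  expect_true(all(ts$Y[1, , ] > 0.2))
  expect_true(all(ts$X[1, , ] < 0.1))
})
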