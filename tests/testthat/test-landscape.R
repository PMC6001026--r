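# Analytic benchmarks for the steady-state solver use drift_fn overrides so
# the checks are independent of any circuit calibration.

test_that("zero drift in a reflecting box gives the uniform distribution", {
  cfg <- fp_config(D = 0.01, domain = c(1, 1), resolution = c(60, 60))
  # a uniform density necessarily carries mass near the boundary: the
  # small-domain warning is expected here
  ls <- suppressWarnings(
    solve_fokker_planck(cfg = cfg,
                        drift_fn = function(x, y) list(fx = 0 * x, fy = 0 * y)))
  expect_lt(max(abs(ls$Pss - 1 / (60 * 60))), 1e-8)
  expect_lt(abs(sum(ls$Pss) - 1), 1e-8)
})

test_that("decoupled linear drift reproduces the Gaussian stationary density", {
  lam <- 2; D <- 0.01
  cfg <- fp_config(D = D, domain = c(1, 1), resolution = c(200, 200))
  ls <- solve_fokker_planck(cfg = cfg,
    drift_fn = function(x, y) list(fx = -lam * (x - 0.5), fy = -lam * (y - 0.5)))
  g <- stats::dnorm(ls$x, 0.5, sqrt(D / lam))
  ref <- outer(g, g); ref <- ref / sum(ref)
  expect_lt(max(abs(ls$Pss - ref) / max(ref)), 0.02)
  # the potential is quadratic with curvature lambda / (2 D) per axis
  U <- potential(ls)
  i0 <- which.min(abs(ls$x - 0.5))
  xs <- abs(ls$x - 0.5) < 0.2
  fit <- stats::lm(U[xs, i0] ~ I((ls$x[xs] - 0.5)^2))
  expect_equal(unname(stats::coef(fit)[2]), lam / (2 * D), tolerance = 0.03)
})

test_that("potential transform floors, inverts and shifts correctly", {
  P <- matrix(c(0.5, 0.25, 0.25, 0), 2, 2)
  U <- potential(P)
  expect_equal(which.min(U), which.max(P))
  expect_true(all(is.finite(U)))
  # uniform probability: constant potential
  expect_equal(max(potential(matrix(0.25, 2, 2))) -
               min(potential(matrix(0.25, 2, 2))), 0)
  # scaling Pss shifts U by a constant: barriers unchanged
  U2 <- potential(P * 7)
  expect_equal(U - U[1, 1], U2 - U2[1, 1])
})

test_that("attractor detection finds analytic minima and merges noise minima", {
  x <- seq(-2, 2, length.out = 161); y <- seq(-1, 1, length.out = 81)
  # single bowl
  bowl <- outer(x, y, function(x, y) 4 * (x^2 + y^2))
  a1 <- find_attractors(bowl)
  expect_equal(nrow(a1), 1L)
  expect_equal(x[a1$i], 0, tolerance = 0.03)
  # symmetric double well: exactly two minima near (+-1, 0)
  dw <- outer(x, y, function(x, y) (x^2 - 1)^2 + y^2)
  a2 <- find_attractors(dw)
  expect_equal(nrow(a2), 2L)
  expect_equal(sort(x[a2$i]), c(-1, 1), tolerance = 0.03)
  # a shallow perturbing dimple (depth << 0.5) is filtered out
  dimple <- dw + outer(x, y, function(x, y) -0.2 * exp(-((x - 0.2)^2 +
    y^2) / 0.005))
  expect_equal(nrow(find_attractors(dimple)), 2L)
})

test_that("minimax barrier matches the analytic double-well saddle", {
  x <- seq(-2, 2, length.out = 201); y <- seq(-1, 1, length.out = 101)
  U <- outer(x, y, function(x, y) (x^2 - 1)^2 + y^2)
  at <- find_attractors(U)
  b <- barrier(U, at[1, ], at[2, ])
  expect_equal(b$delta_U, 1, tolerance = 1e-3)
  expect_equal(b$delta_U_rev, 1, tolerance = 1e-3)
  expect_equal(x[b$i], 0, tolerance = 0.03)
  # tilted well: barrier is larger from the deeper side
  U2 <- outer(x, y, function(x, y) (x^2 - 1)^2 + 0.3 * x + y^2)
  a2 <- find_attractors(U2); a2 <- a2[order(a2$X), ]
  b2 <- barrier(U2, a2[1, ], a2[2, ])
  expect_gt(b2$delta_U, b2$delta_U_rev)
  expect_error(barrier(U, at[1, ], at[1, ]), "identical")
})

test_that("probability is conserved and the solve is deterministic", {
  p <- default_params("MRSA")
  cfg <- fp_config(D = 0.005, domain = c(3, 3), resolution = c(80, 80))
  m <- reference_m_levels("MRSA")[["mid"]]
  a <- solve_fokker_planck(p, m, cfg)
  b <- solve_fokker_planck(p, m, cfg)
  expect_identical(a$Pss, b$Pss)
  expect_lt(abs(sum(a$Pss) - 1), 1e-8)
  expect_true(all(a$Pss >= 0))
})

test_that("landscape attractors coincide with stable fixed points", {
  p <- default_params("MRSA")
  cfg <- fp_config(D = 0.002, domain = c(2.5, 2.5), resolution = c(100, 100))
  for (m in reference_m_levels("MRSA")[c("mid", "high")]) {
    ls <- solve_fokker_planck(p, m, cfg)
    at <- find_attractors(ls)
    st <- find_fixed_points(p, m)
    st <- st[st$stability == "stable", ]
    expect_equal(nrow(at), nrow(st))
    cell <- 2 * max(ls$dx, ls$dy)
    for (i in seq_len(nrow(st))) {
      dmin <- min(pmax(abs(at$X - st$X[i]), abs(at$Y - st$Y[i])))
      expect_lt(dmin, cell + 1e-9)
    }
  }
})

test_that("symmetrized circuit yields a swap-symmetric landscape", {
  p <- default_params("MRSA")
  p$A <- 1
  cfg <- fp_config(D = 0.005, domain = c(2.5, 2.5), resolution = c(80, 80))
  ls <- solve_fokker_planck(p, 0.6, cfg)
  expect_lt(max(abs(ls$Pss - t(ls$Pss))) / max(ls$Pss), 1e-6)
})

test_that("X-to-Y barrier falls as the morphogen level rises", {
  p <- default_params("MRSA")
  cfg <- fp_config(D = 0.002, domain = c(2.5, 2.5), resolution = c(100, 100))
  ms <- c(0.5, 0.6, 0.7, 0.8)
  sm <- suppressWarnings(landscape_summary(p, ms, cfg))
  expect_true(all(sm$n_attractors >= 2))
  expect_true(all(diff(sm$dU_XY) < 0))
})
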