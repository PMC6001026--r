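test_that("drift reduces to basal synthesis at the origin with no morphogen", {
  for (mdl in c("MRSA", "MR")) {
    p <- default_params(mdl)
    d0 <- drift(p, 0, 0, 0)
    expect_equal(d0$fx, p$a * p$b / p$A)
    expect_equal(d0$fy, p$a * p$b)
  }
  p <- default_params("SA")
  d0 <- drift(p, 0, 0, 0)
  expect_equal(d0$fx, p$a * p$b1)
  expect_equal(d0$fy, p$a * p$b2)
})

test_that("Hill terms hit half-saturation at the threshold", {
  p <- default_params("MRSA")
  # X = S makes the self-activation term exactly 1/2: isolate it by
  # differencing against X = 0 with Y large enough to freeze repression
  Y0 <- 0
  fx_S <- drift(p, p$S, Y0, 0)$fx
  fx_0 <- drift(p, 0, Y0, 0)$fx
  expect_equal((fx_S + p$k * p$S) - fx_0, p$a * 0.5)
  # morphogen at threshold: input term is a1/2
  expect_equal(drift(p, 0, 0, p$S)$fx - drift(p, 0, 0, 0)$fx, p$a1 * 0.5)
})

test_that("repression factor spans 1 to (1-R) as Y saturates", {
  p <- default_params("MRSA")
  for (R in c(0, 0.6, 1)) {
    p$R <- R
    yinf <- 1e8
    num <- drift(p, 0, yinf, 0)$fx
    den <- drift(p, 0, 0, 0)$fx
    expect_equal(num / den, 1 - R, tolerance = 1e-6)
  }
})

test_that("drift rejects invalid states and morphogen arities", {
  p <- default_params("MRSA")
  expect_error(drift(p, -0.1, 0, 0), "non-negative")
  expect_error(drift(p, 0, 0, -1), "non-negative")
  expect_error(drift(p, 0, 0, list(1, 2)), "single morphogen")
  pc <- default_params("MRSA_CROSS")
  expect_error(drift(pc, 0, 0, 0.5), "two morphogen")
  expect_silent(drift(pc, 0, 0, c(0.5, 0.8)))
})

test_that("pure decay has a single stable fixed point at the origin", {
  p <- circuit_params("MRSA", a = 1e-12, a1 = 0, b = 0, A = 1, R = 0, k = 1,
                      S = 1, n = 4)
  fp <- find_fixed_points(p, 0)
  expect_equal(nrow(fp), 1L)
  expect_equal(fp$stability, "stable")
  expect_lt(max(abs(c(fp$X, fp$Y))), 1e-6)
})

test_that("fixed points are true roots with consistent stability", {
  for (mdl in c("MRSA", "SA", "MR")) {
    p <- default_params(mdl)
    m <- reference_m_levels(mdl)[["mid"]]
    fp <- find_fixed_points(p, m)
    expect_gte(nrow(fp), 3L)  # bistable: 2 stable + 1 saddle
    for (i in seq_len(nrow(fp))) {
      d <- drift(p, fp$X[i], fp$Y[i], m)
      expect_lt(max(abs(c(d$fx, d$fy))), 1e-9)
      re <- c(fp$eig1_re[i], fp$eig2_re[i])
      if (fp$stability[i] == "stable") expect_true(all(re < 0))
      if (fp$stability[i] == "saddle") expect_true(min(re) < 0 && max(re) > 0)
    }
  }
})

test_that("root finder agrees with a brute-force grid sign-change scan", {
  # oracle: detect sign structure of the drift on a dense grid; candidate
  # cells whose 2x2 corners bracket zeros of both components are refined on
  # a 25x-finer local grid to reject near-miss "ghosts" where the two
  # nullclines approach without crossing
  both_change <- function(p, m, gx, gy) {
    nx <- length(gx); ny <- length(gy)
    d <- drift(p, rep(gx, ny), rep(gy, each = nx), m)
    FX <- matrix(d$fx, nx, ny); FY <- matrix(d$fy, nx, ny)
    chg <- function(F) {
      a <- F[-nx, -ny]; b <- F[-1, -ny]; cc <- F[-nx, -1]; dd <- F[-1, -1]
      (a * b < 0) | (a * cc < 0) | (dd * b < 0) | (dd * cc < 0)
    }
    which(chg(FX) & chg(FY), arr.ind = TRUE)
  }
  grid_scan_roots <- function(p, m, n = 200) {
    bx <- max(trapping_box(p)) * 1.05
    g <- seq(0, bx, length.out = n)
    w <- both_change(p, m, g, g)
    if (length(w) == 0) return(NULL)
    cell <- g[2] - g[1]
    hits <- NULL
    for (r in seq_len(nrow(w))) {
      x0 <- g[w[r, 1]]; y0 <- g[w[r, 2]]
      fine <- both_change(p, m, seq(x0 - cell, x0 + 2 * cell, length.out = 76),
                          seq(y0 - cell, y0 + 2 * cell, length.out = 76))
      if (nrow(fine) > 0) hits <- rbind(hits, c(x0, y0))
    }
    hits
  }
  for (mdl in c("MRSA", "MR")) {
    p <- default_params(mdl)
    for (m in reference_m_levels(mdl)[c("low", "high")]) {
      fp <- find_fixed_points(p, m)
      hits <- grid_scan_roots(p, m)
      # every found fixed point is near a sign-change cell
      cell <- max(trapping_box(p)) * 1.05 / 199
      for (i in seq_len(nrow(fp))) {
        dmin <- min(sqrt((hits[, 1] - fp$X[i])^2 + (hits[, 2] - fp$Y[i])^2))
        expect_lt(dmin, 3 * cell)
      }
      # and the root count matches the number of sign-change clusters
      n_cl <- if (nrow(hits) < 2) nrow(hits)
        else length(unique(stats::cutree(stats::hclust(stats::dist(hits),
                                                       "single"),
                                         h = 4 * cell)))
      expect_equal(nrow(fp), n_cl)
    }
  }
})

test_that("bifurcation regimes follow the reference sequence for all variants", {
  for (mdl in c("MRSA", "SA", "MR")) {
    p <- default_params(mdl)
    sc <- bifurcation_scan(p, reference_m_levels(mdl))
    expect_equal(sc$regime, c("bistable", "bistable", "mono_Y"))
  }
  pc <- default_params("MRSA_CROSS")
  sc <- bifurcation_scan(pc, reference_m_levels("MRSA_CROSS"))
  expect_equal(sc$regime, rep("bistable", 3))
})

test_that("morphogen-disconnected circuit has an m-independent scan", {
  p <- default_params("MRSA")
  p$a1 <- 0
  sc <- bifurcation_scan(p, c(0.1, 0.6, 1.3))
  expect_equal(length(unique(sc$regime)), 1L)
  expect_equal(length(unique(sc$n_stable)), 1L)
})

test_that("scan rows are independent of grid ordering", {
  p <- default_params("MRSA")
  m <- c(0.5, 0.8, 1.2)
  a <- bifurcation_scan(p, m)
  b <- bifurcation_scan(p, rev(m))
  expect_equal(a[order(a$m), -1], b[order(b$m), -1], ignore_attr = TRUE)
})

test_that("symmetrized circuit has a drift field symmetric under swap", {
  p <- default_params("MRSA")
  p$A <- 1
  xy <- cbind(runif(20, 0, 2), runif(20, 0, 2))
  d1 <- drift(p, xy[, 1], xy[, 2], 0.6)
  d2 <- drift(p, xy[, 2], xy[, 1], 0.6)
  expect_equal(d1$fx, d2$fy)
  expect_equal(d1$fy, d2$fx)
  # fixed points come in swapped pairs or on the diagonal
  fp <- find_fixed_points(p, 0.6)
  for (i in seq_len(nrow(fp))) {
    swapped <- sqrt((fp$X - fp$Y[i])^2 + (fp$Y - fp$X[i])^2)
    expect_lt(min(swapped), 1e-4)
  }
})

test_that("trapping box traps: outward drift is negative beyond it", {
  for (mdl in c("MRSA", "SA", "MR", "MRSA_CROSS")) {
    p <- default_params(mdl)
    tb <- trapping_box(p)
    m <- if (mdl == "MRSA_CROSS") c(1, 1) else 1.5
    d <- drift(p, tb[1] * 1.01, tb[2] * 1.01, m)
    expect_lt(d$fx, 0)
    expect_lt(d$fy, 0)
  }
})

test_that("parameter validation enforces the documented invariants", {
  expect_error(circuit_params("MRSA", a = -1, a1 = 0), "'a'")
  expect_error(circuit_params("MRSA", a = 1, a1 = 0, R = 1.2), "R")
  expect_error(circuit_params("MRSA", a = 1, a1 = 0, n = 2.5), "'n'")
  expect_error(circuit_params("NOPE", a = 1, a1 = 0))
})

test_that("config round-trip: shipped YAML reproduces default_params", {
  path <- system.file("extdata", "circuit_params.yaml", package = "sharpland")
  sets <- read_params_config(path)
  expect_true(all(c("MRSA", "SA", "MR", "MRSA_CROSS") %in% names(sets)))
  expect_equal(sets$MRSA, default_params("MRSA"))
  expect_s3_class(default_params("MR", variant = 2L), "circuit_params")
})
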