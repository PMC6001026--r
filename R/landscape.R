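#' Configuration of the steady-state Fokker-Planck solve
#'
#' @param D constant diffusion coefficient of the probability-evolution
#'   equation (concentration^2/time, > 0). This is an explicit solver input,
#'   deliberately decoupled from the multiplicative SDE noise amplitude
#'   \code{d}; for cross-checks against trajectory ensembles the mapping
#'   \code{D = (d_eff * x_ref)^2 / 2} with \code{x_ref = 0.5} and
#'   \code{d_eff = d * sqrt(2 * noise_psd)} is used. The default 0.002 keeps
#'   both basins of every calibrated bistable condition inside the
#'   representable probability range while the shallow near-fold basin stays
#'   above the attractor-detection prominence.
#' @param domain upper bounds \code{c(x_max, y_max)} of the state-space box
#'   (origin at 0); must contain the circuit's trapping box.
#' @param resolution grid cells per axis, \code{c(n_x, n_y)}, each >= 50.
#' @param solver_tol residual tolerance of the steady-state solve.
#' @return Object of class \code{fp_config}.
#' @export
fp_config <- function(D = 0.002, domain = c(3, 3), resolution = c(200, 200),
                      solver_tol = 1e-8) {
  stopifnot_scalar(D, "D", positive = TRUE)
  if (length(domain) != 2 || any(domain <= 0)) stop("bad 'domain'", call. = FALSE)
  if (length(resolution) != 2 || any(resolution < 50))
    stop("'resolution' must be two integers >= 50", call. = FALSE)
  structure(list(D = D, domain = as.numeric(domain),
                 resolution = as.integer(resolution),
                 solver_tol = solver_tol),
            class = "fp_config")
}

# Bernoulli function of the exponential-fitting flux, stable for large |z|
.bern <- function(z) {
  out <- numeric(length(z))
  small <- abs(z) < 1e-8
  out[small] <- 1 - z[small] / 2
  big <- z > 700
  out[big] <- 0
  rest <- !small & !big
  out[rest] <- z[rest] / expm1(z[rest])
  out
}

#' Steady-state probability landscape of a stochastic circuit
#'
#' Solves the stationary 2-D probability-evolution (Fokker-Planck) equation
#' \deqn{0 = -\partial_x (F_1 P) - \partial_y (F_2 P) + D (\partial_x^2 P +
#' \partial_y^2 P)}
#' with zero-flux (reflecting) boundaries, by an exponential-fitting
#' finite-volume discretization (Scharfetter-Gummel fluxes, drift evaluated
#' at face midpoints). Probability is conserved exactly by construction; the
#' steady state is obtained as the null vector of the discrete operator, with
#' an implicit pseudo-time fallback. The result is deterministic.
#'
#' @param params a \code{circuit_params} object, or NULL when \code{drift_fn}
#'   is supplied.
#' @param m morphogen level(s), as in [drift()].
#' @param cfg an \code{fp_config}.
#' @param drift_fn optional override: \code{function(x, y)} returning
#'   \code{list(fx, fy)} for vectors x, y. Used for analytic benchmark
#'   drifts.
#' @return Object of class \code{landscape}: cell-center coordinates
#'   \code{x}, \code{y}, the per-cell steady-state probability \code{Pss}
#'   (n_x x n_y, sums to 1), the potential \code{U = -ln(Pss)} (floored, see
#'   [potential()]), the floor used, and the solve residual.
#' @export
solve_fokker_planck <- function(params = NULL, m = NULL, cfg = fp_config(),
                                drift_fn = NULL) {
  stopifnot(inherits(cfg, "fp_config"))
  if (is.null(drift_fn)) {
    stopifnot(inherits(params, "circuit_params"))
    tb <- trapping_box(params)
    if (any(tb > cfg$domain))
      warning("domain does not contain the trapping box; enlarge 'domain'")
    drift_fn <- function(x, y) drift(params, x, y, m)
  }
  nx <- cfg$resolution[1]; ny <- cfg$resolution[2]
  dx <- cfg$domain[1] / nx; dy <- cfg$domain[2] / ny
  xc <- (seq_len(nx) - 0.5) * dx
  yc <- (seq_len(ny) - 0.5) * dy
  D <- cfg$D
  idx <- function(i, j) i + nx * (j - 1L)

  # x-faces between (i, j) and (i+1, j), i = 1..nx-1
  xf <- seq_len(nx - 1) * dx
  fx <- drift_fn(rep(xf, ny), rep(yc, each = nx - 1))$fx
  vx <- fx * dx / D
  cx <- D / dx^2
  ip <- rep(seq_len(nx - 1), ny); jp <- rep(seq_len(ny), each = nx - 1)
  pA <- idx(ip, jp); pB <- idx(ip + 1L, jp)
  bm <- .bern(-vx); bp <- .bern(vx)
  # y-faces between (i, j) and (i, j+1), j = 1..ny-1
  yf <- seq_len(ny - 1) * dy
  fy <- drift_fn(rep(xc, ny - 1), rep(yf, each = nx))$fy
  vy <- fy * dy / D
  cy <- D / dy^2
  ipy <- rep(seq_len(nx), ny - 1); jpy <- rep(seq_len(ny - 1), each = nx)
  qA <- idx(ipy, jpy); qB <- idx(ipy, jpy + 1L)
  bmy <- .bern(-vy); bpy <- .bern(vy)

  ii <- c(pA, pA, pB, pB, qA, qA, qB, qB)
  jj <- c(pA, pB, pA, pB, qA, qB, qA, qB)
  vv <- c(-cx * bm, cx * bp, cx * bm, -cx * bp,
          -cy * bmy, cy * bpy, cy * bmy, -cy * bpy)
  n <- nx * ny
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))

  # Null vector of A: every column of A sums to zero (exact probability
  # conservation), so dropping one balance row and pinning that cell to 1
  # yields the null vector up to scale; normalize afterwards. The solve is
  # well conditioned only when the pinned cell carries non-negligible
  # probability, so anchor at the domain center first and re-anchor at the
  # resulting probability peak if needed.
  resid_of <- function(P) max(abs(A %*% P))
  scale_ref <- max(abs(vv))
  solve_anchored <- function(anchor) {
    keep <- ii != anchor
    M <- Matrix::sparseMatrix(i = c(ii[keep], anchor), j = c(jj[keep], anchor),
                              x = c(vv[keep], 1), dims = c(n, n))
    b <- numeric(n); b[anchor] <- 1
    tryCatch(as.numeric(Matrix::solve(M, b)), error = function(e) NULL)
  }
  is_ok <- function(P) !is.null(P) && all(is.finite(P)) &&
    min(P) > -1e-8 * max(P) &&
    resid_of(pmax(P, 0) / sum(pmax(P, 0))) < cfg$solver_tol * scale_ref
  P <- solve_anchored(idx(max(1L, nx %/% 2L), max(1L, ny %/% 2L)))
  if (!is_ok(P) && !is.null(P) && all(is.finite(P))) {
    # even an ill-conditioned solve points at the true peak: error is
    # dominated by the null-vector direction
    P <- solve_anchored(which.max(abs(P)))
  }
  ok <- is_ok(P)
  if (!ok) {
    # implicit pseudo-time integration to stationarity
    tau <- 10 / scale_ref
    Mt <- Matrix::Diagonal(n) - tau * A
    P <- rep(1 / n, n)
    for (it in seq_len(400)) {
      P <- as.numeric(Matrix::solve(Mt, P))
      P <- pmax(P, 0); P <- P / sum(P)
      if (resid_of(P) < cfg$solver_tol * scale_ref) break
    }
    if (resid_of(P) >= cfg$solver_tol * scale_ref)
      stop(sprintf("Fokker-Planck solve did not converge (residual %.3g)",
                   resid_of(P)), call. = FALSE)
  }
  P <- pmax(P, 0); P <- P / sum(P)
  resid <- resid_of(P)
  Pm <- matrix(P, nx, ny)
  edge <- rep(FALSE, n)
  em <- matrix(FALSE, nx, ny)
  em[c(1, 2, nx - 1, nx), ] <- TRUE; em[, c(1, 2, ny - 1, ny)] <- TRUE
  if (sum(Pm[em]) > 0.01)
    warning(sprintf("%.1f%% of probability mass within 2 cells of the boundary; domain may be too small",
                    100 * sum(Pm[em])))
  ls <- structure(list(x = xc, y = yc, dx = dx, dy = dy, Pss = Pm,
                       U = NULL, floor = NULL, D = D, params = params, m = m,
                       cfg = cfg, residual = resid),
                  class = "landscape")
  ls$U <- potential(ls)
  ls$floor <- 1e-12 * max(Pm)
  ls
}

#' Potential of a probability landscape
#'
#' \eqn{U = -\ln(\max(P_{ss}, \mathrm{floor}))} with floor
#' \code{1e-12 * max(Pss)}, so the potential is finite everywhere and its
#' minimum coincides with the probability maximum. Rescaling Pss by a
#' constant shifts U uniformly and leaves all barrier heights unchanged.
#'
#' @param x a \code{landscape} object or a probability matrix.
#' @return Matrix of dimensionless potential values.
#' @export
potential <- function(x) {
  P <- if (inherits(x, "landscape")) x$Pss else as.matrix(x)
  -log(pmax(P, 1e-12 * max(P)))
}

#' @export
print.landscape <- function(x, ...) {
  at <- find_attractors(x)
  cat(sprintf("<landscape> %d x %d grid on [0, %g] x [0, %g], D = %g\n",
              nrow(x$Pss), ncol(x$Pss), x$cfg$domain[1], x$cfg$domain[2], x$D))
  cat(sprintf("  solve residual %.2g; %d attractor(s):\n", x$residual, nrow(at)))
  for (r in seq_len(nrow(at)))
    cat(sprintf("   (X = %.3f, Y = %.3f)  U = %.2f\n", at$X[r], at$Y[r], at$U[r]))
  invisible(x)
}

#' Plot the potential surface of a landscape
#'
#' Filled contours of U, capped at \code{u_max} above the global minimum.
#'
#' @param x a \code{landscape}.
#' @param u_max potential range above the minimum to display (default 15).
#' @param ... passed to \code{filled.contour}.
#' @export
plot.landscape <- function(x, u_max = 15, ...) {
  U <- pmin(x$U, min(x$U) + u_max)
  graphics::filled.contour(x$x, x$y, U, color.palette = grDevices::terrain.colors,
                           xlab = "X", ylab = "Y", ...)
  invisible(x)
}

#' Detect attractors (potential minima) on a landscape
#'
#' Strict local minima of U over 8-cell neighbourhoods, filtered by
#' topographic prominence: a minimum whose minimax barrier to a deeper
#' minimum is less than \code{min_depth} potential units is discarded as a
#' discretization artefact. Results are sorted by U (deepest first).
#'
#' @param x a \code{landscape} or potential matrix.
#' @param min_depth prominence threshold in potential units (default 0.5).
#' @return Data frame with grid indices \code{i}, \code{j}, coordinates
#'   \code{X}, \code{Y} (cell centers; column index when a bare matrix is
#'   given) and \code{U}.
#' @export
find_attractors <- function(x, min_depth = 0.5) {
  U <- if (inherits(x, "landscape")) x$U else as.matrix(x)
  nx <- nrow(U); ny <- ncol(U)
  pad <- matrix(Inf, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- U
  ismin <- matrix(TRUE, nx, ny)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- pad[2:(nx + 1) + di, 2:(ny + 1) + dj]
    ismin <- ismin & (U < nb)
  }
  w <- which(ismin, arr.ind = TRUE)
  if (nrow(w) == 0) return(data.frame(i = integer(0), j = integer(0),
                                      X = numeric(0), Y = numeric(0),
                                      U = numeric(0)))
  cand <- data.frame(i = w[, 1], j = w[, 2], U = U[w])
  cand <- cand[order(cand$U), , drop = FALSE]
  # prominence filter: drop shallow minima merged below min_depth
  keep <- rep(TRUE, nrow(cand))
  if (nrow(cand) > 1) {
    for (a in rev(seq_len(nrow(cand)))[-length(keep)]) {  # shallowest first
      if (!keep[a]) next
      for (b in seq_len(a - 1)) {
        if (!keep[b]) next
        sad <- .cpp_minimax_saddle(U, cand$i[a] - 1L, cand$j[a] - 1L,
                                   cand$i[b] - 1L, cand$j[b] - 1L)
        if (sad$U - cand$U[a] < min_depth) { keep[a] <- FALSE; break }
      }
    }
  }
  cand <- cand[keep, , drop = FALSE]
  if (inherits(x, "landscape")) {
    cand$X <- x$x[cand$i]; cand$Y <- x$y[cand$j]
  } else {
    cand$X <- cand$i; cand$Y <- cand$j
  }
  rownames(cand) <- NULL
  cand[, c("i", "j", "X", "Y", "U")]
}

#' Barrier height between two attractors
#'
#' The saddle is the exact minimax point over all grid paths from A to B
#' (cells activated in increasing U with union-find connectivity, 8-cell
#' adjacency). The barrier for the A-to-B transition is
#' \code{U(saddle) - U(A)}; both directions share the saddle but differ in
#' height.
#'
#' @param x a \code{landscape} or potential matrix.
#' @param a,b attractor rows as returned by [find_attractors()] (data frames
#'   or lists with fields \code{i}, \code{j}).
#' @return Object of class \code{barrier}: saddle indices/coordinates,
#'   \code{U_saddle}, \code{delta_U} (A to B) and \code{delta_U_rev}.
#' @export
barrier <- function(x, a, b) {
  U <- if (inherits(x, "landscape")) x$U else as.matrix(x)
  if (a$i == b$i && a$j == b$j) stop("attractors are identical", call. = FALSE)
  sad <- .cpp_minimax_saddle(U, a$i - 1L, a$j - 1L, b$i - 1L, b$j - 1L)
  if (is.na(sad$U)) stop("no connecting path found", call. = FALSE)
  out <- list(i = sad$i, j = sad$j, U_saddle = sad$U,
              delta_U = sad$U - U[a$i, a$j],
              delta_U_rev = sad$U - U[b$i, b$j])
  if (inherits(x, "landscape")) { out$X <- x$x[sad$i]; out$Y <- x$y[sad$j] }
  structure(out, class = "barrier")
}

#' @export
print.barrier <- function(x, ...) {
  cat(sprintf("<barrier> saddle U = %.3f; dU(A->B) = %.3f, dU(B->A) = %.3f\n",
              x$U_saddle, x$delta_U, x$delta_U_rev))
  invisible(x)
}

#' Per-condition landscape summary
#'
#' Solves the landscape at each morphogen level and tabulates attractor
#' count, locations and the X-to-Y / Y-to-X barriers (NA when not bistable).
#' The X (Y) attractor is the minimum with the larger X (Y) coordinate.
#'
#' @param params a \code{circuit_params}.
#' @param m_values morphogen levels (vector, or two-column matrix for
#'   \code{MRSA_CROSS}).
#' @param cfg an \code{fp_config}.
#' @param file optional CSV output path.
#' @return Data frame, one row per condition.
#' @export
landscape_summary <- function(params, m_values, cfg = fp_config(),
                              file = NULL) {
  cross <- params$model_id == "MRSA_CROSS"
  nper <- if (cross) nrow(m_values) else length(m_values)
  rows <- lapply(seq_len(nper), function(k) {
    m <- if (cross) c(m_values[k, 1], m_values[k, 2]) else m_values[k]
    ls <- solve_fokker_planck(params, m, cfg)
    at <- find_attractors(ls)
    xa <- at[which.max(at$X - at$Y), , drop = FALSE]
    ya <- at[which.max(at$Y - at$X), , drop = FALSE]
    two <- nrow(at) >= 2
    data.frame(m1 = m[1], m2 = m[length(m)], n_attractors = nrow(at),
               X_attr_x = if (two) xa$X else NA, X_attr_y = if (two) xa$Y else NA,
               Y_attr_x = ya$X, Y_attr_y = ya$Y,
               dU_XY = if (two) barrier(ls, xa, ya)$delta_U else NA,
               dU_YX = if (two) barrier(ls, xa, ya)$delta_U_rev else NA)
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' Long-run SDE ensemble with matched additive noise
#'
#' Samples the stationary distribution of the circuit by Euler-Maruyama with
#' additive noise of intensity D per gene (amplitude \eqn{\sqrt{2D}}),
#' matching the constant-diffusion probability-evolution operator solved by
#' [solve_fokker_planck()]; states reflect at the axes as the zero-flux
#' boundaries do. Used to cross-check landscape attractor locations against
#' trajectory-ensemble histogram modes.
#'
#' @param params a \code{circuit_params}.
#' @param m morphogen level(s).
#' @param D additive noise intensity (use the landscape's \code{D}).
#' @param n_samples number of stored samples (default 1e4).
#' @param burnin,thin burn-in time and time between stored samples.
#' @param dt integration step.
#' @param seed RNG seed.
#' @param start optional \code{c(X, Y)} initial state (default: mid-domain).
#' @return Matrix with columns X, Y.
#' @export
sample_stationary <- function(params, m, D, n_samples = 1e4, burnin = 100,
                              thin = 1, dt = 0.01, seed = 1L, start = NULL) {
  stopifnot(inherits(params, "circuit_params"))
  if (params$model_id == "MRSA_CROSS") {
    m1 <- if (is.list(m)) m[[1]] else m[1]; m2 <- if (is.list(m)) m[[2]] else m[2]
  } else { m1 <- m; m2 <- m }
  if (is.null(start)) start <- trapping_box(params) / 2
  out <- with_seed(seed,
    .cpp_sample_additive(.model_code(params$model_id), .param_vec(params),
                         m1, m2, D, as.integer(n_samples), burnin, thin, dt,
                         start[1], start[2]))
  colnames(out) <- c("X", "Y")
  out
}

#' Landscape regimes at given morphogen conditions
#'
#' Classifies each condition by combining the potential landscape with the
#' deterministic skeleton: attractors are local minima of U (prominence
#' \code{min_depth}) that coincide with a stable fixed point of the drift
#' within \code{match_tol} (max-norm). Because the rendering diffusion D
#' trades the visibility of a shallow minor basin (prominence) against the
#' representable probability range (the floor under the log), each condition
#' is solved over a small ladder of D values and the maximal consistent
#' attractor count is kept.
#'
#' @param params a \code{circuit_params}.
#' @param m_values morphogen levels (vector, or two-column matrix for
#'   \code{MRSA_CROSS}).
#' @param D_ladder diffusion coefficients tried per condition.
#' @param cfg an \code{fp_config}; its D is replaced by the ladder values.
#' @param min_depth prominence threshold for candidate minima.
#' @param match_tol max-norm tolerance for matching minima to stable fixed
#'   points.
#' @return Data frame with one row per condition: morphogen level(s),
#'   \code{n_attractors}, \code{regime} (\code{"bistable"}, \code{"mono_X"},
#'   \code{"mono_Y"}).
#' @export
landscape_regimes <- function(params, m_values,
                              D_ladder = c(2e-3, 1e-3, 5e-4),
                              cfg = fp_config(), min_depth = 0.1,
                              match_tol = 0.1) {
  cross <- params$model_id == "MRSA_CROSS"
  nper <- if (cross) nrow(m_values) else length(m_values)
  rows <- lapply(seq_len(nper), function(k) {
    m <- if (cross) c(m_values[k, 1], m_values[k, 2]) else m_values[k]
    fp <- find_fixed_points(params, m)
    st <- fp[fp$stability == "stable", , drop = FALSE]
    best <- NULL
    for (D in D_ladder) {
      c2 <- cfg; c2$D <- D
      ls <- suppressWarnings(solve_fokker_planck(params, m, c2))
      at <- find_attractors(ls, min_depth = min_depth)
      ok <- vapply(seq_len(nrow(at)), function(i)
        any(pmax(abs(st$X - at$X[i]), abs(st$Y - at$Y[i])) < match_tol),
        logical(1))
      at <- at[ok, , drop = FALSE]
      if (is.null(best) || nrow(at) > nrow(best)) best <- at
    }
    regime <- if (nrow(best) >= 2) "bistable"
      else if (nrow(best) == 0) "none"
      else if (best$X[1] > best$Y[1]) "mono_X" else "mono_Y"
    base <- if (cross) data.frame(m1 = m[1], m2 = m[2]) else data.frame(m = m)
    cbind(base, data.frame(n_attractors = nrow(best), regime = regime))
  })
  do.call(rbind, rows)
}
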