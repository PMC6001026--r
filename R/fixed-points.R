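#' Locate and classify fixed points of the drift field
#'
#' Multi-start root search on the deterministic drift. Starts are laid out on
#' a jittered regular grid over the search box; converged roots are merged
#' when closer than \code{tol_merge} in max-norm and classified by the
#' eigenvalues of the (numerically differentiated) Jacobian.
#'
#' @param params a \code{circuit_params} object.
#' @param m morphogen level(s), as in [drift()].
#' @param search_box numeric \code{c(lo, hi)} applied to both axes; default
#'   covers the trapping box of the variant.
#' @param n_starts number of root-search starts (default 64).
#' @param seed RNG seed controlling the start jitter (deterministic result).
#' @param tol_merge max-norm distance below which two roots are considered
#'   the same fixed point.
#' @return A data frame with columns \code{X}, \code{Y}, \code{stability}
#'   (\code{"stable"}, \code{"saddle"} or \code{"unstable"}), and the real and
#'   imaginary parts of the two Jacobian eigenvalues. Zero rows when no root
#'   is found.
#' @export
find_fixed_points <- function(params, m, search_box = NULL, n_starts = 64L,
                              seed = 1L, tol_merge = 1e-4) {
  stopifnot(inherits(params, "circuit_params"))
  if (is.null(search_box)) search_box <- c(0, max(trapping_box(params)) * 1.05)
  f <- function(v) {
    d <- drift(params, max(v[1], 0), max(v[2], 0), m)
    c(d$fx, d$fy)
  }
  side <- ceiling(sqrt(n_starts))
  g <- seq(search_box[1], search_box[2], length.out = side + 2L)[-c(1, side + 2L)]
  starts <- as.matrix(expand.grid(X = g, Y = g))[seq_len(min(n_starts, side^2)), , drop = FALSE]
  starts <- with_seed(seed,
    starts + matrix(stats::rnorm(length(starts), 0, diff(search_box) / (20 * side)),
                    ncol = 2))
  starts <- pmin(pmax(starts, search_box[1]), search_box[2])
  roots <- NULL
  for (i in seq_len(nrow(starts))) {
    v <- .newton2(f, starts[i, ], search_box)
    if (is.null(v)) next
    if (is.null(roots) ||
        all(apply(roots, 1, function(r) max(abs(r - v))) > tol_merge))
      roots <- rbind(roots, v)
  }
  if (is.null(roots))
    return(data.frame(X = numeric(0), Y = numeric(0),
                      stability = character(0), eig1_re = numeric(0),
                      eig1_im = numeric(0), eig2_re = numeric(0),
                      eig2_im = numeric(0)))
  out <- do.call(rbind, lapply(seq_len(nrow(roots)), function(i) {
    v <- roots[i, ]
    J <- .jac2(f, v)
    ev <- eigen(J, only.values = TRUE)$values
    re <- Re(ev)
    stab <- if (all(re < 0)) "stable" else if (all(re > 0)) "unstable" else "saddle"
    data.frame(X = v[1], Y = v[2], stability = stab,
               eig1_re = Re(ev[1]), eig1_im = Im(ev[1]),
               eig2_re = Re(ev[2]), eig2_im = Im(ev[2]))
  }))
  rownames(out) <- NULL
  out[order(out$X), , drop = FALSE]
}

# damped Newton iteration with central-difference Jacobian; NULL on failure
.newton2 <- function(f, v, box, tol = 1e-11, maxit = 80L) {
  for (it in seq_len(maxit)) {
    fv <- f(v)
    if (any(!is.finite(fv))) return(NULL)
    if (max(abs(fv)) < tol) break
    J <- .jac2(f, v)
    dv <- tryCatch(solve(J, fv), error = function(e) NULL)
    if (is.null(dv) || any(!is.finite(dv))) return(NULL)
    step <- 1
    repeat {
      vn <- v - step * dv
      if (max(abs(f(pmax(vn, 0)))) < max(abs(fv)) || step < 1 / 64) break
      step <- step / 2
    }
    v <- pmax(vn, 0)
    if (any(v > box[2] * 1.5 + 1)) return(NULL)
  }
  if (max(abs(f(v))) < 1e-9 && all(v >= -1e-10) &&
      all(v <= box[2] * 1.2 + 1e-9)) pmax(v, 0) else NULL
}

.jac2 <- function(f, v, h = 1e-6) {
  cbind((f(v + c(h, 0)) - f(v - c(h, 0))) / (2 * h),
        (f(v + c(0, h)) - f(v - c(0, h))) / (2 * h))
}

#' Scan bistability regimes along a morphogen axis
#'
#' Runs [find_fixed_points()] for each morphogen level and assigns a regime:
#' \code{"bistable"} when two or more stable fixed points coexist,
#' \code{"mono_X"} / \code{"mono_Y"} when the single stable state has X > Y /
#' Y >= X, and \code{"none"} when no stable state is found.
#'
#' @param params a \code{circuit_params} object.
#' @param m_grid numeric vector of morphogen levels, or for
#'   \code{MRSA_CROSS} a two-column matrix of (M1, M2) pairs.
#' @param file optional path; when given, the table is also written as CSV.
#' @param ... passed to [find_fixed_points()].
#' @return Data frame with columns \code{m} (or \code{m1}, \code{m2}),
#'   \code{n_stable}, \code{n_saddle}, \code{regime}.
#' @export
bifurcation_scan <- function(params, m_grid, file = NULL, ...) {
  cross <- params$model_id == "MRSA_CROSS"
  if (cross && is.null(dim(m_grid)))
    stop("MRSA_CROSS needs a two-column matrix of (M1, M2) levels", call. = FALSE)
  n <- if (cross) nrow(m_grid) else length(m_grid)
  rows <- lapply(seq_len(n), function(i) {
    m <- if (cross) c(m_grid[i, 1], m_grid[i, 2]) else m_grid[i]
    fp <- find_fixed_points(params, m, ...)
    st <- fp[fp$stability == "stable", , drop = FALSE]
    regime <- if (nrow(st) >= 2) "bistable"
      else if (nrow(st) == 0) "none"
      else if (st$X[1] > st$Y[1]) "mono_X" else "mono_Y"
    base <- if (cross) data.frame(m1 = m[1], m2 = m[2]) else data.frame(m = m)
    cbind(base, data.frame(n_stable = nrow(st),
                           n_saddle = sum(fp$stability == "saddle"),
                           regime = regime))
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
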