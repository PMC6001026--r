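#' Morphogen field over the tissue axis
#'
#' A morphogen field holds one morphogen level per tissue column and saved
#' time, plus the noise amplitude used to generate it. Fields are produced by
#' [parametric_gradient()], [cross_gradients()] or [simulate_ra_gradient()].
#'
#' @param values numeric matrix, n_times x n_columns, all values >= 0.
#' @param times numeric vector of saved times (length = nrow(values)).
#' @param x column positions in `[0, 1]` (length = ncol(values)).
#' @param noise_amp the multiplicative noise amplitude used (epsilon).
#' @param kind \code{"PARAMETRIC"} or \code{"RA_PDE"}.
#' @param base optional deterministic per-column profile underlying the
#'   realized values; required for per-cell morphogen sensing in
#'   [simulate_tissue()].
#' @return Object of class \code{morphogen_field}.
#' @export
morphogen_field <- function(values, times, x = NULL, noise_amp = 0,
                            kind = c("PARAMETRIC", "RA_PDE"), base = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(x)) x <- seq(0, 1, length.out = ncol(values))
  stopifnot(nrow(values) == length(times), ncol(values) == length(x))
  if (any(values < 0)) stop("morphogen values must be >= 0", call. = FALSE)
  if (!is.null(base) && length(base) != ncol(values))
    stop("'base' must have one value per column", call. = FALSE)
  structure(list(values = values, times = as.numeric(times), x = x,
                 noise_amp = noise_amp, kind = kind, base = base),
            class = "morphogen_field")
}

#' @export
print.morphogen_field <- function(x, ...) {
  cat(sprintf("<morphogen_field> %s: %d columns x %d times, eps = %g\n",
              x$kind, ncol(x$values), nrow(x$values), x$noise_amp))
  cat(sprintf("  deterministic span (last time): [%.3g, %.3g]\n",
              min(x$values[nrow(x$values), ]), max(x$values[nrow(x$values), ])))
  invisible(x)
}

#' Default single-gradient morphogen profile
#'
#' Linear profile rising from 0 at the left edge to \code{m_max} at the right
#' edge of the tissue, so that the high-morphogen (Y-fated) domain sits on the
#' right. The span covers the full regime sequence of the calibrated
#' variants.
#'
#' @param m_max morphogen level at the rightmost column (default 1.5).
#' @return A function of normalized position x in `[0, 1]`.
#' @export
linear_profile <- function(m_max = 1.5) {
  force(m_max)
  function(x) m_max * x
}

#' Opposed exponential profiles for the cross-gradient circuit
#'
#' M1 decays from 1 at the left edge to 0.38 at the right edge as
#' \eqn{0.38^x}; M2 is its mirror image. The two profiles cross at the tissue
#' center where M1 = M2 = 0.61(6), matching the reference positions
#' (1, 0.38), (0.61, 0.61) and (0.38, 1).
#'
#' @return List of two profile functions, \code{m1} and \code{m2}.
#' @export
cross_profiles <- function() {
  list(m1 = function(x) 0.38^x, m2 = function(x) 0.38^(1 - x))
}

#' Noisy morphogen gradient from a parametric profile
#'
#' Generates \code{values[t, j] = profile(x_j) * max(0, 1 + eps * xi)} with
#' i.i.d. standard normal \code{xi} per column and saved time; \code{eps = 0}
#' reproduces the deterministic profile at every time. This is the default
#' morphogen generator: it decouples the circuit analysis from any specific
#' gradient-formation kinetics while preserving the monotone noisy gradient
#' the circuits respond to.
#'
#' @param profile function of normalized position in `[0, 1]`, or a numeric
#'   vector of length \code{n_columns}; must be >= 0.
#' @param eps multiplicative noise amplitude (>= 0).
#' @param n_columns number of tissue columns.
#' @param times saved times at which an independent noise realization is
#'   drawn (default \code{0:100}).
#' @param seed RNG seed.
#' @return A \code{morphogen_field}.
#' @export
parametric_gradient <- function(profile, eps, n_columns, times = 0:100,
                                seed = 1L) {
  stopifnot_scalar(eps, "eps", nonneg = TRUE)
  x <- seq(0, 1, length.out = n_columns)
  base <- if (is.function(profile)) profile(x) else as.numeric(profile)
  if (length(base) != n_columns) stop("profile length != n_columns", call. = FALSE)
  if (any(base < 0)) stop("profile must be >= 0", call. = FALSE)
  nt <- length(times)
  vals <- with_seed(seed, {
    xi <- matrix(stats::rnorm(nt * n_columns), nt, n_columns)
    sweep(pmax(1 + eps * xi, 0), 2, base, `*`)
  })
  morphogen_field(vals, times, x, noise_amp = eps, kind = "PARAMETRIC",
                  base = base)
}

#' Pair of opposed noisy morphogen gradients
#'
#' Builds two fields with independent noise streams derived from one seed.
#' Default profiles are [cross_profiles()].
#'
#' @param profile1,profile2 profile functions (M1 non-increasing, M2
#'   non-decreasing).
#' @param eps noise amplitude applied to both fields.
#' @param n_columns,times,seed as in [parametric_gradient()].
#' @return List of two \code{morphogen_field}s, \code{m1} and \code{m2}.
#' @export
cross_gradients <- function(profile1 = cross_profiles()$m1,
                            profile2 = cross_profiles()$m2,
                            eps = 0, n_columns = 100L, times = 0:100,
                            seed = 1L) {
  list(m1 = parametric_gradient(profile1, eps, n_columns, times, seed = seed),
       m2 = parametric_gradient(profile2, eps, n_columns, times, seed = seed + 1L))
}

#' Parameters of the extracellular/intracellular morphogen exchange model
#'
#' Reaction-diffusion description of a diffusible morphogen (retinoic
#' acid-like) with extracellular diffusion, a localized production region,
#' first-order exchange between the extracellular and intracellular pools,
#' intracellular degradation, and multiplicative space-time white noise on
#' both pools.
#'
#' @param D_RA extracellular diffusion coefficient (length^2/time).
#' @param V_RA production profile: function of normalized position x returning
#'   production rate; default localizes production in the posterior (right)
#'   fifth of the axis.
#' @param k_A exchange rate between the pools (1/time).
#' @param beta extra extracellular loss factor (dimensionless, >= 0).
#' @param cyp intracellular degradation response: non-negative non-decreasing
#'   function of the intracellular level (1/time); default a constant basal
#'   rate.
#' @param eps_out,eps multiplicative noise amplitudes of the extracellular and
#'   intracellular pools.
#' @param leak posterior-boundary leak rate (Robin condition, flux =
#'   -leak times the extracellular level); default \code{0.1 * k_A}.
#' @return Object of class \code{ra_params}.
#' @export
ra_params <- function(D_RA = 0.02, V_RA = function(x) 2 * (x > 0.8),
                      k_A = 1, beta = 0.5, cyp = function(rin) rep(1, length(rin)),
                      eps_out = 0, eps = 0, leak = 0.1 * k_A) {
  stopifnot_scalar(D_RA, "D_RA", positive = TRUE)
  stopifnot_scalar(k_A, "k_A", positive = TRUE)
  stopifnot_scalar(beta, "beta", nonneg = TRUE)
  stopifnot_scalar(eps_out, "eps_out", nonneg = TRUE)
  stopifnot_scalar(eps, "eps", nonneg = TRUE)
  stopifnot_scalar(leak, "leak", nonneg = TRUE)
  structure(list(D_RA = D_RA, V_RA = V_RA, k_A = k_A, beta = beta, cyp = cyp,
                 eps_out = eps_out, eps = eps, leak = leak),
            class = "ra_params")
}

#' Simulate the stochastic morphogen reaction-diffusion model
#'
#' Explicit Euler-Maruyama integration of the coupled extracellular /
#' intracellular equations on a 1-D column grid. The anterior (left) boundary
#' is no-flux; the posterior (right) boundary leaks extracellular morphogen at
#' rate \code{leak}. The multiplicative space-time white noise is discretized
#' as independent Gaussian increments per column scaled by
#' \eqn{1/\sqrt{dt\,dx}}; states are clamped at 0. The intracellular pool is
#' the morphogen M seen by the cells. The intracellular and extracellular
#' noise terms use independent Wiener fields.
#'
#' @param params an \code{ra_params} object.
#' @param n_columns number of columns (>= 3).
#' @param dx column width; total axis length is \code{n_columns * dx}.
#' @param dt time step; must satisfy \code{dt <= dx^2 / (2 * D_RA)}.
#' @param t_end final time.
#' @param save_times times at which the intracellular profile is stored
#'   (default 20 times up to \code{t_end}).
#' @param seed RNG seed.
#' @param init_out,init_in initial levels (scalars or length-n vectors).
#' @return A \code{morphogen_field} (kind \code{"RA_PDE"}) of the
#'   intracellular pool, with the extracellular pool attached as attribute
#'   \code{"outer"}.
#' @export
simulate_ra_gradient <- function(params, n_columns = 100L, dx = 1 / n_columns,
                                 dt = 0.4 * dx^2 / params$D_RA, t_end = 50,
                                 save_times = NULL, seed = 1L,
                                 init_out = 0, init_in = 0) {
  stopifnot(inherits(params, "ra_params"))
  if (n_columns < 3) stop("n_columns must be >= 3", call. = FALSE)
  if (dt > dx^2 / (2 * params$D_RA) + 1e-12)
    stop("dt violates the explicit stability bound dx^2 / (2 * D_RA)",
         call. = FALSE)
  if (is.null(save_times)) save_times <- seq(t_end / 20, t_end, length.out = 20)
  x <- (seq_len(n_columns) - 0.5) * dx
  V <- params$V_RA(x / (n_columns * dx))
  u <- rep_len(init_out, n_columns)   # extracellular
  w <- rep_len(init_in, n_columns)    # intracellular
  n_steps <- ceiling(t_end / dt - 1e-9)
  keep <- matrix(0, length(save_times), n_columns)
  keep_out <- matrix(0, length(save_times), n_columns)
  isave <- 1L
  amp <- sqrt(dt / dx)
  with_seed(seed, {
    for (s in seq_len(n_steps)) {
      # diffusive fluxes at interior faces; no-flux left, leaky right
      flux <- c(0, -params$D_RA * diff(u) / dx, params$leak * u[n_columns])
      lap <- -diff(flux) / dx
      du <- lap + V - (1 + params$beta) * params$k_A * u + params$k_A * w
      dw <- params$k_A * u - (params$k_A + params$cyp(w)) * w
      u <- pmax(0, u + du * dt + params$eps_out * u * amp * stats::rnorm(n_columns))
      w <- pmax(0, w + dw * dt + params$eps * w * amp * stats::rnorm(n_columns))
      while (isave <= length(save_times) && save_times[isave] <= s * dt + 1e-9) {
        keep[isave, ] <- w
        keep_out[isave, ] <- u
        isave <- isave + 1L
      }
    }
  })
  out <- morphogen_field(keep, save_times, x / (n_columns * dx),
                         noise_amp = params$eps, kind = "RA_PDE")
  attr(out, "outer") <- keep_out
  out
}

#' Write a morphogen field as long-format CSV
#'
#' Columns: \code{time}, \code{x_index} (0-based), \code{value}.
#'
#' @param field a \code{morphogen_field}.
#' @param file output path.
#' @export
write_morphogen_csv <- function(field, file) {
  stopifnot(inherits(field, "morphogen_field"))
  d <- data.frame(time = rep(field$times, ncol(field$values)),
                  x_index = rep(seq_len(ncol(field$values)) - 1L,
                                each = nrow(field$values)),
                  value = as.vector(field$values))
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}
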