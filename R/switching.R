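#' Configuration of mean-first-passage-time estimation
#'
#' @param d multiplicative gene-expression noise amplitude (same convention
#'   as [sde_config()]: effective Wiener amplitude
#'   \code{d * sqrt(2 * noise_psd)}).
#' @param n_runs number of replicate trajectories (default 200).
#' @param r capture radius around the target attractor, max-norm (default
#'   0.1).
#' @param t_max censoring horizon in time units (default 1e5); runs that have
#'   not switched by then are censored and excluded from the mean.
#' @param dt Euler-Maruyama step.
#' @param seed RNG seed.
#' @param start optional \code{c(X, Y)} start; default: the X-attractor fixed
#'   point at the given morphogen level.
#' @param target optional \code{c(X, Y)} target; default: the Y-attractor
#'   fixed point.
#' @param noise_psd spectral level of the driving white noise, as in
#'   [sde_config()] (default 50).
#' @return Object of class \code{mfpt_config}.
#' @export
mfpt_config <- function(d = 0.02, n_runs = 200L, r = 0.1, t_max = 2e4,
                        dt = 0.01, seed = 1L, start = NULL, target = NULL,
                        noise_psd = 50) {
  stopifnot_scalar(d, "d", nonneg = TRUE)
  stopifnot_scalar(r, "r", positive = TRUE)
  stopifnot_scalar(t_max, "t_max", positive = TRUE)
  stopifnot_scalar(dt, "dt", positive = TRUE)
  stopifnot_scalar(noise_psd, "noise_psd", positive = TRUE)
  if (n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  structure(list(d = d, n_runs = as.integer(n_runs), r = r, t_max = t_max,
                 dt = dt, seed = seed, start = start, target = target,
                 noise_psd = noise_psd),
            class = "mfpt_config")
}

#' Mean first passage time from the X attractor to the Y attractor
#'
#' Integrates the multiplicative-noise SDE (the same integrator as the tissue
#' simulation, for a single cell) from the X attractor until the trajectory
#' first enters a max-norm ball of radius \code{r} around the Y attractor, or
#' until the censoring horizon. The mean first passage time is the average
#' over uncensored runs.
#'
#' @param params a \code{circuit_params}.
#' @param m morphogen level(s), as in [drift()].
#' @param cfg an \code{mfpt_config}.
#' @return Object of class \code{mfpt_result}: \code{mean} (Inf when every
#'   run is censored), \code{sem}, \code{n_censored}, \code{n_runs},
#'   \code{fpt} (per-run times, NA = censored), \code{bistable} flag and the
#'   start/target used.
#' @export
mfpt <- function(params, m, cfg = mfpt_config()) {
  stopifnot(inherits(params, "circuit_params"), inherits(cfg, "mfpt_config"))
  fp <- find_fixed_points(params, m)
  st <- fp[fp$stability == "stable", , drop = FALSE]
  bistable <- nrow(st) >= 2
  if (!bistable)
    warning("system is not bistable at this morphogen level; the result is a relaxation time")
  xa <- st[which.max(st$X - st$Y), , drop = FALSE]
  ya <- st[which.max(st$Y - st$X), , drop = FALSE]
  start <- if (!is.null(cfg$start)) cfg$start else c(xa$X, xa$Y)
  target <- if (!is.null(cfg$target)) cfg$target else c(ya$X, ya$Y)
  if (params$model_id == "MRSA_CROSS") {
    m1 <- if (is.list(m)) m[[1]] else m[1]; m2 <- if (is.list(m)) m[[2]] else m[2]
  } else { m1 <- m; m2 <- m }
  fpt <- with_seed(cfg$seed,
    .cpp_fpt(.model_code(params$model_id), .param_vec(params), m1, m2,
             cfg$d * sqrt(2 * cfg$noise_psd),
             start[1], start[2], target[1], target[2], cfg$r, cfg$n_runs,
             cfg$dt, cfg$t_max))
  ok <- !is.na(fpt)
  if (!any(ok)) warning("all runs censored at t_max; MFPT reported as Inf")
  structure(list(mean = if (any(ok)) mean(fpt[ok]) else Inf,
                 sem = if (sum(ok) > 1) stats::sd(fpt[ok]) / sqrt(sum(ok)) else NA_real_,
                 n_censored = sum(!ok), n_runs = cfg$n_runs, fpt = fpt,
                 bistable = bistable, start = start, target = target,
                 d = cfg$d, m = m),
            class = "mfpt_result")
}

#' @export
print.mfpt_result <- function(x, ...) {
  cat(sprintf("<mfpt_result> mean = %.4g (sem %.3g), %d/%d censored%s\n",
              x$mean, x$sem, x$n_censored, x$n_runs,
              if (x$bistable) "" else " [not bistable]"))
  invisible(x)
}

#' Sweep the mean switching time against a parameter or condition
#'
#' Runs [mfpt()] for each value of the sweep variable, splitting one seed
#' stream into independent per-condition substreams. \code{sweep_var} may be
#' the noise amplitude \code{"d"}, the morphogen level \code{"M"}, or any of
#' the kinetic parameters \code{"A"}, \code{"R"}, \code{"k_selfact"}.
#'
#' @param params base \code{circuit_params}.
#' @param sweep_var one of \code{"d"}, \code{"M"}, \code{"A"}, \code{"R"},
#'   \code{"k_selfact"}.
#' @param values sorted values of the sweep variable.
#' @param m morphogen level used when \code{sweep_var != "M"}.
#' @param cfg an \code{mfpt_config}; its \code{d} is used unless swept.
#' @param file optional CSV output path.
#' @return Data frame with columns \code{sweep_var}, \code{value}, \code{d},
#'   \code{mean}, \code{sem}, \code{n_censored}, \code{bistable}.
#' @export
mfpt_sweep <- function(params, sweep_var = c("d", "M", "A", "R", "k_selfact"),
                       values, m, cfg = mfpt_config(), file = NULL) {
  sweep_var <- match.arg(sweep_var)
  rows <- lapply(seq_along(values), function(i) {
    v <- values[i]
    p <- params; cnd_m <- m; cnd <- cfg
    if (sweep_var == "d") cnd$d <- v
    else if (sweep_var == "M") cnd_m <- v
    else p[[sweep_var]] <- v
    cnd$seed <- cfg$seed + 7919L * i
    res <- withCallingHandlers(mfpt(p, cnd_m, cnd),
                               warning = function(w) invokeRestart("muffleWarning"))
    data.frame(sweep_var = sweep_var, value = v, d = cnd$d, mean = res$mean,
               sem = res$sem, n_censored = res$n_censored,
               bistable = res$bistable)
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' Barrier heights and switching times across the bistable window
#'
#' For each morphogen level, solves the potential landscape, measures the
#' X-to-Y barrier height, and estimates the MFPT from trajectories, giving
#' the paired table behind the barrier-vs-switching-time relation.
#'
#' @param params a \code{circuit_params}.
#' @param m_values morphogen levels inside the bistable window.
#' @param fp_cfg an \code{fp_config} for the landscape solves.
#' @param mfpt_cfg an \code{mfpt_config}.
#' @param min_depth prominence threshold passed to [find_attractors()];
#'   lower it when sweeping close to the fold, where the X minimum is
#'   shallow.
#' @return Data frame with columns \code{m}, \code{delta_U}, \code{mfpt},
#'   \code{sem}, \code{n_censored}.
#' @export
barrier_vs_mfpt <- function(params, m_values, fp_cfg = fp_config(),
                            mfpt_cfg = mfpt_config(), min_depth = 0.5) {
  rows <- lapply(seq_along(m_values), function(i) {
    m <- m_values[i]
    ls <- solve_fokker_planck(params, m, fp_cfg)
    at <- find_attractors(ls, min_depth = min_depth)
    dU <- if (nrow(at) >= 2) {
      xa <- at[which.max(at$X - at$Y), ]; ya <- at[which.max(at$Y - at$X), ]
      barrier(ls, xa, ya)$delta_U
    } else NA_real_
    cnd <- mfpt_cfg; cnd$seed <- mfpt_cfg$seed + 104729L * i
    res <- withCallingHandlers(mfpt(params, m, cnd),
                               warning = function(w) invokeRestart("muffleWarning"))
    data.frame(m = m, delta_U = dU, mfpt = res$mean, sem = res$sem,
               n_censored = res$n_censored)
  })
  do.call(rbind, rows)
}

#' First passage times on the 1-D quartic double well
#'
#' Benchmark \eqn{dx = -U'(x)\,dt + \sqrt{2D}\,dW} with
#' \eqn{U = (x^2 - 1)^2}: escape from the left well at x = -1 into a ball of
#' radius \code{r} around x = +1. At small D the mean agrees with the Kramers
#' closed form [kramers_mfpt()].
#'
#' @param D additive noise intensity.
#' @param n_runs,dt,t_max,seed as in [mfpt_config()].
#' @param r capture radius (default 0.1).
#' @return Numeric vector of first passage times (NA = censored).
#' @export
mfpt_double_well <- function(D, n_runs = 200L, dt = 0.005, t_max = 1e5,
                             seed = 1L, r = 0.1) {
  stopifnot_scalar(D, "D", positive = TRUE)
  with_seed(seed, .cpp_fpt_doublewell(D, n_runs, dt, t_max, -1, 1, r))
}

#' Kramers escape time for the quartic double well
#'
#' Closed-form small-noise mean escape time
#' \deqn{\tau \approx \frac{2\pi}{\sqrt{U''(x_{min})\,|U''(x_{saddle})|}}
#' \exp(\Delta U / D)}
#' for \eqn{U = (x^2-1)^2} (so \eqn{U''(\pm 1) = 8}, \eqn{U''(0) = -4},
#' \eqn{\Delta U = 1}).
#'
#' @param D additive noise intensity.
#' @return Predicted mean escape time.
#' @export
kramers_mfpt <- function(D) {
  2 * pi / sqrt(8 * 4) * exp(1 / D)
}
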