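#' Configuration of random parameter perturbation
#'
#' @param sigma relative perturbation amplitude (default 0.1).
#' @param n_replicates number of perturbed replicates (default 100; reduce
#'   for quick runs).
#' @param which parameter names to perturb; default: all kinetic constants of
#'   the variant, excluding the Hill coefficient \code{n}.
#' @param perturb_n also perturb the (integer, structural) Hill coefficient;
#'   off by default.
#' @param seed RNG seed.
#' @return Object of class \code{perturbation_config}.
#' @export
perturbation_config <- function(sigma = 0.1, n_replicates = 100L,
                                which = NULL, perturb_n = FALSE, seed = 1L) {
  stopifnot_scalar(sigma, "sigma", nonneg = TRUE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  structure(list(sigma = sigma, n_replicates = as.integer(n_replicates),
                 which = which, perturb_n = perturb_n, seed = seed),
            class = "perturbation_config")
}

#' Randomly perturb a circuit parameter set
#'
#' Each selected parameter p is replaced by
#' \code{p * max(0.01, 1 + sigma * xi)} with independent standard normal xi
#' (multiplicative Gaussian, truncated at 1\% of the base value so every rate
#' stays positive). \code{R} is additionally clipped to `[0, 1]`. Deterministic
#' under the seed.
#'
#' @param params base \code{circuit_params}.
#' @param cfg a \code{perturbation_config}; its \code{seed} is used.
#' @return A perturbed \code{circuit_params}.
#' @export
perturb_params <- function(params, cfg = perturbation_config()) {
  stopifnot(inherits(params, "circuit_params"),
            inherits(cfg, "perturbation_config"))
  sel <- if (is.null(cfg$which)) .perturbable(params) else cfg$which
  if (cfg$perturb_n) sel <- c(sel, "n")
  p <- params
  with_seed(cfg$seed, {
    xi <- stats::rnorm(length(sel))
    for (i in seq_along(sel)) {
      nm <- sel[i]
      val <- p[[nm]] * max(0.01, 1 + cfg$sigma * xi[i])
      if (nm == "R") val <- min(max(val, 0), 1)
      if (nm == "n") val <- max(1L, as.integer(round(val)))
      p[[nm]] <- val
    }
  })
  p
}

#' Paired robustness comparison of circuit topologies
#'
#' For each model and replicate: perturb the calibrated parameter set
#' (sigma-relative Gaussian), simulate the tissue on a shared morphogen
#' realization, and record the sharpening-index trace. Replicates are paired
#' across models: identical grid, morphogen field seeds, gene-noise seeds,
#' noise level and save times; only the circuit drift (and its own
#' perturbation draw) differs. Replicates whose perturbed set is no longer
#' bistable at the variant's intermediate reference morphogen level are
#' flagged and kept.
#'
#' @param models character vector of variant names (default the three
#'   single-gradient topologies).
#' @param grid \code{c(n_rows, n_columns)} (default 10 x 30).
#' @param cfg an \code{sde_config} shared by all models.
#' @param pert a \code{perturbation_config}.
#' @param eps amplitude of the quenched per-cell morphogen sensing noise
#'   (default 0.06).
#' @param profile morphogen profile (default [linear_profile()]).
#' @return Object of class \code{comparison_report}: per-model mean/median SI
#'   trace with SEM, terminal mean SI, count of non-bistable replicates, and
#'   full per-replicate terminal values.
#' @export
compare_models <- function(models = c("MRSA", "SA", "MR"),
                           grid = c(10L, 30L), cfg = sde_config(),
                           pert = perturbation_config(), eps = 0.06,
                           profile = linear_profile()) {
  n_rep <- pert$n_replicates
  times <- cfg$save_times
  res <- lapply(seq_along(models), function(mi) {
    mdl <- models[mi]
    base <- default_params(mdl)
    mid_m <- reference_m_levels(mdl)[["mid"]]
    si <- matrix(NA_integer_, n_rep, length(times))
    lost <- logical(n_rep)
    for (r in seq_len(n_rep)) {
      p <- perturb_params(base, perturbation_config(
        sigma = pert$sigma, which = pert$which, perturb_n = pert$perturb_n,
        seed = pert$seed + 1000L * mi + r))
      fp <- find_fixed_points(p, mid_m)
      lost[r] <- sum(fp$stability == "stable") < 2
      fld <- parametric_gradient(profile, eps, grid[2], times = 0,
                                 seed = pert$seed + 500000L + r)
      tcfg <- cfg; tcfg$seed <- pert$seed + 900000L + r
      ts <- simulate_tissue(p, fld, tcfg, n_rows = grid[1])
      si[r, ] <- si_trace(ts)$si
    }
    list(model = mdl, si = si, lost = lost)
  })
  traces <- lapply(res, function(x) data.frame(
    time = times,
    mean_si = colMeans(x$si),
    median_si = apply(x$si, 2, stats::median),
    sem = apply(x$si, 2, stats::sd) / sqrt(nrow(x$si))))
  names(traces) <- models
  structure(list(models = models, times = times, traces = traces,
                 terminal = vapply(res, function(x) mean(x$si[, ncol(x$si)]), 0),
                 terminal_by_rep = lapply(res, function(x) x$si[, ncol(x$si)]),
                 n_lost_bistability = vapply(res, function(x) sum(x$lost), 0L),
                 sigma = pert$sigma, n_replicates = n_rep, eps = eps,
                 grid = grid, seed = pert$seed),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> sigma = %g, %d replicates, grid %d x %d\n",
              x$sigma, x$n_replicates, x$grid[1], x$grid[2]))
  for (i in seq_along(x$models))
    cat(sprintf("  %-5s terminal mean SI = %.2f (%d replicates lost bistability)\n",
                x$models[i], x$terminal[i], x$n_lost_bistability[i]))
  invisible(x)
}

#' Plot sharpening-index traces of a model comparison
#'
#' @param x a \code{comparison_report}.
#' @param ... passed to \code{matplot}.
#' @export
plot.comparison_report <- function(x, ...) {
  m <- sapply(x$traces, function(tr) tr$mean_si)
  graphics::matplot(x$times, m, type = "b", pch = 16, lty = 1, log = "x",
                    xlab = "time", ylab = "mean SI", col = seq_along(x$models),
                    ...)
  graphics::legend("topright", legend = x$models, col = seq_along(x$models),
                   lty = 1, pch = 16, bty = "n")
  invisible(x)
}

#' Terminal sharpening index over a noise grid
#'
#' Terminal mean SI per (gene-noise d, amplitude-ratio L) cell, with the
#' morphogen noise amplitude set to \code{eps = L * d}. Each cell averages
#' \code{n_replicates} paired simulations.
#'
#' @param params a \code{circuit_params} (unperturbed).
#' @param d_values gene-expression noise amplitudes.
#' @param L_values amplitude ratios \code{L = eps / d}.
#' @param grid \code{c(n_rows, n_columns)}.
#' @param cfg an \code{sde_config} (its \code{d} is overridden per cell).
#' @param n_replicates replicates per cell (default 10).
#' @param profile morphogen profile.
#' @param eps0 morphogen sensing noise used when \code{d = 0} (the ratio is
#'   undefined there); default 0.06.
#' @return Matrix of terminal mean SI, rows = d_values, cols = L_values.
#' @export
noise_grid <- function(params, d_values, L_values, grid = c(10L, 30L),
                       cfg = sde_config(), n_replicates = 10L,
                       profile = linear_profile(), eps0 = 0.06) {
  out <- matrix(NA_real_, length(d_values), length(L_values),
                dimnames = list(paste0("d=", d_values), paste0("L=", L_values)))
  for (i in seq_along(d_values)) for (j in seq_along(L_values)) {
    d <- d_values[i]
    eps <- if (d > 0) L_values[j] * d else eps0
    term <- vapply(seq_len(n_replicates), function(r) {
      fld <- parametric_gradient(profile, eps, grid[2], times = 0,
                                 seed = cfg$seed + 500000L + r)
      tcfg <- cfg; tcfg$d <- d; tcfg$seed <- cfg$seed + 900000L + r
      ts <- simulate_tissue(params, fld, tcfg, n_rows = grid[1])
      tr <- si_trace(ts)
      tr$si[nrow(tr)]
    }, 0L)
    out[i, j] <- mean(term)
  }
  out
}
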