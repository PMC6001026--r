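#' Configuration of the stochastic tissue simulation
#'
#' @param d gene-expression noise amplitude: the multiplicative noise term is
#'   \eqn{d\,x\,\zeta} with white noise \eqn{\zeta} of correlation
#'   \eqn{\langle\zeta(t)\zeta(t')\rangle = 2 D_\zeta \delta(t-t')}, so the
#'   effective Wiener amplitude is \code{d * sqrt(2 * noise_psd)} (>= 0).
#' @param dt Euler-Maruyama step (default 0.01).
#' @param save_times times at which the tissue state is stored; the last one
#'   is the final time (default \code{c(10, 50, 100, 200, 500, 1000)}).
#' @param seed RNG seed.
#' @param init_mode \code{"X_HIGH"} starts every cell near the X state,
#'   \code{(X0, Y0) = (0.5 + s N(0,1), 0.01)}; \code{"Y_HIGH"} mirrors it.
#' @param s initial-condition jitter magnitude (default 0.05).
#' @param noise_psd spectral level \eqn{D_\zeta} of the driving white noise
#'   (default 50, calibrated once together with the circuit constants; see
#'   the package vignette).
#' @return Object of class \code{sde_config}.
#' @export
sde_config <- function(d = 0.01, dt = 0.01,
                       save_times = c(10, 50, 100, 200, 500, 1000),
                       seed = 1L, init_mode = c("X_HIGH", "Y_HIGH"),
                       s = 0.05, noise_psd = 50) {
  init_mode <- match.arg(init_mode)
  stopifnot_scalar(d, "d", nonneg = TRUE)
  stopifnot_scalar(dt, "dt", positive = TRUE)
  stopifnot_scalar(s, "s", nonneg = TRUE)
  stopifnot_scalar(noise_psd, "noise_psd", positive = TRUE)
  if (is.unsorted(save_times) || any(save_times < 0))
    stop("save_times must be non-negative and ascending", call. = FALSE)
  structure(list(d = d, dt = dt, save_times = as.numeric(save_times),
                 t_end = max(save_times), seed = seed, init_mode = init_mode,
                 s = s, noise_psd = noise_psd),
            class = "sde_config")
}

#' Simulate a 2-D tissue of independent stochastic cells
#'
#' Each cell of the rows x columns grid evolves by the multiplicative-noise
#' SDE \eqn{dX = F_X\,dt + d\,X\,\sqrt{2 D_\zeta}\,dW} (and likewise for Y), driven by its
#' column's morphogen level. Morphogen values are piecewise constant between
#' the field's saved times and shared by all rows of a column (the morphogen
#' is extracellular); gene-expression noise is independent per cell, gene and
#' step. States are clamped at 0.
#'
#' @param params a \code{circuit_params} object.
#' @param field a \code{morphogen_field}; its column count fixes the number of
#'   tissue columns.
#' @param cfg an \code{sde_config}.
#' @param n_rows number of rows (default 10).
#' @param field2 second morphogen field, required for \code{MRSA_CROSS}.
#' @param morphogen_noise \code{"per_cell"} (default): each cell senses its
#'   column's deterministic morphogen level with its own multiplicative noise
#'   of amplitude \code{field$noise_amp}, redrawn at every morphogen time
#'   step (receptor-level sensing noise; requires a field carrying its
#'   deterministic \code{base} profile). \code{"per_column"}: all rows share
#'   the field's realized per-column values (a purely extracellular
#'   realization).
#' @return Object of class \code{tissue_state}: arrays \code{X}, \code{Y} and
#'   \code{labels} of shape (n_times, n_rows, n_columns), plus times and
#'   configuration provenance.
#' @export
simulate_tissue <- function(params, field, cfg = sde_config(), n_rows = 10L,
                            field2 = NULL,
                            morphogen_noise = c("per_cell", "per_column")) {
  stopifnot(inherits(params, "circuit_params"),
            inherits(field, "morphogen_field"),
            inherits(cfg, "sde_config"))
  morphogen_noise <- match.arg(morphogen_noise)
  cross <- params$model_id == "MRSA_CROSS"
  if (cross && is.null(field2))
    stop("MRSA_CROSS requires two morphogen fields", call. = FALSE)
  if (!cross && !is.null(field2))
    stop(params$model_id, " takes a single morphogen field", call. = FALSE)
  nc <- ncol(field$values)
  if (!is.null(field2) && ncol(field2$values) != nc)
    stop("the two morphogen fields must share the column grid", call. = FALSE)
  per_cell <- morphogen_noise == "per_cell"
  if (per_cell && is.null(field$base)) {
    if (field$noise_amp > 0)
      stop("per-cell morphogen sensing needs a field with a deterministic 'base' profile; use parametric_gradient() or morphogen_noise = \"per_column\"",
           call. = FALSE)
    per_cell <- FALSE  # noiseless field: modes coincide
  }
  if (per_cell) {
    m1 <- matrix(field$base, 1, nc)
    m2 <- if (is.null(field2)) matrix(0, 1, nc) else matrix(field2$base, 1, nc)
    if (!is.null(field2) && is.null(field2$base))
      stop("both fields need 'base' profiles for per-cell sensing", call. = FALSE)
  } else {
    m1 <- field$values
    m2 <- if (is.null(field2)) matrix(0, 1, nc) else field2$values
  }
  out <- with_seed(cfg$seed, {
    hi <- 0.5 + cfg$s * stats::rnorm(n_rows * nc)
    if (cfg$init_mode == "X_HIGH") {
      X0 <- matrix(hi, n_rows, nc); Y0 <- matrix(0.01, n_rows, nc)
    } else {
      X0 <- matrix(0.01, n_rows, nc); Y0 <- matrix(hi, n_rows, nc)
    }
    .cpp_simulate_tissue(.model_code(params$model_id), .param_vec(params),
                         m1, m2, field$times, pmax(X0, 0),
                         pmax(Y0, 0), cfg$d * sqrt(2 * cfg$noise_psd),
                         cfg$dt, cfg$save_times, per_cell, field$noise_amp)
  })
  labels <- array(ifelse(out$X > out$Y, 1L, 2L), dim = dim(out$X))
  structure(list(X = out$X, Y = out$Y, labels = labels,
                 times = cfg$save_times, params = params, cfg = cfg,
                 morphogen_kind = field$kind, eps = field$noise_amp),
            class = "tissue_state")
}

#' @export
print.tissue_state <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf("<tissue_state> %s: %d rows x %d columns, %d saved times (t = %g..%g)\n",
              x$params$model_id, d[2], d[3], d[1], min(x$times), max(x$times)))
  tr <- si_trace(x)
  cat("  sharpening index:", paste(sprintf("t=%g:%d", tr$time, tr$si),
                                   collapse = "  "), "\n")
  invisible(x)
}

#' Plot a tissue label map
#'
#' Blue cells express X, red cells express Y.
#'
#' @param x a \code{tissue_state}.
#' @param t_index index into the saved times (default: last).
#' @param ... passed to \code{image}.
#' @export
plot.tissue_state <- function(x, t_index = dim(x$X)[1], ...) {
  lab <- t(matrix(x$labels[t_index, , ], dim(x$X)[2], dim(x$X)[3]))
  graphics::image(seq_len(nrow(lab)), seq_len(ncol(lab)), lab,
                  col = c("#2166AC", "#B2182B"), zlim = c(1, 2),
                  xlab = "column", ylab = "row",
                  main = sprintf("%s, t = %g", x$params$model_id,
                                 x$times[t_index]), ...)
  invisible(x)
}

#' Classify a cell's expression state
#'
#' \code{X_STATE} when X > Y, otherwise \code{Y_STATE} (ties go to Y).
#'
#' @param X,Y non-negative expression levels (vectors or arrays of equal
#'   shape).
#' @return Factor (or factor-valued array) with levels \code{X_STATE},
#'   \code{Y_STATE}.
#' @export
classify_expression <- function(X, Y) {
  if (any(X < 0) || any(Y < 0)) stop("expression must be >= 0", call. = FALSE)
  factor(ifelse(X > Y, "X_STATE", "Y_STATE"),
         levels = c("X_STATE", "Y_STATE"))
}

#' Sharpening index of a label grid
#'
#' The number of tissue columns containing both an X-expressing and a
#' Y-expressing cell. A smaller value means a sharper boundary; 0 means every
#' column is homogeneous.
#'
#' @param labels rows x columns matrix of binary labels (integer 1/2, the
#'   \code{labels} slice of a \code{tissue_state}, or the factor returned by
#'   [classify_expression()]).
#' @return Integer count of mixed columns.
#' @export
sharpening_index <- function(labels) {
  if (is.factor(labels)) labels <- array(as.integer(labels), dim = dim(labels))
  if (is.null(dim(labels)) || any(dim(labels) == 0))
    stop("'labels' must be a non-empty rows x columns matrix", call. = FALSE)
  mixed <- apply(labels, 2, function(col) length(unique(col)) > 1)
  sum(mixed)
}

#' Sharpening-index time course of a tissue simulation
#'
#' @param tissue a \code{tissue_state} with at least one saved time.
#' @return Data frame with columns \code{time} and \code{si}.
#' @export
si_trace <- function(tissue) {
  stopifnot(inherits(tissue, "tissue_state"))
  nt <- dim(tissue$labels)[1]
  si <- vapply(seq_len(nt), function(t)
    sharpening_index(matrix(tissue$labels[t, , ], dim(tissue$labels)[2])),
    integer(1))
  data.frame(time = tissue$times, si = si)
}
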