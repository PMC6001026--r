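#' Deterministic drift field of a circuit variant
#'
#' Evaluates the right-hand side (dX/dt, dY/dt) of the two-gene ODE system at
#' the given expression state(s) and morphogen level(s). All regulation terms
#' are Hill functions with shared threshold \code{S} and coefficient \code{n}:
#' self-activation enters as \eqn{X^n/(S^n + X^n)}, repression of X by Y as
#' the factor \eqn{1 - R + R\,S^n/(S^n + Y^n)}, and the morphogen input as
#' \eqn{a_1 M^n/(S^n + M^n)}. Each gene decays at rate \code{k}.
#'
#' @param params a \code{circuit_params} object.
#' @param X,Y non-negative expression levels (vectors of equal length).
#' @param m morphogen level: a non-negative scalar/vector for single-input
#'   variants, or a list \code{list(M1, M2)} (or length-2 vector) for
#'   \code{MRSA_CROSS}.
#' @return A list with numeric components \code{fx} and \code{fy}.
#' @examples
#' p <- default_params("MRSA")
#' drift(p, X = 0, Y = 0, m = 0)   # basal synthesis only
#' @export
drift <- function(params, X, Y, m) {
  stopifnot(inherits(params, "circuit_params"))
  if (any(X < 0) || any(Y < 0))
    stop("expression state must be non-negative", call. = FALSE)
  cross <- params$model_id == "MRSA_CROSS"
  if (cross) {
    if (is.list(m)) { m1 <- m[[1]]; m2 <- m[[2]] }
    else if (length(m) == 2L) { m1 <- m[1]; m2 <- m[2] }
    else stop("MRSA_CROSS takes two morphogen levels (M1, M2)", call. = FALSE)
  } else {
    if (is.list(m) || (length(m) > 1L && length(m) != length(X)))
      stop(params$model_id, " takes a single morphogen level", call. = FALSE)
    m1 <- m; m2 <- m
  }
  if (any(m1 < 0) || any(m2 < 0))
    stop("morphogen level must be non-negative", call. = FALSE)
  .cpp_drift(.model_code(params$model_id), .param_vec(params),
             as.numeric(X), as.numeric(Y), as.numeric(m1), as.numeric(m2))
}

#' Trapping box of the drift field
#'
#' Upper bounds beyond which each drift component is strictly negative:
#' synthesis saturates while degradation grows linearly, so trajectories and
#' probability mass are confined to \code{[0, xmax] x [0, ymax]}.
#'
#' @param params a \code{circuit_params} object.
#' @return Numeric vector \code{c(xmax, ymax)}.
#' @export
trapping_box <- function(params) {
  p <- params
  with(p, switch(model_id,
    MRSA = c((a * (b / A + 1) + a1) / k, (a * (b + 1) + a1) / k),
    SA = c((a * b1 + a1) / k, (a * (b2 + k_selfact) + a1) / k),
    MR = c((a * b / A + a1) / k, (a * b + a1) / k),
    MRSA_CROSS = c((a * (b / A + 1) + a1) / k, (a * (b + 1) + a1) / k)))
}
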