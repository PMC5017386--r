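#' Scaled conjugate gradient minimization
#'
#' Batch minimizer in the style of Moller's scaled conjugate gradient:
#' conjugate search directions, a Hessian-vector product approximated by a
#' one-sided finite difference of the gradient (step `sigma / |p|`), and a
#' Levenberg-Marquardt scaling `lambda` adapted from the comparison ratio
#' between predicted and actual objective decrease. No line searches are
#' performed. Used here to train the per-gesture networks with
#' cross-entropy, but usable on any differentiable scalar objective.
#'
#' @param fn Objective: function of a numeric parameter vector returning a
#'   scalar.
#' @param gr Gradient of `fn`.
#' @param x0 Numeric start vector.
#' @param max_iter Iteration cap.
#' @param grad_tol Stop when the gradient norm falls below this.
#' @param sigma Finite-difference scale for the Hessian-vector
#'   approximation.
#' @param lambda0 Initial Levenberg-Marquardt scale.
#' @return A list: `par` (best parameters seen), `value`, `trace` (tibble
#'   with one row per accepted step: `iter`, `value`, `grad_norm`),
#'   `iterations`, `converged` (gradient tolerance reached).
#' @examples
#' sq <- function(x) sum((x - c(1, -2))^2)
#' gsq <- function(x) 2 * (x - c(1, -2))
#' scg_minimize(sq, gsq, c(0, 0))$par
#' @export
scg_minimize <- function(fn, gr, x0, max_iter = 300L, grad_tol = 1e-6,
                         sigma = 1e-4, lambda0 = 1e-6) {
  w <- as.numeric(x0)
  f_w <- fn(w)
  if (!is.finite(f_w)) {
    abort("objective is not finite at the starting point",
          class = "handwashr_numeric_error")
  }
  g <- gr(w)
  r <- -g
  p <- r
  lambda <- lambda0
  lambda_bar <- 0
  success <- TRUE
  n <- length(w)
  trace_iter <- integer(0); trace_val <- numeric(0); trace_gn <- numeric(0)
  best_w <- w; best_f <- f_w
  delta <- 0
  k <- 0L
  converged <- FALSE
  while (k < max_iter) {
    k <- k + 1L
    p2 <- sum(p * p)
    if (p2 < .Machine$double.eps) {
      # degenerate search direction (can happen right after a near-exact
      # step): restart along steepest descent, or stop if the gradient
      # itself is below tolerance
      if (sqrt(sum(r * r)) < grad_tol) {
        converged <- TRUE
        break
      }
      p <- r
      success <- TRUE
      p2 <- sum(p * p)
    }
    pnorm <- sqrt(p2)
    if (success) {
      # second-order information along p via finite-differenced gradient
      sk <- sigma / pnorm
      s <- (gr(w + sk * p) - g) / sk
      delta <- sum(p * s)
    }
    # scale: make the curvature estimate positive definite
    delta_s <- delta + (lambda - lambda_bar) * p2
    if (delta_s <= 0) {
      lambda_bar <- 2 * (lambda - delta / p2)
      delta_s <- -delta + lambda * p2
      lambda <- lambda_bar
    }
    mu <- sum(p * r)
    alpha <- mu / delta_s
    f_new <- fn(w + alpha * p)
    Delta <- 2 * delta_s * (f_w - f_new) / mu^2
    if (is.finite(Delta) && Delta >= 0) {
      # accepted step
      w <- w + alpha * p
      f_w <- f_new
      g_new <- gr(w)
      r_new <- -g_new
      lambda_bar <- 0
      success <- TRUE
      if (f_w < best_f) { best_f <- f_w; best_w <- w }
      gn <- sqrt(sum(r_new^2))
      trace_iter <- c(trace_iter, k); trace_val <- c(trace_val, f_w)
      trace_gn <- c(trace_gn, gn)
      if (gn < grad_tol) {
        r <- r_new
        converged <- TRUE
        break
      }
      if (k %% n == 0) {
        p <- r_new                           # restart with steepest descent
      } else {
        beta <- (sum(r_new^2) - sum(r_new * r)) / mu
        p <- r_new + beta * p
      }
      r <- r_new
      g <- g_new
      if (Delta >= 0.75) lambda <- lambda / 4
    } else {
      lambda_bar <- lambda
      success <- FALSE
    }
    if (!is.finite(Delta) || Delta < 0.25) {
      lambda <- lambda + delta_s * (1 - max(Delta, 0, na.rm = TRUE)) / p2
      if (!is.finite(lambda) || lambda > 1e100) break
    }
  }
  list(par = best_w, value = best_f,
       trace = tibble(iter = trace_iter, value = trace_val,
                      grad_norm = trace_gn),
       iterations = k, converged = converged)
}
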