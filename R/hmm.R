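#' Build the left-to-right WHO routine chain HMM
#'
#' The routine is a fixed sequence of nine gestures, so the hidden states
#' form a chain: each state may only persist (`self_prob`) or advance to its
#' immediate successor (`1 - self_prob`); the final state is absorbing.
#' Observations are the classifier's hard frame labels, emitted through a
#' discrete confusion-style matrix: the true gesture is observed with
#' probability `emission_correct`, anything else with the remainder spread
#' evenly. At 50 Hz the defaults make a state switch cost about
#' `log(0.005 / 0.995)`, so isolated misclassified frames cannot pull the
#' decoded path off the routine.
#'
#' @param self_prob Self-transition probability in (0, 1); default 0.995.
#' @param emission_correct Probability that a state emits its own label, in
#'   (1/9, 1); default 0.9.
#' @param start_at_first If `TRUE` (default) the initial distribution is
#'   concentrated on G1 (the routine starts at palm cleaning); otherwise
#'   uniform.
#' @param log_floor Probability floor applied before logs in decoding.
#' @return A `chain_hmm` with transition matrix `A`, emission matrix `B`,
#'   initial distribution `pi`.
#' @export
build_who_chain <- function(self_prob = 0.995, emission_correct = 0.9,
                            start_at_first = TRUE, log_floor = 1e-12) {
  if (self_prob <= 0 || self_prob >= 1) {
    abort("self_prob must be in (0, 1)", class = "handwashr_validation_error")
  }
  if (emission_correct <= 1 / 9 || emission_correct >= 1) {
    abort("emission_correct must be in (1/9, 1)",
          class = "handwashr_validation_error")
  }
  n <- 9L
  A <- matrix(0, n, n, dimnames = list(gesture_codes(), gesture_codes()))
  for (i in seq_len(n - 1)) {
    A[i, i] <- self_prob
    A[i, i + 1] <- 1 - self_prob
  }
  A[n, n] <- 1
  B <- matrix((1 - emission_correct) / 8, n, n,
              dimnames = list(gesture_codes(), gesture_codes()))
  diag(B) <- emission_correct
  pi0 <- if (start_at_first) c(1, rep(0, n - 1)) else rep(1 / n, n)
  names(pi0) <- gesture_codes()
  structure(list(n_states = n, A = A, B = B, pi = pi0, log_floor = log_floor),
            class = "chain_hmm")
}

#' @export
print.chain_hmm <- function(x, ...) {
  cat(sprintf("<chain_hmm> 9-state left-to-right chain: self %.4g, advance %.4g, emission correct %.4g\n",
              x$A[1, 1], x$A[1, 2], x$B[1, 1]))
  invisible(x)
}

#' Log-space parameters of a chain HMM
#'
#' Positive probabilities are floored at `log_floor` before taking logs so
#' that rounding never produces `-Inf` for a possible event; structural
#' zeros of the transition matrix (the transitions the left-to-right chain
#' forbids) stay impossible (`-Inf`), which is what guarantees decoded
#' paths are monotone in routine order. The state-value recursion itself
#' never becomes `-Inf`: every state is reachable through the floored
#' emission and initial probabilities.
#'
#' @param hmm A [build_who_chain()] model.
#' @return A list with `logA`, `logB`, `logpi`.
#' @export
hmm_log_params <- function(hmm) {
  logm <- function(M) ifelse(M > 0, log(pmax(M, hmm$log_floor)), -Inf)
  list(logA = logm(hmm$A),
       logB = log(pmax(hmm$B, hmm$log_floor)),
       logpi = log(pmax(hmm$pi, hmm$log_floor)))
}

#' Viterbi decoding of a frame-label sequence
#'
#' Returns the maximum a posteriori hidden-state path under the chain model,
#' computed in log space with the probabilities of [hmm_log_params()]. Ties
#' are broken toward the lower gesture ordinal, making decoding
#' deterministic.
#'
#' @param observations Character vector or factor of observed gesture codes.
#' @param hmm A [build_who_chain()] model.
#' @return A factor of decoded gesture codes, same length as
#'   `observations`.
#' @export
viterbi_decode <- function(observations, hmm) {
  stopifnot(inherits(hmm, "chain_hmm"))
  obs <- as.integer(gesture_factor(observations))
  Tn <- length(obs)
  if (Tn == 0) {
    abort("observation sequence must be non-empty",
          class = "handwashr_validation_error")
  }
  lp <- hmm_log_params(hmm)
  logA <- lp$logA; logB <- lp$logB; logpi <- lp$logpi
  n <- hmm$n_states
  delta <- logpi + logB[, obs[1]]
  psi <- matrix(0L, n, Tn)
  if (Tn > 1) {
    for (t in 2:Tn) {
      cand <- delta + logA                    # cand[i, j] = delta[i] + logA[i, j]
      # which.max over rows per column, first (lowest ordinal) wins ties
      psi[, t] <- max.col(t(cand), ties.method = "first")
      delta <- cand[cbind(psi[, t], seq_len(n))] + logB[, obs[t]]
    }
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta)
  if (Tn > 1) {
    for (t in (Tn - 1):1) path[t] <- psi[path[t + 1], t + 1]
  }
  gesture_factor(gesture_codes()[path])
}

#' @rdname viterbi_decode
#' @param frame_labels Character vector or factor of per-frame classifier
#'   labels.
#' @return `smooth_predictions()` is a convenience wrapper returning the
#'   decoded (smoothed) label track; with the left-to-right chain the result
#'   is monotone non-decreasing in routine order, hence has at most 8 label
#'   switches.
#' @export
smooth_predictions <- function(frame_labels, hmm = build_who_chain()) {
  viterbi_decode(frame_labels, hmm)
}
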