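#' Plot a hyperparameter sweep
#'
#' Recognition rate of the raw classifier and of the HMM-smoothed sequence
#' against the swept hyperparameter, one line per stage.
#'
#' @param object A `sweep_result` from [run_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sweep_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
                              cols = c("mean_rate_ann", "mean_rate_hmm"),
                              names_to = "stage", values_to = "rate")
  long$stage <- ifelse(long$stage == "mean_rate_ann", "ANN", "HMM")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = 100 * .data$rate,
                                     colour = .data$stage)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = object$axis[1], y = "recognition rate [%]",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param report A `cv_report` from [run_cv()].
#' @param stage `"ann"` or `"hmm"`.
#' @return A ggplot heatmap of row-normalized recognition/error rates
#'   (rows = truth, columns = prediction).
#' @export
plot_confusion <- function(report, stage = c("ann", "hmm")) {
  stage <- match.arg(stage)
  cm <- confusion_matrix(report, stage)
  rates <- cm / pmax(rowSums(cm), 1)
  df <- as_tibble(as.table(rates), .name_repair = ~c("truth", "pred", "rate"))
  df$truth <- factor(df$truth, levels = rev(gesture_codes()))
  df$pred <- factor(df$pred, levels = gesture_codes())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$truth,
                                   fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rate)),
                       size = 2.6) +
    ggplot2::scale_fill_gradient(low = "white", high = "darkgreen",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "predicted", y = "true",
                  title = sprintf("Confusion (%s)", toupper(stage))) +
    ggplot2::theme_minimal()
}

#' Illustrate HMM smoothing of a frame-label track
#'
#' Shows the ground-truth gesture sequence, the raw per-frame classifier
#' output, and the Viterbi-smoothed sequence as step traces over time — the
#' smoothed track removes the isolated switches the chain model deems
#' implausible.
#'
#' @param truth,ann,hmm Equal-length gesture label vectors (truth, raw
#'   classifier output, smoothed output).
#' @param frame_rate Frames per second (default 50).
#' @return A ggplot.
#' @export
plot_smoothing <- function(truth, ann, hmm, frame_rate = IMU_RATE) {
  n <- length(truth)
  stopifnot(length(ann) == n, length(hmm) == n)
  df <- tibble(
    time = rep((seq_len(n) - 1) / frame_rate, 3),
    ordinal = c(gesture_ordinal(truth), gesture_ordinal(ann),
                gesture_ordinal(hmm)),
    track = factor(rep(c("truth", "ANN", "ANN + HMM"), each = n),
                   levels = c("truth", "ANN", "ANN + HMM")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$ordinal)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~track, ncol = 1) +
    ggplot2::scale_y_continuous(breaks = 0:8, labels = gesture_codes()) +
    ggplot2::labs(x = "time [s]", y = NULL) +
    ggplot2::theme_minimal()
}
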