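# Subunit prediction model for contrast-reversing patterned spots: if the
# only nonlinearity acts locally, before spatial pooling, the response to a
# patterned spot follows from the uniform-spot response alone — each
# receptive-field half contributes half of the corresponding full-spot
# response, and the two halves are summed linearly.

#' Predict the patterned-spot response from the uniform-spot response
#'
#' The 1-s cycle average of the uniform contrast-reversing spot is
#' multiplied by 0.5 and the parts from the first 500 ms (one contrast) and
#' the second 500 ms (the other) are summed; the full-cycle prediction is
#' two concatenated copies of this 500-ms trace.  By construction the same
#' prediction applies to every patterned layout (halves, quarters,
#' checkerboards), and no latency correction is applied: the reversing
#' patterned spot incurs the same response delay as the uniform spot.
#'
#' @param uniform_cycle_avg 1-s cycle average of the uniform reversing spot
#'   (first cycle dropped), sampled at `rate_hz`.
#' @param rate_hz sampling rate.
#' @return predicted full-cycle trace (same length as the input).
#' @export
predict_patterned_from_uniform <- function(uniform_cycle_avg, rate_hz) {
  n <- length(uniform_cycle_avg)
  if (n != round(rate_hz))
    stop(sprintf("cycle average has %d samples but one 1-s cycle at %g Hz needs %d",
                 n, rate_hz, round(rate_hz)))
  half <- n / 2
  pred_half <- 0.5 * (uniform_cycle_avg[seq_len(half)] +
                        uniform_cycle_avg[half + seq_len(half)])
  rep(pred_half, 2)
}

#' Accuracy of the patterned-spot prediction
#'
#' `1 - sum((V_pattern - V_pred)^2) / sum((V_uniform - mean(V_uniform))^2)`;
#' the prediction is first shifted to have the same mean as the measured
#' patterned-spot response (baseline drift).  The denominator normalizes by
#' the scale of a generic response of the cell rather than by the patterned
#' response itself, which is near zero for spatially linear cells.  Near 1
#' for matching traces, near 0 for unrelated ones.
#'
#' @param pattern_response measured cycle-averaged patterned-spot response
#'   (choose the pattern with the highest spatial nonlinearity index).
#' @param predicted prediction from [predict_patterned_from_uniform()].
#' @param uniform_response cycle-averaged uniform-spot response.
#' @return prediction accuracy (<= 1), `NA` when the uniform response has
#'   zero variance.
#' @export
prediction_accuracy <- function(pattern_response, predicted,
                                uniform_response) {
  stopifnot(length(pattern_response) == length(predicted))
  denom <- sum((uniform_response - mean(uniform_response))^2)
  if (denom == 0) return(NA_real_)
  pred <- predicted - mean(predicted) + mean(pattern_response)
  1 - sum((pattern_response - pred)^2) / denom
}
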