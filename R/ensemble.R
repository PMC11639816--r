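# Voting ensembles over fitted classifiers.

#' Soft/hard voting over fitted members
#'
#' Soft voting averages the members' predicted class probabilities
#' (unweighted) and picks the class with the highest mean; hard voting takes
#' a plurality over the members' predicted labels, breaking ties first by
#' the mean probability of the tied classes and then by the lowest class
#' index. A single-member "ensemble" reproduces that member exactly.
#'
#' @param members list of fitted models supporting
#'   `predict(m, x, type = "prob")`.
#' @param x feature matrix.
#' @param mode `"soft"` or `"hard"`.
#' @return list with `class` (0-based labels) and `prob` (mean probability
#'   matrix; for hard voting, provided for tie-breaking/inspection).
#' @export
vote <- function(members, x, mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  stopifnot(length(members) >= 1L)
  probs <- lapply(members, function(m) predict(m, x, type = "prob"))
  k <- unique(vapply(probs, ncol, integer(1)))
  if (length(k) != 1L)
    stop("members produce probability vectors of unequal dimension")
  mean_prob <- Reduce(`+`, probs) / length(probs)
  if (mode == "soft") {
    cls <- max.col(mean_prob, ties.method = "first") - 1L
  } else {
    labels <- vapply(probs, function(p) max.col(p, ties.method = "first"),
                     integer(nrow(mean_prob)))
    if (is.null(dim(labels))) labels <- matrix(labels, nrow = 1L)
    cls <- integer(nrow(labels))
    for (i in seq_len(nrow(labels))) {
      tab <- tabulate(labels[i, ], nbins = k)
      top <- which(tab == max(tab))
      if (length(top) > 1L) {
        # tie: prefer higher mean probability, then lower class index
        top <- top[order(-mean_prob[i, top], top)]
      }
      cls[i] <- top[1L] - 1L
    }
  }
  list(class = cls, prob = mean_prob)
}
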