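.check_trio <- function(preds) {
  preds <- as.data.frame(preds)
  if (nrow(preds) != 3L || !setequal(preds$kind, c("SVM", "RF", "NN")) ||
      anyDuplicated(preds$kind)) {
    stop("exactly one prediction per classifier kind (SVM, RF, NN) required")
  }
  if (!all(preds$class %in% c(-1L, 1L))) stop("classes must be -1 or +1")
  if (!all(preds$posterior >= 0.5 & preds$posterior <= 1)) {
    stop("posteriors must be the predicted-class probability in [0.5, 1]")
  }
  preds
}

#' Jury vote over the three classifiers
#'
#' Each classifier casts one vote; the majority class wins.
#'
#' @param preds data.frame with one row per classifier kind (SVM, RF, NN)
#'   and columns `kind`, `class`, `posterior`.
#' @return +1 or -1.
#' @export
jury_vote <- function(preds) {
  preds <- .check_trio(preds)
  if (sum(preds$class == 1L) >= 2L) 1L else -1L
}

#' Posterior-weighted consensus score
#'
#' The consensus score `c = sum_i p_i * class_i` over the three classifiers,
#' where `p_i` is each classifier's posterior probability for its predicted
#' class. Unlike the jury vote it ranks proteins within a class; the class
#' is +1 when `c > 0` and -1 otherwise (a score of exactly 0 is called
#' negative — no liability flag without positive evidence).
#'
#' @inheritParams jury_vote
#' @return list with `score` (in `[-3, 3]`) and `class`.
#' @export
consensus_vote <- function(preds) {
  preds <- .check_trio(preds)
  score <- sum(preds$posterior * preds$class)
  list(score = score, class = if (score > 0) 1L else -1L)
}

#' Red-flag vote
#'
#' Accepts the dissenting opinion: on a 2-1 split the minority class is
#' returned; on unanimity the unanimous class.
#'
#' @inheritParams jury_vote
#' @return +1 or -1.
#' @export
red_flag <- function(preds) {
  preds <- .check_trio(preds)
  n_pos <- sum(preds$class == 1L)
  if (n_pos == 3L) 1L
  else if (n_pos == 0L) -1L
  else if (n_pos == 2L) -1L
  else 1L
}

#' Combine three classifier predictions with all voting rules
#'
#' @inheritParams jury_vote
#' @return list of class `voting_result`: `jury_class`, `consensus_score`,
#'   `consensus_class`, `redflag_class`.
#' @export
combine_votes <- function(preds) {
  cons <- consensus_vote(preds)
  structure(list(jury_class = jury_vote(preds),
                 consensus_score = cons$score,
                 consensus_class = cons$class,
                 redflag_class = red_flag(preds)),
            class = "voting_result")
}
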