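#' Consensus label from three raters with a re-presentation round
#'
#' Implements the two-round consensus rule used to turn three independent
#' expert judgements into one ground-truth label. A recording is a response
#' only if the applicable round is unanimously positive: three first-round
#' positives decide immediately; exactly two positives trigger a second,
#' re-presented round whose unanimity decides; one or zero positives decide
#' "noise" with no second round.
#'
#' @param firstRound logical vector of exactly 3 first-round labels.
#' @param secondRound optional logical vector of exactly 3 second-round
#'   labels; must be supplied exactly when the first round was a 2-of-3
#'   split. Supplying it when not required is an error; omitting it when
#'   required leaves `final = NA` (pending).
#' @return A list with `final` (logical, `NA` while a required second round
#'   is missing) and `needsSecondRound` (logical).
#' @examples
#' consensusLabel(c(TRUE, TRUE, TRUE))
#' consensusLabel(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE))
#' consensusLabel(c(TRUE, FALSE, FALSE))
#' @export
consensusLabel <- function(firstRound, secondRound = NULL) {
  stopifnot(is.logical(firstRound), length(firstRound) == 3L,
            !anyNA(firstRound))
  npos <- sum(firstRound)
  if (npos == 3L) {
    if (!is.null(secondRound))
      stop("secondRound supplied but the first round was unanimous")
    return(list(final = TRUE, needsSecondRound = FALSE))
  }
  if (npos <= 1L) {
    if (!is.null(secondRound))
      stop("secondRound supplied but no second round is required")
    return(list(final = FALSE, needsSecondRound = FALSE))
  }
  ## 2-of-3 split: re-present to all three raters; unanimity decides.
  if (is.null(secondRound))
    return(list(final = NA, needsSecondRound = TRUE))
  stopifnot(is.logical(secondRound), length(secondRound) == 3L,
            !anyNA(secondRound))
  list(final = all(secondRound), needsSecondRound = TRUE)
}
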