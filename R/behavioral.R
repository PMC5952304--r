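# Behavioral instruments: modified Racine scale (with its SE rule),
# modified Irwin test, and novel-object-recognition scoring.

#' Modified Racine scale reference table
#'
#' The 0-7 rubric used to score motor seizure behavior after
#' organophosphate exposure. Score 5 is the SE declaration rule applied
#' by [declare_se()], not an observed motor behavior of its own.
#'
#' @return A data.frame with `score`, `label` and `behaviors`.
#' @export
racine_scale <- function() {
  data.frame(
    score = 0:7,
    label = c("Normal behavior", "Freeze behavior", "Repetitive behavior",
              "Early seizure behavior", "Advance seizure behavior", "SE",
              "Intense seizure behavior", "Death"),
    behaviors = c(
      "Walking, exploring, sniffing, grooming",
      "Immobile, staring, heightened startle, curled-up posture",
      "Blinking, chewing, head bobbing, scratching, face washing, whisker twitching",
      "Myoclonic jerks, partial body clonus",
      "Whole-body clonus",
      "Repeated seizure activity (>=2 events in stages 3, 4, or 6 within a 5-min window)",
      "Repetitive jumping or bouncing, wild running, tonic seizures",
      "Death"),
    stringsAsFactors = FALSE)
}

#' Declare status epilepticus from Racine observations
#'
#' SE is declared at the first time at which two or more observations
#' with score 3, 4 or 6 fall within any sliding 5-min window (window
#' endpoints inclusive).
#'
#' @param observations A data.frame with `time` (minutes from dosing)
#'   and `score` (0-7), time-sorted.
#' @return The SE declaration time (minutes), or `NULL`.
#' @examples
#' declare_se(data.frame(time = c(35, 40, 43), score = c(2, 4, 4)))
#' @export
declare_se <- function(observations) {
  stopifnot(is.data.frame(observations),
            all(c("time", "score") %in% names(observations)))
  if (is.unsorted(observations$time)) {
    stop("observations must be sorted by time")
  }
  if (!all(observations$score %in% 0:7)) {
    stop("Racine scores must be integers in 0..7")
  }
  ev <- observations$time[observations$score %in% c(3, 4, 6)]
  if (length(ev) < 2L) return(NULL)
  for (j in 2:length(ev)) {
    if (ev[j] - ev[j - 1L] <= 5) return(ev[j])
  }
  NULL
}

#' Modified Irwin test total and classification
#'
#' Twelve observational health items each scored 0 (normal) to 2
#' (markedly abnormal), total 0-24. A total of 0 is a normal healthy
#' rat; 1-11 is a healthy animal that appears slightly impaired; a total
#' of 12 or more is a failed test.
#'
#' @param item_scores Integer vector of exactly 12 scores in `{0, 1, 2}`.
#' @return A list with `total` and `classification` (one of `"normal"`,
#'   `"impaired"`, `"fail"`).
#' @export
irwin_total <- function(item_scores) {
  if (length(item_scores) != 12L) {
    stop("the modified Irwin test has exactly 12 items (got ",
         length(item_scores), ")")
  }
  if (!all(item_scores %in% 0:2)) {
    stop("Irwin item scores must be 0, 1 or 2")
  }
  total <- sum(item_scores)
  classification <- if (total == 0L) {
    "normal"
  } else if (total < 12L) {
    "impaired"
  } else {
    "fail"
  }
  list(total = total, classification = classification)
}

#' Novel-object-recognition discrimination index
#'
#' `DI = (time_novel - time_familiar) / (time_novel + time_familiar)`,
#' in `[-1, 1]`; 0 means no preference.
#'
#' @param time_novel,time_familiar Exploration times (s), not both zero.
#' @return The discrimination index.
#' @export
discrimination_index <- function(time_novel, time_familiar) {
  stopifnot(time_novel >= 0, time_familiar >= 0)
  total <- time_novel + time_familiar
  if (total == 0) stop("no exploration time recorded; DI undefined")
  (time_novel - time_familiar) / total
}

#' Familiarization validity for NOR testing
#'
#' A rat that spent less than 30% of its training exploration with
#' either identical object did not familiarize and is excluded from the
#' discrimination-index analysis. Exactly 30% is valid.
#'
#' @param time_left,time_right Exploration times (s) with the two
#'   identical objects.
#' @return `TRUE` if the training trial is valid.
#' @export
familiarization_valid <- function(time_left, time_right) {
  stopifnot(time_left >= 0, time_right >= 0)
  total <- time_left + time_right
  if (total == 0) stop("no exploration time recorded")
  min(time_left, time_right) / total >= 0.30
}
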