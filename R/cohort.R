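#' Participant record for eye selection and quality filtering
#'
#' @param participant_id identifier.
#' @param birth_year integer year of birth; its parity selects the study
#'   eye (even -> right, odd -> left).
#' @param age,sex optional demographics.
#' @param right_eye,left_eye per-eye quality descriptors as produced by
#'   [eye_quality()].
#' @return a list of class `participant_record`.
#' @export
participant_record <- function(participant_id, birth_year,
                               age = NA_real_, sex = NA_character_,
                               right_eye = eye_quality(),
                               left_eye = eye_quality()) {
  structure(list(participant_id = participant_id,
                 birth_year = as.integer(birth_year), age = age, sex = sex,
                 right_eye = right_eye, left_eye = left_eye),
            class = "participant_record")
}

#' @rdname participant_record
#' @param signal_strength device signal-strength index on a 0-10 scale;
#'   below 7 is inadequate.
#' @param segmentation_ok,artefact_free,interpretable quality booleans:
#'   automated layer segmentation plausible, perfusion map free of
#'   significant artefacts (lines or gaps), scan interpretable.
#' @export
eye_quality <- function(signal_strength = 10, segmentation_ok = TRUE,
                        artefact_free = TRUE, interpretable = TRUE) {
  if (signal_strength < 0 || signal_strength > 10)
    stop_config("signal_strength must lie in [0, 10]")
  list(signal_strength = signal_strength,
       segmentation_ok = isTRUE(segmentation_ok),
       artefact_free = isTRUE(artefact_free),
       interpretable = isTRUE(interpretable))
}

eye_passes <- function(q) {
  q$interpretable && q$segmentation_ok && q$artefact_free &&
    q$signal_strength >= 7
}

#' Study-eye selection by birth-year parity with quality fallback
#'
#' The analysed eye is the right eye for participants born in
#' even-numbered years and the left eye for odd-numbered years. If the
#' parity-selected eye fails quality (uninterpretable, abnormal
#' segmentation, significant artefacts, or signal strength below 7/10),
#' the other eye is used; if both fail, the participant is excluded.
#'
#' @param record a [participant_record()].
#' @return `"right"`, `"left"` or `"excluded"`.
#' @export
select_study_eye <- function(record) {
  preferred <- if (record$birth_year %% 2L == 0L) "right" else "left"
  other <- if (preferred == "right") "left" else "right"
  q <- list(right = record$right_eye, left = record$left_eye)
  if (eye_passes(q[[preferred]])) return(preferred)
  if (eye_passes(q[[other]])) return(other)
  "excluded"
}

#' Apply the study's participant-level quality filters
#'
#' Runs [select_study_eye()] over a cohort and splits it into included
#' participants (with their selected eye) and an exclusion log naming the
#' rule that fired for each excluded participant.
#'
#' @param cohort a list of [participant_record()] objects.
#' @return list with `included` (data frame `participant_id`, `study_eye`)
#'   and `exclusions` (data frame `participant_id`, `decision`,
#'   `rule_fired`).
#' @export
apply_quality_filters <- function(cohort) {
  if (length(cohort) == 0L) stop_input("cohort must be non-empty")
  inc <- list(); exc <- list()
  for (rec in cohort) {
    eye <- select_study_eye(rec)
    if (eye == "excluded") {
      qr <- rec$right_eye; ql <- rec$left_eye
      rule <- if (!qr$artefact_free || !ql$artefact_free) {
        "significant_artefacts"
      } else if (qr$signal_strength < 7 && ql$signal_strength < 7) {
        "inadequate_signal_strength"
      } else if (!qr$segmentation_ok || !ql$segmentation_ok) {
        "abnormal_segmentation"
      } else {
        "uninterpretable"
      }
      exc[[length(exc) + 1L]] <-
        data.frame(participant_id = rec$participant_id,
                   decision = "excluded", rule_fired = rule)
    } else {
      inc[[length(inc) + 1L]] <-
        data.frame(participant_id = rec$participant_id, study_eye = eye)
    }
  }
  list(included = if (length(inc)) do.call(rbind, inc) else
         data.frame(participant_id = character(), study_eye = character()),
       exclusions = if (length(exc)) do.call(rbind, exc) else
         data.frame(participant_id = character(), decision = character(),
                    rule_fired = character()))
}

#' The study's observer/scan design
#'
#' Scan 1 is acquired by observer 1; scans 2 and 3 by observer 2.
#' Repeatability (same operator) compares scans 2 vs 3; reproducibility
#' (different operators) compares scan 1 vs scan 2.
#'
#' @return a list of class `study_design`.
#' @export
study_design <- function() {
  structure(list(repeatability_pair = c(2L, 3L),
                 reproducibility_pair = c(1L, 2L),
                 observer_of_scan = c(`1` = 1L, `2` = 2L, `3` = 2L)),
            class = "study_design")
}

#' Assemble repeatability and reproducibility tables per plexus
#'
#' Pivots a long measurement table (one fractal-dimension value per
#' participant x scan x plexus) into the two-column agreement tables named
#' by the design: per plexus, an n x 2 table of scans 2 and 3
#' (repeatability) and an n x 2 table of scans 1 and 2 (reproducibility).
#' Participants missing a scan are dropped from the comparisons that need
#' it, and logged.
#'
#' @param measurements data frame with columns `participant_id`,
#'   `scan_index`, `plexus`, `fd` (optionally `observer_id`).
#' @param design a [study_design()].
#' @return list with one entry per plexus, each holding `repeatability`
#'   and `reproducibility` long tables (columns `participant_id`,
#'   `rater_id`, `value`), plus a `dropped` log data frame.
#' @export
assemble_comparisons <- function(measurements, design = study_design()) {
  need <- c("participant_id", "scan_index", "plexus", "fd")
  if (!all(need %in% names(measurements)))
    stop_input("measurements must have columns ",
               paste(need, collapse = ", "))
  out <- list()
  dropped <- list()
  for (plx in unique(measurements$plexus)) {
    sub <- measurements[measurements$plexus == plx, , drop = FALSE]
    mk <- function(scans, comparison) {
      wide <- lapply(scans, function(s)
        sub[sub$scan_index == s, c("participant_id", "fd")])
      ids <- Reduce(intersect, lapply(wide, `[[`, "participant_id"))
      missing <- setdiff(unique(sub$participant_id), ids)
      if (length(missing))
        dropped[[length(dropped) + 1L]] <<-
          data.frame(participant_id = missing, plexus = plx,
                     comparison = comparison)
      if (length(ids) == 0L)
        return(data.frame(participant_id = character(),
                          rater_id = character(), value = numeric()))
      do.call(rbind, lapply(seq_along(scans), function(i) {
        w <- wide[[i]]
        w <- w[match(ids, w$participant_id), ]
        data.frame(participant_id = ids,
                   rater_id = sprintf("scan%d", scans[i]),
                   value = w$fd)
      }))
    }
    out[[plx]] <- list(repeatability = mk(design$repeatability_pair,
                                          "repeatability"),
                       reproducibility = mk(design$reproducibility_pair,
                                            "reproducibility"))
  }
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(participant_id = character(), plexus = character(),
               comparison = character())
  out
}
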