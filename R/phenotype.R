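#' Classify participants into hearing phenotype groups
#'
#' Applies the longitudinal self-report rules to a cohort table and assigns
#' every participant to exactly one of `normal`, `difficulty` or `excluded`.
#'
#' A participant is `normal` when they reported no hearing difficulty, no
#' difficulty in noise and no hearing aid use at any assessment, were asked
#' about their hearing at least once at or above `min_age`, never reported
#' high noise exposure or moderate/severe tinnitus, and never reported an
#' otologic disorder or cochlear implant. A participant is `difficulty` when
#' they reported consistent or worsening hearing difficulty (or were ever a
#' hearing aid user), were asked at least once at or above `min_age`, and
#' have no otologic disorder or implant. Everyone else is `excluded` with a
#' coded reason.
#'
#' "Consistent or worsening" is read strictly: difficulty answered yes at
#' every visit where it was asked, or a no-to-yes transition with no later
#' reversal; any yes-to-no reversal without hearing aid use excludes the
#' participant. A "yes" to either the difficulty or the difficulty-in-noise
#' question counts as a difficulty report. Unknown answers are ignored,
#' but a participant with no concrete answer at all is excluded.
#'
#' @param cohort A tibble with one row per participant-visit, with columns
#'   `participant_id`, `sex`, `age`, `hearing_difficulty`,
#'   `difficulty_in_noise` (`"yes"/"no"/"unknown"`), `hearing_aid`,
#'   `cochlear_implant`, `otologic_disorder`, `noise_exposure_high`
#'   (`"yes"/"no"`), `tinnitus` (`"none"/"mild"/"moderate"/"severe"`).
#' @param min_age Minimum age at which the hearing question must have been
#'   asked at least once (default 55).
#' @return A tibble with one row per participant: `participant_id`,
#'   `group` (`normal`, `difficulty`, `excluded`) and `reason` (rule code;
#'   `NA` for classified participants).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_participants = 50, seed = 1))
#' classify_hearing(cohort)
#' @export
classify_hearing <- function(cohort, min_age = 55) {
  if (nrow(cohort) == 0L) stop_validation("cohort has no visits")
  required <- c("participant_id", "age", "hearing_difficulty",
                "difficulty_in_noise", "hearing_aid", "cochlear_implant",
                "otologic_disorder", "noise_exposure_high", "tinnitus")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols)) {
    stop_validation(paste("cohort is missing columns:",
                          paste(missing_cols, collapse = ", ")))
  }

  cohort |>
    dplyr::arrange(.data$participant_id, .data$age) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(call = list(classify_one(
      age = .data$age,
      difficulty = .data$hearing_difficulty,
      noise_diff = .data$difficulty_in_noise,
      aid = .data$hearing_aid,
      implant = .data$cochlear_implant,
      otologic = .data$otologic_disorder,
      noise_exp = .data$noise_exposure_high,
      tinnitus = .data$tinnitus,
      min_age = min_age)), .groups = "drop") |>
    tidyr::unnest_wider("call")
}

# rule engine for a single participant's ordered visits
classify_one <- function(age, difficulty, noise_diff, aid, implant,
                         otologic, noise_exp, tinnitus, min_age) {
  excluded <- function(reason) list(group = "excluded", reason = reason)

  # a visit-level difficulty report: yes on either question beats no;
  # no requires a concrete no with no yes; otherwise unknown
  report <- dplyr::case_when(
    difficulty == "yes" | noise_diff == "yes" ~ "yes",
    difficulty == "no" | noise_diff == "no" ~ "no",
    TRUE ~ "unknown")

  if (any(implant == "yes")) return(excluded("cochlear_implant"))
  if (any(otologic == "yes")) return(excluded("otologic_disorder"))

  asked <- report != "unknown"
  if (!any(asked & age >= min_age)) {
    return(excluded("not_asked_at_min_age"))
  }

  concrete <- report[asked]
  aid_ever <- any(aid == "yes")

  # consistent-or-worsening: no yes-to-no reversal among concrete answers
  yes_idx <- which(concrete == "yes")
  no_idx <- which(concrete == "no")
  reversal <- length(yes_idx) > 0L && length(no_idx) > 0L &&
    max(no_idx) > min(yes_idx)

  if (reversal && !aid_ever) return(excluded("difficulty_reversal"))

  if (aid_ever || length(yes_idx) > 0L) {
    return(list(group = "difficulty", reason = NA_character_))
  }

  # no difficulty evidence: candidate for the normal group, which applies
  # the extra noise/tinnitus screens
  if (length(no_idx) == 0L) return(excluded("no_concrete_answer"))
  if (any(noise_exp == "yes")) return(excluded("noise_exposure"))
  if (any(tinnitus %in% c("moderate", "severe"))) {
    return(excluded("tinnitus_moderate_or_severe"))
  }
  list(group = "normal", reason = NA_character_)
}

#' Summarise phenotype groups
#'
#' Tabulates classified participants by group and sex (with mean age at the
#' last qualifying visit) and by group, sex and ethnicity.
#'
#' @param calls Output of [classify_hearing()].
#' @param cohort The cohort visit table the calls were derived from.
#' @param min_age Age threshold used for the qualifying visit (default 55).
#' @return A list with two tibbles: `by_sex` (`group`, `sex`, `n`,
#'   `mean_age`; `mean_age` is `NA` for empty cells) and `by_ethnicity`
#'   (`group`, `sex`, `ethnicity`, `n`). Counts sum to the cohort size.
#' @export
summarize_groups <- function(calls, cohort, min_age = 55) {
  anchor <- cohort |>
    dplyr::arrange(.data$participant_id, .data$age) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      sex = dplyr::first(.data$sex),
      ethnicity = dplyr::first(.data$ethnicity),
      anchor_age = {
        asked <- (.data$hearing_difficulty != "unknown" |
                    .data$difficulty_in_noise != "unknown") &
          .data$age >= min_age
        if (any(asked)) max(.data$age[asked]) else max(.data$age)
      },
      .groups = "drop") |>
    dplyr::inner_join(calls, by = "participant_id")

  grid <- tidyr::expand_grid(group = c("normal", "difficulty", "excluded"),
                             sex = sort(unique(anchor$sex)))
  by_sex <- anchor |>
    dplyr::group_by(.data$group, .data$sex) |>
    dplyr::summarise(n = dplyr::n(), mean_age = mean(.data$anchor_age),
                     .groups = "drop") |>
    dplyr::right_join(grid, by = c("group", "sex")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::arrange(.data$group, .data$sex)

  by_ethnicity <- anchor |>
    dplyr::count(.data$group, .data$sex, .data$ethnicity)

  list(by_sex = by_sex, by_ethnicity = by_ethnicity)
}
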