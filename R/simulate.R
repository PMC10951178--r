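#' Simulate one participant's double-pass session
#'
#' Draws trial-level responses for every scheduled trial of a design under
#' the four-state latent model of [latent_params()]: per target-present
#' display an unfindability indicator is drawn once and persists across
#' copies (converting to findable with probability `(d1 - d2)/d1` only on
#' cued second copies); unfindable copies are missed with certainty and
#' findable copies with the round's stochastic probability; target-absent
#' trials produce false alarms at `fa_rate`. Reaction times come from the
#' [rt_model()] and motor-correction flags are drawn independently.
#'
#' @param design A `search_design` from [build_design()] or [pair_design()].
#' @param latent A [latent_params()] object (the simulation ground truth).
#' @param rt An [rt_model()] object.
#' @param seed Integer seed.
#' @param participant_id Identifier recorded on every trial.
#' @param resplit_cues If `TRUE` (the exp3 default in [simulate_cohort()]),
#'   re-randomize the noCue-Cue / noCue-noCue display split for this
#'   participant before scheduling cues.
#' @return A tibble with one row per trial: `participant_id`, `trial_index`,
#'   `block`, `display_id`, `copy`, `set_size`, `target_present`,
#'   `cue_group`, `cue_condition`, `tb_contrast`, `response`
#'   (`"present"`/`"absent"`), `rt_ms`, `corrected`, `latent_state`. The
#'   generating `latent_params` are attached as attribute `"latent"`.
#' @examples
#' des <- pair_design(100, 100, seed = 1)
#' trials <- simulate_participant(des, latent_params(d1 = 0, d2 = 0), seed = 2)
#' mean(trials$response[trials$target_present] == "present")
#' @export
simulate_participant <- function(design, latent = latent_params(),
                                 rt = rt_model(), seed = 1L,
                                 participant_id = "p01",
                                 resplit_cues = FALSE) {
  stopifnot(inherits(design, "search_design"),
            inherits(latent, "latent_params"), inherits(rt, "rt_model"))
  local_seed_eval(seed, {
    displays <- design$displays
    schedule <- design$schedule
    if (resplit_cues) {
      displays$cue_group <- sample(rep(c("noCue-Cue", "noCue-noCue"),
                                       length.out = nrow(displays)))
      grp <- displays$cue_group[match(schedule$display_id,
                                      displays$display_id)]
      schedule$cue_condition <- ifelse(grp == "noCue-Cue" &
                                         schedule$copy == 2L, "cued", "none")
    }

    # display-level latent draws
    p_unfind <- display_unfindability(displays, latent)
    unfind1 <- runif(nrow(displays)) < p_unfind
    keep_prob <- if (latent$d1 > 0) latent$d2 / latent$d1 else 1
    cued_copy2 <- displays$cue_group == "noCue-Cue"
    unfind2 <- unfind1 &
      ifelse(cued_copy2, runif(nrow(displays)) < keep_prob, TRUE)

    idx <- match(schedule$display_id, displays$display_id)
    tr <- tibble(
      participant_id = participant_id,
      trial_index = schedule$trial_index,
      block = schedule$block,
      display_id = schedule$display_id,
      copy = schedule$copy,
      set_size = displays$set_size[idx],
      target_present = displays$target_present[idx],
      cue_group = displays$cue_group[idx],
      cue_condition = schedule$cue_condition,
      tb_contrast = displays$tb_contrast[idx]
    )

    n <- nrow(tr)
    unfind <- ifelse(tr$copy == 1L, unfind1[idx], unfind2[idx]) &
      tr$target_present
    s_round <- ifelse(tr$copy == 1L, latent$s1, latent$s2)
    stoch <- runif(n) < s_round
    fa <- runif(n) < latent$fa_rate

    state <- character(n)
    present <- tr$target_present
    state[present & unfind & stoch] <- "unfindable_stoch_miss"
    state[present & unfind & !stoch] <- "det_miss"
    state[present & !unfind & stoch] <- "stoch_miss"
    state[present & !unfind & !stoch] <- "hit"
    state[!present & fa] <- "false_alarm"
    state[!present & !fa] <- "correct_reject"

    tr$response <- ifelse(
      state %in% c("hit", "false_alarm"), "present", "absent")
    tr$latent_state <- state

    med <- ifelse(present,
                  rt$median_present_ms +
                    rt$slope_present_ms * (tr$set_size - 18L),
                  rt$median_absent_ms +
                    rt$slope_absent_ms * (tr$set_size - 18L))
    med <- med * ifelse(!present & tr$copy == 2L,
                        rt$repeat_speedup_absent, 1)
    rt_ms <- rlnorm(n, meanlog = log(med), sdlog = rt$sdlog)
    rt_ms <- rt_ms * ifelse(runif(n) < rt$outlier_rate, 10, 1)
    tr$rt_ms <- rt_ms
    tr$corrected <- runif(n) < rt$correction_rate

    attr(tr, "latent") <- latent
    tr
  })
}

# per-display unfindability probability, optionally contrast-linked
display_unfindability <- function(displays, latent) {
  p <- rep(latent$d1, nrow(displays))
  link <- latent$contrast_link
  if (!is.null(link)) {
    tb <- abs(displays$tb_contrast)
    linked <- latent$d1 *
      stats::plogis((link["threshold"] - tb) / link["slope"])
    p <- ifelse(is.na(tb), p, linked)
  }
  ifelse(displays$target_present, p, 0)
}

#' Simulate a cohort of independent participants
#'
#' Runs [simulate_participant()] once per participant with seeds derived from
#' `seed`. Latent parameters may be shared (`latent` a single
#' [latent_params()]) or participant-specific (`latent` a function
#' `f(participant_index)` returning one). The generating parameters are
#' stored in the `"latent"` attribute as a tibble keyed by `participant_id`
#' so recovery studies can compare estimates against truth.
#'
#' @param n_participants Number of participants (>= 1).
#' @param design A `search_design`; exp3 designs get a fresh random cue split
#'   per participant (see `resplit_cues`).
#' @param latent A `latent_params` or a function of the participant index.
#' @param rt An [rt_model()].
#' @param seed Integer master seed.
#' @param resplit_cues Re-randomize the cue split per participant; defaults
#'   to `TRUE` for exp3 designs.
#' @return Tibble of all trials (one participant stacked after another) with
#'   attribute `"latent"` (tibble of true parameters per participant).
#' @export
simulate_cohort <- function(n_participants, design, latent = latent_params(),
                            rt = rt_model(), seed = 1L,
                            resplit_cues = identical(design$experiment,
                                                     "exp3")) {
  stopifnot(n_participants >= 1)
  seeds <- derive_seeds(seed, n_participants)
  ids <- sprintf("p%02d", seq_len(n_participants))
  sessions <- vector("list", n_participants)
  truth <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    li <- if (is.function(latent)) latent(i) else latent
    sessions[[i]] <- simulate_participant(design, li, rt, seed = seeds[i],
                                          participant_id = ids[i],
                                          resplit_cues = resplit_cues)
    truth[[i]] <- tibble(participant_id = ids[i], d1 = li$d1, d2 = li$d2,
                         s1 = li$s1, s2 = li$s2, fa_rate = li$fa_rate)
  }
  out <- dplyr::bind_rows(sessions)
  attr(out, "latent") <- dplyr::bind_rows(truth)
  out
}

#' True latent parameters stored with simulated data
#'
#' @param trials A tibble from [simulate_participant()] or
#'   [simulate_cohort()].
#' @return The `latent_params` object or per-participant tibble recorded at
#'   simulation time, or `NULL` for real data.
#' @export
latent_truth <- function(trials) {
  attr(trials, "latent")
}
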