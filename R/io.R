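#' Write / read a trial log as delimited text
#'
#' The trial log is the pipeline's interchange format: one CSV row per trial
#' with the schema produced by [simulate_participant()]. When simulated data
#' carry latent ground truth, it is written to a JSON sidecar
#' (`<path>.latent.json`) keyed by participant and restored on read.
#'
#' @param trials Trial tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(tibble::as_tibble(trials), path)
  truth <- latent_truth(trials)
  if (!is.null(truth)) {
    truth <- if (inherits(truth, "latent_params")) {
      truth[c("d1", "d2", "s1", "s2", "fa_rate")]
    } else {
      truth
    }
    jsonlite::write_json(truth, paste0(path, ".latent.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_trials
#' @return For `read_trials()`, the trial tibble (with the `"latent"`
#'   attribute restored when the sidecar exists).
#' @export
read_trials <- function(path) {
  trials <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  sidecar <- paste0(path, ".latent.json")
  if (file.exists(sidecar)) {
    attr(trials, "latent") <-
      tibble::as_tibble(jsonlite::fromJSON(sidecar))
  }
  trials
}

#' Serialize a search design to JSON
#'
#' Writes the displays (letters inlined per display) and the two-copy
#' schedule as one JSON document, and reads it back into a `search_design`.
#'
#' @param design A `search_design`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "search_design"))
  has_letters <- "letters" %in% names(design$displays)
  has_bg <- "background" %in% names(design$displays)
  payload <- list(
    experiment = design$experiment,
    seed = design$seed,
    displays = lapply(seq_len(nrow(design$displays)), function(i) {
      row <- design$displays[i, ]
      list(
        display_id = row$display_id, set_size = row$set_size,
        target_present = row$target_present, quadrant = row$quadrant,
        tb_contrast = row$tb_contrast, cue_group = row$cue_group,
        background = if (has_bg) row$background[[1]],
        letters = if (has_letters) row$letters[[1]]
      )
    }),
    schedule = design$schedule
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  displays <- dplyr::bind_rows(lapply(raw$displays, function(d) {
    tibble(
      display_id = d$display_id, set_size = as.integer(d$set_size),
      target_present = d$target_present,
      quadrant = d$quadrant %||% NA_character_,
      tb_contrast = if (is.null(d$tb_contrast)) NA_real_ else
        as.numeric(d$tb_contrast),
      cue_group = d$cue_group,
      letters = list(if (is.null(d$letters)) NULL else
        dplyr::bind_rows(lapply(d$letters, tibble::as_tibble))),
      background = list(d$background)
    )
  }))
  schedule <- dplyr::bind_rows(lapply(raw$schedule, tibble::as_tibble))
  schedule$copy <- as.integer(schedule$copy)
  schedule$trial_index <- as.integer(schedule$trial_index)
  schedule$block <- as.integer(schedule$block)
  structure(list(experiment = raw$experiment, seed = as.integer(raw$seed),
                 displays = displays, schedule = schedule),
            class = "search_design")
}

#' Write a rendered display as an 8-bit grayscale PNG
#'
#' @param image Gray matrix from [render_display()] or [generate_noise()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_display_png <- function(image, path) {
  png::writePNG(unclass(image) / 255, path)
  invisible(path)
}
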