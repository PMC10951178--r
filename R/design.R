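#' Build a complete double-pass search design
#'
#' Generates the full stimulus set and two-copy presentation schedule for one
#' of the four experiment dialects of the T-among-L double-pass paradigm:
#'
#' * `"exp1"` — 75 versions of each target presence (2) x set size (18, 36)
#'   combination: 300 unique displays of white (gray 255) letters on a uniform
#'   gray background, letters confined to the centered square of side 0.7
#'   screen height. Each display is scheduled twice, randomly intermixed
#'   across six 100-trial blocks (600 trials).
#' * `"exp2a"` — 300 displays as in exp1, but letter grays are uniform random
#'   (drawn in \[-1, 1\] and mapped to 0-255) on a 1/f^1.3 noise background;
#'   letter positions range over x, y in \[0.15, 0.85\].
#' * `"exp2b"` — the controlled-contrast dialect: target presence (2) x set
#'   size (2) x signed target-background contrast level
#'   (-105, -75, -45, -15, 15, 45, 75, 105) x target quadrant (4) gives 128
#'   combinations; two arrays per combination yield 256 displays, scheduled
#'   twice over four 128-trial blocks (512 trials). The designated item (the T
#'   when present, an L otherwise) has gray `128 + tb_contrast` and sits in
#'   its quadrant; other letters have random grays.
#' * `"exp3"` — the exp2b stimulus set plus a cue grouping: half the displays
#'   are tagged `noCue-Cue` (the second copy is cued) and half `noCue-noCue`.
#'   The split is re-randomized per participant by [simulate_cohort()].
#'
#' @param experiment One of `"exp1"`, `"exp2a"`, `"exp2b"`, `"exp3"`.
#' @param seed Integer seed; the same seed reproduces the design exactly.
#' @return A `search_design` object: a list with `experiment`, `seed`,
#'   `displays` (tibble, one row per display: `display_id`, `set_size`,
#'   `target_present`, `quadrant`, `tb_contrast`, `cue_group`, list-columns
#'   `letters` and `background`) and `schedule` (tibble, one row per scheduled
#'   trial: `trial_index`, `block`, `display_id`, `copy`, `cue_condition`).
#' @examples
#' des <- build_design("exp1", seed = 1)
#' nrow(des$displays)   # 300
#' nrow(des$schedule)   # 600
#' @export
build_design <- function(experiment = c("exp1", "exp2a", "exp2b", "exp3"),
                         seed = 1L) {
  experiment <- match.arg(experiment)
  local_seed_eval(seed, {
    displays <- switch(experiment,
      exp1 = build_displays_uniform(noise_background = FALSE),
      exp2a = build_displays_uniform(noise_background = TRUE),
      exp2b = build_displays_controlled(),
      exp3 = build_displays_controlled()
    )
    if (experiment == "exp3") {
      grp <- sample(rep(c("noCue-Cue", "noCue-noCue"),
                        each = nrow(displays) / 2))
      displays$cue_group <- grp
    } else {
      displays$cue_group <- "noCue-noCue"
    }
    schedule <- schedule_two_copies(
      displays,
      n_blocks = if (experiment %in% c("exp1", "exp2a")) 6L else 4L
    )
    structure(
      list(experiment = experiment, seed = as.integer(seed),
           displays = displays, schedule = schedule),
      class = "search_design"
    )
  })
}

# map a gray drawn uniformly in [-1, 1] to 0-255 (round half away from zero)
unit_gray_to_255 <- function(g) {
  as.integer(floor((g + 1) / 2 * 255 + 0.5))
}

EXP1_REGION <- c(0.15, 0.85, 0.15, 0.85)

QUADRANT_REGIONS <- list(
  UL = c(0.15, 0.45, 0.15, 0.45),
  UR = c(0.55, 0.85, 0.15, 0.45),
  BL = c(0.15, 0.45, 0.55, 0.85),
  BR = c(0.55, 0.85, 0.55, 0.85)
)

TB_LEVELS <- c(-105, -75, -45, -15, 15, 45, 75, 105)

# exp1 / exp2a: 75 versions x presence x set size = 300 free-gray displays
build_displays_uniform <- function(noise_background, n_versions = 75L,
                                   set_sizes = c(18L, 36L)) {
  noise_seeds <- if (noise_background) {
    sample.int(.Machine$integer.max, 10L)   # pool of 10 background textures
  }
  grid <- expand.grid(version = seq_len(n_versions), set_size = set_sizes,
                      target_present = c(TRUE, FALSE))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ss <- grid$set_size[i]
    present <- grid$target_present[i]
    pos <- place_letters_impl(ss, EXP1_REGION, 0.1, NULL, 10000L)
    grays <- if (noise_background) {
      unit_gray_to_255(runif(ss, -1, 1))
    } else {
      rep(255L, ss)
    }
    letters <- tibble(
      kind = c(if (present) "T", rep("L", ss - present)),
      x = pos$x, y = pos$y,
      orientation = sample(LETTER_ORIENTATIONS, ss, replace = TRUE),
      gray = grays, stroke_len = 0.03
    )
    bg <- if (noise_background) {
      list(type = "noise", seed = sample(noise_seeds, 1L), exponent = 1.3,
           size = 2000L)
    } else {
      list(type = "uniform", gray = 128L)
    }
    tb <- if (noise_background && present) letters$gray[1] - 128L else NA_real_
    tibble(
      set_size = ss, target_present = present,
      quadrant = NA_character_, tb_contrast = as.numeric(tb),
      letters = list(letters), background = list(bg)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$display_id <- sprintf("d%03d", seq_len(nrow(out)))
  dplyr::relocate(out, "display_id")
}

# exp2b / exp3: presence x set size x T-B level x quadrant, two arrays each
build_displays_controlled <- function() {
  grid <- expand.grid(array = 1:2, quadrant = names(QUADRANT_REGIONS),
                      tb = TB_LEVELS, set_size = c(18L, 36L),
                      target_present = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ss <- grid$set_size[i]
    present <- grid$target_present[i]
    tb <- grid$tb[i]
    quad <- grid$quadrant[i]
    qreg <- QUADRANT_REGIONS[[quad]]
    qpos <- tibble(x = runif(1, qreg[1], qreg[2]),
                   y = runif(1, qreg[3], qreg[4]))
    rest <- place_letters_impl(ss - 1L, EXP1_REGION, 0.1, qpos, 10000L)
    letters <- tibble(
      kind = c(if (present) "T" else "L", rep("L", ss - 1L)),
      x = c(qpos$x, rest$x), y = c(qpos$y, rest$y),
      orientation = sample(LETTER_ORIENTATIONS, ss, replace = TRUE),
      gray = c(128L + as.integer(tb), unit_gray_to_255(runif(ss - 1L, -1, 1))),
      stroke_len = 0.03
    )
    tibble(
      set_size = ss, target_present = present, quadrant = quad,
      tb_contrast = as.numeric(tb), letters = list(letters),
      background = list(list(type = "noise",
                             seed = sample.int(.Machine$integer.max, 1L),
                             exponent = 1.3, size = 1000L))
    )
  })
  out <- dplyr::bind_rows(rows)
  out$display_id <- sprintf("d%03d", seq_len(nrow(out)))
  dplyr::relocate(out, "display_id")
}

# randomly intermix the two copies of every display across equal-size blocks;
# the chronologically first occurrence is copy 1
schedule_two_copies <- function(displays, n_blocks) {
  ids <- rep(displays$display_id, each = 2L)
  ord <- sample(ids)
  copy <- stats::ave(seq_along(ord), ord, FUN = seq_along)
  n <- length(ord)
  sched <- tibble(
    trial_index = seq_len(n),
    block = rep(seq_len(n_blocks), each = n %/% n_blocks),
    display_id = ord,
    copy = as.integer(copy)
  )
  grp <- displays$cue_group[match(sched$display_id, displays$display_id)]
  sched$cue_condition <- ifelse(grp == "noCue-Cue" & sched$copy == 2L,
                                "cued", "none")
  sched
}

#' @export
print.search_design <- function(x, ...) {
  cat(sprintf(
    "<search_design: %s, seed %d>\n  %d displays (%d target-present), %d scheduled trials\n",
    x$experiment, x$seed, nrow(x$displays), sum(x$displays$target_present),
    nrow(x$schedule)))
  invisible(x)
}

#' Validate the structural invariants of a search design
#'
#' Checks, for every display: the letter count equals the set size; exactly
#' one T if and only if the target is present; all pairwise letter distances
#' exceed `min_dist`; grays lie in 0-255 and orientations in the 30-degree
#' rotation set; controlled-contrast displays use the eight signed contrast
#' levels and keep the designated item inside its quadrant. The schedule must
#' present every display exactly twice with copy indices 1 and 2.
#'
#' @param design A `search_design` from [build_design()].
#' @param min_dist Minimum pairwise letter distance to enforce.
#' @return Invisibly `TRUE`; aborts with a message on the first violation.
#' @export
validate_design <- function(design, min_dist = 0.1) {
  d <- design$displays
  for (i in seq_len(nrow(d))) {
    let <- d$letters[[i]]
    if (nrow(let) != d$set_size[i]) {
      abort(sprintf("Display %s: %d letters but set_size %d.",
                    d$display_id[i], nrow(let), d$set_size[i]))
    }
    n_t <- sum(let$kind == "T")
    if (n_t != as.integer(d$target_present[i])) {
      abort(sprintf("Display %s: %d T letters with target_present = %s.",
                    d$display_id[i], n_t, d$target_present[i]))
    }
    if (nrow(let) > 1 && min(stats::dist(cbind(let$x, let$y))) <= min_dist) {
      abort(sprintf("Display %s: letters closer than %.3g.",
                    d$display_id[i], min_dist))
    }
    if (any(let$gray < 0 | let$gray > 255)) {
      abort(sprintf("Display %s: gray outside 0-255.", d$display_id[i]))
    }
    if (!all(let$orientation %in% LETTER_ORIENTATIONS)) {
      abort(sprintf("Display %s: orientation outside the 30-degree set.",
                    d$display_id[i]))
    }
    if (!is.na(d$quadrant[i])) {
      if (!(d$tb_contrast[i] %in% TB_LEVELS)) {
        abort(sprintf("Display %s: contrast %s not a design level.",
                      d$display_id[i], d$tb_contrast[i]))
      }
      qreg <- QUADRANT_REGIONS[[d$quadrant[i]]]
      if (let$x[1] < qreg[1] || let$x[1] > qreg[2] ||
          let$y[1] < qreg[3] || let$y[1] > qreg[4]) {
        abort(sprintf("Display %s: designated item outside quadrant %s.",
                      d$display_id[i], d$quadrant[i]))
      }
    }
  }
  counts <- table(design$schedule$display_id)
  if (!all(counts == 2L)) {
    abort("Schedule must present every display exactly twice.")
  }
  if (!all(sort(unique(design$schedule$copy)) == c(1L, 2L))) {
    abort("Schedule copy indices must be 1 and 2.")
  }
  invisible(TRUE)
}

#' Minimal paired design for simulation studies
#'
#' Builds a bare-bones double-pass design — display attributes and a two-copy
#' schedule, without letter geometry — for Monte-Carlo work where only the
#' response model matters (e.g. estimator recovery at a chosen number of
#' present pairs).
#'
#' @param n_present,n_absent Number of target-present / target-absent
#'   displays.
#' @param set_size Nominal set size recorded on every display.
#' @param tb_contrast Optional vector of signed contrast values recycled over
#'   the present displays (absent displays get `NA`).
#' @param seed Integer seed for the schedule permutation.
#' @return A `search_design` with `experiment = "pairs"`.
#' @export
pair_design <- function(n_present, n_absent = n_present, set_size = 18L,
                        tb_contrast = NULL, seed = 1L) {
  stopifnot(n_present >= 1, n_absent >= 0)
  n <- n_present + n_absent
  tb <- rep(NA_real_, n)
  if (!is.null(tb_contrast)) {
    tb[seq_len(n_present)] <- rep_len(tb_contrast, n_present)
  }
  displays <- tibble(
    display_id = sprintf("d%05d", seq_len(n)),
    set_size = as.integer(set_size),
    target_present = rep(c(TRUE, FALSE), c(n_present, n_absent)),
    quadrant = NA_character_, tb_contrast = tb,
    cue_group = "noCue-noCue"
  )
  schedule <- local_seed_eval(seed, schedule_two_copies(displays, 1L))
  structure(
    list(experiment = "pairs", seed = as.integer(seed),
         displays = displays, schedule = schedule),
    class = "search_design"
  )
}
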