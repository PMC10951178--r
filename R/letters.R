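#' Letter rotations available to the display generator
#' @keywords internal
LETTER_ORIENTATIONS <- seq(30, 360, by = 30)

# Stroke endpoints for one letter in letter-local units (stroke length = 1,
# y increasing downward, orientation 360 = upright). The T is a horizontal
# stroke centered on top of the vertical stroke; the L joins the two strokes
# at one end. Returns a 2-stroke matrix: x1, y1, x2, y2 per row.
letter_strokes <- function(kind) {
  switch(kind,
    T = rbind(c(0, -0.5, 0, 0.5), c(-0.5, -0.5, 0.5, -0.5)),
    L = rbind(c(0, -0.5, 0, 0.5), c(0, 0.5, 1, 0.5)),
    abort(sprintf("Unknown letter kind '%s' (must be 'T' or 'L').", kind))
  )
}

# rotate stroke endpoints clockwise (screen coordinates) by `deg` degrees
rotate_strokes <- function(strokes, deg) {
  th <- deg * pi / 180
  rot <- function(x, y) cbind(x * cos(th) - y * sin(th),
                              x * sin(th) + y * cos(th))
  a <- rot(strokes[, 1], strokes[, 2])
  b <- rot(strokes[, 3], strokes[, 4])
  cbind(a, b)
}

#' Place letters with a minimum pairwise separation
#'
#' Rejection-samples `set_size` positions uniformly inside a rectangular
#' region, keeping only candidates farther than `min_dist` from every letter
#' already placed (and from any `existing` points, e.g. a pre-placed target).
#' All coordinates are fractions of screen height, origin top-left, y downward.
#'
#' @param set_size Number of positions to place.
#' @param region Numeric length-4 vector `c(xmin, xmax, ymin, ymax)` in
#'   screen-height units. The default is the centered square of side 0.7 used
#'   by the uniform-background dialect.
#' @param min_dist Minimum center-to-center distance (default 0.1 screen
#'   height, preventing letter overlap).
#' @param seed Integer seed.
#' @param existing Optional data frame/tibble with `x`, `y` columns of points
#'   that count for the distance constraint but are not returned.
#' @param max_attempts Candidate budget per placement run. Greedy rejection
#'   sampling can paint itself into a corner at dense packings, so an
#'   exhausted run is restarted from scratch up to `restarts` times before a
#'   placement-failure error is raised.
#' @param restarts Number of fresh runs allowed.
#' @return Tibble with `x`, `y` columns of length `set_size`.
#' @examples
#' pos <- place_letters(18, seed = 1)
#' min(dist(pos)) > 0.1
#' @export
place_letters <- function(set_size, region = c(0.15, 0.85, 0.15, 0.85),
                          min_dist = 0.1, seed = 1L, existing = NULL,
                          max_attempts = 10000L, restarts = 20L) {
  stopifnot(set_size >= 0, length(region) == 4,
            region[2] > region[1], region[4] > region[3], min_dist >= 0)
  local_seed_eval(seed, place_letters_impl(set_size, region, min_dist,
                                           existing, max_attempts, restarts))
}

# same algorithm but drawing from the current RNG stream (used inside
# build_design so one design seed drives everything)
place_letters_impl <- function(set_size, region, min_dist, existing,
                               max_attempts = 10000L, restarts = 20L) {
  ex <- if (!is.null(existing)) cbind(existing$x, existing$y) else NULL
  for (run in seq_len(restarts)) {
    res <- place_letters_run(set_size, region, min_dist, ex, max_attempts)
    if (!is.null(res)) {
      return(res)
    }
  }
  abort(sprintf(
    paste0("Could not place %d letters at min_dist %.3g in region ",
           "[%.2f, %.2f] x [%.2f, %.2f] within %d attempts x %d runs."),
    set_size, min_dist, region[1], region[2], region[3], region[4],
    max_attempts, restarts))
}

place_letters_run <- function(set_size, region, min_dist, ex, max_attempts) {
  xs <- ys <- numeric(set_size)
  n_placed <- 0L
  attempts <- 0L
  while (n_placed < set_size) {
    if (attempts >= max_attempts) {
      return(NULL)
    }
    attempts <- attempts + 1L
    cx <- runif(1, region[1], region[2])
    cy <- runif(1, region[3], region[4])
    ok <- TRUE
    if (n_placed > 0L) {
      ok <- all((xs[seq_len(n_placed)] - cx)^2 +
                  (ys[seq_len(n_placed)] - cy)^2 > min_dist^2)
    }
    if (ok && !is.null(ex)) {
      ok <- all((ex[, 1] - cx)^2 + (ex[, 2] - cy)^2 > min_dist^2)
    }
    if (ok) {
      n_placed <- n_placed + 1L
      xs[n_placed] <- cx
      ys[n_placed] <- cy
    }
  }
  tibble(x = xs, y = ys)
}

#' Render a display specification to a grayscale image
#'
#' Draws each letter as two strokes of length `stroke_len` times the image
#' height at its orientation, on the display's background (uniform gray or
#' seeded 1/f noise). Stroke width is `max(1, 0.003 * height)` pixels with
#' butt caps, so the bounding extent of each stroke equals its nominal length.
#' Rendering is deterministic: the same specification always yields the
#' identical image.
#'
#' @param display A one-row slice of a design's `displays` tibble (or any list
#'   with `letters` and `background` fields; see [build_design()]).
#' @param height,width Output size in pixels (default 1000 x 1000, the
#'   pre-generated-stimulus dialect's resolution).
#' @return Integer matrix of gray values 0-255 (class `display_image`).
#' @export
render_display <- function(display, height = 1000L, width = height) {
  bg <- display_background(display)
  img <- background_matrix(bg, height, width)
  letters <- display_letters(display)
  if (!is.null(letters) && nrow(letters) > 0) {
    for (i in seq_len(nrow(letters))) {
      img <- draw_letter(img, letters[i, ], height)
    }
  }
  structure(img, class = c("display_image", "matrix", "array"))
}

display_letters <- function(display) {
  if (is.data.frame(display) && "letters" %in% names(display)) {
    display$letters[[1]]
  } else {
    display$letters
  }
}

display_background <- function(display) {
  if (is.data.frame(display) && "background" %in% names(display)) {
    display$background[[1]]
  } else {
    display$background
  }
}

background_matrix <- function(bg, height, width) {
  if (is.null(bg) || identical(bg$type, "uniform")) {
    gray <- as.integer(bg$gray %||% 128L)
    matrix(gray, height, width)
  } else if (identical(bg$type, "noise")) {
    unclass(generate_noise(height, width, exponent = bg$exponent %||% 1.3,
                           seed = bg$seed %||% 1L))
  } else {
    abort("Unknown background type; use 'uniform' or 'noise'.")
  }
}

# paint one letter's strokes into the image (pixel coords derived from
# screen-height fractions; x maps through the height so geometry is isotropic)
draw_letter <- function(img, letter, height) {
  len_px <- letter$stroke_len * height
  hw <- max(1, 0.003 * height) / 2
  local <- letter_strokes(letter$kind) * len_px
  # inset the cross stroke by its half-width so the glyph bounding box
  # equals the nominal stroke length exactly
  local[2, c(2, 4)] <- local[2, c(2, 4)] +
    if (letter$kind == "T") hw else -hw
  strokes <- rotate_strokes(local, letter$orientation)
  cx <- letter$x * height
  cy <- letter$y * height
  ext <- max(abs(strokes)) + hw
  if (cx - ext < 0 || cx + ext > ncol(img) ||
      cy - ext < 0 || cy + ext > nrow(img)) {
    abort(sprintf("Letter at (%.3f, %.3f) extends outside the image.",
                  letter$x, letter$y))
  }
  for (k in seq_len(nrow(strokes))) {
    img <- draw_stroke(img, cx + strokes[k, 1], cy + strokes[k, 2],
                       cx + strokes[k, 3], cy + strokes[k, 4], hw,
                       as.integer(letter$gray))
  }
  img
}

# pixels whose centers fall within half-width of the segment (butt-capped)
draw_stroke <- function(img, x1, y1, x2, y2, hw, gray) {
  rows <- max(1L, floor(min(y1, y2) - hw) + 1L):
    min(nrow(img), ceiling(max(y1, y2) + hw))
  cols <- max(1L, floor(min(x1, x2) - hw) + 1L):
    min(ncol(img), ceiling(max(x1, x2) + hw))
  px <- outer(rep(1, length(rows)), cols - 0.5)
  py <- outer(rows - 0.5, rep(1, length(cols)))
  dx <- x2 - x1
  dy <- y2 - y1
  len2 <- dx^2 + dy^2
  if (len2 == 0) {
    hit <- (px - x1)^2 + (py - y1)^2 <= hw^2
  } else {
    t <- ((px - x1) * dx + (py - y1) * dy) / len2
    perp2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
    hit <- t >= 0 & t <= 1 & perp2 <= hw^2
  }
  img[rows, cols][hit] <- gray
  img
}

# logical mask of the pixels a letter occupies, same geometry as draw_letter
letter_mask <- function(letter, height, width = height) {
  probe <- as.list(letter)
  probe$gray <- 1L   # marker value; the letter's own gray may be 0
  img <- matrix(0L, height, width)
  img <- draw_letter(img, probe, height)
  img != 0L
}

#' Target-background contrast from a rendered image
#'
#' Computes the signed contrast used to relate miss errors to target
#' visibility: target gray minus the mean background gray in a square patch
#' centered on the target. The patch side is `patch_scale` times the stroke
#' length (default twice), and the target's own pixels are excluded from the
#' background mean. The patch is clipped to the image bounds.
#'
#' @param image Gray matrix (e.g. from [render_display()]).
#' @param target One-row tibble/list describing the target letter (`kind`,
#'   `x`, `y`, `orientation`, `gray`, `stroke_len`).
#' @param patch_scale Patch side as a multiple of the stroke length.
#' @return Signed numeric contrast (target gray minus mean patch gray).
#' @export
tb_contrast <- function(image, target, patch_scale = 2) {
  image <- unclass(image)
  h <- nrow(image)
  w <- ncol(image)
  half <- patch_scale * target$stroke_len * h / 2
  cx <- target$x * h
  cy <- target$y * h
  rows <- max(1L, floor(cy - half) + 1L):min(h, ceiling(cy + half))
  cols <- max(1L, floor(cx - half) + 1L):min(w, ceiling(cx + half))
  if (length(rows) == 0 || length(cols) == 0) {
    abort("Contrast patch has zero area after clipping to the image.")
  }
  mask <- letter_mask(target, h, w)[rows, cols]
  patch <- image[rows, cols]
  bg <- patch[!mask]
  if (length(bg) == 0) {
    abort("Contrast patch contains no background pixels.")
  }
  as.numeric(target$gray) - mean(bg)
}
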