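# Shared fixtures for the test suite. Designs are cached per session because
# building the letter layouts is the slow part.

derive_acceptance_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max, n))
}

upright_letter <- function(kind = "T", x = 0.5, y = 0.5, gray = 255L,
                           orientation = 360, stroke_len = 0.03) {
  tibble::tibble(kind = kind, x = x, y = y, orientation = orientation,
                 gray = as.integer(gray), stroke_len = stroke_len)
}

uniform_display <- function(letters, gray = 128L) {
  list(letters = letters, background = list(type = "uniform", gray = gray))
}

cached_design <- local({
  cache <- list()
  function(experiment, seed) {
    key <- paste(experiment, seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- build_design(experiment, seed = seed)
    }
    cache[[key]]
  }
})

# hand-built four-pair session: display A missed on both copies, B missed on
# copy 1 only, C and D hit on both; used for direct rate enumeration
tiny_paired_session <- function() {
  miss <- c(A1 = TRUE, A2 = TRUE, B1 = TRUE, B2 = FALSE,
            C1 = FALSE, C2 = FALSE, D1 = FALSE, D2 = FALSE)
  tibble::tibble(
    participant_id = "p01",
    trial_index = seq_along(miss),
    display_id = rep(c("A", "B", "C", "D"), each = 2),
    copy = rep(1:2, 4),
    set_size = 18L,
    target_present = TRUE,
    response = ifelse(miss, "absent", "present"),
    rt_ms = 1000,
    corrected = FALSE
  )
}
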