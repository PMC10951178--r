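#' Synthesize a 1/f^exponent noise background image
#'
#' Generates a grayscale noise image whose radially averaged power spectrum
#' falls off as \eqn{1/f^{\alpha}} with frequency, the textured background used
#' to make letter targets harder to segment (a rough stand-in for mammogram-like
#' texture). `exponent = 0` gives white noise; the package default elsewhere is
#' 1.3.
#'
#' The image is built in the frequency domain: a white-noise field is filtered
#' by \eqn{f^{-\alpha/2}} in amplitude (so power goes as \eqn{f^{-\alpha}}),
#' inverse-transformed, standardized, and mapped to 8-bit grays with mid-gray
#' mean (pixel = 127.5 + 127.5 z / 3.5, clipped to \[0, 255\] and rounded).
#'
#' @param height,width Image size in pixels; both must be at least 32.
#' @param exponent Spectral exponent \eqn{\alpha \ge 0}.
#' @param seed Integer seed; the same seed always yields the identical image.
#' @return An object of class `noise_image`: the `height x width` integer
#'   matrix of gray values in 0-255, with attributes `exponent` and `seed`.
#' @examples
#' img <- generate_noise(128, 128, exponent = 1.3, seed = 7)
#' fit_spectral_exponent(img)
#' @seealso [fit_spectral_exponent()], [render_display()]
#' @export
generate_noise <- function(height, width, exponent = 1.3, seed = 1L) {
  if (!is.numeric(height) || !is.numeric(width) ||
      length(height) != 1 || length(width) != 1 ||
      height < 32 || width < 32) {
    abort("`height` and `width` must be single integers >= 32.")
  }
  if (!is.numeric(exponent) || length(exponent) != 1 || exponent < 0) {
    abort("`exponent` must be a single non-negative number.")
  }
  height <- as.integer(height)
  width <- as.integer(width)

  z <- local_seed_eval(seed, {
    white <- matrix(stats::rnorm(height * width), height, width)
    f <- radial_frequency(height, width)
    filt <- ifelse(f == 0, 0, f^(-exponent / 2))
    shaped <- Re(stats::fft(stats::fft(white) * filt, inverse = TRUE))
    (shaped - mean(shaped)) / stats::sd(shaped)
  })

  px <- round(127.5 + 127.5 * pmin(pmax(z / 3.5, -1), 1))
  px <- matrix(as.integer(px), height, width)
  structure(px, exponent = exponent, seed = as.integer(seed),
            class = c("noise_image", "matrix", "array"))
}

# matrix of radial frequency magnitudes (cycles/pixel) in FFT layout
radial_frequency <- function(height, width) {
  fy <- c(0:(height %/% 2), -((height - height %/% 2 - 1):1)) / height
  fx <- c(0:(width %/% 2), -((width - width %/% 2 - 1):1)) / width
  sqrt(outer(fy^2, fx^2, `+`))
}

#' Estimate the spectral exponent of an image
#'
#' Computes the 2-D power spectrum, averages it in logarithmic radial-frequency
#' bins, and fits a straight line to log power versus log frequency over the
#' mid-frequency range. The negated slope estimates the exponent \eqn{\alpha}
#' of a \eqn{1/f^{\alpha}} texture; on white noise it is near 0.
#'
#' Frequencies below `f_min` (dominated by a handful of Fourier coefficients)
#' and above `f_max` (where the square sampling grid is anisotropic) are
#' excluded from the fit.
#'
#' @param image Numeric matrix of pixel values (e.g. a [generate_noise()]
#'   result).
#' @param f_min,f_max Radial frequency range (cycles/pixel) used in the fit.
#' @param n_bins Number of log-spaced radial bins.
#' @return A one-row tibble with columns `exponent` (negated fitted slope),
#'   `intercept` and `n_bins_used`.
#' @export
fit_spectral_exponent <- function(image, f_min = 4 / min(dim(image)),
                                  f_max = 0.25, n_bins = 24) {
  image <- unclass(image)
  stopifnot(is.matrix(image), is.numeric(image))
  centered <- image - mean(image)
  pow <- Mod(stats::fft(centered))^2
  f <- radial_frequency(nrow(image), ncol(image))

  keep <- f >= f_min & f <= f_max
  edges <- exp(seq(log(f_min), log(f_max), length.out = n_bins + 1))
  bin <- cut(f[keep], breaks = edges, include.lowest = TRUE)
  mean_pow <- tapply(pow[keep], bin, mean)
  mean_f <- tapply(f[keep], bin, mean)
  ok <- !is.na(mean_pow) & mean_pow > 0
  fit <- stats::lm.fit(cbind(1, log(mean_f[ok])), log(mean_pow[ok]))
  tibble(
    exponent = -unname(fit$coefficients[2]),
    intercept = unname(fit$coefficients[1]),
    n_bins_used = sum(ok)
  )
}
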