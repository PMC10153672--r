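# Small in-code fixtures shared across test files.

tiny_config <- function(n_cases = 4, seed = 1, noise_sigma = 6, ...) {
  synth_config(n_cases = n_cases, frame_count = 16, frame_shape = c(48, 48),
               lesion_axes_range = c(6, 10), noise_sigma = noise_sigma,
               seed = seed, ...)
}

# a constant-coordinate track of n frames
const_track <- function(n, x_min = 10, y_min = 12, x_max = 30, y_max = 28,
                        case_id = "t") {
  tibble::tibble(case_id = case_id, frame_index = 0:(n - 1),
                 x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
                 status = "observed")
}

random_roi <- function(nr, nc, seed) {
  set.seed(seed)
  matrix(runif(nr * nc, 0, 255), nr, nc)
}

# two-Gaussian-blob toy classification set
toy_blobs <- function(n = 200, sep = 6, seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(rnorm(n, sep * y), rnorm(n, sep * y))
  list(x = x, y = y)
}
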