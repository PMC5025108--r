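#' Default ICM synaptic weight matrix
#'
#' The constant 3x3 link kernel: a fired pixel contributes 1 to its own
#' feeding input on the next step and 0.01 to each 4-neighbour, stimulating
#' similar-intensity neighbours to fire.
#'
#' @return A 3x3 numeric matrix.
#' @export
icm_weights <- function() {
  matrix(c(0, 0.01, 0,
           0.01, 1, 0.01,
           0, 0.01, 0), nrow = 3, byrow = TRUE)
}

#' ICM network parameters
#'
#' Bundles and validates the constants of the intersecting cortical model:
#' the feeding decay `f`, threshold decay `g`, threshold amplitude `h`, the
#' number of iterations `n_iterations`, the initial threshold `e_init` and
#' the 3x3 link weight matrix `w`.
#'
#' Constraints enforced: `0 < g < f < 1` (both decays below 1, and `f > g`
#' so every stimulated neuron eventually fires); `h < 0` (a negative
#' threshold amplitude keeps a fired neuron firing on all later steps);
#' `e_init > 1` so that no pixel with stimulus `S <= 1` can fire on the very
#' first step.
#'
#' @param f Feeding decay coefficient, in (0, 1), greater than `g`.
#' @param g Threshold decay coefficient, in (0, `f`).
#' @param h Threshold amplitude, strictly negative.
#' @param n_iterations Number of network iterations (>= 1).
#' @param e_init Initial threshold value (default 5).
#' @param w 3x3 link weight matrix (default [icm_weights()]).
#' @return An object of class `icm_params`.
#' @export
icm_params <- function(f, g, h, n_iterations, e_init = 5, w = icm_weights()) {
  stopifnot(is.numeric(f), is.numeric(g), is.numeric(h))
  if (!(0 < g && g < f && f < 1)) {
    stop("ICM decay coefficients must satisfy 0 < g < f < 1 (got f = ",
         f, ", g = ", g, ")")
  }
  if (h >= 0) stop("threshold amplitude h must be negative (got ", h, ")")
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (e_init <= 1) stop("e_init must exceed 1 so no pixel fires at step 1")
  if (!is.matrix(w) || any(dim(w) != 3L) || any(w < 0)) {
    stop("w must be a non-negative 3x3 matrix")
  }
  structure(
    list(f = f, g = g, h = h, n_iterations = as.integer(n_iterations),
         e_init = e_init, w = w),
    class = "icm_params"
  )
}

#' @export
print.icm_params <- function(x, ...) {
  cat(sprintf("ICM parameters: f = %.4f, g = %.4f, h = %.4f, n = %d, E0 = %g\n",
              x$f, x$g, x$h, x$n_iterations, x$e_init))
  invisible(x)
}

#' Initial ICM state
#'
#' Feeding `F` and pulse `Y` start at zero; the dynamic threshold `E` starts
#' uniformly at `e_init`, set high so the network produces output within few
#' iterations only once thresholds have decayed below the strongest stimuli.
#'
#' @param image Stimulus matrix (defines the grid shape).
#' @param params [icm_params()] object.
#' @return An `icm_state` list with elements `F`, `E`, `Y` (matrices sharing
#'   the image's shape) and `iteration = 0`.
#' @export
icm_init <- function(image, params) {
  stopifnot(inherits(params, "icm_params"))
  d <- dim(image)
  structure(
    list(F = matrix(0, d[1], d[2]),
         E = matrix(params$e_init, d[1], d[2]),
         Y = matrix(0, d[1], d[2]),
         iteration = 0L),
    class = "icm_state"
  )
}

#' One ICM iteration
#'
#' Advances the three coupled recurrences by one step:
#' \deqn{F' = f F + S + (W * Y)}
#' \deqn{Y' = [F' > E]}
#' \deqn{E' = g E + h Y'}
#' where `W * Y` is the same-shape 2-D correlation of the previous pulse
#' image with the link kernel (zero padding outside the grid). The freshly
#' updated feeding `F'` is compared against the threshold from the previous
#' step, and the threshold then decays and is pushed by `h` where the pixel
#' fired; with `h < 0` a fired pixel's threshold drops so it keeps firing.
#' Firing requires strict inequality; exact ties do not fire.
#'
#' This is the readable reference implementation; [run_icm()] uses a
#' compiled equivalent.
#'
#' @param state `icm_state` from [icm_init()] or a previous step.
#' @param s Stimulus matrix (same shape as the state grids).
#' @param params [icm_params()] object.
#' @return The updated `icm_state`.
#' @export
icm_step <- function(state, s, params) {
  stopifnot(inherits(state, "icm_state"), inherits(params, "icm_params"))
  if (!all(dim(state$F) == dim(s))) {
    stop("state shape ", paste(dim(state$F), collapse = "x"),
         " does not match stimulus shape ", paste(dim(s), collapse = "x"))
  }
  f_new <- params$f * state$F + s + link_input(state$Y, params$w)
  y_new <- (f_new > state$E) + 0
  e_new <- params$g * state$E + params$h * y_new
  structure(
    list(F = f_new, E = e_new, Y = y_new, iteration = state$iteration + 1L),
    class = "icm_state"
  )
}

# Same-shape 2-D correlation of the pulse image with a 3x3 kernel, zero
# padding at the borders (border pixels simply receive less linking input).
link_input <- function(y, w) {
  nr <- nrow(y)
  nc <- ncol(y)
  pad <- matrix(0, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- y
  out <- matrix(0, nr, nc)
  for (a in -1:1) {
    for (b in -1:1) {
      wv <- w[a + 2L, b + 2L]
      if (wv == 0) next
      out <- out + wv * pad[(2L + a):(nr + 1L + a), (2L + b):(nc + 1L + b)]
    }
  }
  out
}

#' Run the ICM network and return the final pulse image
#'
#' Iterates [icm_step()] `params$n_iterations` times from [icm_init()] and
#' returns the pulse image `Y` at the final iteration as the segmentation,
#' optionally with the full per-iteration pulse history for diagnostics.
#' The loop runs in compiled code; results are identical to iterating
#' [icm_step()].
#'
#' @param image Stimulus matrix `S` in `[0, 1]` (typically the
#'   LoG-preprocessed frame from [apply_log()]).
#' @param params [icm_params()] object.
#' @param history If `TRUE`, also return every iteration's pulse image.
#' @return A list with `mask` (0/1 matrix, the pulse image after the final
#'   iteration) and `history` (list of 0/1 matrices, or `NULL`).
#' @export
run_icm <- function(image, params, history = FALSE) {
  stopifnot(inherits(params, "icm_params"))
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("stimulus must be a numeric matrix")
  }
  res <- icm_run_cpp(image, params$f, params$g, params$h,
                     params$n_iterations, params$e_init, params$w,
                     isTRUE(history))
  list(mask = res$mask, history = if (isTRUE(history)) res$history else NULL)
}
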