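#' Synthetic sperm-frame specification
#'
#' Describes a phase-contrast-like test frame: dark elliptical sperm heads
#' on a brighter, non-uniformly illuminated background, thin 1-px tails,
#' small mid-intensity debris blobs, an optional fraction of agglutinated
#' (touching) head pairs, and optional additive Gaussian noise. Defaults
#' emulate the acquisition the detector targets: 480x640 frames holding 60
#' sperm cells at 40x magnification, heads a few pixels across, debris
#' intensity between head and background so intensity-based rejection is
#' exercised.
#'
#' @param height,width Frame size in pixels (default 480 x 640).
#' @param n_heads Number of sperm heads (default 60).
#' @param head_minor,head_major Ranges (low, high) of the head ellipse
#'   semi-minor and semi-major axes in pixels (defaults 2-4 and 3-6).
#' @param head_intensity Head pixel intensity (default 0.35; heads are the
#'   dark blobs).
#' @param background_intensity Mean background intensity (default 0.75).
#' @param illumination_amplitude Peak amplitude of the smooth illumination
#'   field, a tilted plane plus a centred Gaussian vignette (default 0.1).
#' @param tail_intensity Tail pixel intensity (default 0.6).
#' @param tail_length Range of tail lengths in pixels (default 25-50).
#' @param n_debris Number of small debris blobs of 1-3 px (default 15).
#' @param debris_intensity Debris intensity (default 0.55, between heads and
#'   background).
#' @param agglutinated_fraction Fraction of heads placed as touching pairs
#'   (default 0.1).
#' @param noise_sigma Standard deviation of additive Gaussian noise in
#'   intensity units (default 0, none).
#' @param seed RNG seed used by [generate_scene()], or `NULL`.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(height = 480, width = 640, n_heads = 60,
                       head_minor = c(2, 4), head_major = c(3, 6),
                       head_intensity = 0.35, background_intensity = 0.75,
                       illumination_amplitude = 0.1, tail_intensity = 0.6,
                       tail_length = c(25, 50), n_debris = 15,
                       debris_intensity = 0.55, agglutinated_fraction = 0.1,
                       noise_sigma = 0, seed = NULL) {
  stopifnot(height >= 16, width >= 16, n_heads >= 0,
            head_intensity < background_intensity,
            head_intensity >= 0, background_intensity <= 1,
            agglutinated_fraction >= 0, agglutinated_fraction <= 1,
            noise_sigma >= 0)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_heads = as.integer(n_heads), head_minor = head_minor,
                 head_major = head_major, head_intensity = head_intensity,
                 background_intensity = background_intensity,
                 illumination_amplitude = illumination_amplitude,
                 tail_intensity = tail_intensity, tail_length = tail_length,
                 n_debris = as.integer(n_debris),
                 debris_intensity = debris_intensity,
                 agglutinated_fraction = agglutinated_fraction,
                 noise_sigma = noise_sigma, seed = seed),
            class = "scene_spec")
}

#' Generate a synthetic sperm frame with exact ground truth
#'
#' Heads are filled rotated ellipses at uniform random interior positions,
#' rejection-sampled so that no two heads overlap except intentionally
#' agglutinated pairs, which are placed touching (slightly overlapping, with
#' centre separation of at least 2 px). Each head gets a 1-px random-walk
#' tail anchored at one tip of its major axis; debris blobs are drawn away
#' from heads and are NOT part of the truth mask. The truth mask is the
#' union of head ellipses only; truth centroids are the analytic ellipse
#' centres.
#'
#' @param spec A [scene_spec()].
#' @param seed Overrides `spec$seed` if given. Fixed seed gives identical
#'   output.
#' @return A list: `image` (matrix in `[0, 1]`), `mask` (0/1 truth matrix),
#'   `centroids` (n_heads x 2 matrix of (row, col) centres), `heads` (data
#'   frame with row, col, minor, major, theta, pair -- the pair id for
#'   agglutinated heads, NA otherwise) and `spec`.
#' @export
generate_scene <- function(spec = scene_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "scene_spec"))
  if (!is.null(seed)) set.seed(seed)
  h <- spec$height
  w <- spec$width

  image <- matrix(spec$background_intensity, h, w) + illumination_field(h, w,
    spec$illumination_amplitude)
  mask <- matrix(0, h, w)

  heads <- place_heads(spec)
  n <- nrow(heads)

  # rasterise heads into the truth mask
  head_px <- vector("list", n)
  if (n > 0) {
    for (i in seq_len(n)) {
      px <- ellipse_pixels(heads$row[i], heads$col[i], heads$minor[i],
                           heads$major[i], heads$theta[i], h, w)
      head_px[[i]] <- px
      mask[px] <- 1
    }
  }

  # tails (drawn first so heads overwrite their anchor pixels)
  if (n > 0) {
    for (i in seq_len(n)) {
      tl <- stats::runif(1, spec$tail_length[1], spec$tail_length[2])
      tpx <- tail_pixels(heads$row[i], heads$col[i], heads$major[i],
                         heads$theta[i], tl, h, w)
      if (length(tpx)) {
        tpx <- tpx[mask[tpx] == 0]
        image[tpx] <- spec$tail_intensity
      }
    }
  }

  # debris: small blobs kept clear of the truth mask (2-px clearance)
  if (spec$n_debris > 0) {
    placed <- 0L
    attempts <- 0L
    while (placed < spec$n_debris && attempts < 200L * spec$n_debris) {
      attempts <- attempts + 1L
      r0 <- sample(3:(h - 2), 1)
      c0 <- sample(3:(w - 2), 1)
      win_r <- max(1, r0 - 3):min(h, r0 + 3)
      win_c <- max(1, c0 - 3):min(w, c0 + 3)
      if (any(mask[win_r, win_c] == 1)) next
      size <- sample(1:3, 1)
      px <- (c0 - 1L) * h + r0
      if (size > 1) {
        nb <- rbind(c(r0 - 1L, c0), c(r0 + 1L, c0), c(r0, c0 - 1L),
                    c(r0, c0 + 1L))
        pick <- nb[sample(4, size - 1L), , drop = FALSE]
        px <- c(px, (pick[, 2] - 1L) * h + pick[, 1])
      }
      image[px] <- spec$debris_intensity
      placed <- placed + 1L
    }
  }

  # heads last: head pixels take the exact head intensity
  if (n > 0) {
    for (i in seq_len(n)) image[head_px[[i]]] <- spec$head_intensity
  }

  image <- pmin(pmax(image, 0), 1)
  if (spec$noise_sigma > 0) {
    image <- add_gaussian_noise(image, spec$noise_sigma)
  }

  cents <- cbind(row = heads$row, col = heads$col)
  list(image = image, mask = mask, centroids = cents, heads = heads,
       spec = spec)
}

#' Add i.i.d. zero-mean Gaussian noise to an image
#'
#' @param image Matrix in `[0, 1]`.
#' @param sigma Noise standard deviation in intensity units (>= 0;
#'   `sigma = 0` returns the image unchanged).
#' @param seed Optional RNG seed; `NULL` uses the current RNG state.
#' @return The noisy image, clipped back to `[0, 1]`.
#' @export
add_gaussian_noise <- function(image, sigma, seed = NULL) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(image)
  if (!is.null(seed)) set.seed(seed)
  noisy <- image + stats::rnorm(length(image), mean = 0, sd = sigma)
  dim(noisy) <- dim(image)
  pmin(pmax(noisy, 0), 1)
}

# ---- internal scene helpers ----------------------------------------------

# smooth non-uniform illumination: tilted plane + centred Gaussian vignette
illumination_field <- function(h, w, amplitude) {
  if (amplitude == 0) return(matrix(0, h, w))
  rn <- (seq_len(h) - 0.5) / h - 0.5
  cn <- (seq_len(w) - 0.5) / w - 0.5
  a <- stats::runif(2, -1, 1)
  plane <- outer(a[1] * rn, a[2] * cn, `+`)
  depth <- stats::runif(1, 0.5, 1)
  s2 <- 0.125  # vignette scale in normalised coordinates (sd ~ 0.35)
  vign <- -depth * exp(-(outer(rn^2, cn^2, `+`)) / (2 * s2))
  amplitude * 0.5 * (plane + vign)
}

# radius of an ellipse (semi-axes a >= b, orientation theta) along the
# direction phi, measured from the centre
ellipse_radius <- function(a, b, theta, phi) {
  psi <- phi - theta
  a * b / sqrt((b * cos(psi))^2 + (a * sin(psi))^2)
}

place_heads <- function(spec) {
  n <- spec$n_heads
  empty <- data.frame(row = numeric(0), col = numeric(0),
                      minor = numeric(0), major = numeric(0),
                      theta = numeric(0), pair = integer(0))
  if (n == 0L) return(empty)
  n_pairs <- floor(spec$agglutinated_fraction * n / 2)
  margin <- ceiling(spec$head_major[2]) + 3

  draw_axes <- function() {
    minor <- stats::runif(1, spec$head_minor[1], spec$head_minor[2])
    major <- stats::runif(1, max(spec$head_major[1], minor),
                          spec$head_major[2])
    c(minor, major)
  }
  heads <- empty
  clear_of_all <- function(r, c, major, exclude = integer(0)) {
    if (nrow(heads) == 0L) return(TRUE)
    keep <- setdiff(seq_len(nrow(heads)), exclude)
    if (length(keep) == 0L) return(TRUE)
    d <- sqrt((heads$row[keep] - r)^2 + (heads$col[keep] - c)^2)
    all(d >= heads$major[keep] + major + 2)
  }

  pair_id <- 0L
  placed <- 0L
  attempts <- 0L
  max_attempts <- 500L * n
  while (placed < n) {
    if ((attempts <- attempts + 1L) > max_attempts) {
      stop("could not place ", n, " heads without overlap; ",
           "reduce n_heads or enlarge the frame")
    }
    as_pair <- pair_id < n_pairs && (n - placed) >= 2L
    ax <- draw_axes()
    theta <- stats::runif(1, 0, pi)
    r0 <- stats::runif(1, margin, spec$height - margin)
    c0 <- stats::runif(1, margin, spec$width - margin)
    if (!clear_of_all(r0, c0, ax[2])) next
    if (!as_pair) {
      heads <- rbind(heads, data.frame(row = r0, col = c0, minor = ax[1],
                                       major = ax[2], theta = theta,
                                       pair = NA_integer_))
      placed <- placed + 1L
    } else {
      ax2 <- draw_axes()
      theta2 <- stats::runif(1, 0, pi)
      phi <- stats::runif(1, 0, 2 * pi)
      # agglutinated: membranes in contact, so the dark nuclei (the ground
      # truth regions) sit a ~2 px membrane seam apart along the contact
      # direction
      gap <- ellipse_radius(ax[2], ax[1], theta, phi) +
        ellipse_radius(ax2[2], ax2[1], theta2, phi) + 2
      gap <- max(gap, 2)  # guaranteed centre separation
      r1 <- r0 + gap * cos(phi)
      c1 <- c0 + gap * sin(phi)
      if (r1 < margin || r1 > spec$height - margin ||
          c1 < margin || c1 > spec$width - margin) next
      if (!clear_of_all(r1, c1, ax2[2])) next
      pair_id <- pair_id + 1L
      heads <- rbind(heads,
                     data.frame(row = c(r0, r1), col = c(c0, c1),
                                minor = c(ax[1], ax2[1]),
                                major = c(ax[2], ax2[2]),
                                theta = c(theta, theta2),
                                pair = c(pair_id, pair_id)))
      placed <- placed + 2L
    }
  }
  heads
}

# linear pixel indices of a filled rotated ellipse, clipped to the frame
ellipse_pixels <- function(r0, c0, minor, major, theta, h, w) {
  ext <- ceiling(major) + 1L
  rows <- max(1L, floor(r0 - ext)):min(h, ceiling(r0 + ext))
  cols <- max(1L, floor(c0 - ext)):min(w, ceiling(c0 + ext))
  dr <- outer(rows - r0, rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - c0)
  u <- (dr * cos(theta) + dc * sin(theta)) / major
  v <- (-dr * sin(theta) + dc * cos(theta)) / minor
  inside <- which(u^2 + v^2 <= 1)
  rr <- rows[((inside - 1L) %% length(rows)) + 1L]
  cc <- cols[((inside - 1L) %/% length(rows)) + 1L]
  (cc - 1L) * h + rr
}

# 1-px random-walk tail anchored at one tip of the head's major axis
tail_pixels <- function(r0, c0, major, theta, length_px, h, w) {
  dir <- sample(c(-1, 1), 1)
  ang <- theta + ifelse(dir < 0, pi, 0)
  pos <- c(r0 + dir * (major + 0.5) * cos(theta),
           c0 + dir * (major + 0.5) * sin(theta))
  px <- integer(0)
  for (k in seq_len(round(length_px))) {
    ang <- ang + stats::rnorm(1, 0, 0.25)
    pos <- pos + c(cos(ang), sin(ang))
    r <- round(pos[1]); c <- round(pos[2])
    if (r < 1 || r > h || c < 1 || c > w) break
    px <- c(px, (c - 1L) * h + r)
  }
  unique(px)
}
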