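# Independent reference implementations used as oracles. These are literal,
# slow transcriptions kept deliberately separate from the package's code
# paths.

# naive quadruple-loop 2-D convolution with mirror padding (edge not
# duplicated), matching the contract of apply_log()'s convolution
naive_convolve_reflect <- function(image, kernel) {
  nr <- nrow(image)
  nc <- ncol(image)
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  reflect <- function(i, n) {
    if (i < 1L) 2L - i else if (i > n) 2L * n - i else i
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (a in -kr:kr) {
        for (b in -kc:kc) {
          acc <- acc + kernel[a + kr + 1L, b + kc + 1L] *
            image[reflect(i - a, nr), reflect(j - b, nc)]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# literal per-pixel transcription of the three ICM recurrences:
# F' = f*F + S + (W correlated with previous Y, zero padded),
# Y' = (F' > previous E), E' = g*E + h*Y'
icm_reference <- function(s, params) {
  nr <- nrow(s)
  nc <- ncol(s)
  Fm <- matrix(0, nr, nc)
  Em <- matrix(params$e_init, nr, nc)
  Ym <- matrix(0, nr, nc)
  hist <- vector("list", params$n_iterations)
  for (it in seq_len(params$n_iterations)) {
    Fn <- matrix(0, nr, nc)
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        link <- 0
        for (a in -1:1) {
          for (b in -1:1) {
            ii <- i + a
            jj <- j + b
            if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
              link <- link + params$w[a + 2, b + 2] * Ym[ii, jj]
            }
          }
        }
        Fn[i, j] <- params$f * Fm[i, j] + s[i, j] + link
      }
    }
    Yn <- matrix(0, nr, nc)
    En <- matrix(0, nr, nc)
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        Yn[i, j] <- if (Fn[i, j] > Em[i, j]) 1 else 0
        En[i, j] <- params$g * Em[i, j] + params$h * Yn[i, j]
      }
    }
    Fm <- Fn
    Em <- En
    Ym <- Yn
    hist[[it]] <- Yn
  }
  list(mask = Ym, history = hist)
}

# scalar single-pixel ICM recurrence with no neighbours (the isolated-pixel
# dynamics): returns per-iteration F, E and the firing indicator
scalar_icm <- function(s, f, g, h, e_init, n, w_self = 1) {
  Fv <- 0
  Ev <- e_init
  out <- data.frame(iteration = seq_len(n), F = NA_real_, E = NA_real_,
                    fired = NA)
  y <- 0
  for (it in seq_len(n)) {
    Fv <- f * Fv + s + w_self * y
    y <- as.integer(Fv > Ev)
    Ev <- g * Ev + h * y
    out$F[it] <- Fv
    out$E[it] <- Ev
    out$fired[it] <- y == 1L
  }
  out
}

# recursive flood fill connected-component labelling
flood_fill_labels <- function(mask, connectivity = 8) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  nxt <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (mask[i, j] == 1 && lab[i, j] == 0L) {
        nxt <- nxt + 1L
        queue <- list(c(i, j))
        lab[i, j] <- nxt
        while (length(queue) > 0) {
          p <- queue[[1]]
          queue <- queue[-1]
          for (k in seq_len(nrow(offs))) {
            ii <- p[1] + offs[k, 1]
            jj <- p[2] + offs[k, 2]
            if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
                mask[ii, jj] == 1 && lab[ii, jj] == 0L) {
              lab[ii, jj] <- nxt
              queue <- c(queue, list(c(ii, jj)))
            }
          }
        }
      }
    }
  }
  lab
}

# brute-force mutual information from an explicit contingency table
mi_bruteforce <- function(x, y, bins = 256) {
  xq <- pmin(floor(x * bins) + 1, bins)
  tab <- table(factor(xq, levels = 1:bins), factor(y, levels = c(0, 1)))
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  ent <- function(v) {
    v <- v[v > 0]
    -sum(v * log2(v))
  }
  ent(px) + ent(py) - ent(as.vector(p))
}

# random valid ICM parameter set
random_icm_params <- function() {
  f <- runif(1, 0.1, 0.99)
  icm_params(
    f = f,
    g = runif(1, 0.01, 0.99) * f,
    h = -runif(1, 0.1, 10),
    n_iterations = sample(1:5, 1),
    e_init = 5
  )
}

# small deterministic test scene (fast to segment)
small_scene <- function(seed = 1, noise = 0.02, n_heads = 8) {
  generate_scene(
    scene_spec(height = 140, width = 180, n_heads = n_heads, n_debris = 4,
               noise_sigma = noise),
    seed = seed
  )
}
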