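# Independent brute-force oracles. Each recomputes the quantity under test
# by direct enumeration, sharing no code path with the package internals.

# Per-pixel Gaussian-weighted window mean with symmetric reflection padding.
oracle_local_gaussian_mean <- function(img, W, sigma = 0.3 * ((W - 1) / 2 - 1) + 0.8) {
  p <- (W - 1) %/% 2
  H <- nrow(img); Wd <- ncol(img)
  ri <- c(p:1, 1:H, H:(H - p + 1))
  ci <- c(p:1, 1:Wd, Wd:(Wd - p + 1))
  padded <- img[ri, ci, drop = FALSE]
  x <- seq_len(W) - (W + 1) / 2
  w2 <- outer(exp(-x^2 / (2 * sigma^2)), exp(-x^2 / (2 * sigma^2)))
  w2 <- w2 / sum(w2)
  out <- matrix(NA_real_, H, Wd)
  for (r in seq_len(H)) {
    for (c in seq_len(Wd)) {
      out[r, c] <- sum(w2 * padded[r:(r + W - 1), c:(c + W - 1)])
    }
  }
  out
}

oracle_binarize <- function(img, W, C, sigma = 0.3 * ((W - 1) / 2 - 1) + 0.8,
                            polarity = "dark_jet") {
  mu <- oracle_local_gaussian_mean(img, W, sigma)
  if (polarity == "dark_jet") (img < mu - C) + 0L else (img > mu + C) + 0L
}

# Exhaustive ZNCC argmax over every placement, via stats::cor per window.
oracle_zncc_argmax <- function(img, tpl) {
  th <- nrow(tpl); tw <- ncol(tpl)
  best <- -Inf; best_rc <- c(NA, NA)
  tv <- as.vector(tpl)
  for (r in 1:(nrow(img) - th + 1)) {
    for (c in 1:(ncol(img) - tw + 1)) {
      wv <- as.vector(img[r:(r + th - 1), c:(c + tw - 1)])
      s <- if (sd(wv) == 0 || sd(tv) == 0) 0 else cor(wv, tv)
      if (s > best + 1e-12) {
        best <- s
        best_rc <- c(r, c)
      }
    }
  }
  list(top_left = best_rc, score = best)
}

# Enumerate bounded false-runs in a presence profile by explicit scanning.
oracle_find_breaks <- function(profile, max_gap_px, max_dist_um, pixel_size_um) {
  n <- length(profile)
  out <- NULL
  i <- 1
  while (i <= n) {
    if (!profile[i]) {
      j <- i
      while (j < n && !profile[j + 1]) j <- j + 1
      bounded <- i > 1 && j < n && profile[i - 1] && profile[j + 1]
      gap <- j - i + 1
      dist <- (i - 1) * pixel_size_um
      if (bounded && gap <= max_gap_px && dist <= max_dist_um) {
        out <- rbind(out, c(start = i, end = j, gap = gap, dist = dist))
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

# Trailing windowed OR by direct indexing.
oracle_windowed_or <- function(hits, w) {
  vapply(seq_along(hits),
         function(k) any(hits[max(1, k - w + 1):k]),
         logical(1))
}
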