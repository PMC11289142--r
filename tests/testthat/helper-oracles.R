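# Independent brute-force oracles used to cross-check the pixel-level
# operations. These deliberately share no code with the implementation.

# Per-pixel colour bound check; HSV conversion via grDevices::rgb2hsv,
# looping over pixels one at a time.
oracle_color_mask <- function(frame, spec) {
  H <- dim(frame)[1]; W <- dim(frame)[2]
  out <- matrix(FALSE, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      px <- frame[i, j, ]
      ch <- if (spec$space == "HSV") {
        hsv <- grDevices::rgb2hsv(px[1], px[2], px[3], maxColorValue = 255)
        c(hsv[1] * 360, hsv[2], hsv[3])
      } else px
      for (k in seq_len(nrow(spec$lower))) {
        if (all(ch >= spec$lower[k, ]) && all(ch <= spec$upper[k, ])) {
          out[i, j] <- TRUE
          break
        }
      }
    }
  }
  out
}

# Sliding-window morphological opening: min filter then max filter over a
# disk element, with out-of-image pixels treated as background.
oracle_opening <- function(mask, radius) {
  H <- nrow(mask); W <- ncol(mask)
  off <- expand.grid(dv = -radius:radius, du = -radius:radius)
  off <- off[off$du^2 + off$dv^2 <= radius^2, ]
  filt <- function(m, f) {
    out <- matrix(FALSE, H, W)
    for (i in seq_len(H)) {
      for (j in seq_len(W)) {
        vals <- logical(nrow(off))
        for (k in seq_len(nrow(off))) {
          ii <- i + off$dv[k]; jj <- j + off$du[k]
          vals[k] <- ii >= 1 && ii <= H && jj >= 1 && jj <= W && m[ii, jj]
        }
        out[i, j] <- f(vals)
      }
    }
    out
  }
  filt(filt(mask, all), any)
}

# Connected-component labelling by iterative label propagation: seed every
# foreground pixel with a unique id and repeatedly take the min over the
# 8-neighbourhood until a fixed point.
oracle_label <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  lab[mask] <- seq_len(sum(mask))
  big <- sum(mask) + 1L
  repeat {
    padded <- matrix(big, H + 2, W + 2)
    work <- lab
    work[!mask] <- big
    padded[2:(H + 1), 2:(W + 1)] <- work
    new <- work
    for (dv in -1:1) for (du in -1:1) {
      new <- pmin(new, padded[(2 + dv):(H + 1 + dv), (2 + du):(W + 1 + du)])
    }
    new[!mask] <- 0L
    new[mask & new == big] <- lab[mask & new == big]
    if (all(new == lab)) break
    lab <- new
  }
  # Renumber components densely.
  ids <- sort(unique(lab[lab > 0]))
  out <- match(lab, ids, nomatch = 0L)
  dim(out) <- dim(lab)
  out
}

# Count of pixel centers inside a disk, by explicit distance check over the
# whole image.
oracle_disk_count <- function(H, W, u0, v0, r) {
  count <- 0L
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      u <- j - 1; v <- i - 1
      if ((u - u0)^2 + (v - v0)^2 <= r^2) count <- count + 1L
    }
  }
  count
}

# Explicit 3-D ray-plane intersection for the laser geometry.
oracle_ray_plane <- function(model, pose) {
  pan <- (pose$pan_deg + model$pan_zero_deg) * pi / 180
  tilt <- pose$tilt_deg * pi / 180
  origin <- c(model$mount_x_m, model$mount_y_m, model$mount_z_m)
  dir <- c(sin(tilt) * cos(pan), sin(tilt) * sin(pan), -cos(tilt))
  s <- -origin[3] / dir[3]
  (origin + s * dir)[1:2]
}

# Random well-conditioned pixel->arena homography: a scale/translation map
# perturbed by small projective terms, checked to keep w well away from 0
# over the pixel domain.
random_homography <- function(width = 640, height = 640) {
  repeat {
    H <- matrix(c(runif(1, 2e-4, 5e-4), runif(1, -5e-5, 5e-5), runif(1, -0.02, 0.02),
                  runif(1, -5e-5, 5e-5), runif(1, 2e-4, 5e-4), runif(1, -0.02, 0.02),
                  runif(1, -1e-5, 1e-5), runif(1, -1e-5, 1e-5), 1),
                3, 3, byrow = TRUE)
    corners <- cbind(c(0, width, width, 0), c(0, 0, height, height))
    w <- cbind(corners, 1) %*% H[3, ]
    if (all(w > 0.5)) return(H)
  }
}

random_mask <- function(H = 64, W = 64, p = 0.2) {
  matrix(runif(H * W) < p, H, W)
}

# Small fast scene used throughout the tests: same 20 x 20 cm floor imaged
# at 16 px/cm, marker radius 8 px (= 5 mm).
test_scene <- function(...) {
  args <- list(image_width_px = 320L, image_height_px = 320L,
               body_axes_px = c(55, 28), marker_radius_px = 8,
               noise_sigma = 0, n_frames = 40L, seed = 1L)
  over <- list(...)
  args[names(over)] <- over
  do.call(scene_config, args)
}

frame_occluded_test <- function(scene, i) beamtrack:::frame_occluded(scene, i)
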