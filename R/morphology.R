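# Vectorized binary morphology on (z, y, x) arrays.
# Outside the grid counts as background: erosion shrinks at the border,
# dilation does not wrap.

shift3d <- function(a, axis, by, fill) {
  d <- dim(a)
  n <- d[axis]
  out <- array(fill, dim = d)
  if (abs(by) >= n) return(out)
  src <- if (by >= 0) 1:(n - by) else (1 - by):n
  dst <- if (by >= 0) (1 + by):n else 1:(n + by)
  ix <- function(which) switch(which, src = src, dst = dst)
  if (axis == 1) out[ix("dst"), , ] <- a[ix("src"), , ]
  else if (axis == 2) out[, ix("dst"), ] <- a[, ix("src"), ]
  else out[, , ix("dst")] <- a[, , ix("src")]
  out
}

# one erosion step with a cross (city-block radius 1) element;
# axes = c(2, 3) gives the slice-wise in-plane cross, 1:3 the 3D ball
erode_step <- function(m, axes = c(2, 3)) {
  out <- m
  for (ax in axes) {
    out <- out & shift3d(m, ax, 1L, FALSE) & shift3d(m, ax, -1L, FALSE)
  }
  out
}

dilate_step <- function(m, axes = c(2, 3)) {
  out <- m
  for (ax in axes) {
    out <- out | shift3d(m, ax, 1L, FALSE) | shift3d(m, ax, -1L, FALSE)
  }
  out
}

# morphological closing with the 1-voxel 3D ball (6-connected cross)
close3d <- function(m) {
  erode_step(dilate_step(m, axes = 1:3), axes = 1:3)
}

label_components <- function(bin, connectivity = 26L) {
  lab <- label_components_cpp(as.vector(bin), as.integer(dim(bin)),
                              as.integer(connectivity))
  n <- attr(lab, "n_components")
  lab <- array(lab, dim = dim(bin))
  attr(lab, "n_components") <- n
  lab
}

fill_holes_slicewise <- function(bin) {
  array(fill_holes_slicewise_cpp(as.vector(bin), as.integer(dim(bin))),
        dim = dim(bin))
}

# separable Gaussian smoothing; fwhm_mm scalar, spacing per axis (z,y,x).
# Zero-padded at the borders (kernel normalized over the full support).
gaussian_blur <- function(a, fwhm_mm, spacing_mm) {
  if (fwhm_mm <= 0) return(a)
  sigma_vox <- (fwhm_mm / 2.3548) / spacing_mm
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s < 0.05) next
    r <- max(1L, ceiling(2.5 * s))
    w <- exp(-(0:r)^2 / (2 * s^2))
    w <- c(rev(w[-1]), w)
    w <- w / sum(w)
    out <- a * w[r + 1]
    for (k in 1:r) {
      out <- out + w[r + 1 + k] * shift3d(a, ax, k, 0) +
        w[r + 1 - k] * shift3d(a, ax, -k, 0)
    }
    a <- out
  }
  a
}
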