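# 2-D affine transforms represented as p_out = A %*% p + t on 0-based
# pixel-centre coordinates (x = column, y = row). Images are warped by
# inverse-mapping every output pixel through the same transform, so points and
# pixels move together exactly.

affine_new <- function(A = diag(2), t = c(0, 0)) {
  list(A = A, t = as.numeric(t))
}

affine_identity <- function() affine_new()

# compose: apply `first`, then `second`
affine_compose <- function(second, first) {
  affine_new(second$A %*% first$A, as.numeric(second$A %*% first$t) + second$t)
}

affine_invert <- function(af) {
  Ainv <- solve(af$A)
  affine_new(Ainv, as.numeric(-Ainv %*% af$t))
}

# pts: matrix with columns (x, y); returns transformed matrix
affine_apply_points <- function(af, pts) {
  if (length(pts) == 0) return(matrix(numeric(0), ncol = 2))
  pts <- matrix(as.numeric(pts), ncol = 2)
  out <- pts %*% t(af$A)
  out[, 1] <- out[, 1] + af$t[1]
  out[, 2] <- out[, 2] + af$t[2]
  out
}

# horizontal mirror of a width-w image: x -> (w - 1) - x
affine_hflip <- function(width) {
  affine_new(matrix(c(-1, 0, 0, 1), 2, 2), c(width - 1, 0))
}

# rotation (degrees, counterclockwise in image axes) and isotropic scaling
# about the image centre
affine_rot_scale <- function(theta_deg, scale, width, height) {
  th <- theta_deg * pi / 180
  R <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ctr <- c((width - 1) / 2, (height - 1) / 2)
  affine_new(R, ctr - as.numeric(R %*% ctr))
}

affine_translate <- function(dx, dy) affine_new(diag(2), c(dx, dy))

# Warp a matrix through a forward point transform `af` (bilinear, constant fill).
warp_matrix <- function(px, af, out_h = nrow(px), out_w = ncol(px), fill = 0) {
  inv <- affine_invert(af)
  warp_affine_cpp(px, inv$A, inv$t, as.integer(out_h), as.integer(out_w), fill)
}
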