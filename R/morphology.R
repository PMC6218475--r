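# Low-level 3D binary morphology on plain logical arrays.
#
# All distances follow one discrete-ball convention: a voxel belongs to a
# ball of radius r iff its center lies within Euclidean distance r of the
# ball center. With unit spacing every squared center-to-center distance is
# an integer, so thresholding the exact squared EDT at r^2 + eps reproduces
# direct offset enumeration voxel-for-voxel.

.dist_eps <- 1e-7

# squared Euclidean distance of every voxel to the nearest TRUE voxel
edt_sq <- function(site, spacing = c(1, 1, 1)) {
  stopifnot(is.logical(site), length(dim(site)) == 3L)
  d <- cpp_edt_sq(as.vector(site), dim(site), as.numeric(spacing))
  array(d, dim = dim(site))
}

pad_array <- function(x, p, value = FALSE) {
  d <- dim(x)
  out <- array(value, dim = d + 2L * p)
  out[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3])] <- x
  out
}

crop_array <- function(x, p, d) {
  x[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3])]
}

# Dilation by the discrete Euclidean ball on Z^3: everything within r of a
# foreground voxel. Assumes the caller has padded if out-of-grid growth
# matters.
dilate_ball <- function(mask, r, spacing = c(1, 1, 1)) {
  edt_sq(mask, spacing) <= r^2 + .dist_eps
}

# Erosion by the same ball: voxels with no background voxel within r.
erode_ball <- function(mask, r, spacing = c(1, 1, 1)) {
  edt_sq(!mask, spacing) > r^2 + .dist_eps
}

# Morphological closing on Z^3 (outside the grid is background). Padding by
# ceiling(r) + 1 makes the grid computation identical to the infinite-lattice
# result, so closing is always extensive.
close_ball <- function(mask, r, spacing = c(1, 1, 1)) {
  p <- as.integer(ceiling(r)) + 1L
  d <- dim(mask)
  m <- pad_array(mask, p)
  m <- dilate_ball(m, r, spacing)
  m <- erode_ball(m, r, spacing)
  crop_array(m, p, d)
}

# Fill background components not reachable from the volume border
# (6-connected background).
fill_holes <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  out <- cpp_fill_holes(as.vector(mask), dim(mask))
  array(out, dim = dim(mask))
}

label_components_array <- function(mask, connectivity = 26L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  lab <- cpp_label_components(as.vector(mask), dim(mask),
                              as.integer(connectivity))
  array(lab, dim = dim(mask))
}
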