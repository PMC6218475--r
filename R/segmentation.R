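# Grayscale-to-mask segmentation and per-bone labeling.

# Otsu's threshold on a 256-bin histogram: the bin boundary maximizing
# between-class variance. Returns an intensity value t; the mask is x >= t.
.otsu_threshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (rng[1] == rng[2]) {
    stop("volume has a single intensity value; Otsu thresholding is ",
         "undefined - use method = \"fixed\" with an explicit value")
  }
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  counts <- as.numeric(tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                             all.inside = TRUE), nbins))
  mids <- (breaks[-1] + breaks[-(nbins + 1L)]) / 2
  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  total_w <- w[nbins]
  total_m <- m[nbins]
  # between-class variance for a split after bin k
  k <- seq_len(nbins - 1L)
  w0 <- w[k]
  w1 <- total_w - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, nbins - 1L)
  mu0 <- m[k][valid] / w0[valid]
  mu1 <- (total_m - m[k][valid]) / w1[valid]
  sigma_b[valid] <- w0[valid] * w1[valid] * (mu0 - mu1)^2
  best <- which.max(sigma_b)
  breaks[best + 1L]
}

#' Threshold a grayscale volume into a bone mask
#'
#' Voxels with intensity greater than or equal to the threshold become bone.
#' The threshold is either chosen by Otsu's method (parameter-free,
#' histogram-based) or supplied as a fixed value; either way the value used
#' is logged via `message()` and attached to the result as attribute
#' `"threshold"`.
#'
#' @param volume a [voxel_volume()].
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param fixed_value intensity threshold, required for `method = "fixed"`.
#' @return A [bone_mask()] with attribute `threshold`.
#' @export
threshold_bone <- function(volume, method = c("otsu", "fixed"),
                           fixed_value = NULL) {
  stopifnot(inherits(volume, "voxel_volume"))
  method <- match.arg(method)
  thr <- if (method == "otsu") {
    .otsu_threshold(volume$data)
  } else {
    if (is.null(fixed_value) || !is.numeric(fixed_value)) {
      stop("method = \"fixed\" requires a numeric fixed_value")
    }
    as.numeric(fixed_value)
  }
  message(sprintf("threshold_bone: method=%s threshold=%.6g", method, thr))
  out <- bone_mask(volume$data >= thr, volume$voxel_size_um)
  attr(out, "threshold") <- thr
  attr(out, "threshold_method") <- method
  out
}

#' Remove small connected components from a mask
#'
#' Despeckling before metric computation: only connected components with at
#' least `min_voxels` voxels are retained. Never adds voxels and is
#' idempotent at fixed parameters.
#'
#' @param mask a [bone_mask()].
#' @param min_voxels minimum component size to keep (>= 1).
#' @param connectivity foreground connectivity, 6 or 26 (default 26).
#' @return A [bone_mask()].
#' @export
keep_components <- function(mask, min_voxels, connectivity = 26L) {
  stopifnot(inherits(mask, "bone_mask"))
  if (!is.numeric(min_voxels) || min_voxels < 1) {
    stop("min_voxels must be >= 1")
  }
  lab <- label_components_array(mask$data, connectivity)
  nlab <- max(lab)
  if (nlab == 0L) {
    warning("keep_components: mask is empty")
    return(mask)
  }
  sizes <- tabulate(lab[lab > 0L], nlab)
  keep <- which(sizes >= min_voxels)
  out <- array(lab %in% keep & lab > 0L, dim = dim(mask$data))
  if (!any(out)) warning("keep_components: no component reaches min_voxels; ",
                         "result is empty")
  bone_mask(out, mask$voxel_size_um)
}

#' Restrict a label volume to a bone mask
#'
#' Returns labels that are nonzero only where the mask is bone. Bone voxels
#' the input labeling misses are assigned to a reserved `"unassigned"` label
#' (one above the largest named label) and counted in the attribute
#' `"unassigned_voxels"`. Per-bone delineation itself is taken as user input
#' (painted or registered), not computed.
#'
#' @param mask a [bone_mask()].
#' @param labels a [labeled_bones()] of the same shape.
#' @return A [labeled_bones()] restricted to the mask.
#' @export
label_bones <- function(mask, labels) {
  stopifnot(inherits(mask, "bone_mask"), inherits(labels, "labeled_bones"))
  if (!identical(dim(mask$data), dim(labels$data))) {
    stop("labels shape ", paste(dim(labels$data), collapse = "x"),
         " does not match mask shape ", paste(dim(mask$data), collapse = "x"))
  }
  out <- labels$data
  out[!mask$data] <- 0L
  unassigned <- mask$data & out == 0L
  n_un <- sum(unassigned)
  nm <- labels$label_names
  if (n_un > 0L) {
    reserve <- max(c(0L, as.integer(names(nm)), out)) + 1L
    out[unassigned] <- reserve
    nm[as.character(reserve)] <- "unassigned"
  }
  res <- labeled_bones(out, mask$voxel_size_um, label_names = nm)
  attr(res, "unassigned_voxels") <- n_un
  res
}
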