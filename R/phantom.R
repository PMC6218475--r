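# Synthetic bone phantom: a hollow ellipsoidal cortical shell with carved
# hemispherical surface pits and fully enclosed intracortical cavities, plus
# additive Gaussian intensity noise. Every carve is tallied voxel-exactly so
# downstream erosion metrics can be validated against known ground truth.

#' Specify a synthetic bone phantom
#'
#' The phantom is a hollow ellipsoid ("cortical shell") of bone intensity
#' over background, centered in the volume. Surface erosion is emulated by
#' hemispherical pits: balls centered on the outer shell surface whose
#' intersection with the bone is carved away. Intracortical porosity is
#' emulated by spherical cavities that must lie entirely inside the cortical
#' wall. A voxel belongs to a ball of radius `r` iff its center is within
#' Euclidean distance `r` of the ball center — the same convention the
#' morphology operators use.
#'
#' @param shape integer triple, voxels per axis (z, y, x).
#' @param voxel_size_um voxel edge length in micrometers (default 4.5, the
#'   typical reconstructed micro-CT voxel size for murine hindfeet).
#' @param outer_radii real triple (>= 3 voxels), outer semi-axes of the
#'   shell in (z, y, x) voxel units.
#' @param cortical_thickness wall thickness in voxels (>= 2); inner semi-axes
#'   are `outer_radii - cortical_thickness`.
#' @param pits list of `list(center_direction = <3-vector>, radius_vox = r)`;
#'   the direction is normalized and anchors the pit center on the outer
#'   surface.
#' @param cavities list of `list(center = <voxel coordinate>, radius_vox = r)`
#'   with the ball strictly inside the cortical wall.
#' @param intensities named numeric `c(bone = , background = )` with
#'   `bone > background`.
#' @param noise_sigma standard deviation of additive Gaussian intensity
#'   noise (>= 0).
#' @param seed integer seed making generation bitwise reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(160L, 160L, 160L),
                         voxel_size_um = DEFAULT_VOXEL_SIZE_UM,
                         outer_radii = c(60, 50, 45),
                         cortical_thickness = 12,
                         pits = list(),
                         cavities = list(),
                         intensities = c(bone = 180, background = 20),
                         noise_sigma = 8,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L)) {
    stop("shape must be three integers >= 8")
  }
  outer_radii <- as.numeric(outer_radii)
  if (length(outer_radii) != 3L || any(outer_radii < 3)) {
    stop("outer_radii must be three reals >= 3 voxels")
  }
  if (!is.numeric(cortical_thickness) || cortical_thickness < 2) {
    stop("cortical_thickness must be >= 2 voxels")
  }
  if (cortical_thickness >= min(outer_radii)) {
    stop("cortical_thickness must be smaller than the smallest outer radius")
  }
  if (any(outer_radii > (shape - 1) / 2 - 1)) {
    stop("shell does not fit: outer_radii too large for shape")
  }
  if (!all(c("bone", "background") %in% names(intensities)) ||
      intensities[["bone"]] <= intensities[["background"]]) {
    stop("intensities must name bone and background with bone > background")
  }
  if (!is.numeric(noise_sigma) || noise_sigma < 0) {
    stop("noise_sigma must be >= 0")
  }
  pits <- lapply(pits, function(p) {
    d <- as.numeric(p$center_direction)
    if (length(d) != 3L || sqrt(sum(d^2)) == 0) {
      stop("pit center_direction must be a nonzero 3-vector")
    }
    r <- as.numeric(p$radius_vox)
    if (length(r) != 1L || r <= 0) stop("pit radius_vox must be > 0")
    list(center_direction = d / sqrt(sum(d^2)), radius_vox = r)
  })
  cavities <- lapply(cavities, function(cv) {
    ctr <- as.numeric(cv$center)
    if (length(ctr) != 3L) stop("cavity center must be a 3-vector")
    r <- as.numeric(cv$radius_vox)
    if (length(r) != 1L || r <= 0) stop("cavity radius_vox must be > 0")
    list(center = ctr, radius_vox = r)
  })
  structure(list(shape = shape, voxel_size_um = .check_spacing(voxel_size_um),
                 outer_radii = outer_radii,
                 cortical_thickness = as.numeric(cortical_thickness),
                 pits = pits, cavities = cavities,
                 intensities = c(bone = as.numeric(intensities[["bone"]]),
                                 background =
                                   as.numeric(intensities[["background"]])),
                 noise_sigma = as.numeric(noise_sigma),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# squared normalized ellipsoid coordinate field for semi-axes `radii`
# centered at `ctr` (1-based voxel coordinates)
.ellipsoid_field <- function(shape, ctr, radii) {
  gz <- ((seq_len(shape[1]) - ctr[1]) / radii[1])^2
  gy <- ((seq_len(shape[2]) - ctr[2]) / radii[2])^2
  gx <- ((seq_len(shape[3]) - ctr[3]) / radii[3])^2
  outer(outer(gz, gy, "+"), gx, "+")
}

# discrete ball membership array
.ball_array <- function(shape, center, r) {
  dz <- (seq_len(shape[1]) - center[1])^2
  dy <- (seq_len(shape[2]) - center[2])^2
  dx <- (seq_len(shape[3]) - center[3])^2
  outer(outer(dz, dy, "+"), dx, "+") <= r^2 + .dist_eps
}

# 6-neighborhood dilation by one voxel (used only for geometry validation)
.dilate6_once <- function(b) {
  d <- dim(b)
  out <- b
  out[-1, , ] <- out[-1, , ] | b[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | b[-1, , ]
  out[, -1, ] <- out[, -1, ] | b[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | b[, -1, ]
  out[, , -1] <- out[, , -1] | b[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | b[, , -1]
  out
}

#' Generate a synthetic bone phantom with exact ground truth
#'
#' Builds the noise-free true bone mask (intact shell minus pits minus
#' cavities), records exact carved voxel tallies, and renders a grayscale
#' volume with seeded additive Gaussian noise. Identical spec and seed give
#' bitwise identical output.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom` with elements `volume`
#'   (`voxel_volume`), `mask` (`bone_mask`, the true noise-free occupancy)
#'   and `truth` (class `ground_truth`: `bone_voxels_intact`, `pit_voxels`,
#'   `cavity_voxels`, `expected_erosion_fraction`,
#'   `expected_full_pore_voxels`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  ctr <- (shape + 1) / 2
  inner_radii <- spec$outer_radii - spec$cortical_thickness
  g_out <- .ellipsoid_field(shape, ctr, spec$outer_radii)
  g_in <- .ellipsoid_field(shape, ctr, inner_radii)
  inner_space <- g_in <= 1
  mask <- (g_out <= 1) & !inner_space
  rm(g_out, g_in)
  intact <- sum(mask)

  pit_voxels <- integer(0)
  for (idx in seq_along(spec$pits)) {
    p <- spec$pits[[idx]]
    dvec <- p$center_direction
    tt <- 1 / sqrt(sum((dvec / spec$outer_radii)^2))
    pc <- ctr + tt * dvec
    ball <- .ball_array(shape, pc, p$radius_vox)
    if (any(ball & inner_space)) {
      stop("invalid geometry: pit ", idx,
           " punches through the cortical wall into the inner space ",
           "(radius ", p$radius_vox, " vs cortical thickness ",
           spec$cortical_thickness, ")")
    }
    pit_voxels[idx] <- sum(mask & ball)
    mask <- mask & !ball
  }

  cavity_voxels <- integer(0)
  for (idx in seq_along(spec$cavities)) {
    cv <- spec$cavities[[idx]]
    ball <- .ball_array(shape, cv$center, cv$radius_vox)
    if (!any(ball)) {
      stop("invalid geometry: cavity ", idx, " contains no voxel")
    }
    halo <- .dilate6_once(ball)
    if (any(halo & !mask)) {
      stop("invalid geometry: cavity ", idx,
           " touches the bone surface, a pit, the inner space or the ",
           "background; it must lie entirely within the cortical wall")
    }
    cavity_voxels[idx] <- sum(ball)
    mask <- mask & !ball
  }

  truth <- structure(list(
    bone_voxels_intact = intact,
    pit_voxels = pit_voxels,
    cavity_voxels = cavity_voxels,
    expected_erosion_fraction = if (intact > 0) sum(pit_voxels) / intact else 0,
    expected_full_pore_voxels = sum(cavity_voxels)
  ), class = "ground_truth")

  vol <- array(spec$intensities[["background"]], dim = shape)
  vol[mask] <- spec$intensities[["bone"]]
  if (spec$noise_sigma > 0) {
    vol <- withr::with_seed(spec$seed, {
      vol + array(stats::rnorm(prod(shape), 0, spec$noise_sigma), dim = shape)
    })
  }

  structure(list(volume = voxel_volume(vol, spec$voxel_size_um),
                 mask = bone_mask(mask, spec$voxel_size_um),
                 truth = truth, spec = spec),
            class = "phantom")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(paste0("<ground_truth> intact %d voxels; %d pit(s) carving %d; ",
                     "%d cavity(ies) carving %d; expected erosion fraction ",
                     "%.6g\n"),
              x$bone_voxels_intact, length(x$pit_voxels), sum(x$pit_voxels),
              length(x$cavity_voxels), sum(x$cavity_voxels),
              x$expected_erosion_fraction))
  invisible(x)
}

#' Read a phantom specification from a YAML or JSON file
#'
#' The file holds the fields of [phantom_spec()]; `.yaml`/`.yml` parse as
#' YAML, anything else as JSON.
#'
#' @param path file path.
#' @return A `phantom_spec`.
#' @export
phantom_spec_from_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$pits) && is.data.frame(raw$pits)) {
    raw$pits <- lapply(seq_len(nrow(raw$pits)), function(i) {
      list(center_direction = unlist(raw$pits$center_direction[i]),
           radius_vox = raw$pits$radius_vox[i])
    })
  }
  if (!is.null(raw$cavities) && is.data.frame(raw$cavities)) {
    raw$cavities <- lapply(seq_len(nrow(raw$cavities)), function(i) {
      list(center = unlist(raw$cavities$center[i]),
           radius_vox = raw$cavities$radius_vox[i])
    })
  }
  if (!is.null(raw$intensities)) raw$intensities <- unlist(raw$intensities)
  do.call(phantom_spec, raw)
}

#' Write phantom ground truth to JSON
#'
#' @param truth a `ground_truth` object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
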