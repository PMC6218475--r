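make_report <- function(labels, ep, r = 8, d = 8) {
  df <- data.frame(label = as.character(labels), bone_name = as.character(labels),
                   bone_voxels = 1000L,
                   filled_voxels_in_shell = as.integer(round(ep * 10)),
                   erosion_percent = ep, full_pore_voxels = 0L,
                   full_pore_percent = 0, normalized_erosion = NA_real_,
                   closing_radius_vox = r, surface_distance_vox = d,
                   stringsAsFactors = FALSE)
  class(df) <- c("erosion_report", "data.frame")
  df
}

test_that("fill_pores leaves a convex solid unchanged at any radius", {
  cube <- bone_mask(solid_cube(21, 3))
  for (r in c(2, 5, 10)) {
    out <- fill_pores(cube, erosion_params(r, 5))
    expect_identical(out$data, cube$data)
  }
})

test_that("fill_pores adds exactly the enclosed cavity, any closing radius", {
  arr <- solid_cube(21, 3)
  arr[12:14, 12:14, 12:14] <- FALSE
  m <- bone_mask(arr)
  for (r in c(1.5, 4, 8)) {
    out <- fill_pores(m, erosion_params(r, 5))
    expect_identical(sum(out$data) - sum(arr), 27L)
    expect_true(all(out$data[12:14, 12:14, 12:14]))
  }
})

test_that("oversized structuring elements are rejected", {
  cube <- bone_mask(solid_cube(15, 2))
  expect_error(fill_pores(cube, erosion_params(12, 5)), "larger than volume")
  expect_error(erosion_params(0.5, 5), "closing_radius_vox")
  expect_error(erosion_params(2, 0.2), "surface_distance_vox")
  expect_error(erosion_params(2, 5, connectivity = 18), "connectivity")
})

test_that("surface_shell matches the distance-transform oracle on a ball", {
  n <- 21
  ctr <- (n + 1) / 2
  coord <- seq_len(n) - ctr
  rad2 <- outer(outer(coord^2, coord^2, "+"), coord^2, "+")
  ball <- rad2 <= 8^2 + 1e-7
  m <- bone_mask(ball)
  shell <- surface_shell(m, 2)$data
  # oracle: exact center distance to the complementary set, by enumeration
  d_bone <- oracle_edt_sq(ball)
  d_back <- oracle_edt_sq(!ball)
  ref <- ifelse(ball, d_back <= 4 + 1e-7, d_bone <= 4 + 1e-7)
  expect_identical(shell, array(ref, dim(ball)))
  # center-distance criterion: a distance-2 shell of a radius-8 ball spans
  # radii (6, 10]
  radii <- sqrt(rad2[shell])
  expect_gt(min(radii), 6)
  expect_lte(max(radii), 10 + 1e-7)
})

test_that("surface_shell saturates and is monotone in distance", {
  m <- bone_mask(solid_cube(5, 5))
  d <- dim(m$data)
  expect_true(all(surface_shell(m, sqrt(sum(d^2)))$data))
  prev <- surface_shell(m, 1)$data
  for (dist in c(2, 4, 8)) {
    cur <- surface_shell(m, dist)$data
    expect_true(all(cur | !prev))  # nested superlevel sets
    prev <- cur
  }
})

test_that("intact phantoms have exactly zero erosion", {
  ph <- generate_phantom(small_shell_spec())
  res <- erosion_percent(ph$mask, erosion_params(8, 8))
  expect_identical(res$filled_voxels_in_shell, 0L)
  expect_identical(res$erosion_percent, 0)
  expect_identical(res$bone_voxels, sum(ph$mask$data))
})

test_that("pit erosion is positive, bounded by the carved truth, and monotone", {
  params <- erosion_params(8, 8)
  pit1 <- list(list(center_direction = c(1, 0, 0), radius_vox = 4))
  pit2 <- c(pit1, list(list(center_direction = c(0, -1, 0), radius_vox = 5)))
  ph1 <- generate_phantom(small_shell_spec(pits = pit1))
  ph2 <- generate_phantom(small_shell_spec(pits = pit2))
  r1 <- erosion_percent(ph1$mask, params)
  r2 <- erosion_percent(ph2$mask, params)
  expect_gt(r1$erosion_percent, 0)
  # ball closing under-fills the pit mouth, so the measurement cannot exceed
  # the carved ground truth
  expect_lte(r1$filled_voxels_in_shell, sum(ph1$truth$pit_voxels))
  expect_lte(r2$filled_voxels_in_shell, sum(ph2$truth$pit_voxels))
  # adding a pit never decreases erosion %
  expect_gte(r2$erosion_percent, r1$erosion_percent)
})

test_that("deep enclosed cavities are excluded from erosion but count as pores", {
  arr <- solid_cube(31, 3)
  arr[18:20, 18:20, 18:20] <- FALSE
  m <- bone_mask(arr)
  params <- erosion_params(4, 8)
  # distance-transform oracle: every cavity voxel is deeper than the surface
  # distance from the filled solid's boundary
  depth <- sqrt(oracle_edt_sq(!solid_cube(31, 3)))
  expect_true(all(depth[18:20, 18:20, 18:20] > 8))
  res <- erosion_percent(m, params)
  expect_identical(res$filled_voxels_in_shell, 0L)
  fp <- full_pores(m, params)
  expect_identical(fp$full_pore_voxels, 27L)
})

test_that("full_pores ignores the surface distance entirely", {
  arr <- solid_cube(21, 3)
  arr[12:14, 12:14, 12:14] <- FALSE
  m <- bone_mask(arr)
  vals <- vapply(c(2, 5, 10), function(d) {
    full_pores(m, erosion_params(3, d))$full_pore_voxels
  }, numeric(1))
  expect_identical(vals, rep(27, 3))
  expect_gte(vals[1], 27)
  # shell restriction can only remove voxels
  res <- erosion_percent(m, erosion_params(3, 5))
  expect_lte(res$filled_voxels_in_shell, vals[1])
  # convex solid: no pores at any parameters
  cube <- bone_mask(solid_cube(15, 3))
  for (r in c(2, 6)) {
    expect_identical(full_pores(cube, erosion_params(r, 5))$full_pore_voxels, 0L)
  }
})

test_that("single-label reports duplicate the whole-mask row", {
  ph <- generate_phantom(small_shell_spec(
    pits = list(list(center_direction = c(0, 0, 1), radius_vox = 4))))
  lab <- labeled_bones(array(ifelse(ph$mask$data, 1L, 0L), dim(ph$mask$data)))
  rep1 <- per_bone_report(ph$mask, lab, erosion_params(8, 8))
  expect_identical(nrow(rep1), 2L)
  one <- rep1[rep1$label == "1", ]
  whole <- rep1[rep1$label == "whole", ]
  for (col in c("bone_voxels", "filled_voxels_in_shell", "erosion_percent",
                "full_pore_voxels", "full_pore_percent")) {
    expect_identical(one[[col]], whole[[col]])
  }
  expect_identical(one$bone_name, "Talus")
})

test_that("two-shell phantoms: counts are conserved and attribution is local", {
  sub_spec <- function(pits = list()) {
    phantom_spec(shape = c(64, 64, 64), outer_radii = c(24, 22, 20),
                 cortical_thickness = 10, pits = pits, noise_sigma = 0,
                 seed = 9L)
  }
  phA <- generate_phantom(sub_spec(
    pits = list(list(center_direction = c(1, 0, 0), radius_vox = 4),
                list(center_direction = c(0, 1, 0), radius_vox = 4))))
  phB <- generate_phantom(sub_spec())
  big <- array(FALSE, dim = c(64, 64, 142))
  big[, , 1:64] <- phA$mask$data
  big[, , 79:142] <- phB$mask$data
  lab <- array(0L, dim = dim(big))
  lab[, , 1:64][phA$mask$data] <- 1L
  lab[, , 79:142][phB$mask$data] <- 2L
  mask <- bone_mask(big)
  labels <- labeled_bones(lab)
  params <- erosion_params(6, 6)
  rep2 <- per_bone_report(mask, labels, params)
  a <- rep2[rep2$label == "1", ]
  b <- rep2[rep2$label == "2", ]
  whole <- rep2[rep2$label == "whole", ]
  # per-label counts sum exactly to the whole-mask values
  expect_identical(a$filled_voxels_in_shell + b$filled_voxels_in_shell,
                   whole$filled_voxels_in_shell)
  expect_identical(a$full_pore_voxels + b$full_pore_voxels,
                   whole$full_pore_voxels)
  expect_identical(a$bone_voxels + b$bone_voxels, whole$bone_voxels)
  # pits live only in shell A; the intact shell reports zero erosion
  expect_identical(b$filled_voxels_in_shell, 0L)
  expect_identical(b$erosion_percent, 0)
  expect_gt(a$erosion_percent, 0)
})

test_that("normalization: self gives 1, arithmetic matches, flags not Inf", {
  ph <- generate_phantom(small_shell_spec(
    pits = list(list(center_direction = c(1, 0, 0), radius_vox = 5))))
  lab <- labeled_bones(array(ifelse(ph$mask$data, 1L, 0L), dim(ph$mask$data)))
  rep1 <- per_bone_report(ph$mask, lab, erosion_params(8, 8))
  self <- normalize_report(rep1, rep1)
  expect_equal(self$normalized_erosion, rep(1, nrow(self)))

  base <- list(make_report(c("A", "B"), c(1, 3)), make_report(c("A", "B"), c(3, 5)))
  rpt <- normalize_report(make_report(c("A", "B"), c(4, 4)), base)
  expect_equal(rpt$normalized_erosion, c(2, 1))

  # zero baseline and absent labels: flagged NA, never infinite
  base0 <- make_report(c("A", "B"), c(0, 2))
  expect_warning(r0 <- normalize_report(make_report(c("A", "B", "C"), c(4, 4, 4)),
                                        base0),
                 "zero_baseline")
  expect_true(is.na(r0$normalized_erosion[1]))
  expect_equal(r0$normalized_erosion[2], 2)
  expect_true(is.na(r0$normalized_erosion[3]))
  flags <- attr(r0, "norm_flags")
  expect_identical(unname(flags[c("A", "C")]), c("zero_baseline", "no_baseline"))
  expect_false(any(is.infinite(r0$normalized_erosion), na.rm = TRUE))

  expect_error(normalize_report(rep1, list()), "nonempty")
  expect_error(normalize_report(make_report("A", 1, r = 8),
                                make_report("A", 1, r = 4)),
               "different parameters")
})

test_that("reports round-trip through CSV with the exact column contract", {
  ph <- generate_phantom(small_shell_spec(
    pits = list(list(center_direction = c(0, 1, 0), radius_vox = 4))))
  rep1 <- per_bone_report(ph$mask, NULL, erosion_params(8, 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(rep1, path)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_identical(gsub('"', "", header),
                   c("label", "bone_name", "bone_voxels",
                     "filled_voxels_in_shell", "erosion_percent",
                     "full_pore_voxels", "full_pore_percent",
                     "normalized_erosion", "closing_radius_vox",
                     "surface_distance_vox"))
  back <- read_report(path)
  expect_equal(back$erosion_percent, rep1$erosion_percent)
  expect_identical(back$label, rep1$label)
})
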