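test_that("intact noise-free phantom has zero erosion truth and two intensities", {
  ph <- generate_phantom(small_shell_spec())
  expect_identical(ph$truth$expected_erosion_fraction, 0)
  expect_identical(ph$truth$expected_full_pore_voxels, 0L)
  expect_setequal(unique(as.vector(ph$volume$data)), c(20, 180))
  expect_identical(sum(ph$mask$data), ph$truth$bone_voxels_intact)
})

test_that("cavity carving matches brute-force discrete ball enumeration", {
  # a ball of radius 1.5 centered on a voxel center covers 19 lattice points
  expected <- nrow(oracle_ball_offsets(1.5))
  expect_identical(expected, 19L)
  # odd shape puts the volume center on a voxel center so the cavity center
  # is a lattice point and the discrete ball count is the enumerated one
  ctr <- c(37, 37, 37) + c(24, 0, 0)  # mid-wall on the +z pole
  ph <- generate_phantom(small_shell_spec(
    shape = c(73, 73, 73),
    cavities = list(list(center = ctr, radius_vox = 1.5))))
  expect_identical(ph$truth$cavity_voxels, 19L)
  # larger radius cross-checked against the same enumeration oracle
  # (placed deeper in the wall so its validation halo clears the surface)
  ph2 <- generate_phantom(small_shell_spec(
    shape = c(73, 73, 73),
    cavities = list(list(center = c(37 + 22, 37, 37), radius_vox = 2.5))))
  expect_identical(ph2$truth$cavity_voxels, nrow(oracle_ball_offsets(2.5)))
})

test_that("generation is bitwise reproducible for identical spec and seed", {
  spec <- small_shell_spec(noise_sigma = 8, seed = 123,
                           pits = list(list(center_direction = c(1, 1, 0),
                                            radius_vox = 4)))
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask$data, b$mask$data)
  expect_identical(a$truth, b$truth)
  # different seed changes the noise but not the mask or tallies
  spec2 <- spec
  spec2$seed <- 124L
  c <- generate_phantom(spec2)
  expect_false(identical(a$volume$data, c$volume$data))
  expect_identical(a$mask$data, c$mask$data)
})

test_that("carve bookkeeping: intact - pits - cavities equals mask popcount", {
  specs <- list(
    small_shell_spec(),
    small_shell_spec(pits = list(list(center_direction = c(1, 0, 0),
                                      radius_vox = 4),
                                 list(center_direction = c(0, -1, 0),
                                      radius_vox = 5))),
    small_shell_spec(
      pits = list(list(center_direction = c(0, 0, 1), radius_vox = 3)),
      cavities = list(list(center = c(36.5 + 22, 36.5, 36.5),
                           radius_vox = 2)))
  )
  for (spec in specs) {
    ph <- generate_phantom(spec)
    expect_identical(
      ph$truth$bone_voxels_intact - sum(ph$truth$pit_voxels) -
        sum(ph$truth$cavity_voxels),
      sum(ph$mask$data))
  }
})

test_that("midpoint threshold on a noise-free volume reproduces the mask", {
  ph <- generate_phantom(small_shell_spec(
    pits = list(list(center_direction = c(0, 1, 1), radius_vox = 4))))
  mid <- mean(c(20, 180))
  suppressMessages(
    m <- threshold_bone(ph$volume, method = "fixed", fixed_value = mid))
  expect_identical(m$data, ph$mask$data)
})

test_that("invalid geometry is rejected with a diagnostic", {
  # pit deeper than the cortical wall punches into the inner space
  expect_error(generate_phantom(small_shell_spec(
    pits = list(list(center_direction = c(1, 0, 0), radius_vox = 15)))),
    "punches through")
  # cavity poking out of the wall touches background
  expect_error(generate_phantom(small_shell_spec(
    cavities = list(list(center = c(36.5 + 26, 36.5, 36.5),
                         radius_vox = 3)))),
    "cortical wall")
  # cavity overlapping a carved pit is no longer enclosed
  expect_error(generate_phantom(small_shell_spec(
    pits = list(list(center_direction = c(1, 0, 0), radius_vox = 5)),
    cavities = list(list(center = c(36.5 + 24, 36.5, 36.5),
                         radius_vox = 3)))),
    "cortical wall")
})

test_that("spec validation rejects malformed parameters", {
  expect_error(phantom_spec(outer_radii = c(2, 50, 45)), "outer_radii")
  expect_error(phantom_spec(cortical_thickness = 1), "cortical_thickness")
  expect_error(phantom_spec(intensities = c(bone = 10, background = 20)),
               "intensities")
  expect_error(phantom_spec(noise_sigma = -1), "noise_sigma")
  expect_error(small_shell_spec(
    pits = list(list(center_direction = c(0, 0, 0), radius_vox = 3))),
    "center_direction")
  expect_error(phantom_spec(shape = c(160, 160, 160), outer_radii = c(90, 50, 45)),
               "does not fit")
})

test_that("phantom specs round-trip through YAML and JSON files", {
  spec <- small_shell_spec(pits = list(list(center_direction = c(1, 0, 0),
                                            radius_vox = 4)))
  raw <- list(shape = spec$shape, outer_radii = spec$outer_radii,
              cortical_thickness = spec$cortical_thickness,
              pits = list(list(center_direction = c(1, 0, 0),
                               radius_vox = 4)),
              intensities = list(bone = 180, background = 20),
              noise_sigma = 0, seed = 7)
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(raw, yml)
  from_yaml <- phantom_spec_from_file(yml)
  expect_equal(from_yaml$outer_radii, spec$outer_radii)
  expect_equal(from_yaml$pits, spec$pits)
  jsn <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(raw, jsn, auto_unbox = TRUE)
  from_json <- phantom_spec_from_file(jsn)
  expect_equal(from_json$pits, spec$pits)
  expect_identical(generate_phantom(from_yaml)$mask$data,
                   generate_phantom(from_json)$mask$data)
})
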