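# Symmetry definition files: parser, frame resolution, writer, validator.

test_that("set_dof lines parse into allowed sets, inits and ranges", {
  sd <- parse_sdf(c(
    "symmetry_name t",
    "E = 2*VRT0 + 1*(VRT0:VRT1)",
    "virtual_coordinates_start",
    "xyz VRT0 1,0,0 0,1,0 0,0,0",
    "xyz VRT1 -1,0,0 0,-1,0 0,0,0",
    "virtual_coordinates_stop",
    "connect_virtual R0 ROOT VRT0",
    "connect_virtual R1 ROOT VRT1",
    "connect_virtual J0 VRT0 SUBUNIT",
    "connect_virtual J1 VRT1 SUBUNIT",
    "set_jump_group G J0 J1",
    "set_dof J0 x(21.28) angle_x"))
  d <- sd$dofs$J0
  expect_setequal(d$allowed, c("x", "angle_x"))
  expect_equal(d$init[["x"]], 21.28)
  expect_length(d$range, 0)

  sd2 <- parse_sdf(c(
    "E = 2*VRT0 + 1*(VRT0:VRT1)",
    "virtual_transforms_start",
    "start -1,0,0 0,1,0 0,0,0",
    "rot Rz 2",
    "virtual_transforms_stop",
    "connect_virtual R0 ROOT VRT0",
    "connect_virtual R1 ROOT VRT1",
    "connect_virtual B0 VRT0 SUBUNIT",
    "connect_virtual B1 VRT1 SUBUNIT",
    "set_jump_group G B0 B1",
    "set_dof B0 x(50) angle_x(0:360) angle_y(0:360) angle_z(0:360)"))
  d2 <- sd2$dofs$B0
  expect_setequal(d2$allowed, c("x", "angle_x", "angle_y", "angle_z"))
  expect_equal(d2$range$angle_y, c(0, 360))
})

test_that("the energy line parses one intra and weighted interface terms", {
  sd <- parse_sdf(c(
    "E = 2*VRT0_base + 1*(VRT0_base:VRT1_base)",
    "virtual_coordinates_start",
    "xyz VRT0_base 1,0,0 0,1,0 0,0,0",
    "xyz VRT1_base -1,0,0 0,-1,0 0,0,0",
    "virtual_coordinates_stop",
    "connect_virtual R0 ROOT VRT0_base",
    "connect_virtual R1 ROOT VRT1_base",
    "connect_virtual J0 VRT0_base SUBUNIT",
    "connect_virtual J1 VRT1_base SUBUNIT"))
  expect_equal(sd$energy$intra$frame, "VRT0_base")
  expect_equal(sd$energy$intra$mult, 2)
  expect_length(sd$energy$interfaces, 1)
  expect_equal(sd$energy$interfaces[[1]]$mult, 1)
})

test_that("an SDF without set_dof builds but permits no rigid-body move", {
  sd <- generate_point_sdf("cn", 2)
  sd$dofs <- list()
  conf <- build_conformation(sd, toy8())
  expect_s3_class(conf, "symmetric_conformation")
  expect_error(set_jump_dof(conf, "BASEJUMP", "x", 10), "not allowed")
})

test_that("parser raises diagnostics with line numbers for unknown directives", {
  expect_error(parse_sdf(c(
    "E = 1*VRT0",
    "virtual_coordinates_start",
    "xyz VRT0 1,0,0 0,1,0 0,0,0",
    "virtual_coordinates_stop",
    "connect_virtual J0 VRT0 SUBUNIT",
    "frobnicate yes")), "line 6")
  expect_error(parse_sdf("   "), "empty")
  expect_error(parse_sdf(c(
    "E = 1*VRT0 + 2*VRT1",
    "virtual_coordinates_start",
    "xyz VRT0 1,0,0 0,1,0 0,0,0",
    "virtual_coordinates_stop",
    "connect_virtual J0 VRT0 SUBUNIT")), "intra")
})

test_that("frame resolution expands transform recipes about global axes", {
  sd <- parse_sdf(c(
    "E = 2*VRT0 + 1*(VRT0:VRT1)",
    "virtual_transforms_start",
    "start -1,0,0 0,1,0 0,0,0",
    "rot Rz 2",
    "virtual_transforms_stop",
    "connect_virtual R0 ROOT VRT0",
    "connect_virtual R1 ROOT VRT1",
    "connect_virtual J0 VRT0 SUBUNIT",
    "connect_virtual J1 VRT1 SUBUNIT",
    "set_jump_group G J0 J1"))
  fr <- resolve_frames(sd)
  expect_equal(fr$VRT1$x_axis, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(fr$VRT1$y_axis, c(0, -1, 0), tolerance = 1e-12)
  expect_equal(fr$VRT1$origin, c(0, 0, 0), tolerance = 1e-12)
})

test_that("n-fold expansion produces rotations with trace 1 + 2cos(2 pi k/n)", {
  sd <- generate_point_sdf("cn", 4)
  fr <- resolve_frames(sd)
  B0 <- symmdef:::frame_basis(fr$VRT0)
  for (k in 1:3) {
    Bk <- symmdef:::frame_basis(fr[[paste0("VRT", k)]])
    R <- Bk %*% t(B0)
    expect_equal(sum(diag(R)), 1 + 2 * cos(2 * pi * k / 4), tolerance = 1e-9)
  }
})

test_that("explicit frames keep their printed coordinates and tolerate 7-decimal rounding", {
  f <- virtual_frame("VRT0",
                     c(3.6626788, 5.0513324, -47.0664146),
                     c(0.1035485, -0.2974247, -0.9491134),
                     c(0.9444017, 0.3287938, 0.0000000))
  expect_equal(f$origin, c(3.6626788, 5.0513324, -47.0664146))
  expect_equal(f$x_axis, c(0.1035485, -0.2974247, -0.9491134),
               tolerance = 1e-6)
  expect_equal(sum(f$x_axis * f$y_axis), 0, tolerance = 1e-12)
  expect_error(virtual_frame("bad", c(0, 0, 0), c(1, 0.2, 0), c(0, 1, 0)),
               "orthonormal")
})

test_that("write/parse round-trips every generated definition field-by-field", {
  cases <- list(
    generate_point_sdf("cn", 2),
    generate_point_sdf("cn", 5, init_x = 12.25),
    generate_point_sdf("cn", 38, subsystem = TRUE),
    generate_point_sdf("dn", 4),
    generate_point_sdf("dn", 8, init_x = 9, init_z = 3.5),
    generate_helical_sdf_denovo(100, 4.8, 12, nsub = 5),
    generate_helical_sdf_denovo(-37.5, 2.25, 0, nsub = 6))
  for (sd in cases)
    expect_true(symmdef:::sdf_equal(sd, parse_sdf(write_sdf(sd))))
  # randomized variations of dof inits/ranges and multipliers
  set.seed(11)
  for (i in 1:10) {
    sd <- generate_point_sdf("cn", sample(2:7, 1),
                             init_x = runif(1, 5, 60))
    sd$energy$intra$mult <- sd$energy$intra$mult * runif(1, 0.5, 2)
    sd$dofs$BASEJUMP$init[["x"]] <- runif(1, 1, 99)
    expect_true(symmdef:::sdf_equal(sd, parse_sdf(write_sdf(sd))))
  }
})

test_that("validator reports cycles, undeclared frames and duplicate jumps", {
  base <- c(
    "E = 1*VRT0",
    "virtual_coordinates_start",
    "xyz VRT0 1,0,0 0,1,0 0,0,0",
    "xyz VRT1 -1,0,0 0,-1,0 0,0,0",
    "virtual_coordinates_stop")
  expect_error(parse_sdf(c(base,
    "connect_virtual J0 VRT0 VRT1",
    "connect_virtual J1 VRT1 VRT0",
    "connect_virtual A0 VRT0 SUBUNIT")), "cycle")
  expect_error(parse_sdf(c(
    "E = 1*VRT0 + 1*(VRT0:VRTX)",
    "virtual_coordinates_start",
    "xyz VRT0 1,0,0 0,1,0 0,0,0",
    "virtual_coordinates_stop",
    "connect_virtual J0 VRT0 SUBUNIT")), "VRTX")
  expect_error(parse_sdf(c(base,
    "connect_virtual J0 VRT0 SUBUNIT",
    "connect_virtual J0 VRT1 SUBUNIT")), "duplicate")
  expect_error(parse_sdf(c(base,
    "connect_virtual J0 VRT0 SUBUNIT",
    "set_dof NOPE x(1)")), "NOPE")
})

test_that("the bundled example definitions parse, validate and round-trip", {
  for (f in c("c2_ncs_example.symm", "c2_denovo_example.symm")) {
    path <- system.file("extdata", f, package = "symmdef")
    sd <- parse_sdf(path, is_path = TRUE)
    expect_length(validate_sdf(sd), 0)
    expect_length(symmdef:::attachment_jumps(sd), 2)
    expect_true(symmdef:::sdf_equal(sd, parse_sdf(write_sdf(sd))))
  }
})
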