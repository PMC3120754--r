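# Kinematics: conformation building, master/slave propagation, torsions,
# uniform orientations, full expansion.

anchor_positions <- function(conf) {
  es <- explicit_structure(conf)
  t(vapply(unique(es$chain), function(ch) {
    row <- es[es$chain == ch & es$resno == conf$anchor_resno &
                es$atom == "CA", ]
    as.numeric(row[1, c("x", "y", "z")])
  }, numeric(3)))
}

test_that("the de novo C2 build places anchors at (50,0,0) and (-50,0,0)", {
  conf <- build_conformation(generate_point_sdf("cn", 2), toy8())
  anc <- anchor_positions(conf)
  expect_equal(unname(sort(anc[, 1])), c(-50, 50), tolerance = 1e-9)
  expect_equal(anc[, 2], c(A = 0, B = 0), tolerance = 1e-9)
  expect_equal(symmdef:::vnorm(anc[1, ] - anc[2, ]), 100, tolerance = 1e-9)
})

test_that("identity frames with zero dofs give slaves identical to the master", {
  sd <- parse_sdf(c(
    "E = 2*VRT0 + 1*(VRT0:VRT1)",
    "virtual_coordinates_start",
    "xyz VRT0 1,0,0 0,1,0 0,0,0",
    "xyz VRT1 1,0,0 0,1,0 0,0,0",
    "virtual_coordinates_stop",
    "connect_virtual R0 ROOT VRT0",
    "connect_virtual R1 ROOT VRT1",
    "connect_virtual J0 VRT0 SUBUNIT",
    "connect_virtual J1 VRT1 SUBUNIT",
    "set_jump_group G J0 J1"))
  conf <- build_conformation(sd, toy8())
  es <- explicit_structure(conf)
  expect_lt(max(abs(symmdef:::coords(es[es$chain == "A", ]) -
                    symmdef:::coords(es[es$chain == "B", ]))), 1e-12)
})

test_that("a C3 build places anchors on an equilateral triangle", {
  conf <- build_conformation(generate_point_sdf("cn", 3, init_x = 20), toy8())
  anc <- anchor_positions(conf)
  d <- c(symmdef:::vnorm(anc[1, ] - anc[2, ]),
         symmdef:::vnorm(anc[2, ] - anc[3, ]),
         symmdef:::vnorm(anc[1, ] - anc[3, ]))
  expect_lt(diff(range(d)), 1e-9)
})

test_that("jump dofs propagate to all slaves and preserve the point group", {
  conf <- build_conformation(generate_point_sdf("cn", 2, init_x = 5), toy8())
  conf <- set_jump_dof(conf, "BASEJUMP", "x", 10)
  anc <- anchor_positions(conf)
  expect_equal(symmdef:::vnorm(anc[1, ] - anc[2, ]), 20, tolerance = 1e-9)
  conf <- set_jump_dof(conf, "BASEJUMP", "angle_x", 37)
  es <- explicit_structure(conf)
  # still exactly C2: a 180-degree rotation about z superposes the chains
  expect_lt(ring_symmetry_error(es, 180), 1e-9)
  expect_error(set_jump_dof(conf, "BASEJUMP", "y", 1), "not allowed")
})

test_that("slave coordinates always equal the subunit transform of the master", {
  set.seed(5)
  conf <- build_conformation(generate_point_sdf("cn", 4, init_x = 9), toy8())
  for (i in 1:5) {
    conf <- random_orientation(conf, "BASEJUMP")
    conf <- set_jump_dof(conf, "BASEJUMP", "x", stats::runif(1, 4, 15))
    conf <- set_torsion(conf, 4, "phi", stats::runif(1, -180, 180))
    es <- explicit_structure(conf)
    Tk <- subunit_transforms(conf)
    pm <- symmdef:::coords(es[es$chain == "A", ])
    for (ch in c("B", "C", "D")) {
      pk <- symmdef:::coords(es[es$chain == ch, ])
      expect_lt(max(abs(symmdef:::tf_apply(Tk[[ch]], pm) - pk)), 1e-9)
    }
  }
})

test_that("torsion changes appear simultaneously in every subunit", {
  conf <- build_conformation(generate_point_sdf("cn", 4, init_x = 12), toy8())
  conf <- set_torsion(conf, 5, "phi", -60)
  expect_equal(get_torsion(conf, 5, "phi"), -60, tolerance = 1e-9)
  es <- explicit_structure(conf)
  for (ch in unique(es$chain)) {
    sc <- es[es$chain == ch, ]
    at <- function(rn, nm) as.numeric(sc[sc$resno == rn & sc$atom == nm,
                                         c("x", "y", "z")])
    expect_equal(symmdef:::dihedral(at(4, "C"), at(5, "N"), at(5, "CA"),
                                    at(5, "C")), -60, tolerance = 1e-9)
  }
  # a no-op set leaves all coordinates unchanged
  before <- symmdef:::coords(explicit_structure(conf))
  conf2 <- set_torsion(conf, 5, "phi", get_torsion(conf, 5, "phi"))
  expect_lt(max(abs(symmdef:::coords(explicit_structure(conf2)) - before)),
            1e-9)
  # internal coordinates of all subunits stay identical: self-superposition
  pm <- symmdef:::coords(es[es$chain == "A", ])
  for (ch in c("B", "C", "D"))
    expect_lt(fit_rmsd(symmdef:::coords(es[es$chain == ch, ]), pm), 1e-9)
})

test_that("psi and chi1 torsions are settable and readable", {
  conf <- build_conformation(generate_point_sdf("cn", 2),
                             make_toy_subunit(8, "helix", sidechain = TRUE))
  conf <- set_torsion(conf, 4, "psi", 10)
  expect_equal(get_torsion(conf, 4, "psi"), 10, tolerance = 1e-9)
  conf <- set_torsion(conf, 4, "chi1", -60)
  expect_equal(get_torsion(conf, 4, "chi1"), -60, tolerance = 1e-9)
  expect_error(set_torsion(conf, 1, "phi", 0), "undefined")
})

test_that("random orientations sample SO(3) uniformly", {
  conf <- build_conformation(generate_point_sdf("cn", 2), toy8())
  set.seed(123)
  n <- 20000
  thetas <- numeric(n)
  for (i in seq_len(n)) {
    R <- symmdef:::random_rotation_matrix()
    thetas[i] <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
  }
  # uniform-rotation angle CDF: (theta - sin(theta)) / pi
  ks <- suppressWarnings(stats::ks.test(thetas,
                                        function(q) (q - sin(q)) / pi))
  expect_lt(unname(ks$statistic), 0.02)
  # determinism: the same seed reproduces the orientation
  c1 <- random_orientation(conf, "BASEJUMP", seed = 77)
  c2 <- random_orientation(conf, "BASEJUMP", seed = 77)
  expect_identical(symmdef:::dof_vector(c1), symmdef:::dof_vector(c2))
})

test_that("restricted rotational ranges confine the orientation to one axis", {
  sd <- generate_point_sdf("cn", 2)
  sd$dofs$BASEJUMP <- list(allowed = c("x", "angle_x"), init = c(x = 50),
                           range = list(angle_x = c(0, 360)))
  conf <- build_conformation(sd, toy8())
  conf <- random_orientation(conf, "BASEJUMP", seed = 9)
  v <- conf$jump_values$BASEGROUP
  expect_true(abs(v[["angle_x"]]) > 0)
  expect_equal(v[["angle_y"]], 0)
  expect_equal(v[["angle_z"]], 0)
})

test_that("full expansion realizes all N subunits of a subsystem definition", {
  sd <- generate_point_sdf("cn", 38, subsystem = TRUE, init_x = 30)
  conf <- build_conformation(sd, toy8())
  expect_equal(nrow(conf$subunits), 3L)
  full <- expand_full(conf)
  expect_length(unique(full$chain), 38)
  # S = N: expansion equals the explicit complex
  conf2 <- build_conformation(generate_point_sdf("cn", 3, init_x = 10), toy8())
  expect_equal(symmdef:::coords(expand_full(conf2)),
               symmdef:::coords(explicit_structure(conf2)))
  # expanded C4 has exact 4-fold symmetry
  conf4 <- build_conformation(generate_point_sdf("cn", 4, init_x = 8), toy8())
  conf4 <- random_orientation(conf4, "BASEJUMP", seed = 2)
  expect_lt(ring_symmetry_error(expand_full(conf4), 90), 1e-9)
})

test_that("symmetry reduces the dof count to at most 6", {
  for (n in c(2, 5, 17)) {
    sd <- generate_point_sdf("cn", n)
    expect_lte(nrow(symmdef:::allowed_dofs(sd)), 6)
  }
})
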