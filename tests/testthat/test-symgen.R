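# Symmetry generation: interface orbits, de novo generators, symmetrization,
# helical fitting, crystal expansion, explicit-subunit selection.

test_that("interface orbits of C4 are {adjacent x4, diagonal x2}", {
  oi <- enumerate_interfaces("cn", 4)
  expect_equal(oi$pair_count, 6)
  cls <- oi$classes[order(oi$classes$rep_b), ]
  expect_equal(cls$multiplicity, c(4, 2))
  expect_equal(cls$rep_a, c(1, 1))
  expect_equal(cls$rep_b, c(2, 3))
})

test_that("interface orbit multiplicities always sum to n(n-1)/2", {
  for (n in 2:8) {
    oi <- enumerate_interfaces("cn", n)
    expect_equal(sum(oi$classes$multiplicity), n * (n - 1) / 2)
  }
  for (n in c(4, 6, 8, 10)) {
    oi <- enumerate_interfaces("dn", n)
    expect_equal(sum(oi$classes$multiplicity), n * (n - 1) / 2)
  }
  # C2: one pair, one class; C5: two classes of five (brute-force orbit count)
  expect_equal(enumerate_interfaces("cn", 2)$classes$multiplicity, 1)
  expect_equal(sort(enumerate_interfaces("cn", 5)$classes$multiplicity),
               c(5, 5))
})

test_that("dihedral permutations match the generated D-group geometry", {
  # every permutation of the abstract group must be realized by a rigid
  # rotation of the generated complex
  sd <- generate_point_sdf("dn", 6, init_x = 8, init_z = 4)
  conf <- build_conformation(sd, toy8())
  s <- explicit_structure(conf)
  chains <- unique(s$chain)
  cas <- lapply(chains, function(ch) as.matrix(s[s$chain == ch, c("x", "y", "z")]))
  perms <- point_group_permutations("dn", 6)
  for (p in perms) {
    src <- do.call(rbind, cas)
    dst <- do.call(rbind, cas[p])
    expect_lt(fit_rmsd(src, dst), 1e-8)
  }
})

test_that("the de novo C2 definition carries the canonical energy line and geometry", {
  sd <- generate_point_sdf("cn", 2)
  expect_equal(sd$energy$intra$mult, 2)
  expect_length(sd$energy$interfaces, 1)
  expect_equal(sd$energy$interfaces[[1]]$mult, 1)
  d <- sd$dofs$BASEJUMP
  expect_equal(d$init[["x"]], 50)
  expect_equal(d$range$angle_x, c(0, 360))
})

test_that("subsystem mode encodes 3 of 38 subunits with full-system weights", {
  sd <- generate_point_sdf("cn", 38, subsystem = TRUE)
  expect_length(symmdef:::attachment_jumps(sd), 3)
  expect_equal(sd$total_subunits, 38L)
  expect_equal(sd$energy$intra$mult, 38)
  expect_equal(sd$energy$interfaces[[1]]$mult, 38)
  expect_length(resolve_frames(sd), 38)
})

test_that("Dn definitions expose two translational dofs", {
  sd <- generate_point_sdf("dn", 4)
  ad <- symmdef:::allowed_dofs(sd)
  tr <- ad[ad$dof %in% c("x", "y", "z"), ]
  expect_equal(nrow(tr), 2)
  expect_setequal(tr$dof, c("x", "z"))
})

test_that("every generated definition validates cleanly", {
  cases <- list(generate_point_sdf("cn", 2), generate_point_sdf("cn", 17),
                generate_point_sdf("cn", 38, subsystem = TRUE),
                generate_point_sdf("dn", 4), generate_point_sdf("dn", 12),
                generate_helical_sdf_denovo(100, 4.8, 0, nsub = 5))
  for (sd in cases) expect_length(validate_sdf(sd), 0)
  expect_error(generate_point_sdf("dn", 5), "even")
  expect_error(generate_point_sdf("cn", 1), ">= 2")
})

test_that("symmetrizing an exact C2 dimer recovers 180 degrees with zero residual", {
  sd <- generate_point_sdf("cn", 2, init_x = 6)
  dimer <- explicit_structure(build_conformation(sd, toy8()))
  res <- symmetrize_ncs(dimer, "A", "B")
  expect_equal(res$report$residual_rmsd, 0, tolerance = 1e-9)
  expect_equal(res$report$fitted_angle, 180)
  expect_equal(res$report$order, 2L)
  # the SDF rebuilds the symmetrized complex exactly
  conf <- build_conformation(res$sd, res$master_input)
  expect_lt(max(abs(symmdef:::coords(explicit_structure(conf)) -
                    symmdef:::coords(res$symmetrized))), 1e-8)
})

test_that("a perturbed dimer symmetrizes to an exactly symmetric complex", {
  sd <- generate_point_sdf("cn", 2, init_x = 6)
  dimer <- explicit_structure(build_conformation(sd, toy8()))
  set.seed(3)
  rowsB <- dimer$chain == "B"
  dimer[rowsB, c("x", "y", "z")] <- dimer[rowsB, c("x", "y", "z")] +
    matrix(stats::rnorm(sum(rowsB) * 3, 0, 0.3), ncol = 3)
  res <- symmetrize_ncs(symmdef:::new_structure(dimer), "A", "B")
  expect_gt(res$report$residual_rmsd, 0.05)
  # rebuilt complex is C2 to machine precision
  sy <- res$symmetrized
  R <- symmdef:::rot_axis(res$report$fitted_axis, 180)
  ctr <- res$report$center
  img <- symmdef:::tf_apply(symmdef:::tf_new(R, ctr - R %*% ctr),
                            symmdef:::coords(sy[sy$chain == "A", ]))
  expect_lt(max(abs(img - symmdef:::coords(sy[sy$chain == "B", ]))), 1e-9)
  # idempotent: re-symmetrizing its own output leaves nothing to fix
  res2 <- symmetrize_ncs(res$symmetrized, "A", "B")
  expect_lt(res2$report$residual_rmsd, 1e-8)
})

test_that("a D4 stack symmetrizes through a two-level ring + flip hierarchy", {
  sdd <- generate_point_sdf("dn", 8, init_x = 10, init_z = 5)
  d4 <- explicit_structure(build_conformation(sdd, toy8()))
  res <- symmetrize_ncs(d4, "A", c("B", "E"))
  expect_equal(res$report$order, 4L)
  expect_lt(res$report$residual_rmsd, 1e-8)
  expect_length(unique(res$symmetrized$chain), 8)
  expect_length(validate_sdf(res$sd), 0)
  expect_true(all(c("VRTRING0", "VRTRING1") %in%
                    names(resolve_frames(res$sd))))
})

test_that("helical parameters are recovered from a constructed fiber", {
  sub <- toy8()
  for (params in list(c(100, 4.8, 12), c(-60, 3.1, 7.5))) {
    sdh <- generate_helical_sdf_denovo(params[1], params[2], params[3],
                                       nsub = 4)
    fib <- explicit_structure(build_conformation(sdh, sub))
    rec <- generate_helical_sdf(fib, "A", "B")
    expect_equal(rec$params$twist, params[1], tolerance = 1e-6)
    expect_equal(rec$params$rise, params[2], tolerance = 1e-6)
    expect_equal(rec$params$radius, params[3], tolerance = 1e-6)
  }
})

test_that("forcing 3 units per turn overrides the twist to 120 degrees", {
  sdh <- generate_helical_sdf_denovo(100, 4.8, 12, nsub = 4)
  fib <- explicit_structure(build_conformation(sdh, toy8()))
  rec <- generate_helical_sdf(fib, "A", "B", forced_units_per_turn = 3)
  expect_equal(abs(rec$params$twist), 120)
})

test_that("helical rise clones carry integer copy-count weights", {
  sd <- generate_helical_sdf_denovo(100, 4.8, 0, nsub = 5)
  J <- sd$jumps[grepl("RISE", sd$jumps$name), ]
  # master is subunit 3; the jump two rise steps downstream carries weight 2
  expect_equal(J$clone_weight[J$name == "RISEJUMP3"], 2)
  expect_equal(J$clone_weight[J$name == "RISEJUMP2"], 1)
})

test_that("crystal mode encodes twice the per-subunit energy and a fixed cell", {
  s <- make_p1_fixture(gap = 8)
  res <- make_crystal_sdf(s)
  expect_equal(res$sd$energy$intra$mult, 2)
  expect_true(all(vapply(res$sd$energy$interfaces, `[[`, 0, "mult") == 1))
  expect_true(isTRUE(res$sd$lattice))
  expect_length(validate_sdf(res$sd), 0)
})

test_that("P1 lattice neighborhoods have the expected explicit counts", {
  # isolated molecule: cutoff smaller than every image distance
  expect_length(symmdef:::attachment_jumps(
    make_crystal_sdf(make_p1_fixture(gap = 12))$sd), 1)
  # face-contact cell: master + 6 face neighbors
  expect_length(symmdef:::attachment_jumps(
    make_crystal_sdf(make_p1_fixture(gap = 8))$sd), 7)
})

test_that("unsupported spacegroups fail with the supported set named", {
  s <- make_p1_fixture()
  attr(s, "cryst1")$spacegroup <- "P 65"
  expect_error(make_crystal_sdf(s), "P 21 21 21")
})

test_that("explicit-subunit selection keeps master plus contacting chains", {
  fx <- make_symmetric_fixture("c17")
  expect_length(select_explicit_subunits(fx$structure, "A", 10), 3)
  dimer <- explicit_structure(build_conformation(
    generate_point_sdf("cn", 2, init_x = 6), toy8()))
  expect_length(select_explicit_subunits(dimer, "A", 10), 2)
  # widely spaced C8 ring: nearest-neighbor Calpha gaps above the cutoff
  fx8 <- make_symmetric_fixture("c8", radius = 40)
  expect_length(select_explicit_subunits(fx8$structure, "A", 10), 1)
})
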