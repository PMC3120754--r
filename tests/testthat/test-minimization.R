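# Gradients and minimization: analytic/numeric agreement, lattice
# cloned-jump weights, whole-structure correction gradients, descent.

test_that("analytic gradients match finite differences on point-group fixtures", {
  ef <- default_ef()
  set.seed(21)
  for (kind in c("c2", "c3", "d2")) {
    fx <- make_symmetric_fixture(kind)
    conf <- fx$conf
    for (i in 1:3) {
      conf <- random_orientation(conf, "BASEJUMP")
      conf <- set_jump_dof(conf, "BASEJUMP", "x", stats::runif(1, 4, 9))
      tab <- check_derivatives(conf, ef)
      expect_grad_agreement(tab$analytic, tab$numeric)
    }
  }
})

test_that("an isolated system has an all-zero gradient", {
  ef <- default_ef()
  conf <- build_conformation(generate_point_sdf("cn", 2, init_x = 60), toy8())
  g <- dof_gradient(conf, ef)
  expect_true(all(abs(g) < 1e-12))
})

test_that("rise derivatives scale with the clone span: 2 for two steps, 1 for one", {
  fx <- make_symmetric_fixture("helix")
  conf <- fx$conf   # master is chain C (middle of 5)
  expect_equal(lattice_distance_derivative(conf, "C", "E", "RISEJUMP0", "z"),
               2, tolerance = 1e-12)
  expect_equal(lattice_distance_derivative(conf, "C", "D", "RISEJUMP0", "z"),
               1, tolerance = 1e-12)
  # cross-check against a central finite difference of the distance
  anc <- conf$anchor_resno
  dist_at <- function(z) {
    c2 <- set_jump_dof(conf, "RISEJUMP0", "z", z)
    es <- explicit_structure(c2)
    p <- function(ch) as.numeric(es[es$chain == ch & es$resno == anc &
                                      es$atom == "CA", c("x", "y", "z")])
    symmdef:::vnorm(p("C") - p("E"))
  }
  fd <- (dist_at(4.8 + 1e-4) - dist_at(4.8 - 1e-4)) / 2e-4
  expect_equal(fd, 2, tolerance = 1e-6)
})

test_that("all helical dof gradients match finite differences", {
  ef <- default_ef()
  fx <- make_symmetric_fixture("helix")
  tab <- check_derivatives(fx$conf, ef)
  expect_grad_agreement(tab$analytic, tab$numeric)
})

test_that("the cloned-jump decomposition is one-sided and sums to the gradient", {
  ef <- default_ef()
  fx <- make_symmetric_fixture("helix")
  cc <- cloned_jump_chain(fx$conf, ef)
  g <- dof_gradient(fx$conf, ef)
  tot <- attr(cc, "total")
  expect_equal(unname(tot), unname(g[names(tot)]), tolerance = 1e-9)
  # upstream interfaces (weight 0 in the one-sided energy line) contribute 0
  up <- cc[cc$chain %in% c("A", "B"), ]
  expect_true(all(up$contribution == 0))
  # downstream spans carry the stored integer clone weights
  expect_equal(unique(cc$clone_weight[cc$chain == "E"]), 2)
  expect_equal(unique(cc$clone_weight[cc$chain == "D"]), 1)
})

movable_root_c2 <- function() {
  dimer <- explicit_structure(build_conformation(
    generate_point_sdf("cn", 2, init_x = 6), toy8()))
  res <- symmetrize_ncs(dimer, "A", "B", allow_global = TRUE)
  build_conformation(res$sd, res$master_input)
}

test_that("corrected gradients handle an asymmetric tether on a movable-root C2", {
  conf <- movable_root_c2()
  set.seed(31)
  for (trial in 1:12) {
    te <- data.frame(chain = sample(c("A", "B"), 1),
                     resno = sample(2:7, 1), atom = "CA",
                     tx = stats::runif(1, -10, 10),
                     ty = stats::runif(1, -10, 10),
                     tz = stats::runif(1, -10, 10), k = stats::runif(1, 0.5, 2))
    ef <- energy_function(tethers = te)
    cg <- corrected_gradient(conf, ef)
    gn <- numeric_dof_gradient(conf, ef)
    expect_grad_agreement(cg$partials, gn)
    # the literal rotate/correct route agrees with the generic chain rule
    expect_equal(unname(cg$partials), unname(dof_gradient(conf, ef)),
                 tolerance = 1e-9)
    expect_true("VRTGLOBAL" %in% names(cg$ledger))
  }
})

test_that("the correction ledger is empty without an asymmetric term", {
  conf <- movable_root_c2()
  cg <- corrected_gradient(conf, default_ef())
  expect_length(cg$ledger, 0)
})

test_that("a symmetric tether reduces to the plain symmetric gradient", {
  conf <- movable_root_c2()
  # same target in each subunit's local frame: image the master target by
  # the subunit transform
  Tk <- subunit_transforms(conf)
  t0 <- c(2, -1, 3)
  t1 <- as.vector(symmdef:::tf_apply(Tk[["B"]], matrix(t0, 1)))
  te <- data.frame(chain = c("A", "B"), resno = 4, atom = "CA",
                   tx = c(t0[1], t1[1]), ty = c(t0[2], t1[2]),
                   tz = c(t0[3], t1[3]), k = 1)
  ef <- energy_function(tethers = te)
  cg <- corrected_gradient(conf, ef)
  expect_equal(unname(cg$partials), unname(dof_gradient(conf, ef)),
               tolerance = 1e-9)
  expect_grad_agreement(cg$partials, numeric_dof_gradient(conf, ef))
})

test_that("a two-particle C2 minimizes to the analytic optimum separation", {
  ef <- default_ef()
  # single-atom subunit: the only interaction is the inter-subunit pair,
  # whose optimum is r0; with anchors at +-x the separation is 2x
  sub <- symmdef:::new_structure(data.frame(
    chain = "A", resno = 1, resname = "GLY", atom = "CA",
    x = 0, y = 0, z = 0))
  sd <- generate_point_sdf("cn", 2, init_x = 3.2)
  conf <- build_conformation(sd, sub)
  res <- minimize(conf, ef, tol = 1e-8)
  expect_equal(2 * get_jump_dof(res$conf, "BASEJUMP", "x"), ef$r0,
               tolerance = 1e-4)
  expect_lte(res$final_score, res$initial_score)
  # restarting at the optimum changes nothing measurable
  res2 <- minimize(res$conf, ef, tol = 1e-8)
  expect_equal(symmdef:::dof_vector(res2$conf), symmdef:::dof_vector(res$conf),
               tolerance = 1e-6)
})

test_that("helical rise minimization matches a 1-D golden-section scan", {
  ef <- default_ef()
  sd <- generate_helical_sdf_denovo(100, 9, 0, nsub = 5)
  sd$dofs <- list(RISEJUMP0 = list(allowed = "z", init = c(z = 9),
                                   range = list(z = c(5, 14))))
  conf <- build_conformation(sd, make_toy_subunit(6, "helix"))
  res <- minimize(conf, ef, tol = 1e-8)
  scan <- stats::optimize(function(z)
    score(set_jump_dof(conf, "RISEJUMP0", "z", z), ef)$total,
    interval = c(5, 14), tol = 1e-8)
  expect_equal(get_jump_dof(res$conf, "RISEJUMP0", "z"), scan$minimum,
               tolerance = 1e-3)
})

test_that("minimization preserves exact point-group symmetry", {
  ef <- default_ef()
  fx <- make_symmetric_fixture("c4")
  conf <- random_orientation(fx$conf, "BASEJUMP", seed = 6)
  res <- minimize(conf, ef)
  expect_lte(res$final_score, res$initial_score)
  expect_lt(ring_symmetry_error(expand_full(res$conf), 90), 1e-8)
})
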