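# Weighted symmetric scoring: the pair potential, restricted energy graph,
# interface-multiplicity decomposition and the full-expansion oracle.

test_that("the pair potential vanishes at the cutoff and is symmetric", {
  ef <- default_ef()
  one <- function(x) data.frame(x = x, y = 0, z = 0)
  expect_identical(pair_energy(one(0), one(10), ef), 0)
  expect_identical(pair_energy(one(0), one(25), ef), 0)
  set.seed(1)
  for (i in 1:20) {
    a <- data.frame(x = rnorm(3), y = rnorm(3), z = rnorm(3))
    b <- data.frame(x = rnorm(3) + 5, y = rnorm(3), z = rnorm(3))
    expect_equal(pair_energy(a, b, ef), pair_energy(b, a, ef))
  }
  # two single-atom residues at the optimum distance sit at the well depth
  expect_equal(pair_energy(one(0), one(ef$r0), ef), -ef$eps, tolerance = 1e-12)
  # continuity across the softening and switch boundaries
  for (rb in c(ef$r_soft, ef$switch_start, ef$cutoff)) {
    lo <- symmdef:::pair_potential(rb - 1e-9, ef)
    hi <- symmdef:::pair_potential(rb + 1e-9, ef)
    expect_equal(lo, hi, tolerance = 1e-6)
  }
})

test_that("the restricted energy graph matches a quadratic scan and always touches the master", {
  ef <- default_ef()
  conf <- build_conformation(generate_point_sdf("cn", 3, init_x = 7),
                             make_toy_subunit(17, "helix"))
  g <- build_energy_graph(conf, ef)
  expect_true(all(g$edges$resno_a %in% conf$q$resno))
  # brute-force residue-pair scan restricted to master-touching pairs
  es <- g$structure
  brute <- list()
  mres <- unique(es$resno[es$chain == "A"])
  for (ra in mres) {
    pa <- as.matrix(es[es$chain == "A" & es$resno == ra, c("x", "y", "z")])
    for (ch in unique(es$chain)) for (rb in unique(es$resno[es$chain == ch])) {
      if (ch == "A" && (rb <= ra || abs(rb - ra) < 2)) next
      pb <- as.matrix(es[es$chain == ch & es$resno == rb, c("x", "y", "z")])
      d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
      if (min(d2) < ef$cutoff^2)
        brute[[length(brute) + 1]] <- paste(ra, ch, rb)
    }
  }
  got <- paste(g$edges$resno_a, g$edges$chain_b, g$edges$resno_b)
  expect_setequal(got, unlist(brute))
})

test_that("C4 weights follow the interface orbits: adjacent 4, diagonal 2", {
  fx <- make_symmetric_fixture("c4")
  w <- symmdef:::interface_weights(fx$sd)
  expect_equal(unname(w["VRT1"]), 4)
  expect_equal(unname(w["VRT2"]), 2)
  expect_equal(unname(w["VRT3"]), 0)  # covered by the adjacent class
  expect_equal(fx$sd$energy$intra$mult, 4)
})

test_that("the C4 total equals 4 E(A) + 4 E(AB) + 2 E(AC)", {
  ef <- default_ef()
  fx <- make_symmetric_fixture("c4")
  s <- fx$structure
  ea <- chain_intra_energy_oracle(s, "A", ef)
  eab <- chain_pair_energy_oracle(s, "A", "B", ef)
  eac <- chain_pair_energy_oracle(s, "A", "C", ef)
  expected <- 4 * ea + 4 * eab + 2 * eac
  expect_equal(score(fx$conf, ef)$total, expected, tolerance = 1e-9)
  expect_equal(score(fx$conf, ef)$total, score_full_oracle(fx$conf, ef),
               tolerance = 1e-9)
})

test_that("symmetric scoring equals asymmetric scoring on point-group fixtures", {
  ef <- default_ef()
  set.seed(99)
  for (kind in c("c2", "c3", "c4", "d2")) {
    fx <- make_symmetric_fixture(kind)
    conf <- fx$conf
    for (i in 1:15) {
      conf <- random_orientation(conf, "BASEJUMP")
      conf <- set_jump_dof(conf, "BASEJUMP", "x", stats::runif(1, 3, 12))
      s <- score(conf, ef)$total
      o <- score_full_oracle(conf, ef)
      expect_lt(abs(s - o) / abs(o), 1e-6)
    }
  }
})

test_that("a single-subunit system scores like a plain monomer", {
  ef <- default_ef()
  sd <- parse_sdf(c(
    "E = 1*VRT0",
    "virtual_coordinates_start",
    "xyz VRT0 1,0,0 0,1,0 0,0,0",
    "virtual_coordinates_stop",
    "connect_virtual R0 ROOT VRT0",
    "connect_virtual J0 VRT0 SUBUNIT"))
  sub <- toy8()
  conf <- build_conformation(sd, sub)
  expect_equal(score(conf, ef)$total,
               symmdef:::asymmetric_score(explicit_structure(conf), ef),
               tolerance = 1e-9)
})

test_that("truncating a C17 ring to 3 explicit subunits changes nothing", {
  ef <- default_ef()
  fx <- make_symmetric_fixture("c17")
  x0 <- fx$sd$dofs$BASEJUMP$init[["x"]]
  sd3 <- generate_point_sdf("cn", 17, subsystem = TRUE, init_x = x0)
  conf3 <- build_conformation(sd3, fx$subunit)
  expect_equal(score(conf3, ef)$total, score(fx$conf, ef)$total,
               tolerance = 1e-12)
})

test_that("the score is invariant under rigid motion of the whole system", {
  ef <- default_ef()
  dimer <- explicit_structure(build_conformation(
    generate_point_sdf("cn", 2, init_x = 6), toy8()))
  res <- symmetrize_ncs(dimer, "A", "B", allow_global = TRUE)
  conf <- build_conformation(res$sd, res$master_input)
  s0 <- score(conf, ef)$total
  conf <- set_jump_dof(conf, "GLOBALJUMP", "x", 13.7)
  conf <- set_jump_dof(conf, "GLOBALJUMP", "angle_y", 41)
  expect_equal(score(conf, ef)$total, s0, tolerance = 1e-9)
})

test_that("the spatial grid returns exactly the brute-force neighbor sets", {
  set.seed(8)
  xyz <- matrix(stats::runif(300, 0, 30), ncol = 3)
  q <- xyz[sample(100, 20), , drop = FALSE]
  got <- symmdef:::grid_neighbors(xyz, q, 7)
  for (i in seq_len(nrow(q))) {
    d2 <- rowSums(sweep(xyz, 2, q[i, ])^2)
    expect_setequal(got[[i]], which(d2 < 49))
  }
})
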