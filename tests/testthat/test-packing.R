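# Symmetric packing: rotamer sets, the node/edge energy equations (checked
# against the expanded-complex asymmetric packer), annealing, pack().

packable_c2 <- function(n_res = 8, x = 4.5) {
  sub <- make_toy_subunit(n_res, "helix", sidechain = TRUE)
  sub <- symmdef:::transform_structure(sub, symmdef:::tf_new(symmdef:::rot_y(-90)))
  sd <- generate_point_sdf("cn", 2, init_x = x)
  build_conformation(sd, sub)
}

test_that("rotamer sets hold the chi library plus the input state, cloned exactly", {
  conf <- packable_c2()
  rs <- build_rotamers(conf, c(3, 4))
  # input chi1 is 180, a library bin, so exactly 3 unique states
  expect_length(rs[[1]]$coords, 3)
  expect_setequal(round(rs[[1]]$chis), c(-60, 60, 180))
  # a shifted input chi becomes a fourth state
  conf2 <- set_torsion(conf, 3, "chi1", -95)
  rs2 <- build_rotamers(conf2, 3)
  expect_length(rs2[[1]]$coords, 4)
  # residues without a rotatable side chain get a single state
  conf_ala <- build_conformation(generate_point_sdf("cn", 2), toy8())
  expect_length(build_rotamers(conf_ala, 4)[[1]]$coords, 1)
  # clones satisfy the subunit-transform relation exactly
  Tk <- subunit_transforms(conf)
  A <- symmdef:::subunit_placements(conf)
  m <- rs[[1]]$coords[[2]]
  pm <- symmdef:::tf_apply(A[["A"]], m)
  pb <- symmdef:::tf_apply(A[["B"]], m)
  expect_lt(max(abs(symmdef:::tf_apply(Tk[["B"]], pm) - pb)), 1e-9)
})

test_that("symmetric graph energies equal the asymmetric packer on the expanded dimer", {
  ef <- default_ef()
  conf <- packable_c2()
  pos <- c(3, 4, 5)
  g <- build_packer_graph(conf, ef, pos)
  ns <- vapply(g$nodes, function(n) length(n$E1), 0)
  expect_equal(ns, c(3, 3, 3))
  grid <- do.call(expand.grid, lapply(ns, seq_len))
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    expect_equal(symmdef:::assignment_energy(g, a),
                 symmdef:::asym_packer_energy(conf, ef, pos, a),
                 tolerance = 1e-6)
  }
})

test_that("zero-weight subunits contribute nothing to node energies", {
  ef <- default_ef()
  conf <- packable_c2(x = 40)   # far apart: every cross term is zero
  g <- build_packer_graph(conf, ef, 4)
  # node energy reduces to the w_c-weighted own-subunit background term
  rs <- g$rsets[[1]]
  A <- symmdef:::subunit_placements(conf)
  q <- conf$q
  bg_mask <- !(q$resno == 4 & q$atom %in% c("CB", "CG"))
  own <- abs(q$resno[bg_mask] - 4) >= 2
  for (s in seq_along(rs$coords)) {
    sc <- symmdef:::tf_apply(A[["A"]], rs$coords[[s]])
    bg <- symmdef:::tf_apply(A[["A"]], symmdef:::coords(q)[bg_mask, ])[own, ]
    d2 <- outer(rowSums(sc^2), rowSums(bg^2), "+") - 2 * sc %*% t(bg)
    e_own <- sum(symmdef:::pair_potential(sqrt(pmax(as.vector(d2), 1e-12)), ef))
    expect_equal(node_energy(g, 1, s), g$w_c * e_own, tolerance = 1e-9)
  }
})

test_that("edge energies are order-invariant in total even if matrices are not symmetric", {
  ef <- default_ef()
  conf <- packable_c2()
  g <- build_packer_graph(conf, ef, c(3, 4))
  e12 <- edge_energy(g, 1, 2, 1, 3)
  e21 <- edge_energy(g, 2, 1, 3, 1)
  expect_equal(e12, e21)
})

test_that("annealing finds the exhaustive optimum and never undercuts it", {
  ef <- default_ef()
  conf <- packable_c2()
  g <- build_packer_graph(conf, ef, c(3, 4, 5))
  opt <- symmdef:::enumerate_optimum(g)
  hits <- 0
  for (seed in 1:30) {
    res <- anneal(g, seed = seed)
    expect_gte(res$energy, opt$energy - 1e-9)
    if (res$energy <= opt$energy + 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 29)
  # determinism
  expect_identical(anneal(g, seed = 4), anneal(g, seed = 4))
  # single node: the optimum is the argmin of its node-energy vector
  g1 <- build_packer_graph(conf, ef, 4)
  r1 <- anneal(g1, seed = 1)
  expect_equal(r1$assignment, which.min(g1$nodes[[1]]$E1))
})

test_that("pack never worsens the score and keeps all subunits identical", {
  ef <- default_ef()
  for (seed in c(1, 7, 13)) {
    conf <- packable_c2()
    conf <- set_torsion(conf, 4, "chi1", 35)   # a strained start
    s0 <- score(conf, ef)$total
    packed <- pack(conf, ef, seed = seed)
    expect_lte(score(packed, ef)$total, s0 + 1e-9)
    es <- explicit_structure(packed)
    for (rn in unique(packed$q$resno[packed$q$atom == "CG"])) {
      chis <- vapply(unique(es$chain), function(ch) {
        sc <- es[es$chain == ch, ]
        at <- function(nm) as.numeric(sc[sc$resno == rn & sc$atom == nm,
                                         c("x", "y", "z")])
        symmdef:::dihedral(at("N"), at("CA"), at("CB"), at("CG"))
      }, 0)
      expect_lt(diff(range(chis)), 1e-6)
    }
  }
})

test_that("an all-NATRO task leaves the conformation untouched", {
  ef <- default_ef()
  conf <- packable_c2()
  task <- parse_pack_task(c("3 NATRO", "4 NATRO"))
  packed <- pack(conf, ef, positions = c(3, 4), task = task)
  expect_equal(symmdef:::coords(packed$q), symmdef:::coords(conf$q))
  expect_error(pack(conf, ef, positions = 999), "master")
})
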