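# Shared helpers for the test suite. Everything is generated in code; no
# stored binary fixtures.

default_ef <- function(...) energy_function(...)

toy8 <- function(...) make_toy_subunit(8, "helix", ...)

# a contacting Cn conformation with randomizable dofs
contacting_ring <- function(n, x = 7, n_res = 8) {
  sd <- generate_point_sdf("cn", n, init_x = x)
  build_conformation(sd, toy8())
}

# plain asymmetric interaction energy between two chains of a complex
# (quadratic-scan oracle, independent of the energy-graph machinery)
chain_pair_energy_oracle <- function(s, ch_a, ch_b, ef) {
  pa <- as.matrix(s[s$chain == ch_a, c("x", "y", "z")])
  pb <- as.matrix(s[s$chain == ch_b, c("x", "y", "z")])
  tot <- 0
  for (i in seq_len(nrow(pa))) {
    r <- sqrt(rowSums(sweep(pb, 2, pa[i, ])^2))
    tot <- tot + sum(symmdef:::pair_potential(r, ef))
  }
  tot
}

# intra-chain energy (|i - j| >= 2) of one chain plus its one-body sum
chain_intra_energy_oracle <- function(s, ch, ef) {
  sc <- s[s$chain == ch, , drop = FALSE]
  p <- as.matrix(sc[, c("x", "y", "z")])
  tot <- ef$one_body * length(unique(sc$resno))
  for (i in seq_len(nrow(p) - 1)) {
    js <- (i + 1):nrow(p)
    js <- js[abs(sc$resno[js] - sc$resno[i]) >= 2]
    if (length(js) == 0) next
    r <- sqrt(rowSums(sweep(p[js, , drop = FALSE], 2, p[i, ])^2))
    tot <- tot + sum(symmdef:::pair_potential(r, ef))
  }
  tot
}

# gradient agreement: within `rel` relative, with an `abs_floor` absolute
# floor for partials that are numerically zero
expect_grad_agreement <- function(analytic, numeric, rel = 1e-4,
                                  abs_floor = 1e-6) {
  err <- abs(as.numeric(analytic) - as.numeric(numeric))
  testthat::expect_true(all(err <= pmax(rel * abs(as.numeric(numeric)),
                                        abs_floor)))
}

# RMSD of the best superposition of x onto y (matched rows)
fit_rmsd <- function(x, y) kabsch(x, y)$rmsd

# minimum RMSD between a complex and its image under a rotation about the
# z axis by `deg`, over all cyclic chain relabelings — the point-group
# superposability check
ring_symmetry_error <- function(s, deg) {
  R <- symmdef:::rot_z(deg)
  chains <- unique(s$chain)
  n <- length(chains)
  rotated <- as.matrix(s[, c("x", "y", "z")]) %*% t(R)
  best <- Inf
  for (k in seq_len(n)) {
    perm <- chains[((seq_len(n) - 1 + k - 1) %% n) + 1]
    target <- do.call(rbind, lapply(perm, function(ch)
      as.matrix(s[s$chain == ch, c("x", "y", "z")])))
    src <- do.call(rbind, lapply(chains, function(ch)
      rotated[s$chain == ch, , drop = FALSE]))
    best <- min(best, sqrt(mean(rowSums((src - target)^2))))
  }
  best
}
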