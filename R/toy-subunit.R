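# Deterministic toy subunits: ideal-geometry polyalanine chains built from
# internal coordinates, used as synthetic fixtures by every other module.

# ideal backbone geometry (Angstrom, degrees)
IDEAL_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.521, b_cb_cg = 1.530,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.8, a_n_ca_cb = 110.4, a_ca_cb_cg = 114.0,
  t_cb = 122.55   # improper C-N-CA-CB placing the beta carbon
)

#' Build a deterministic toy subunit
#'
#' Constructs an ideal-geometry polyalanine chain from internal coordinates:
#' phi/psi = -57/-47 degrees for `shape = "helix"`, -135/135 for
#' `shape = "extended"`, and for `shape = "hairpin"` two packed antiparallel
#' helices joined by a two-residue turn (loop phi/psi = 70/-130, chosen so
#' the two helices pack without steric strain) — a compact asymmetric
#' subunit suited to docking fixtures. With `sidechain = TRUE`
#' each residue carries a
#' two-atom side chain (CB-CG) whose chi1 torsion (N-CA-CB-CG, initialized to
#' 180 degrees) makes the subunit packable; such residues are labeled `ABU`
#' (alpha-aminobutyrate-like), plain residues `ALA`. Identical parameters and
#' seed always give identical coordinates; `jitter > 0` adds a seeded uniform
#' perturbation to the backbone torsions.
#'
#' @param n_res number of residues (>= 3).
#' @param shape `"helix"` or `"extended"`.
#' @param seed integer seed controlling the torsion jitter.
#' @param sidechain add CB-CG side chains (chi1-packable residues).
#' @param jitter half-width in degrees of the uniform phi/psi jitter
#'   (default 0: strictly ideal geometry).
#' @param chain chain identifier.
#' @return A `symm_structure` with atoms N, CA, C, O, CB (and CG when
#'   `sidechain`).
#' @export
make_toy_subunit <- function(n_res, shape = c("helix", "extended", "hairpin"),
                             seed = 1, sidechain = FALSE, jitter = 0,
                             chain = "A") {
  shape <- match.arg(shape)
  if (n_res < 3) stop("n_res must be >= 3")
  if (shape == "hairpin") {
    if (n_res < 8) stop("a hairpin needs >= 8 residues")
    n1 <- (n_res - 2) %/% 2
    loop <- n1 + seq_len(2)
    phi <- rep(-57, n_res); psi <- rep(-47, n_res)
    phi[loop] <- 70; psi[loop] <- -130
  } else {
    pp <- switch(shape, helix = c(-57, -47), extended = c(-135, 135))
    phi <- rep(pp[1], n_res)
    psi <- rep(pp[2], n_res)
  }
  if (jitter > 0) {
    rng <- local({ set.seed(seed); stats::runif(2 * n_res, -jitter, jitter) })
    phi <- phi + rng[seq_len(n_res)]
    psi <- psi + rng[n_res + seq_len(n_res)]
  }
  g <- IDEAL_GEOM
  resname <- if (sidechain) "ABU" else "ALA"

  # backbone scaffold
  N <- vector("list", n_res); CA <- vector("list", n_res)
  C <- vector("list", n_res)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(g$b_n_ca, 0, 0)
  C[[1]] <- place_atom(c(0, 0, 1), N[[1]], CA[[1]], g$b_ca_c, g$a_n_ca_c, phi[1])
  for (i in 2:n_res) {
    N[[i]] <- place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]],
                         g$b_c_n, g$a_ca_c_n, psi[i - 1])
    CA[[i]] <- place_atom(CA[[i - 1]], C[[i - 1]], N[[i]],
                          g$b_n_ca, g$a_c_n_ca, 180)
    C[[i]] <- place_atom(C[[i - 1]], N[[i]], CA[[i]],
                         g$b_ca_c, g$a_n_ca_c, phi[i])
  }
  rows <- list()
  add <- function(resno, atom, p)
    rows[[length(rows) + 1]] <<- data.frame(
      chain = chain, resno = resno, resname = resname, atom = atom,
      x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
  for (i in seq_len(n_res)) {
    add(i, "N", N[[i]])
    add(i, "CA", CA[[i]])
    add(i, "C", C[[i]])
    o_tors <- if (i < n_res) psi[i] + 180 else 180
    add(i, "O", place_atom(N[[i]], CA[[i]], C[[i]], g$b_c_o, g$a_ca_c_o, o_tors))
    cb <- place_atom(C[[i]], N[[i]], CA[[i]], g$b_ca_cb, g$a_n_ca_cb, g$t_cb)
    add(i, "CB", cb)
    if (sidechain)
      add(i, "CG", place_atom(N[[i]], CA[[i]], cb, g$b_cb_cg, g$a_ca_cb_cg, 180))
  }
  s <- new_structure(do.call(rbind, rows))
  # center on the Calpha centroid so fixtures are origin-friendly
  ctr <- colMeans(ca_coords(s))
  coords(s) <- sweep(coords(s), 2, ctr)
  s
}

# anchor residue convention: residue whose CA is nearest the CA centroid
anchor_residue <- function(s, anchor = "COM", chain = NULL) {
  if (!is.null(chain)) s <- s[s$chain == chain, , drop = FALSE]
  if (!identical(anchor, "COM")) {
    hit <- s[s$resno == anchor & s$atom == "CA", , drop = FALSE]
    if (nrow(hit) == 0) stop("anchor residue ", anchor, " has no CA atom")
    return(list(resno = as.integer(anchor),
                pos = as.numeric(hit[1, c("x", "y", "z")])))
  }
  cas <- s[s$atom == "CA", , drop = FALSE]
  if (nrow(cas) == 0) stop("structure has no CA atoms")
  xyz <- as.matrix(cas[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  i <- which.min(rowSums(sweep(xyz, 2, ctr)^2))
  list(resno = cas$resno[i], pos = xyz[i, ])
}
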