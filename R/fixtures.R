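# Canonical symmetric fixtures: perfectly symmetric complexes paired with the
# SDFs that regenerate them. These are the ground truths used by the
# symmetrization recovery tests and the scoring/minimization oracles.

#' Build a paired symmetric fixture (complex + ground-truth SDF)
#'
#' Deterministically constructs a perfectly symmetric toy complex together
#' with the symmetry definition that regenerates it:
#'
#' * `c2`/`c3`/`c4`/`c8`: cyclic rings of helical subunits (axis along z)
#'   with ring radius chosen so adjacent subunits touch (`contact` Angstrom
#'   between adjacent anchor points) — or any radius via `radius`;
#' * `c17`: a large ring spaced so that only nearest neighbors fall within
#'   the 10 Angstrom interaction cutoff (the explicit-subunit truncation
#'   scenario);
#' * `d2`: two stacked 2-rings with ring-separation and radial dofs;
#' * `helix`: a 5-subunit fiber (twist 100 degrees, rise 4.8 Angstrom,
#'   radius 0 so anchor separations are purely axial) with the cloned
#'   rise-jump group — the lattice-derivative scenario.
#'
#' @param kind fixture name (above).
#' @param n_res residues per subunit.
#' @param seed subunit geometry seed.
#' @param sidechain build packable (CB-CG) side chains.
#' @param contact target adjacent anchor-anchor distance, Angstrom (ring
#'   kinds).
#' @param radius override the ring radius / helical radius directly.
#' @return List with `sd`, `conf` (built conformation), `structure` (the
#'   explicit complex) and `subunit` (the master input).
#' @export
make_symmetric_fixture <- function(kind = c("c2", "c3", "c4", "c8", "c17",
                                            "d2", "helix"),
                                   n_res = 8, seed = 1, sidechain = FALSE,
                                   contact = 7.5, radius = NULL) {
  kind <- match.arg(kind)
  sub <- make_toy_subunit(n_res, "helix", seed = seed, sidechain = sidechain)
  # stand the subunit's long axis along global z so ring footprints are
  # compact in the ring plane
  sub <- transform_structure(sub, tf_new(rot_y(-90)))

  ring <- function(n, x0) {
    sd <- generate_point_sdf("cn", n, init_x = x0)
    conf <- build_conformation(sd, sub)
    list(sd = sd, conf = conf, structure = explicit_structure(conf),
         subunit = sub)
  }
  switch(kind,
    c2 = ring(2, contact / 2),
    c3 = ring(3, contact / (2 * sin(pi / 3))),
    c4 = ring(4, contact / (2 * sin(pi / 4))),
    c8 = ring(8, if (is.null(radius)) contact / (2 * sin(pi / 8)) else radius),
    c17 = {
      # adjacent anchors 9.5 A apart: nearest-neighbor Calphas ~4.7 A
      # (inside the 10 A cutoff), skip-one neighbors ~12.3 A (outside)
      x0 <- if (is.null(radius)) 9.5 / (2 * sin(pi / 17)) else radius
      sd <- generate_point_sdf("cn", 17, init_x = x0)
      conf <- build_conformation(sd, sub)
      list(sd = sd, conf = conf, structure = explicit_structure(conf),
           subunit = sub)
    },
    d2 = {
      sd <- generate_point_sdf("dn", 4, init_x = contact / 2, init_z = 4.5)
      conf <- build_conformation(sd, sub)
      list(sd = sd, conf = conf, structure = explicit_structure(conf),
           subunit = sub)
    },
    helix = {
      sd <- generate_helical_sdf_denovo(100, 4.8,
                                        if (is.null(radius)) 0 else radius,
                                        nsub = 5)
      conf <- build_conformation(sd, sub)
      list(sd = sd, conf = conf, structure = explicit_structure(conf),
           subunit = sub)
    })
}

#' Build a synthetic P1 crystal fixture
#'
#' One toy molecule in a cubic P1 cell sized from its bounding box plus a
#' chosen face gap, so that exactly the six face-neighbor images contact the
#' master when the gap is below the cutoff (and none do when it is above).
#'
#' The default 8 Angstrom gap is inside the 10 Angstrom cutoff while the
#' edge-diagonal gap (8 * sqrt(2) ~ 11.3) is outside it, giving the
#' 7-subunit face-neighbor shell; gaps above the cutoff give an isolated
#' subunit.
#'
#' @param n_res residues in the molecule.
#' @param gap face-neighbor Calpha-Calpha gap, Angstrom.
#' @param seed geometry seed.
#' @return A `symm_structure` with a CRYST1 attribute.
#' @export
make_p1_fixture <- function(n_res = 6, gap = 8, seed = 1) {
  sub <- make_toy_subunit(n_res, "helix", seed = seed)
  span <- apply(ca_coords(sub), 2, function(v) diff(range(v)))
  cell <- c(span + gap, 90, 90, 90)
  s <- sub
  attr(s, "cryst1") <- list(cell = cell, spacegroup = "P 1")
  s
}
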