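# Generation of symmetry definitions: de novo for Cn/Dn point groups and
# helical lattices, and from existing (possibly only approximately symmetric)
# structures for point, helical and crystal symmetry.

## ---- interface orbit enumeration -------------------------------------------

#' Permutation representation of a point group acting on subunit labels
#'
#' For `cn`, the n rotations of the cyclic group. For `dn` (with `nsub = 2m`
#' subunits: 1..m in the upper ring, m+1..2m in the lower ring, lower-ring
#' labels running in the opposite geometric sense, as generated by
#' [generate_point_sdf()]), the 2m elements of the dihedral group.
#'
#' @param symm_type `"cn"` or `"dn"`.
#' @param nsub total number of subunits.
#' @return List of permutations (integer vectors of length `nsub`).
#' @export
point_group_permutations <- function(symm_type = c("cn", "dn"), nsub) {
  symm_type <- match.arg(symm_type)
  if (symm_type == "cn") {
    n <- nsub
    return(lapply(seq_len(n) - 1, function(k) ((seq_len(n) - 1 + k) %% n) + 1))
  }
  if (nsub %% 2 != 0) stop("dn requires an even subunit count")
  m <- nsub / 2
  r <- c(((seq_len(m) - 1 + 1) %% m) + 1,          # upper ring advances
         ((seq_len(m) - 1 - 1) %% m) + m + 1)      # lower ring retreats
  f <- c(seq_len(m) + m, seq_len(m))               # swap rings in place
  compose <- function(p, q) p[q]
  elems <- list(seq_len(nsub))
  cur <- seq_len(nsub)
  for (k in seq_len(m - 1)) {
    cur <- compose(r, cur)
    elems[[length(elems) + 1]] <- cur
  }
  base <- elems
  for (e in base) elems[[length(elems) + 1]] <- compose(e, f)
  elems
}

#' Enumerate unique interfaces of a symmetric complex
#'
#' Partitions all `n(n-1)/2` unordered subunit pairs into orbits under the
#' symmetry group. Each orbit is one unique interface class; its multiplicity
#' (orbit size) is the number of times that interface recurs in the complex
#' and is exactly the weight the energy line assigns to the class's
#' master-touching representative. For C4 this reproduces the canonical
#' {adjacent x4, diagonal x2} decomposition.
#'
#' @param group either a string `"cn"`/`"dn"` (with `nsub`), or a list of
#'   permutations as returned by [point_group_permutations()].
#' @param nsub subunit count (required with a string `group`).
#' @return List with `pair_count` and `classes`, a data.frame with columns
#'   `rep_a`, `rep_b` (a representative pair, containing subunit 1 whenever
#'   the orbit touches it) and `multiplicity`; multiplicities sum to
#'   `pair_count`.
#' @export
enumerate_interfaces <- function(group, nsub = NULL) {
  if (is.character(group)) {
    if (is.null(nsub)) stop("nsub is required with a named group")
    perms <- point_group_permutations(group, nsub)
  } else {
    perms <- group
    nsub <- length(perms[[1]])
  }
  pairs <- utils::combn(nsub, 2)
  key <- function(a, b) paste(min(a, b), max(a, b))
  seen <- character()
  classes <- list()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    if (key(a, b) %in% seen) next
    orbit <- unique(vapply(perms, function(p) key(p[a], p[b]), ""))
    seen <- c(seen, orbit)
    reps <- do.call(rbind, lapply(strsplit(orbit, " "), as.integer))
    touch <- which(reps[, 1] == 1)
    rep_pair <- if (length(touch) > 0) reps[touch[1], ] else reps[1, ]
    classes[[length(classes) + 1]] <- data.frame(
      rep_a = rep_pair[1], rep_b = rep_pair[2], multiplicity = length(orbit))
  }
  list(pair_count = ncol(pairs), classes = do.call(rbind, classes))
}

## ---- de novo point-group SDFs ----------------------------------------------

default_denovo_dofs <- function(init_x = 50) {
  list(allowed = c("x", "angle_x", "angle_y", "angle_z"),
       init = c(x = init_x),
       range = list(angle_x = c(0, 360), angle_y = c(0, 360),
                    angle_z = c(0, 360)))
}

# base frame of the de novo convention: x axis pointing toward the origin
denovo_base_frame <- function(name = "VRT0")
  virtual_frame(name, c(0, 0, 0), c(-1, 0, 0), c(0, 1, 0))

#' Generate a de novo point-symmetry definition
#'
#' Builds an SDF for a Cn or Dn system in a canonical coordinate frame, for
#' use when no symmetric template structure exists (symmetric docking, de
#' novo assembly prediction). Reference frames have their x axis pointing
#' toward the global origin with the translational dof along x, so the
#' default `set_dof BASEJUMP x(50) angle_x(0:360) angle_y(0:360)
#' angle_z(0:360)` initially places, e.g., the two subunits of a C2 system at
#' (50,0,0) and (-50,0,0) with fully randomizable orientations. Energy-line
#' multipliers are the interface orbit sizes from [enumerate_interfaces()].
#' With `subsystem`, only the master and its two ring neighbors are encoded
#' (three attachment jumps) while all `nsub` frames and the full-system
#' multipliers are retained — the large-ring truncation setup.
#'
#' @param symm_type `"cn"` or `"dn"`.
#' @param nsub total subunits (>= 2; even for `dn`).
#' @param subsystem encode only master + neighbors (`cn` only).
#' @param init_x initial radial placement, Angstrom.
#' @param init_z initial ring half-separation for `dn`, Angstrom.
#' @return A validated `symmetry_definition`.
#' @export
generate_point_sdf <- function(symm_type = c("cn", "dn"), nsub,
                               subsystem = FALSE, init_x = 50, init_z = 10) {
  symm_type <- match.arg(symm_type)
  if (nsub < 2) stop("nsub must be >= 2")
  if (symm_type == "dn" && nsub %% 2 != 0)
    stop("dn symmetry requires an even nsub")

  if (symm_type == "cn") {
    frame_spec <- list(kind = "transforms", start = denovo_base_frame(),
                       ops = list(list(kind = "rot", axis = "z", fold = nsub)))
    fnames <- paste0("VRT", seq_len(nsub) - 1)
    enc <- if (subsystem && nsub > 3) c(1, 2, nsub) else seq_len(nsub)
    jumps <- data.frame(
      name = paste0("ROOTJUMP", seq_len(nsub) - 1),
      start = "ROOT", stop = fnames,
      clone_group = "ROOTGROUP", clone_weight = 1, stringsAsFactors = FALSE)
    att <- data.frame(
      name = ifelse(enc == 1, "BASEJUMP", paste0("BASEJUMP", enc - 1)),
      start = fnames[enc], stop = "SUBUNIT",
      clone_group = "BASEGROUP", clone_weight = 1, stringsAsFactors = FALSE)
    jumps <- rbind(jumps, att)
    oi <- enumerate_interfaces("cn", nsub)
    cls <- oi$classes
    interfaces <- lapply(seq_len(nrow(cls)), function(i)
      list(a = fnames[cls$rep_a[i]], b = fnames[cls$rep_b[i]],
           mult = cls$multiplicity[i]))
    if (subsystem && nsub > 3) {
      keep <- vapply(interfaces, function(tm)
        tm$a %in% fnames[enc] && tm$b %in% fnames[enc], logical(1))
      interfaces <- interfaces[keep]
    }
    sd <- new_symmetry_definition(
      name = paste0("C", nsub, if (subsystem && nsub > 3) "_subsystem" else ""),
      frame_spec = frame_spec, jumps = jumps,
      dofs = list(BASEJUMP = default_denovo_dofs(init_x)),
      energy = list(intra = list(frame = "VRT0", mult = nsub),
                    interfaces = interfaces),
      anchor = "COM", recenter = TRUE, total_subunits = nsub,
      full_frames = if (subsystem && nsub > 3) fnames else NULL,
      slide = list(slide_type = "SEQUENTIAL", criteria_type = "CONTACT",
                   criteria_val = 4.5))
  } else {
    m <- nsub / 2
    base <- denovo_base_frame()
    frames <- list(
      virtual_frame("VRTRING0", c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
      virtual_frame("VRTRING1", c(0, 0, 0),
                    as.vector(rot_x(180) %*% c(1, 0, 0)),
                    as.vector(rot_x(180) %*% c(0, 1, 0))))
    fnames <- character(nsub)
    for (j in seq_len(m) - 1) {
      up <- frame_from_tf(paste0("VRT", j),
                          tf_new(rot_z(360 * j / m), c(0, 0, 0)) %*%
                            frame_tf(base))
      lo <- frame_from_tf(paste0("VRT", m + j),
                          tf_new(rot_x(180), c(0, 0, 0)) %*%
                            tf_new(rot_z(360 * j / m), c(0, 0, 0)) %*%
                            frame_tf(base))
      frames[[length(frames) + 1]] <- up
      frames[[length(frames) + 1]] <- lo
      fnames[j + 1] <- up$name
      fnames[m + j + 1] <- lo$name
    }
    names(frames) <- vapply(frames, `[[`, "", "name")
    jumps <- data.frame(
      name = c("RINGJUMP", "RINGJUMP1"), start = "ROOT",
      stop = c("VRTRING0", "VRTRING1"),
      clone_group = "RINGGROUP", clone_weight = 1, stringsAsFactors = FALSE)
    for (j in seq_len(m) - 1) {
      jumps <- rbind(jumps, data.frame(
        name = paste0("FIXJ", c(j, m + j)),
        start = c("VRTRING0", "VRTRING1"),
        stop = c(paste0("VRT", j), paste0("VRT", m + j)),
        clone_group = NA_character_, clone_weight = 1,
        stringsAsFactors = FALSE))
    }
    att <- data.frame(
      name = c("BASEJUMP", paste0("BASEJUMP", seq_len(nsub - 1))),
      start = fnames, stop = "SUBUNIT",
      clone_group = "BASEGROUP", clone_weight = 1, stringsAsFactors = FALSE)
    jumps <- rbind(jumps, att)
    oi <- enumerate_interfaces("dn", nsub)
    cls <- oi$classes
    interfaces <- lapply(seq_len(nrow(cls)), function(i)
      list(a = fnames[cls$rep_a[i]], b = fnames[cls$rep_b[i]],
           mult = cls$multiplicity[i]))
    sd <- new_symmetry_definition(
      name = paste0("D", m),
      frame_spec = list(kind = "explicit", frames = frames),
      jumps = jumps,
      dofs = list(BASEJUMP = default_denovo_dofs(init_x),
                  RINGJUMP = list(allowed = "z", init = c(z = init_z),
                                  range = list())),
      energy = list(intra = list(frame = "VRT0", mult = nsub),
                    interfaces = interfaces),
      anchor = "COM", recenter = TRUE, total_subunits = nsub,
      slide = list(slide_type = "SEQUENTIAL", criteria_type = "CONTACT",
                   criteria_val = 4.5))
  }
  diags <- validate_sdf(sd)
  if (length(diags) > 0)
    stop("internal error: generated SDF invalid:\n  ",
         paste(diags, collapse = "\n  "))
  sd
}

#' Generate a de novo helical symmetry definition
#'
#' Builds a helical (screw) lattice SDF from the three helical parameters:
#' twist (degrees of rotation per subunit about the global z axis), rise
#' (Angstrom of translation per subunit along z) and radius (distance from
#' the axis to the subunit reference point, realized as the attachment x
#' dof). The rise/twist live on a chain of cloned jumps between consecutive
#' frames; each clone stores an integer weight equal to the number of rise
#' copies between it and the master — the scaling that derivative
#' bookkeeping applies to interactions spanning multiple rise steps. The
#' energy line is one-sided (master with its downstream neighbors, each
#' class weighted by the notional subunit count), the lattice convention
#' under which derivatives along the rise are accumulated in one direction
#' only.
#'
#' @param twist degrees per subunit, in (-180, 180].
#' @param rise Angstrom per subunit.
#' @param radius Angstrom from the helical axis (>= 0).
#' @param nsub number of explicitly modeled subunits (>= 3).
#' @param master index (1-based) of the master subunit; defaults to the
#'   middle of the fiber so both upstream and downstream context exist.
#' @return A validated `symmetry_definition` with the `lattice` flag set.
#' @export
generate_helical_sdf_denovo <- function(twist, rise, radius, nsub = 5,
                                        master = (nsub + 1) %/% 2) {
  if (nsub < 3) stop("nsub must be >= 3")
  if (radius < 0) stop("radius must be >= 0")
  if (twist <= -180 || twist > 180) stop("twist must be in (-180, 180]")
  base <- virtual_frame("VRT0", c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  frames <- lapply(seq_len(nsub) - 1, function(k) {
    f <- base; f$name <- paste0("VRT", k); f
  })
  names(frames) <- vapply(frames, `[[`, "", "name")
  jumps <- data.frame(name = "ROOTJUMP", start = "ROOT", stop = "VRT0",
                      clone_group = NA_character_, clone_weight = 1,
                      stringsAsFactors = FALSE)
  for (k in seq_len(nsub - 1)) {
    # jump entering frame k (0-based index k): weight = copies downstream of
    # the master along the path, at least 1
    w <- max(1, k - (master - 1))
    jumps <- rbind(jumps, data.frame(
      name = paste0("RISEJUMP", k - 1), start = paste0("VRT", k - 1),
      stop = paste0("VRT", k), clone_group = "RISEGROUP", clone_weight = w,
      stringsAsFactors = FALSE))
  }
  att <- data.frame(
    name = ifelse(seq_len(nsub) == master, "BASEJUMP",
                  paste0("BASEJUMP", seq_len(nsub) - 1)),
    start = paste0("VRT", seq_len(nsub) - 1), stop = "SUBUNIT",
    clone_group = "BASEGROUP", clone_weight = 1, stringsAsFactors = FALSE)
  jumps <- rbind(jumps, att)
  mfr <- paste0("VRT", master - 1)
  down <- seq(master, nsub - 1)   # 0-based indices downstream of the master
  interfaces <- lapply(down, function(k)
    list(a = mfr, b = paste0("VRT", k), mult = nsub))
  sd <- new_symmetry_definition(
    name = sprintf("HELIX_t%.4g_r%.4g", twist, rise),
    frame_spec = list(kind = "explicit", frames = frames),
    jumps = jumps,
    dofs = list(
      BASEJUMP = list(allowed = c("x", "angle_x"), init = c(x = radius),
                      range = list()),
      RISEJUMP0 = list(allowed = c("z", "angle_z"),
                       init = c(z = rise, angle_z = twist), range = list())),
    energy = list(intra = list(frame = mfr, mult = nsub),
                  interfaces = interfaces),
    anchor = "COM", recenter = TRUE, total_subunits = nsub, lattice = TRUE)
  diags <- validate_sdf(sd)
  if (length(diags) > 0)
    stop("internal error: generated helical SDF invalid:\n  ",
         paste(diags, collapse = "\n  "))
  sd
}

## ---- explicit-subunit selection --------------------------------------------

#' Select the explicitly modeled subunits of a large complex
#'
#' Returns the master chain plus every chain having at least one Calpha
#' within `cutoff_r` of any master Calpha — the subset that must be modeled
#' explicitly for a finite-range energy function to capture every interaction
#' of the master. Input order is preserved.
#'
#' @param complex a multichain `symm_structure`.
#' @param master master chain id.
#' @param cutoff_r maximum Calpha-Calpha interaction distance, Angstrom
#'   (default 10).
#' @return Character vector of chain ids (master first among equals of input
#'   order).
#' @export
select_explicit_subunits <- function(complex, master, cutoff_r = 10) {
  chains <- structure_chains(complex)
  if (!master %in% chains) stop("master chain '", master, "' not in complex")
  mca <- ca_coords(complex, master)
  keep <- vapply(chains, function(ch) {
    if (ch == master) return(TRUE)
    cca <- ca_coords(complex, ch)
    d2 <- outer(rowSums(mca^2), rowSums(cca^2), "+") - 2 * mca %*% t(cca)
    any(d2 < cutoff_r^2 + 1e-12)
  }, logical(1))
  chains[keep]
}

## ---- symmetrization of existing structures ---------------------------------

common_atom_coords <- function(s, ch_a, ch_b) {
  a <- s[s$chain == ch_a, , drop = FALSE]
  b <- s[s$chain == ch_b, , drop = FALSE]
  ka <- paste(a$resno, a$atom)
  kb <- paste(b$resno, b$atom)
  shared <- intersect(ka, kb)
  if (length(shared) < 3)
    stop("chains ", ch_a, " and ", ch_b, " share fewer than 3 atoms")
  if (length(shared) < 0.5 * max(length(ka), length(kb)))
    stop("chains ", ch_a, " and ", ch_b,
         " share fewer than 50% of their residues/atoms")
  list(a = as.matrix(a[match(shared, ka), c("x", "y", "z")]),
       b = as.matrix(b[match(shared, kb), c("x", "y", "z")]))
}

# fit the rigid transform mapping chain a onto chain b and analyse it as a
# (possibly approximate) symmetry operation
fit_symmetry_op <- function(s, ch_a, ch_b, max_order = 60) {
  cc <- common_atom_coords(s, ch_a, ch_b)
  k <- kabsch(cc$a, cc$b)
  aa <- rotation_axis_angle(k$R)
  n <- max(2, min(max_order, round(360 / max(aa$angle, 1e-9))))
  list(R = k$R, t = k$t, rmsd = k$rmsd, axis = aa$axis, angle = aa$angle,
       order = n, angle_dev = abs(aa$angle - 360 / n),
       center = rotation_axis_point(k$R, k$t))
}

# frames and SDF shared by the NCS builders: one frame per symmetry operation,
# each the image of the master frame under the op
ncs_master_frame <- function(anchor_pos, axis, center) {
  u <- unitize(axis)
  o <- center + sum((anchor_pos - center) * u) * u
  xr <- anchor_pos - o
  radius <- vnorm(xr)
  x <- if (radius > 1e-6) xr / radius else {
    pick <- which.min(abs(u))
    unitize(cross3(u, diag(3)[, pick]))
  }
  y <- cross3(u, x)
  list(tf = tf_new(cbind(x, y, u), o), radius = radius)
}

#' Symmetrize a point-symmetric complex and derive its symmetry definition
#'
#' The NCS ("non-crystallographic symmetry") mode: given a (possibly only
#' approximately symmetric) multichain complex, fits the rigid transform from
#' the main chain to one adjacent chain per point subgroup, extracts rotation
#' axis and angle, rounds the angle to the nearest 360/n, and rebuilds an
#' exactly symmetric complex about the fitted axes. One neighbor chain yields
#' a Cn system; two neighbor chains (a ring neighbor plus a cross-ring
#' neighbor) yield a Dn system with a two-level frame hierarchy (ring
#' rotation plus stack flip). The returned SDF encodes explicitly only the
#' chains with a Calpha within `cutoff_r` of the master.
#'
#' @param structure a multichain `symm_structure`.
#' @param main_chain chain id of the master subunit.
#' @param neighbor_chains one chain per point subgroup (see above).
#' @param cutoff_r explicit-subunit contact cutoff, Angstrom.
#' @param allow_global expose rigid-body movement of the complete system via
#'   a movable jump from the root to a global reference frame (needed when
#'   scoring against data in a fixed laboratory frame).
#' @param angle_tolerance warn when the fitted rotation deviates from the
#'   rounded symmetric angle by more than this many degrees.
#' @return List with `sd` (the SDF), `symmetrized` (the exactly symmetric
#'   complex), `interface_model` (explicit chains only), `master_input` (the
#'   master chain as modeling input) and `report` (a `symmetrization_report`:
#'   residual RMSD, fitted axes/angles, mode).
#' @export
symmetrize_ncs <- function(structure, main_chain, neighbor_chains,
                           cutoff_r = 10, allow_global = FALSE,
                           angle_tolerance = 10) {
  chains <- structure_chains(structure)
  stopifnot(main_chain %in% chains, all(neighbor_chains %in% chains))
  if (!length(neighbor_chains) %in% c(1, 2))
    stop("give one neighbor chain (Cn) or two (Dn)")
  master <- structure[structure$chain == main_chain, , drop = FALSE]
  master <- new_structure(master)
  anc <- anchor_residue(master, "COM")

  fit1 <- fit_symmetry_op(structure, main_chain, neighbor_chains[1])
  if (fit1$angle_dev > angle_tolerance)
    warning(sprintf(
      "fitted rotation %.2f deg is %.2f deg from the nearest symmetric angle 360/%d",
      fit1$angle, fit1$angle_dev, fit1$order))
  n <- fit1$order
  axis1 <- fit1$axis

  if (length(neighbor_chains) == 1) {
    center <- fit1$center
    R1 <- rot_axis(axis1, 360 / n)
    ops <- lapply(seq_len(n) - 1, function(k) {
      Rk <- rot_axis(axis1, 360 * k / n)
      tf_new(Rk, center - Rk %*% center)
    })
    mode <- "NCS"
    ring_frames <- NULL
    fitted_angle <- 360 / n
  } else {
    fit2 <- fit_symmetry_op(structure, main_chain, neighbor_chains[2])
    if (abs(fit2$angle - 180) > angle_tolerance)
      warning(sprintf("cross-ring fit angle %.2f deg is far from 180", fit2$angle))
    # force the flip axis perpendicular to the ring axis, through the common
    # center (closest point of the two fitted axes)
    axis2 <- unitize(fit2$axis - sum(fit2$axis * axis1) * axis1)
    # closest-approach midpoint of the two axis lines
    a1 <- fit1$center; a2 <- fit2$center
    d1 <- axis1; d2 <- fit2$axis
    cross12 <- cross3(d1, d2)
    denom <- sum(cross12^2)
    if (denom > 1e-10) {
      t1 <- sum(cross3(a2 - a1, d2) * cross12) / denom
      t2 <- sum(cross3(a2 - a1, d1) * cross12) / denom
      center <- ((a1 + t1 * d1) + (a2 + t2 * d2)) / 2
    } else center <- (a1 + a2) / 2
    Fop <- tf_new(rot_axis(axis2, 180),
                  center - rot_axis(axis2, 180) %*% center)
    ops <- list()
    for (k in seq_len(n) - 1) {
      Rk <- rot_axis(axis1, 360 * k / n)
      ops[[k + 1]] <- tf_new(Rk, center - Rk %*% center)
    }
    for (k in seq_len(n) - 1) {
      Rk <- rot_axis(axis1, 360 * k / n)
      ops[[n + k + 1]] <- Fop %*% tf_new(Rk, center - Rk %*% center)
    }
    mode <- "NCS"
    fitted_angle <- 360 / n
  }

  # exactly symmetric complex: images of the master under every op
  ids <- chain_ids(length(ops))
  pieces <- lapply(seq_along(ops), function(k) {
    sk <- master
    sk$chain <- ids[k]
    coords(sk) <- tf_apply(ops[[k]], coords(master))
    sk
  })
  symmetrized <- new_structure(do.call(rbind, pieces))

  # residual: each non-master input chain against its nearest rebuilt copy
  resid2 <- 0; nresid <- 0
  for (ch in setdiff(chains, main_chain)) {
    cc <- tryCatch(common_atom_coords(structure, main_chain, ch),
                   error = function(e) NULL)
    if (is.null(cc)) next
    ctr <- colMeans(cc$b)
    dists <- vapply(seq_along(ops), function(k)
      vnorm(colMeans(tf_apply(ops[[k]], cc$a)) - ctr), 0)
    k <- which.min(dists)
    rebuilt <- tf_apply(ops[[k]], cc$a)
    resid2 <- resid2 + sum((rebuilt - cc$b)^2)
    nresid <- nresid + nrow(cc$b)
  }
  residual_rmsd <- if (nresid > 0) sqrt(resid2 / nresid) else 0

  # frames: image of the master frame under each op
  mf <- ncs_master_frame(anc$pos, axis1, center)
  frames <- lapply(seq_along(ops), function(k)
    frame_from_tf(paste0("VRT", k - 1), ops[[k]] %*% mf$tf))
  names(frames) <- vapply(frames, `[[`, "", "name")
  fnames <- names(frames)

  jumps <- NULL
  dofs <- list()
  if (length(neighbor_chains) == 2) {
    u1 <- unitize(axis1)
    xr <- (anc$pos - center) - sum((anc$pos - center) * u1) * u1
    xv <- if (vnorm(xr) > 1e-6) unitize(xr) else
      unitize(cross3(u1, diag(3)[, which.min(abs(u1))]))
    rf0 <- frame_from_tf("VRTRING0", tf_new(cbind(xv, cross3(u1, xv), u1),
                                            center))
    rf1 <- frame_from_tf("VRTRING1", Fop %*% frame_tf(rf0))
    frames <- c(list(VRTRING0 = rf0, VRTRING1 = rf1), frames)
    jumps <- data.frame(
      name = c("RINGJUMP", "RINGJUMP1"), start = "ROOT",
      stop = c("VRTRING0", "VRTRING1"), clone_group = "RINGGROUP",
      clone_weight = 1, stringsAsFactors = FALSE)
    ring_of <- c(rep("VRTRING0", n), rep("VRTRING1", n))
    for (k in seq_along(fnames))
      jumps <- rbind(jumps, data.frame(
        name = paste0("FIXJ", k - 1), start = ring_of[k], stop = fnames[k],
        clone_group = NA_character_, clone_weight = 1,
        stringsAsFactors = FALSE))
    dofs$RINGJUMP <- list(allowed = "z", init = c(z = 0), range = list())
  } else if (allow_global) {
    tmp <- frame_from_tf("VRTGLOBAL", mf$tf)
    gf <- virtual_frame("VRTGLOBAL", center, tmp$x_axis, tmp$y_axis)
    frames <- c(list(VRTGLOBAL = gf), frames)
    jumps <- data.frame(
      name = "GLOBALJUMP", start = "ROOT", stop = "VRTGLOBAL",
      clone_group = NA_character_, clone_weight = 1, stringsAsFactors = FALSE)
    for (k in seq_along(fnames))
      jumps <- rbind(jumps, data.frame(
        name = paste0("FIXJ", k - 1), start = "VRTGLOBAL", stop = fnames[k],
        clone_group = NA_character_, clone_weight = 1,
        stringsAsFactors = FALSE))
    dofs$GLOBALJUMP <- list(allowed = DOF_NAMES, init = numeric(),
                            range = list())
  } else {
    jumps <- data.frame(
      name = paste0("ROOTJUMP", seq_along(fnames) - 1), start = "ROOT",
      stop = fnames, clone_group = "ROOTGROUP", clone_weight = 1,
      stringsAsFactors = FALSE)
  }

  explicit <- select_explicit_subunits(symmetrized, ids[1], cutoff_r)
  enc <- match(explicit, ids)
  att <- data.frame(
    name = ifelse(enc == 1, "JUMP0_to_com", paste0("JUMP", enc - 1, "_to_com")),
    start = fnames[enc], stop = "SUBUNIT", clone_group = "COMGROUP",
    clone_weight = 1, stringsAsFactors = FALSE)
  jumps <- rbind(jumps, att)
  dofs$JUMP0_to_com <- list(allowed = c("x", "angle_x"),
                            init = c(x = mf$radius), range = list())

  group_type <- if (length(neighbor_chains) == 2) "dn" else "cn"
  oi <- enumerate_interfaces(group_type, length(ops))
  cls <- oi$classes
  interfaces <- list()
  for (i in seq_len(nrow(cls))) {
    if (cls$rep_a[i] %in% enc && cls$rep_b[i] %in% enc)
      interfaces[[length(interfaces) + 1]] <-
        list(a = fnames[cls$rep_a[i]], b = fnames[cls$rep_b[i]],
             mult = cls$multiplicity[i])
  }

  sd <- new_symmetry_definition(
    name = if (group_type == "cn") paste0("C", n) else paste0("D", n),
    frame_spec = list(kind = "explicit", frames = frames),
    jumps = jumps, dofs = dofs,
    energy = list(intra = list(frame = fnames[1], mult = length(ops)),
                  interfaces = interfaces),
    anchor = anc$resno, recenter = FALSE, total_subunits = length(ops),
    full_frames = if (length(explicit) < length(ops)) fnames else NULL)
  diags <- validate_sdf(sd)
  if (length(diags) > 0)
    stop("internal error: symmetrized SDF invalid:\n  ",
         paste(diags, collapse = "\n  "))

  report <- structure(list(
    residual_rmsd = residual_rmsd, fitted_axis = unitize(axis1),
    fitted_angle = fitted_angle, raw_angle = fit1$angle,
    angle_dev = fit1$angle_dev, order = n, mode = mode,
    center = center), class = "symmetrization_report")
  if (residual_rmsd > 2)
    warning(sprintf(
      "input is far from symmetric (residual RMSD %.2f A); the symmetrized system may be far from the start point",
      residual_rmsd))

  interface_model <- new_structure(
    symmetrized[symmetrized$chain %in% explicit, , drop = FALSE])
  list(sd = sd, symmetrized = symmetrized, interface_model = interface_model,
       master_input = master, report = report)
}

#' @export
print.symmetrization_report <- function(x, ...) {
  cat(sprintf("<symmetrization_report %s> order %d, fitted angle %.3f deg (raw %.3f), residual RMSD %.4f A\n",
              x$mode, x$order, x$fitted_angle, x$raw_angle, x$residual_rmsd))
  invisible(x)
}

#' Fit helical parameters and derive a helical symmetry definition
#'
#' The HELIX mode: fits the screw transform from the main chain to the next
#' chain along the fiber (rotation angle = twist, translation along the
#' rotation axis = rise, perpendicular offset of the subunit reference point
#' = radius), optionally forces an integer number of subunits per turn, and
#' emits a lattice SDF in the canonical frame (helical axis = global z). The
#' master-chain coordinates transformed into that frame are returned as the
#' modeling input.
#'
#' @param structure a multichain `symm_structure`.
#' @param main_chain chain id of the master subunit.
#' @param next_chain chain id of the next subunit along the fiber.
#' @param forced_units_per_turn optional integer n; overrides the fitted
#'   twist with 360/n (same sense as fitted) and re-symmetrizes.
#' @param nsub number of subunits to encode (default: chains in the input,
#'   at least 5).
#' @return List with `sd`, `master_input` (canonical-frame master chain),
#'   `params` (twist/rise/radius) and `report`.
#' @export
generate_helical_sdf <- function(structure, main_chain, next_chain,
                                 forced_units_per_turn = NULL, nsub = NULL) {
  cc <- common_atom_coords(structure, main_chain, next_chain)
  k <- kabsch(cc$a, cc$b)
  aa <- rotation_axis_angle(k$R)
  if (aa$angle < 1e-6 && vnorm(k$t) < 1e-6)
    stop("degenerate main->next transform (identity)")
  u <- aa$axis
  rise <- sum(k$t * u)
  if (rise < 0) { u <- -u; rise <- -rise }
  # sign convention: axis oriented along positive rise; twist in (-180, 180]
  twist <- aa$angle * ifelse(sum(aa$axis * u) >= 0, 1, -1)
  if (twist <= -180) twist <- twist + 360
  if (!is.null(forced_units_per_turn))
    twist <- sign(ifelse(twist == 0, 1, twist)) * 360 / forced_units_per_turn
  t_perp <- k$t - rise * u
  center <- rotation_axis_point(k$R, t_perp)

  master <- new_structure(structure[structure$chain == main_chain, ,
                                    drop = FALSE])
  anc <- anchor_residue(master, "COM")
  radius <- vnorm((anc$pos - center) - sum((anc$pos - center) * u) * u)

  # canonicalize: axis -> z, axis point -> origin, anchor azimuth -> +x
  z <- u
  xr <- (anc$pos - center) - sum((anc$pos - center) * z) * z
  x <- if (vnorm(xr) > 1e-6) unitize(xr) else
    unitize(cross3(z, diag(3)[, which.min(abs(z))]))
  W <- tf_inverse(tf_new(cbind(x, cross3(z, x), z), center))
  master_canon <- transform_structure(master, W)

  if (is.null(nsub))
    nsub <- max(5, length(structure_chains(structure)))
  sd <- generate_helical_sdf_denovo(twist, rise, radius, nsub = nsub)
  report <- structure(list(
    residual_rmsd = k$rmsd, fitted_axis = u, fitted_angle = twist,
    mode = "HELIX", rise = rise, radius = radius),
    class = "symmetrization_report")
  list(sd = sd, master_input = master_canon,
       params = list(twist = twist, rise = rise, radius = radius),
       report = report)
}

## ---- crystal mode ----------------------------------------------------------

# fractional-coordinate symmetry operators of the supported spacegroups
SPACEGROUP_OPS <- list(
  "P 1" = list(list(R = diag(3), t = c(0, 0, 0))),
  "P 1 21 1" = list(
    list(R = diag(3), t = c(0, 0, 0)),
    list(R = diag(c(-1, 1, -1)), t = c(0, 0.5, 0))),
  "C 1 2 1" = list(
    list(R = diag(3), t = c(0, 0, 0)),
    list(R = diag(c(-1, 1, -1)), t = c(0, 0, 0)),
    list(R = diag(3), t = c(0.5, 0.5, 0)),
    list(R = diag(c(-1, 1, -1)), t = c(0.5, 0.5, 0))),
  "P 21 21 21" = list(
    list(R = diag(3), t = c(0, 0, 0)),
    list(R = diag(c(1, -1, -1)), t = c(0.5, 0.5, 0)),
    list(R = diag(c(-1, 1, -1)), t = c(0, 0.5, 0.5)),
    list(R = diag(c(-1, -1, 1)), t = c(0.5, 0, 0.5))),
  "I 2 2 2" = local({
    base <- list(
      list(R = diag(3), t = c(0, 0, 0)),
      list(R = diag(c(1, -1, -1)), t = c(0, 0, 0)),
      list(R = diag(c(-1, 1, -1)), t = c(0, 0, 0)),
      list(R = diag(c(-1, -1, 1)), t = c(0, 0, 0)))
    c(base, lapply(base, function(op) {
      op$t <- op$t + 0.5
      op
    }))
  })
)

# orthogonalization matrix: fractional -> cartesian
cell_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; c0 <- cell[3]
  al <- deg2rad(cell[4]); be <- deg2rad(cell[5]); ga <- deg2rad(cell[6])
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, 0, 0,
           b * cos(ga), b * sin(ga), 0,
           c0 * cos(be), c0 * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           c0 * v / sin(ga)), 3, 3)
}

#' Derive a crystal-lattice symmetry definition
#'
#' The CRYST mode: expands the spacegroup operators of the input's CRYST1
#' record (plus lattice translations) and encodes every symmetry copy with a
#' Calpha within `cutoff_r` of the master. The unit cell is fixed: cell
#' dimensions are not degrees of freedom, only the rigid-body placement of
#' the subunit in the asymmetric unit may move. Following the lattice
#' convention, the energy line encodes the total as twice the per-subunit
#' energy: intra multiplier 2 and multiplier 1 for each explicit interface.
#'
#' Supported spacegroups: P 1, P 1 21 1, C 1 2 1, P 21 21 21, I 2 2 2
#' (anything else can be modeled via user-supplied explicit frames).
#'
#' @param structure a `symm_structure` whose CRYST1 attribute (or the
#'   overrides) defines the lattice; expected to contain the asymmetric unit.
#' @param spacegroup_override,cell_override optional overrides for the CRYST1
#'   spacegroup symbol / six cell parameters.
#' @param cutoff_r explicit-copy contact cutoff, Angstrom.
#' @return List with `sd` (lattice SDF) and `symmetrized` (the explicit
#'   lattice neighborhood as a multichain structure).
#' @export
make_crystal_sdf <- function(structure, spacegroup_override = NULL,
                             cell_override = NULL, cutoff_r = 10) {
  cry <- attr(structure, "cryst1")
  sg <- spacegroup_override %||% cry$spacegroup
  cell <- cell_override %||% cry$cell
  if (is.null(sg) || is.null(cell))
    stop("no CRYST1 record and no overrides given")
  if (!sg %in% names(SPACEGROUP_OPS))
    stop("unsupported spacegroup '", sg, "'; supported: ",
         paste(names(SPACEGROUP_OPS), collapse = ", "))
  A <- cell_matrix(cell)
  Ainv <- solve(A)

  master <- structure
  if (length(structure_chains(master)) > 1)
    stop("crystal mode expects the asymmetric unit as a single chain")
  anc <- anchor_residue(master, "COM")
  mca <- ca_coords(master)

  ops_cart <- list()
  for (op in SPACEGROUP_OPS[[sg]]) {
    for (i in -1:1) for (j in -1:1) for (kz in -1:1) {
      Rc <- A %*% op$R %*% Ainv
      tc <- as.vector(A %*% (op$t + c(i, j, kz)))
      T <- tf_new(Rc, tc)
      if (max(abs(T - diag(4))) < 1e-9) next   # the master itself
      cca <- tf_apply(T, mca)
      d2 <- outer(rowSums(mca^2), rowSums(cca^2), "+") - 2 * mca %*% t(cca)
      if (any(d2 < cutoff_r^2)) ops_cart[[length(ops_cart) + 1]] <- T
    }
  }
  ops_cart <- c(list(diag(4)), ops_cart)

  mf <- tf_new(diag(3), anc$pos)
  frames <- lapply(seq_along(ops_cart), function(k)
    frame_from_tf(paste0("VRT", k - 1), ops_cart[[k]] %*% mf))
  names(frames) <- vapply(frames, `[[`, "", "name")
  fnames <- names(frames)
  jumps <- data.frame(
    name = paste0("ROOTJUMP", seq_along(fnames) - 1), start = "ROOT",
    stop = fnames, clone_group = "ROOTGROUP", clone_weight = 1,
    stringsAsFactors = FALSE)
  att <- data.frame(
    name = ifelse(seq_along(fnames) == 1, "CRYSTJUMP",
                  paste0("CRYSTJUMP", seq_along(fnames) - 1)),
    start = fnames, stop = "SUBUNIT", clone_group = "CRYSTGROUP",
    clone_weight = 1, stringsAsFactors = FALSE)
  jumps <- rbind(jumps, att)
  interfaces <- lapply(seq_along(fnames)[-1], function(k)
    list(a = "VRT0", b = fnames[k], mult = 1))
  sd <- new_symmetry_definition(
    name = paste0("CRYST_", gsub(" ", "", sg)),
    frame_spec = list(kind = "explicit", frames = frames),
    jumps = jumps,
    dofs = list(CRYSTJUMP = list(allowed = DOF_NAMES, init = numeric(),
                                 range = list())),
    energy = list(intra = list(frame = "VRT0", mult = 2),
                  interfaces = interfaces),
    anchor = anc$resno, recenter = FALSE,
    total_subunits = length(ops_cart), lattice = TRUE)
  diags <- validate_sdf(sd)
  if (length(diags) > 0)
    stop("internal error: crystal SDF invalid:\n  ",
         paste(diags, collapse = "\n  "))

  ids <- chain_ids(length(ops_cart))
  pieces <- lapply(seq_along(ops_cart), function(k) {
    sk <- master
    sk$chain <- ids[k]
    coords(sk) <- tf_apply(ops_cart[[k]], coords(master))
    sk
  })
  list(sd = sd, symmetrized = new_structure(do.call(rbind, pieces)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
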