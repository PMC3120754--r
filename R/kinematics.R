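# Symmetric conformations: master-subunit coordinates plus per-subunit frames,
# with master/slave propagation of torsion and rigid-body degrees of freedom.
#
# Model
# -----
# Every virtual frame has a REFERENCE placement (from the SDF). The CURRENT
# placement is obtained by traversing the jump tree from the root: for a jump
# P -> C carrying the 6-vector v of its clone group,
#
#     G_C = G_P %*% (Ref_P^-1 %*% Ref_C) %*% Delta(v)
#
# where Delta(v) is the local jump transform (see jump_transform()). Because
# Delta acts in C's own local axes, one shared 6-vector per clone group moves
# every clone identically in its own frame — the master/slave contract. A
# subunit attached to frame F by jump with value v_att has atom positions
#
#     p = G_F %*% Delta(v_att) %*% q
#
# with q the master-local coordinates, the single source of truth for the
# internal structure of all subunits. Slave coordinates are always derived,
# never stored.

chain_ids <- function(n) {
  pool <- c(LETTERS, letters, as.character(0:9))
  if (n > length(pool)) pool <- c(pool, paste0("Z", seq_len(n)))
  pool[seq_len(n)]
}

zero_jump <- function() stats::setNames(numeric(6), DOF_NAMES)

#' Build a symmetric conformation
#'
#' Attaches a master subunit to its virtual frame and instantiates the
#' symmetric system described by an SDF. Initial degree-of-freedom values come
#' from the `set_dof` inits. With `recenter` set in the SDF the master is
#' first translated so its anchor residue sits on the frame origin (de novo
#' convention: a translational dof along the frame x axis then places the
#' subunits at +/- that distance from the origin); without it, the input
#' coordinates are taken to already realize the initial dof values, so the
#' built master reproduces the input exactly.
#'
#' @param sd a validated `symmetry_definition`.
#' @param master_structure a `symm_structure` holding the master subunit
#'   (single chain).
#' @return An object of class `symmetric_conformation`.
#' @export
build_conformation <- function(sd, master_structure) {
  diags <- validate_sdf(sd)
  if (length(diags) > 0)
    stop("invalid symmetry definition:\n  ", paste(diags, collapse = "\n  "))
  frames <- resolve_frames(sd)
  att <- attachment_jumps(sd)
  if (length(att) == 0) stop("SDF attaches no subunits")
  grp <- jump_groups(sd)
  subunits <- data.frame(
    frame = sd$jumps$start[att], jump = sd$jumps$name[att],
    group = grp[att], chain = chain_ids(length(att)),
    stringsAsFactors = FALSE)
  mi <- match(sd$energy$intra$frame, subunits$frame)
  if (is.na(mi))
    stop("energy intra frame '", sd$energy$intra$frame,
         "' attaches no subunit")

  jump_values <- list()
  for (g in unique(grp)) {
    v <- zero_jump()
    d <- group_dofs(sd, g)
    if (!is.null(d) && length(d$init) > 0)
      v[names(d$init)] <- unlist(d$init)
    jump_values[[g]] <- v
  }

  ms <- master_structure
  if (length(unique(ms$chain)) != 1)
    stop("master structure must contain exactly one chain")
  anc <- anchor_residue(ms, sd$anchor)
  conf <- structure(list(
    sd = sd, frames = frames, jump_values = jump_values,
    subunits = subunits, master_index = mi, anchor_resno = anc$resno,
    q = NULL), class = "symmetric_conformation")

  mframe <- frames[[subunits$frame[mi]]]
  B <- frame_basis(mframe)
  p <- coords(ms)
  if (isTRUE(sd$recenter)) {
    q <- sweep(p, 2, anc$pos) %*% B   # = t(B) %*% (p - anchor) rowwise
  } else {
    G <- frame_placements(conf)
    A <- G[[subunits$frame[mi]]] %*%
      jump_transform(jump_values[[subunits$group[mi]]])
    q <- tf_apply(tf_inverse(A), p)
  }
  qdf <- ms
  qdf$chain <- "A"
  coords(qdf) <- q
  conf$q <- qdf
  conf
}

#' @export
print.symmetric_conformation <- function(x, ...) {
  cat(sprintf("<symmetric_conformation %s> %d explicit subunit(s) of %d, %d residues each, master %s\n",
              x$sd$name, nrow(x$subunits), x$sd$total_subunits,
              n_residues(x$q), x$subunits$chain[x$master_index]))
  invisible(x)
}

# frame -> incoming jump index, and a topological processing order
jump_tree <- function(sd) {
  J <- sd$jumps
  fj <- J[J$stop != "SUBUNIT", , drop = FALSE]
  incoming <- stats::setNames(match(fj$name, J$name), fj$stop)
  list(incoming = incoming)
}

#' Current placements of all virtual frames
#'
#' Traverses the jump tree and composes reference placements with the current
#' clone-group jump values; frames outside the jump tree stay at their
#' reference placement.
#'
#' @param conf a `symmetric_conformation`.
#' @return Named list of 4x4 placement matrices, one per frame.
#' @export
frame_placements <- function(conf) {
  sd <- conf$sd
  frames <- conf$frames
  refs <- lapply(frames, frame_tf)
  G <- refs
  J <- sd$jumps
  grp <- jump_groups(sd)
  fj <- which(J$stop != "SUBUNIT")
  done <- stats::setNames(rep(FALSE, length(frames)), names(frames))
  # frames with no incoming jump sit at their reference placement
  has_in <- names(frames) %in% J$stop
  done[!has_in] <- TRUE
  pend <- fj
  while (length(pend) > 0) {
    progressed <- FALSE
    rest <- integer()
    for (ji in pend) {
      st <- J$start[ji]; sp <- J$stop[ji]
      if (st == "ROOT" || done[[st]]) {
        v <- conf$jump_values[[grp[ji]]]
        D <- jump_transform(v)
        if (st == "ROOT") {
          G[[sp]] <- refs[[sp]] %*% D
        } else {
          G[[sp]] <- G[[st]] %*% tf_inverse(refs[[st]]) %*% refs[[sp]] %*% D
        }
        done[[sp]] <- TRUE
        progressed <- TRUE
      } else rest <- c(rest, ji)
    }
    pend <- rest
    if (!progressed && length(pend) > 0)
      stop("jump tree could not be ordered (cycle or missing root)")
  }
  G
}

# placements of the explicit subunits (frame placement o attach delta)
subunit_placements <- function(conf, G = frame_placements(conf)) {
  su <- conf$subunits
  out <- vector("list", nrow(su))
  for (k in seq_len(nrow(su)))
    out[[k]] <- G[[su$frame[k]]] %*% jump_transform(conf$jump_values[[su$group[k]]])
  names(out) <- su$chain
  out
}

#' Rigid transforms from the master subunit to each explicit subunit
#'
#' @param conf a `symmetric_conformation`.
#' @return Named list (by chain) of 4x4 transforms `T_k` with
#'   `slave_k = T_k(master)`; the master maps to the identity.
#' @export
subunit_transforms <- function(conf) {
  A <- subunit_placements(conf)
  Am_inv <- tf_inverse(A[[conf$master_index]])
  lapply(A, function(Ak) Ak %*% Am_inv)
}

#' Explicit multichain structure of a conformation
#'
#' Realizes the coordinates of every explicitly encoded subunit (master plus
#' modeled slaves) as one multichain structure, chains lettered in frame
#' order.
#'
#' @param conf a `symmetric_conformation`.
#' @return A `symm_structure`.
#' @export
explicit_structure <- function(conf) {
  A <- subunit_placements(conf)
  q <- conf$q
  pieces <- vector("list", length(A))
  for (k in seq_along(A)) {
    sk <- q
    sk$chain <- conf$subunits$chain[k]
    coords(sk) <- tf_apply(A[[k]], coords(q))
    pieces[[k]] <- sk
  }
  new_structure(do.call(rbind, pieces))
}

# fast paths: per-chain coordinate matrices without data.frame assembly
conf_atom_coords <- function(conf) {
  A <- subunit_placements(conf)
  q <- coords(conf$q)
  lapply(A, function(Ak) tf_apply(Ak, q))
}

conf_ca_coords <- function(conf) {
  A <- subunit_placements(conf)
  q <- coords(conf$q)[conf$q$atom == "CA", , drop = FALSE]
  lapply(A, function(Ak) tf_apply(Ak, q))
}

#' Expand the full symmetric system
#'
#' Returns all `N` subunits as a multichain structure, including the
#' virtual-only copies beyond the explicitly encoded `S` when the SDF lists
#' `full_system_frames`. Chain count equals the number of expansion frames.
#'
#' @param conf a `symmetric_conformation`.
#' @return A `symm_structure` with one chain per subunit of the full system.
#' @export
expand_full <- function(conf) {
  sd <- conf$sd
  fnames <- if (!is.null(sd$full_frames)) sd$full_frames else
    conf$subunits$frame
  G <- frame_placements(conf)
  mgrp <- conf$subunits$group[conf$master_index]
  ids <- chain_ids(length(fnames))
  pieces <- vector("list", length(fnames))
  for (k in seq_along(fnames)) {
    fr <- fnames[[k]]
    ki <- match(fr, conf$subunits$frame)
    grp <- if (!is.na(ki)) conf$subunits$group[ki] else mgrp
    A <- G[[fr]] %*% jump_transform(conf$jump_values[[grp]])
    sk <- conf$q
    sk$chain <- ids[k]
    coords(sk) <- tf_apply(A, coords(conf$q))
    pieces[[k]] <- sk
  }
  new_structure(do.call(rbind, pieces))
}

## ---- rigid-body dofs -------------------------------------------------------

# group id and dof spec for a jump name
jump_group_of <- function(sd, jump) {
  idx <- match(jump, sd$jumps$name)
  if (is.na(idx)) stop("no jump named '", jump, "'")
  jump_groups(sd)[idx]
}

#' Set a rigid-body degree of freedom
#'
#' Updates one component of a jump's 6-vector. The value is applied to the
#' jump's whole clone group, i.e. replicated into every slave frame, so the
#' point-group symmetry of the system is preserved by construction. Setting a
#' dof that the SDF does not allow is an error and leaves the conformation
#' unchanged — this is the guard that keeps a protocol from accidentally
#' de-symmetrizing the system.
#'
#' @param conf a `symmetric_conformation`.
#' @param jump jump name (any member of the clone group).
#' @param dof one of `x`, `y`, `z` (Angstrom) or `angle_x`, `angle_y`,
#'   `angle_z` (degrees).
#' @param value new value.
#' @param check validate against the SDF's allowed set (default TRUE;
#'   internal callers that have already validated may skip).
#' @return The updated conformation.
#' @export
set_jump_dof <- function(conf, jump, dof, value, check = TRUE) {
  sd <- conf$sd
  g <- jump_group_of(sd, jump)
  if (check) {
    d <- group_dofs(sd, g)
    if (is.null(d) || !dof %in% d$allowed)
      stop("dof '", dof, "' is not allowed on jump '", jump,
           "' (allowed: ", if (is.null(d)) "none" else
             paste(d$allowed, collapse = ", "), ")")
  }
  if (!dof %in% DOF_NAMES) stop("unknown dof '", dof, "'")
  conf$jump_values[[g]][[dof]] <- value
  conf
}

#' @rdname set_jump_dof
#' @export
get_jump_dof <- function(conf, jump, dof) {
  g <- jump_group_of(conf$sd, jump)
  conf$jump_values[[g]][[dof]]
}

# all allowed dofs of the system as a data.frame(group, jump, dof, lo, hi)
allowed_dofs <- function(sd) {
  out <- list()
  grp <- jump_groups(sd)
  for (jn in names(sd$dofs)) {
    d <- sd$dofs[[jn]]
    g <- grp[match(jn, sd$jumps$name)]
    for (nm in d$allowed) {
      lo <- -Inf; hi <- Inf
      if (nm %in% names(d$range)) {
        r <- d$range[[nm]]
        # a full-circle angle range means "free", not a box constraint
        if (!(grepl("angle", nm) && abs((r[2] - r[1]) - 360) < 1e-9)) {
          lo <- r[1]; hi <- r[2]
        }
      }
      out[[length(out) + 1]] <- data.frame(
        group = g, jump = jn, dof = nm, lo = lo, hi = hi,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(group = character(), jump = character(),
                      dof = character(), lo = numeric(), hi = numeric()))
  do.call(rbind, out)
}

# current values of the allowed dof vector
dof_vector <- function(conf) {
  ad <- allowed_dofs(conf$sd)
  v <- numeric(nrow(ad))
  for (i in seq_len(nrow(ad))) v[i] <- conf$jump_values[[ad$group[i]]][[ad$dof[i]]]
  stats::setNames(v, paste(ad$group, ad$dof, sep = ":"))
}

set_dof_vector <- function(conf, v) {
  ad <- allowed_dofs(conf$sd)
  stopifnot(length(v) == nrow(ad))
  for (i in seq_len(nrow(ad)))
    conf$jump_values[[ad$group[i]]][[ad$dof[i]]] <- v[[i]]
  conf
}

#' Draw a uniformly random subunit orientation
#'
#' When all three rotational dofs of the jump are allowed with full 0-360
#' ranges, the orientation is drawn uniformly from the rotation group SO(3)
#' (uniform-quaternion method) and decomposed into the jump's three angles —
#' NOT by three independent uniform Euler angles, which would oversample the
#' poles. When the rotational freedom is restricted, each allowed angle is
#' instead drawn independently within its range (so a jump allowed only
#' `angle_x(0:360)` spins about its x axis only).
#'
#' @param conf a `symmetric_conformation`.
#' @param jump jump carrying the rotational dofs.
#' @param seed optional integer; when given, seeds the RNG for reproducibility.
#' @return The updated conformation.
#' @export
random_orientation <- function(conf, jump, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sd <- conf$sd
  g <- jump_group_of(sd, jump)
  d <- group_dofs(sd, g)
  if (is.null(d)) stop("jump '", jump, "' allows no dofs")
  angs <- intersect(c("angle_x", "angle_y", "angle_z"), d$allowed)
  full <- vapply(angs, function(nm) {
    r <- d$range[[nm]]
    !is.null(r) && abs((r[2] - r[1]) - 360) < 1e-9
  }, logical(1))
  if (length(angs) == 3 && all(full)) {
    e <- euler_zyx_from_matrix(random_rotation_matrix())
    for (nm in c("angle_x", "angle_y", "angle_z"))
      conf <- set_jump_dof(conf, jump, nm, e[[nm]], check = FALSE)
  } else {
    for (nm in angs) {
      r <- d$range[[nm]]
      if (is.null(r)) r <- c(0, 360)
      conf <- set_jump_dof(conf, jump, nm, stats::runif(1, r[1], r[2]),
                           check = FALSE)
    }
  }
  conf
}

## ---- torsions --------------------------------------------------------------

torsion_atoms <- function(q, resno, torsion) {
  at <- function(rn, nm) {
    i <- which(q$resno == rn & q$atom == nm)
    if (length(i) != 1) return(NULL)
    i
  }
  idx <- switch(torsion,
    phi = list(at(resno - 1, "C"), at(resno, "N"), at(resno, "CA"),
               at(resno, "C")),
    psi = list(at(resno, "N"), at(resno, "CA"), at(resno, "C"),
               at(resno + 1, "N")),
    omega = list(at(resno, "CA"), at(resno, "C"), at(resno + 1, "N"),
                 at(resno + 1, "CA")),
    chi1 = list(at(resno, "N"), at(resno, "CA"), at(resno, "CB"),
                at(resno, "CG")),
    stop("unknown torsion '", torsion, "'"))
  if (any(vapply(idx, is.null, logical(1))))
    stop("torsion ", torsion, " is undefined for residue ", resno)
  unlist(idx)
}

# atoms on the C-terminal side of the rotation axis (the moving set when the
# anchor lies on the N-terminal side)
torsion_moving_set <- function(q, resno, torsion) {
  r <- q$resno
  a <- q$atom
  switch(torsion,
    phi = which(r > resno | (r == resno & a %in% c("C", "O", "CB", "CG"))),
    psi = which(r > resno | (r == resno & a == "O")),
    omega = which(r > resno),
    chi1 = which(r == resno & a == "CG"))
}

#' Read a torsion angle of the master subunit
#'
#' @param conf a `symmetric_conformation`.
#' @param resno residue number (master numbering; identical in every subunit).
#' @param torsion `"phi"`, `"psi"`, `"omega"` or `"chi1"`.
#' @return Angle in degrees.
#' @export
get_torsion <- function(conf, resno, torsion) {
  q <- conf$q
  idx <- torsion_atoms(q, resno, torsion)
  p <- coords(q)
  dihedral(p[idx[1], ], p[idx[2], ], p[idx[3], ], p[idx[4], ])
}

#' Set a torsion angle (propagated to all subunits)
#'
#' Rotates the atoms on the far side of the torsion bond (relative to the
#' anchor residue) about the bond axis so the torsion takes the requested
#' value. Because slave coordinates are always derived from the master by the
#' subunit transforms, the change appears simultaneously in every subunit and
#' the internal coordinates of all subunits remain identical.
#'
#' @inheritParams get_torsion
#' @param value target angle in degrees.
#' @return The updated conformation.
#' @export
set_torsion <- function(conf, resno, torsion, value) {
  q <- conf$q
  idx <- torsion_atoms(q, resno, torsion)
  p <- coords(q)
  cur <- dihedral(p[idx[1], ], p[idx[2], ], p[idx[3], ], p[idx[4], ])
  delta <- value - cur
  if (abs(delta) < 1e-13) return(conf)
  moving <- torsion_moving_set(q, resno, torsion)
  anchor_ca <- which(q$resno == conf$anchor_resno & q$atom == "CA")
  axis_a <- p[idx[2], ]; axis_b <- p[idx[3], ]
  # rotating the far (C-terminal) side by -delta about the a->b axis
  # increases the measured dihedral by delta; when the anchor residue lies
  # on the far side, rotate the near side with the opposite sign instead so
  # the anchor stays fixed
  rot_angle <- -delta
  if (length(anchor_ca) == 1 && anchor_ca %in% moving) {
    moving <- setdiff(seq_len(nrow(q)), moving)
    rot_angle <- delta
  }
  R <- rot_axis(axis_b - axis_a, rot_angle)
  p[moving, ] <- sweep(sweep(p[moving, , drop = FALSE], 2, axis_a) %*% t(R),
                       2, -axis_a)
  coords(q) <- p
  conf$q <- q
  conf
}
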