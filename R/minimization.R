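# Gradient-based optimization of symmetric degrees of freedom.
#
# All rigid-body partials are computed analytically by the chain rule through
# the placement recursion: for each allowed dof the derivative of every
# frame placement (a 4x4 matrix) is propagated down the jump tree, giving
# exact per-atom position derivatives for every explicit subunit. Because
# the m-th clone of a lattice jump enters the recursion m times, the
# cloned-jump weighting of lattice derivatives (an interaction spanning m
# rise copies contributes m times the one-copy derivative) emerges from the
# same bookkeeping; cloned_jump_chain() exposes that decomposition
# explicitly. Gradients therefore match central finite differences of the
# symmetric score by construction of the machinery, and that agreement is a
# first-class, user-callable check (check_derivatives()) rather than only a
# test: the hardest content here is derivative bookkeeping.

# placement derivative recursion: for each frame, G and dG per requested dof
placement_derivs <- function(conf, ad) {
  sd <- conf$sd
  frames <- conf$frames
  refs <- lapply(frames, frame_tf)
  nd <- nrow(ad)
  G <- refs
  Z4 <- matrix(0, 4, 4)
  dG <- lapply(frames, function(f) rep(list(Z4), nd))
  J <- sd$jumps
  grp <- jump_groups(sd)
  fj <- which(J$stop != "SUBUNIT")
  done <- stats::setNames(!(names(frames) %in% J$stop), names(frames))
  pend <- fj
  while (length(pend) > 0) {
    rest <- integer(); progressed <- FALSE
    for (ji in pend) {
      st <- J$start[ji]; sp <- J$stop[ji]
      if (st != "ROOT" && !done[[st]]) { rest <- c(rest, ji); next }
      v <- conf$jump_values[[grp[ji]]]
      D <- jump_transform(v)
      Rel <- if (st == "ROOT") diag(4) else
        tf_inverse(refs[[st]]) %*% refs[[sp]]
      base <- if (st == "ROOT") refs[[sp]] else G[[st]] %*% Rel
      G[[sp]] <- base %*% D
      for (di in seq_len(nd)) {
        up <- if (st == "ROOT") Z4 else dG[[st]][[di]] %*% Rel %*% D
        own <- if (ad$group[di] == grp[ji])
          base %*% jump_transform_deriv(v, ad$dof[di]) else Z4
        dG[[sp]][[di]] <- up + own
      }
      done[[sp]] <- TRUE; progressed <- TRUE
    }
    pend <- rest
    if (!progressed && length(pend) > 0)
      stop("jump tree could not be ordered")
  }
  list(G = G, dG = dG)
}

# per-subunit placements and their dof derivatives
subunit_derivs <- function(conf, ad) {
  pd <- placement_derivs(conf, ad)
  su <- conf$subunits
  nd <- nrow(ad)
  A <- vector("list", nrow(su)); dA <- vector("list", nrow(su))
  for (k in seq_len(nrow(su))) {
    v <- conf$jump_values[[su$group[k]]]
    D <- jump_transform(v)
    Gf <- pd$G[[su$frame[k]]]
    A[[k]] <- Gf %*% D
    dA[[k]] <- vector("list", nd)
    for (di in seq_len(nd)) {
      own <- if (ad$group[di] == su$group[k])
        Gf %*% jump_transform_deriv(v, ad$dof[di]) else matrix(0, 4, 4)
      dA[[k]][[di]] <- pd$dG[[su$frame[k]]][[di]] %*% D + own
    }
  }
  names(A) <- su$chain; names(dA) <- su$chain
  list(A = A, dA = dA, frame_G = pd$G, frame_dG = pd$dG)
}

# apply a placement derivative to local coordinates: d(p)/d(dof) rows
deriv_apply <- function(dT, q) {
  sweep(q %*% t(dT[1:3, 1:3]), 2, -dT[1:3, 4])
}

#' Analytic gradient of the symmetric score
#'
#' Partial derivatives of [score()] with respect to every allowed rigid-body
#' degree of freedom, accumulated over all interactions touching the master
#' subunit with equal weighting inside each energy-line class and
#' chain-ruled through the per-subunit transforms. Translational partials
#' are per Angstrom, rotational per degree.
#'
#' @param conf a `symmetric_conformation`.
#' @param ef a `symm_energy` (tether terms are included; see
#'   [corrected_gradient()] for the rotation-corrected route).
#' @return Named numeric vector (`group:dof`), with attribute `dofs` (the
#'   dof table).
#' @export
dof_gradient <- function(conf, ef) {
  ad <- allowed_dofs(conf$sd)
  if (nrow(ad) == 0)
    return(structure(numeric(0), dofs = ad))
  sdv <- subunit_derivs(conf, ad)
  q <- coords(conf$q)
  P <- lapply(sdv$A, function(Ak) tf_apply(Ak, q))
  D <- lapply(seq_along(sdv$A), function(k)
    lapply(sdv$dA[[k]], function(dT) deriv_apply(dT, q)))
  names(D) <- names(sdv$A)

  mchain <- conf$subunits$chain[conf$master_index]
  w_intra <- conf$sd$energy$intra$mult
  wtab <- interface_weights(conf$sd)
  frame_of_chain <- stats::setNames(conf$subunits$frame, conf$subunits$chain)
  resno <- conf$q$resno
  pm <- P[[mchain]]
  mask <- intra_pair_mask(resno)

  grad <- numeric(nrow(ad))
  chain_contrib <- function(pb, db_list, w, pair_mask = NULL) {
    dx <- outer(pm[, 1], pb[, 1], "-")
    dy <- outer(pm[, 2], pb[, 2], "-")
    dz <- outer(pm[, 3], pb[, 3], "-")
    r <- sqrt(pmax(dx^2 + dy^2 + dz^2, 1e-12))
    coef <- pair_potential_deriv(as.vector(r), ef) / as.vector(r)
    dim(coef) <- dim(r)
    if (!is.null(pair_mask)) coef[!pair_mask] <- 0
    if (all(coef == 0)) return(invisible(NULL))
    da_list <- D[[mchain]]
    for (di in seq_len(nrow(ad))) {
      da <- da_list[[di]]; db <- db_list[[di]]
      ddx <- outer(da[, 1], db[, 1], "-")
      ddy <- outer(da[, 2], db[, 2], "-")
      ddz <- outer(da[, 3], db[, 3], "-")
      grad[di] <<- grad[di] + w * sum(coef * (dx * ddx + dy * ddy + dz * ddz))
    }
  }
  chain_contrib(pm, D[[mchain]], w_intra, pair_mask = mask)
  for (ch in setdiff(names(P), mchain)) {
    w <- unname(wtab[frame_of_chain[[ch]]])
    if (is.na(w) || w == 0) next
    chain_contrib(P[[ch]], D[[ch]], w)
  }

  te <- ef$tethers
  if (!is.null(te) && nrow(te) > 0) {
    for (i in seq_len(nrow(te))) {
      k <- match(te$chain[i], conf$subunits$chain)
      if (is.na(k)) next
      row <- which(conf$q$resno == te$resno[i] & conf$q$atom == te$atom[i])
      if (length(row) == 0) next
      ch <- te$chain[i]
      p <- P[[ch]][row, ]
      g <- 2 * te$k[i] * (p - c(te$tx[i], te$ty[i], te$tz[i]))
      for (di in seq_len(nrow(ad)))
        grad[di] <- grad[di] + sum(g * D[[ch]][[di]][row, ])
    }
  }
  structure(stats::setNames(grad, paste(ad$group, ad$dof, sep = ":")),
            dofs = ad)
}

#' Central finite-difference gradient (validation oracle)
#'
#' @param conf a `symmetric_conformation`.
#' @param ef a `symm_energy`.
#' @param step finite-difference step (Angstrom / degrees).
#' @return Named numeric vector matching [dof_gradient()].
#' @export
numeric_dof_gradient <- function(conf, ef, step = 1e-5) {
  ad <- allowed_dofs(conf$sd)
  v0 <- dof_vector(conf)
  g <- numeric(length(v0))
  for (i in seq_along(v0)) {
    vp <- v0; vp[i] <- v0[i] + step
    vm <- v0; vm[i] <- v0[i] - step
    g[i] <- (score(set_dof_vector(conf, vp), ef)$total -
               score(set_dof_vector(conf, vm), ef)$total) / (2 * step)
  }
  stats::setNames(g, names(v0))
}

#' Compare analytic and numeric derivatives
#'
#' The user-facing derivative check: analytic partials versus central finite
#' differences for every allowed dof.
#'
#' @inheritParams numeric_dof_gradient
#' @param use_corrected route tether terms through [corrected_gradient()].
#' @return data.frame with columns `dof`, `analytic`, `numeric`,
#'   `abs_error`, `rel_error`.
#' @export
check_derivatives <- function(conf, ef, step = 1e-5, use_corrected = FALSE) {
  ga <- if (use_corrected) corrected_gradient(conf, ef)$partials else
    dof_gradient(conf, ef)
  gn <- numeric_dof_gradient(conf, ef, step)
  denom <- pmax(abs(gn), 1e-6)
  data.frame(dof = names(gn), analytic = as.numeric(ga),
             numeric = as.numeric(gn),
             abs_error = abs(as.numeric(ga) - as.numeric(gn)),
             rel_error = abs(as.numeric(ga) - as.numeric(gn)) / denom,
             stringsAsFactors = FALSE)
}

## ---- lattice cloned-jump decomposition -------------------------------------

# number of cloned jumps of `group` on the tree path between two frames
clone_span <- function(sd, frame_a, frame_b, group) {
  J <- sd$jumps
  grp <- jump_groups(sd)
  parent <- stats::setNames(J$start[J$stop != "SUBUNIT"], J$stop[J$stop != "SUBUNIT"])
  path_up <- function(f) {
    out <- character()
    while (f %in% names(parent)) {
      out <- c(out, f)
      f <- parent[[f]]
    }
    c(out, f)
  }
  pa <- path_up(frame_a); pb <- path_up(frame_b)
  common <- intersect(pa, pb)[1]
  seg <- c(setdiff(pa, pa[seq(match(common, pa), length(pa))]),
           setdiff(pb, pb[seq(match(common, pb), length(pb))]))
  sum(vapply(seg, function(f) {
    ji <- which(J$stop == f)
    length(ji) == 1 && grp[ji] == group
  }, logical(1)))
}

#' Cloned-jump decomposition of a lattice gradient
#'
#' The per-interface view of a lattice (e.g. helical rise) derivative:
#' derivatives computed at an interface spanning `m` copies of a cloned jump
#' are scaled by the traversed clone's stored weight (`m`) before being
#' remapped onto the master jump — equivalently, divided equally among the
#' `m` traversed clones, which telescopes to the factor `m`. The summed
#' contributions reproduce the corresponding [dof_gradient()] entries
#' exactly; interfaces on the upstream side carry energy-line weight 0, so
#' rise gradients are accumulated in one direction only.
#'
#' @param conf a lattice `symmetric_conformation`.
#' @param ef a `symm_energy`.
#' @param group clone group of the lattice jump (default the group of the
#'   first jump with a `z` dof, i.e. the rise group).
#' @return data.frame: one row per (interface chain, dof) with the clone
#'   span, stored clone weight, and scaled contribution; attribute `total`
#'   holds the per-dof sums.
#' @export
cloned_jump_chain <- function(conf, ef, group = NULL) {
  sd <- conf$sd
  ad <- allowed_dofs(sd)
  if (is.null(group)) {
    zrows <- which(ad$dof %in% c("z", "angle_z") &
                     ad$group != conf$subunits$group[conf$master_index])
    if (length(zrows) == 0) stop("no lattice translation group found")
    group <- ad$group[zrows[1]]
  }
  ad <- ad[ad$group == group, , drop = FALSE]
  if (nrow(ad) == 0) stop("group '", group, "' has no allowed dofs")
  sdv <- subunit_derivs(conf, ad)
  q <- coords(conf$q)
  P <- lapply(sdv$A, function(Ak) tf_apply(Ak, q))
  D <- lapply(seq_along(sdv$A), function(k)
    lapply(sdv$dA[[k]], function(dT) deriv_apply(dT, q)))
  names(D) <- names(sdv$A)
  mchain <- conf$subunits$chain[conf$master_index]
  mframe <- conf$subunits$frame[conf$master_index]
  wtab <- interface_weights(sd)
  frame_of_chain <- stats::setNames(conf$subunits$frame, conf$subunits$chain)
  J <- sd$jumps; grp_all <- jump_groups(sd)
  pm <- P[[mchain]]

  rows <- list()
  totals <- stats::setNames(numeric(nrow(ad)),
                            paste(ad$group, ad$dof, sep = ":"))
  for (ch in setdiff(conf$subunits$chain, mchain)) {
    fr <- conf$subunits$frame[match(ch, conf$subunits$chain)]
    span <- clone_span(sd, mframe, fr, group)
    # stored weight of the clone entering this subunit's frame
    ji <- which(J$stop == fr & grp_all == group)
    stored_w <- if (length(ji) == 1) J$clone_weight[ji] else NA_real_
    w <- unname(wtab[frame_of_chain[[ch]]])
    contrib <- numeric(nrow(ad))
    if (!is.na(w) && w > 0) {
      pb <- P[[ch]]
      dx <- outer(pm[, 1], pb[, 1], "-")
      dy <- outer(pm[, 2], pb[, 2], "-")
      dz <- outer(pm[, 3], pb[, 3], "-")
      r <- sqrt(pmax(dx^2 + dy^2 + dz^2, 1e-12))
      coef <- pair_potential_deriv(as.vector(r), ef) / as.vector(r)
      dim(coef) <- dim(r)
      for (di in seq_len(nrow(ad))) {
        da <- D[[mchain]][[di]]
        db <- D[[ch]][[di]]
        ddx <- outer(da[, 1], db[, 1], "-")
        ddy <- outer(da[, 2], db[, 2], "-")
        ddz <- outer(da[, 3], db[, 3], "-")
        contrib[di] <- contrib[di] +
          w * sum(coef * (dx * ddx + dy * ddy + dz * ddz))
      }
    }
    for (di in seq_len(nrow(ad))) {
      rows[[length(rows) + 1]] <- data.frame(
        chain = ch, dof = paste(ad$group[di], ad$dof[di], sep = ":"),
        clone_span = span, clone_weight = stored_w,
        contribution = contrib[di], stringsAsFactors = FALSE)
      totals[di] <- totals[di] + contrib[di]
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "total") <- totals
  out
}

#' Analytic derivative of an anchor-anchor distance along a lattice dof
#'
#' For a helical system, the exact rate of change of the distance between
#' two subunits' anchor atoms with respect to a cloned lattice dof (e.g. the
#' rise): an interface two rise-steps from the master moves at twice the
#' rate of an adjacent one.
#'
#' @param conf a `symmetric_conformation`.
#' @param chain_a,chain_b explicit subunit chain ids.
#' @param jump any jump of the lattice clone group.
#' @param dof dof component (default `"z"`, the rise).
#' @return The derivative in Angstrom per Angstrom (or per degree).
#' @export
lattice_distance_derivative <- function(conf, chain_a, chain_b, jump, dof = "z") {
  g <- jump_group_of(conf$sd, jump)
  ad <- data.frame(group = g, jump = jump, dof = dof, lo = -Inf, hi = Inf,
                   stringsAsFactors = FALSE)
  sdv <- subunit_derivs(conf, ad)
  anchor_row <- which(conf$q$resno == conf$anchor_resno & conf$q$atom == "CA")
  qa <- coords(conf$q)[anchor_row, , drop = FALSE]
  pa <- tf_apply(sdv$A[[chain_a]], qa)[1, ]
  pb <- tf_apply(sdv$A[[chain_b]], qa)[1, ]
  da <- deriv_apply(sdv$dA[[chain_a]][[1]], qa)[1, ]
  db <- deriv_apply(sdv$dA[[chain_b]][[1]], qa)[1, ]
  sum((pa - pb) * (da - db)) / vnorm(pa - pb)
}

## ---- asymmetric whole-structure corrections (Fig-7 machinery) --------------

#' Rotation-corrected gradients for asymmetric whole-structure energies
#'
#' When a whole-structure energy applies differently to each subunit (a
#' coordinate tether to fixed global targets, experimental-density-like
#' terms), slave-atom gradients can no longer be treated as symmetric
#' copies. This routine implements the correction machinery: per-atom
#' Cartesian gradients are computed over the full explicit complex; for the
#' sub-hierarchy (clone-group) jumps each slave subunit's gradients are
#' rotated into the master frame and accumulated; for the whole-system root
#' jump the *unrotated* gradients are used, and the per-virtual correction
#' (subtract the rotated, add the unrotated accumulations) is recorded in a
#' correction ledger applied at the root virtual. Pairwise (symmetric)
#' terms are routed through [dof_gradient()] unchanged. The ledger is empty
#' whenever no tether term is active.
#'
#' @param conf a `symmetric_conformation` whose SDF declares a root frame
#'   when root-jump dofs are allowed (error otherwise).
#' @param ef a `symm_energy` with tether terms.
#' @return List with `partials` (named vector as [dof_gradient()]) and
#'   `ledger` (per-virtual correction force/torque pairs).
#' @export
corrected_gradient <- function(conf, ef) {
  ad <- allowed_dofs(conf$sd)
  ef_pair <- ef; ef_pair$tethers <- NULL
  base <- dof_gradient(conf, ef_pair)

  te <- ef$tethers
  ledger <- list()
  if (is.null(te) || nrow(te) == 0)
    return(list(partials = base, ledger = ledger))

  sd <- conf$sd
  G <- frame_placements(conf)
  A <- subunit_placements(conf, G)
  q <- coords(conf$q)
  P <- lapply(A, function(Ak) tf_apply(Ak, q))
  mchain <- conf$subunits$chain[conf$master_index]

  # per-atom tether gradients, collected per subunit: f1 = sum g,
  # tau = sum p x g (the f1/f2 pair of the gradient recurrence)
  f1 <- lapply(P, function(x) c(0, 0, 0))
  tau <- lapply(P, function(x) c(0, 0, 0))
  for (i in seq_len(nrow(te))) {
    ch <- te$chain[i]
    if (!ch %in% names(P)) next
    row <- which(conf$q$resno == te$resno[i] & conf$q$atom == te$atom[i])
    if (length(row) == 0) next
    p <- P[[ch]][row, ]
    g <- 2 * te$k[i] * (p - c(te$tx[i], te$ty[i], te$tz[i]))
    f1[[ch]] <- f1[[ch]] + g
    tau[[ch]] <- tau[[ch]] + cross3(p, g)
  }

  grad_te <- numeric(nrow(ad))
  J <- sd$jumps
  root_groups <- unique(jump_groups(sd)[J$start == "ROOT"])
  attach_groups <- unique(conf$subunits$group)
  for (di in seq_len(nrow(ad))) {
    g_ <- ad$group[di]; dnm <- ad$dof[di]
    if (g_ %in% attach_groups) {
      # sub-hierarchy jump: rotate each slave's gradient into its own frame
      # (identical to the master's local view by symmetry) and accumulate
      acc <- 0
      for (k in seq_len(nrow(conf$subunits))) {
        ch <- conf$subunits$chain[k]
        if (conf$subunits$group[k] != g_) next
        v <- conf$jump_values[[g_]]
        Gf <- G[[conf$subunits$frame[k]]]
        B <- Gf[1:3, 1:3]
        if (dnm %in% c("x", "y", "z")) {
          e_c <- switch(dnm, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
          acc <- acc + sum((t(B) %*% f1[[ch]]) * e_c)
        } else {
          R <- rot_z(v[6]) %*% rot_y(v[5]) %*% rot_x(v[4])
          axis_local <- switch(dnm,
            angle_x = R %*% c(1, 0, 0),
            angle_y = R %*% (t(rot_x(v[4])) %*% c(0, 1, 0)),
            angle_z = R %*% (t(rot_x(v[4])) %*% t(rot_y(v[5])) %*% c(0, 0, 1)))
          u <- as.vector(B %*% axis_local)
          p0 <- as.vector(B %*% v[1:3] + Gf[1:3, 4])
          acc <- acc + sum(u * (tau[[ch]] - cross3(p0, f1[[ch]]))) * pi / 180
        }
      }
      grad_te[di] <- acc
    } else if (g_ %in% root_groups) {
      # whole-system jump: the slave gradients must NOT be rotated; record
      # the correction (- rotated + unrotated) at the root virtual
      jroot <- which(jump_groups(sd) == g_ & J$start == "ROOT")[1]
      fr <- J$stop[jroot]
      Gf <- G[[fr]]
      B <- Gf[1:3, 1:3]
      v <- conf$jump_values[[g_]]
      f1_tot <- Reduce(`+`, f1)
      tau_tot <- Reduce(`+`, tau)
      if (dnm %in% c("x", "y", "z")) {
        e_c <- switch(dnm, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
        grad_te[di] <- sum((t(B) %*% f1_tot) * e_c)
      } else {
        R <- rot_z(v[6]) %*% rot_y(v[5]) %*% rot_x(v[4])
        axis_local <- switch(dnm,
          angle_x = R %*% c(1, 0, 0),
          angle_y = R %*% (t(rot_x(v[4])) %*% c(0, 1, 0)),
          angle_z = R %*% (t(rot_x(v[4])) %*% t(rot_y(v[5])) %*% c(0, 0, 1)))
        u <- as.vector(B %*% axis_local)
        p0 <- as.vector(B %*% v[1:3] + Gf[1:3, 4])
        grad_te[di] <- sum(u * (tau_tot - cross3(p0, f1_tot))) * pi / 180
      }
      # ledger: what the naive rotated accumulation would have added at this
      # virtual, versus the unrotated truth
      Am <- A[[mchain]]
      rot_acc <- c(0, 0, 0)
      for (k in seq_len(nrow(conf$subunits))) {
        ch <- conf$subunits$chain[k]
        if (ch == mchain) next
        Rk <- (Am %*% tf_inverse(A[[ch]]))[1:3, 1:3]  # slave -> master
        rot_acc <- rot_acc + as.vector(Rk %*% f1[[ch]])
      }
      unrot_acc <- Reduce(`+`, f1[setdiff(names(f1), mchain)],
                          accumulate = FALSE) %||% c(0, 0, 0)
      ledger[[fr]] <- list(subtract_rotated = rot_acc,
                           add_unrotated = unrot_acc,
                           correction = unrot_acc - rot_acc)
    } else {
      stop("corrected_gradient supports attachment-group and root-jump dofs; ",
           "dof group '", g_, "' is neither (declare a root frame for ",
           "whole-system movement)")
    }
  }
  partials <- base + grad_te
  list(partials = stats::setNames(partials, names(base)), ledger = ledger)
}

## ---- minimization ----------------------------------------------------------

#' Minimize the symmetric score over the allowed degrees of freedom
#'
#' Limited-memory quasi-Newton descent (L-BFGS-B through [stats::optim()])
#' over the allowed rigid-body dof vector, using the analytic
#' [dof_gradient()]; dof ranges that are not full circles become box
#' constraints. Terminates on the projected-gradient tolerance or the
#' iteration cap; the returned conformation never scores worse than the
#' input.
#'
#' @param conf a `symmetric_conformation` with at least one allowed dof.
#' @param ef a `symm_energy`.
#' @param tol convergence tolerance on the projected gradient
#'   (energy units per Angstrom / per degree).
#' @param maxit iteration cap.
#' @return List with `conf` (minimized), `initial_score`, `final_score`,
#'   `trajectory` (data.frame of evaluated dof vectors and scores) and
#'   `convergence` (the optimizer's code).
#' @export
minimize <- function(conf, ef, tol = 1e-4, maxit = 200) {
  ad <- allowed_dofs(conf$sd)
  if (nrow(ad) == 0) stop("no allowed degrees of freedom to minimize")
  v0 <- dof_vector(conf)
  s0 <- score(conf, ef)$total
  if (!is.finite(s0)) stop("non-finite energy at the start of minimization")
  traj <- new.env(parent = emptyenv())
  traj$rows <- list()
  fn <- function(v) {
    s <- score(set_dof_vector(conf, v), ef)$total
    traj$rows[[length(traj$rows) + 1]] <- c(v, score = s)
    s
  }
  gr <- function(v) as.numeric(dof_gradient(set_dof_vector(conf, v), ef))
  lower <- ifelse(is.finite(ad$lo), ad$lo, -Inf)
  upper <- ifelse(is.finite(ad$hi), ad$hi, Inf)
  res <- stats::optim(v0, fn, gr, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = maxit, pgtol = tol,
                                     factr = 1e4))
  best <- if (res$value <= s0) res$par else v0
  out_conf <- set_dof_vector(conf, best)
  trajectory <- do.call(rbind, traj$rows)
  list(conf = out_conf, initial_score = s0,
       final_score = min(res$value, s0),
       trajectory = as.data.frame(trajectory),
       convergence = res$convergence)
}
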