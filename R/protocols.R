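# Symmetric assembly protocols: slide moves, rigid-body Monte Carlo docking,
# the symmetric RMSD metric, and a reduced pack+minimize relax loop.

## ---- slide moves -----------------------------------------------------------

# minimum atom-atom distance between the master subunit and any other
# explicit subunit
min_intersubunit_distance <- function(conf) {
  P <- conf_atom_coords(conf)
  mchain <- conf$subunits$chain[conf$master_index]
  pm <- P[[mchain]]
  po <- do.call(rbind, P[setdiff(names(P), mchain)])
  if (is.null(po) || nrow(po) == 0) return(Inf)
  d2 <- outer(rowSums(pm^2), rowSums(po^2), "+") - 2 * pm %*% t(po)
  sqrt(max(0, min(d2)))
}

#' Slide subunits into contact
#'
#' Steps each symmetrically allowed translational dof toward the origin
#' until the slide criterion fires, then backs off one step. With the
#' `CONTACT` criterion (default) the slide stops when any inter-subunit
#' atom pair comes closer than `criteria_val` (default 4.5 Angstrom); with
#' `SCORE` it stops at the step of lowest symmetric score along the ray.
#' For systems with several translational dofs (D groups: ring radius and
#' stack separation) the dofs are slid in declaration order
#' (`SEQUENTIAL`/`ORDERED`) or in seeded random order (`RANDOM`), so
#' contact is established in every slide direction.
#'
#' @param conf a `symmetric_conformation` with >= 1 translational dof.
#' @param ef a `symm_energy` (used by the SCORE criterion).
#' @param step slide step, Angstrom.
#' @param policy optional list overriding the SDF's slide options:
#'   `slide_type`, `criteria_type`, `criteria_val`.
#' @return The updated conformation.
#' @export
slide_into_contact <- function(conf, ef = energy_function(), step = 0.5,
                               policy = NULL) {
  sl <- policy %||% conf$sd$slide %||% list()
  slide_type <- sl$slide_type %||% "SEQUENTIAL"
  crit_type <- sl$criteria_type %||% "CONTACT"
  crit_val <- sl$criteria_val %||% 4.5
  if (crit_type == "CONTACT" && crit_val <= 0)
    stop("CONTACT criteria_val must be positive")
  ad <- allowed_dofs(conf$sd)
  tr <- ad[ad$dof %in% c("x", "y", "z"), , drop = FALSE]
  if (nrow(tr) == 0) stop("no translational dof allowed; cannot slide")
  ord <- seq_len(nrow(tr))
  if (slide_type == "RANDOM") ord <- sample(ord)
  for (i in ord) {
    g <- tr$group[i]; dnm <- tr$dof[i]
    v <- conf$jump_values[[g]][[dnm]]
    dir <- if (v >= 0) -1 else 1
    if (crit_type == "CONTACT") {
      if (min_intersubunit_distance(conf) < crit_val) next
      for (it in seq_len(1000)) {
        v2 <- v + dir * step
        conf$jump_values[[g]][[dnm]] <- v2
        if (min_intersubunit_distance(conf) < crit_val) {
          conf$jump_values[[g]][[dnm]] <- v2 - dir * step
          break
        }
        v <- v2
        if (abs(v) < step) break
      }
    } else {
      best_v <- v; best_s <- score(conf, ef)$total
      for (it in seq_len(1000)) {
        v2 <- v + dir * step
        conf$jump_values[[g]][[dnm]] <- v2
        s2 <- score(conf, ef)$total
        if (s2 < best_s) { best_s <- s2; best_v <- v2 }
        if (s2 > best_s + abs(crit_val)) break
        v <- v2
        if (abs(v) < step) break
      }
      conf$jump_values[[g]][[dnm]] <- best_v
    }
  }
  conf
}

## ---- low-resolution score --------------------------------------------------

# residue-centroid (Calpha) contact score: reward for master-slave centroid
# pairs in the 8-12 A band, quadratic clash penalty below 4 A
lowres_score <- function(conf) {
  P <- conf_ca_coords(conf)
  mchain <- conf$subunits$chain[conf$master_index]
  pm <- P[[mchain]]
  tot <- 0
  for (ch in setdiff(names(P), mchain)) {
    po <- P[[ch]]
    d2 <- outer(rowSums(pm^2), rowSums(po^2), "+") - 2 * pm %*% t(po)
    d <- sqrt(pmax(d2, 0))
    clash <- d < 4
    tot <- tot + 5 * sum((4 - d[clash])^2)
    contact <- pmin(1, pmax(0, (12 - d) / 4))
    tot <- tot - sum(contact[!clash])
  }
  tot
}

## ---- symmetric RMSD --------------------------------------------------------

#' Symmetric root-mean-square deviation
#'
#' Minimum Calpha RMSD between two equal-chain-count assemblies over all
#' chain relabelings consistent with the symmetry group (cyclic rotations
#' plus reversed ring order for Cn; the full dihedral permutations for Dn),
#' each candidate relabeling with its own optimal rigid superposition.
#' Always <= the fixed-order RMSD, since the identity relabeling is in the
#' candidate set.
#'
#' @param model,reference multichain `symm_structure`s with matching chain
#'   counts and per-chain residue counts.
#' @param group `"cn"` or `"dn"` (default `cn`).
#' @return RMSD in Angstrom.
#' @export
symmetric_rmsd <- function(model, reference, group = c("cn", "dn")) {
  group <- match.arg(group)
  chm <- structure_chains(model)
  chr <- structure_chains(reference)
  if (length(chm) != length(chr))
    stop("model and reference have different chain counts")
  n <- length(chm)
  cam <- lapply(chm, function(ch) ca_coords(model, ch))
  car <- lapply(chr, function(ch) ca_coords(reference, ch))
  if (any(vapply(cam, nrow, 0L) != vapply(car, nrow, 0L)))
    stop("per-chain residue counts differ")
  perms <- if (group == "cn") {
    shifts <- lapply(seq_len(n) - 1, function(k) ((seq_len(n) - 1 + k) %% n) + 1)
    c(shifts, lapply(shifts, rev))
  } else {
    point_group_permutations("dn", n)
  }
  ref_all <- do.call(rbind, car)
  best <- Inf
  for (p in unique(perms)) {
    mod_all <- do.call(rbind, cam[p])
    best <- min(best, kabsch(mod_all, ref_all)$rmsd)
  }
  best
}

## ---- relax-lite ------------------------------------------------------------

#' Reduced all-atom refinement: alternating pack and minimize
#'
#' @param conf a `symmetric_conformation`.
#' @param ef a `symm_energy`.
#' @param cycles number of pack+minimize cycles (>= 1).
#' @param seed packing seed.
#' @return The refined conformation with attribute `scores` (per-cycle
#'   totals, non-increasing).
#' @export
relax_lite <- function(conf, ef, cycles = 2, seed = 1) {
  stopifnot(cycles >= 1)
  scores <- score(conf, ef)$total
  for (cy in seq_len(cycles)) {
    if (any(conf$q$atom == "CG"))
      conf <- pack(conf, ef, seed = seed + cy)
    if (nrow(allowed_dofs(conf$sd)) > 0)
      conf <- minimize(conf, ef)$conf
    scores <- c(scores, score(conf, ef)$total)
  }
  attr(conf, "scores") <- scores
  conf
}

## ---- docking ---------------------------------------------------------------

#' Symmetric rigid-body docking
#'
#' Predicts the assembly of a symmetric complex from a single subunit and an
#' SDF. Per model: `n_starts` independent trajectories of (uniformly random
#' starting orientation, slide into contact, rigid-body Metropolis Monte
#' Carlo over all allowed dofs under the residue-centroid low-resolution
#' score, symmetric minimization), of which the best-scoring survives into
#' all-atom refinement — Monte-Carlo-minimization cycles of rigid-body
#' perturbation, symmetric packing (where side chains exist) and symmetric
#' minimization, Metropolis-accepted on the all-atom score. Deterministic
#' for a given seed.
#'
#' @param subunit master subunit (`symm_structure`, one chain).
#' @param sd a `symmetry_definition` (de novo generator output or
#'   equivalent, with randomizable rotational ranges).
#' @param n_models number of models.
#' @param seeds integer vector of seeds (recycled to `n_models`).
#' @param ef a `symm_energy` for the all-atom stages.
#' @param n_starts independent low-resolution starts per model.
#' @param mc_moves low-resolution Monte Carlo moves per start.
#' @param mc_temp Metropolis temperature of the low-resolution phase,
#'   energy units.
#' @param refine_cycles all-atom Monte-Carlo-minimization cycles.
#' @param perturb rigid-body perturbation magnitudes of the refinement
#'   cycles, `c(translation A, rotation degrees)`.
#' @return List of dock results: each has `conf`, `lowres_score`,
#'   `allatom_score`, `accepted` (move acceptance count), `seed`.
#' @export
symmetric_dock <- function(subunit, sd, n_models = 1,
                           seeds = seq_len(n_models), ef = energy_function(),
                           n_starts = 3, mc_moves = 100, mc_temp = 2.0,
                           refine_cycles = 10, perturb = c(2, 25)) {
  if (n_models == 0) return(list())
  seeds <- rep_len(seeds, n_models)
  ad <- allowed_dofs(sd)
  angs <- ad[grepl("angle", ad$dof), , drop = FALSE]
  full_random <- nrow(angs) >= 3 &&
    all(vapply(seq_len(nrow(angs)), function(i) {
      d <- group_dofs(sd, angs$group[i])
      r <- d$range[[angs$dof[i]]]
      !is.null(r) && abs((r[2] - r[1]) - 360) < 1e-9
    }, logical(1)))
  if (!full_random)
    warning("SDF lacks full rotational randomization ranges; ",
            "starts will be only partially randomized")
  out <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    set.seed(seeds[m])
    base <- build_conformation(sd, subunit)
    mjump <- base$subunits$jump[base$master_index]
    packable <- any(base$q$atom == "CG")
    accepted <- 0L
    best_lr <- NA_real_
    conf <- NULL; conf_s <- Inf
    for (st in seq_len(n_starts)) {
      cand <- random_orientation(base, mjump)
      cand <- slide_into_contact(cand, ef)
      cur <- lowres_score(cand)
      for (it in seq_len(mc_moves)) {
        i <- sample.int(nrow(ad), 1)
        delta <- if (ad$dof[i] %in% c("x", "y", "z"))
          stats::rnorm(1, 0, 0.7) else stats::rnorm(1, 0, 3)
        prop <- cand
        g <- ad$group[i]; dnm <- ad$dof[i]
        prop$jump_values[[g]][[dnm]] <- prop$jump_values[[g]][[dnm]] + delta
        if (min_intersubunit_distance(prop) > 8)
          prop <- slide_into_contact(prop, ef)
        s <- lowres_score(prop)
        if (s <= cur || stats::runif(1) < exp(-(s - cur) / mc_temp)) {
          cand <- prop; cur <- s; accepted <- accepted + 1L
        }
      }
      cand <- minimize(cand, ef)$conf
      s_aa <- score(cand, ef)$total
      if (s_aa < conf_s) { conf <- cand; conf_s <- s_aa; best_lr <- cur }
    }
    # all-atom Monte-Carlo minimization: rigid perturbation + pack +
    # minimize, accepted by Metropolis on the all-atom score
    if (packable) {
      conf <- pack(conf, ef, seed = seeds[m])
      conf <- minimize(conf, ef)$conf
      conf_s <- score(conf, ef)$total
    }
    best_aa <- conf; best_s <- conf_s
    cur_aa <- conf_s
    for (cy in seq_len(refine_cycles)) {
      prop <- conf
      for (i in seq_len(nrow(ad))) {
        delta <- if (ad$dof[i] %in% c("x", "y", "z"))
          stats::rnorm(1, 0, perturb[1]) else stats::rnorm(1, 0, perturb[2])
        g <- ad$group[i]; dnm <- ad$dof[i]
        prop$jump_values[[g]][[dnm]] <- prop$jump_values[[g]][[dnm]] + delta
      }
      if (min_intersubunit_distance(prop) > 8)
        prop <- slide_into_contact(prop, ef)
      if (packable) prop <- pack(prop, ef, seed = seeds[m] + cy)
      prop <- minimize(prop, ef)$conf
      s_aa <- score(prop, ef)$total
      if (s_aa <= cur_aa || stats::runif(1) < exp(-(s_aa - cur_aa) / 1.0)) {
        conf <- prop; cur_aa <- s_aa
        if (s_aa < best_s) { best_s <- s_aa; best_aa <- prop }
      }
    }
    conf <- best_aa
    out[[m]] <- list(conf = conf, lowres_score = best_lr,
                     allatom_score = best_s,
                     accepted = accepted, seed = seeds[m])
  }
  out
}
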