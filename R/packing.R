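# Symmetric discrete side-chain optimization (the packer).
#
# One state s_i per master position stands for the whole collection of its
# symmetric rotamer copies s_i^k = T_k(s_i^c). With w_c the intra-subunit
# weight and w_k the master/subunit-k interface weight from the energy line,
#
#   node(s_i) = w_c * [eps1(s_i^c) + eps2(s_i^c, bg_c)]
#             + sum_k w_k * [eps2(s_i^c, bg_k) + eps2(s_i^k, bg_c)]
#             + sum_k w_k * eps2(s_i^c, s_i^k)        (rotamer vs own clones)
#
#   edge(s_i, s_j) = w_c * eps2(s_i^c, s_j^c)
#                  + sum_k w_k * [eps2(s_i^c, s_j^k) + eps2(s_j^c, s_i^k)]
#
# where bg_k are the background (non-packable) residues of subunit k. When
# w_k = 0 every subunit-k term is skipped. With these energies the standard
# interaction-graph + stochastic-annealing machinery of asymmetric packing
# applies unchanged, and the total of any assignment equals the plain
# asymmetric packer energy of the replicated assignment on the expanded
# complex (the oracle identity tested per assignment).

CHI_LIBRARY <- c(-60, 60, 180)   # canonical chi1 bins

#' Build symmetric rotamer sets
#'
#' Enumerates discrete side-chain states at the requested master positions:
#' the canonical chi1 bins plus the input conformation's own chi1 (so the
#' input state is always available; a duplicate of a library bin is
#' dropped). Positions without a rotatable side
#' chain (no CG atom) get a single-state set. Each state stores the master
#' side-chain coordinates; clones on the other subunits are generated by the
#' subunit transforms, exactly.
#'
#' @param conf a `symmetric_conformation`.
#' @param positions master residue numbers to make packable.
#' @return List of rotamer sets: `list(resno, chis, coords)` where `coords`
#'   is a list (one per state) of the master-local side-chain atom coordinate
#'   matrix (rows CB, CG as available).
#' @export
build_rotamers <- function(conf, positions) {
  q <- conf$q
  out <- list()
  for (rn in positions) {
    rows <- which(q$resno == rn)
    if (length(rows) == 0) stop("no residue ", rn, " in the master subunit")
    has_cg <- any(q$atom[rows] == "CG")
    if (!has_cg) {
      out[[length(out) + 1]] <- list(resno = rn, chis = NA_real_,
                                     coords = list(sidechain_coords(q, rn)))
      next
    }
    cur <- get_torsion(conf, rn, "chi1")
    chis <- c(CHI_LIBRARY, cur)
    # drop a duplicate input state (angles are circular)
    wrap <- function(a) ((a + 180) %% 360) - 180
    dup <- duplicated(round(wrap(chis), 6))
    chis <- chis[!dup]
    coords_list <- lapply(chis, function(chi) {
      c2 <- set_torsion(conf, rn, "chi1", chi)
      sidechain_coords(c2$q, rn)
    })
    out[[length(out) + 1]] <- list(resno = rn, chis = chis,
                                   coords = coords_list)
  }
  out
}

# side-chain atom coordinates (the atoms a chi1 change can move) of one
# residue, in master-local coordinates
sidechain_coords <- function(q, rn) {
  rows <- which(q$resno == rn & q$atom %in% c("CB", "CG"))
  m <- coords(q)[rows, , drop = FALSE]
  rownames(m) <- q$atom[rows]
  m
}

# apply a rotamer state to master-local coordinates
apply_state <- function(q, rset, state) {
  m <- rset$coords[[state]]
  for (nm in rownames(m)) {
    i <- which(q$resno == rset$resno & q$atom == nm)
    q[i, c("x", "y", "z")] <- m[nm, , drop = FALSE]
  }
  q
}

#' Build the symmetric packer graph
#'
#' Precomputes node-energy vectors and edge-energy matrices for a set of
#' packable positions under the symmetric weighting scheme (see the module
#' notes). Edges are kept only where some clone pairing of the two
#' positions' atoms can fall within the interaction cutoff.
#'
#' @param conf a `symmetric_conformation`.
#' @param ef a `symm_energy`.
#' @param positions master residue numbers to pack.
#' @return An object of class `packer_graph`: nodes (with `E1` vectors),
#'   edges (with `E2` matrices), and the rotamer sets.
#' @export
build_packer_graph <- function(conf, ef, positions) {
  rsets <- build_rotamers(conf, positions)
  Tk <- subunit_transforms(conf)
  A <- subunit_placements(conf)
  w_c <- conf$sd$energy$intra$mult
  wtab <- interface_weights(conf$sd)
  frame_of_chain <- stats::setNames(conf$subunits$frame, conf$subunits$chain)
  mchain <- conf$subunits$chain[conf$master_index]
  w_k <- vapply(conf$subunits$chain, function(ch)
    if (ch == mchain) 0 else unname(wtab[frame_of_chain[[ch]]]), 0)
  names(w_k) <- conf$subunits$chain

  # background: all explicit atoms except side chains of packable positions
  q <- conf$q
  pack_res <- vapply(rsets, `[[`, 0, "resno")
  # per-subunit global coordinates of the background and of each state
  bg_mask <- !(q$resno %in% pack_res & q$atom %in% c("CB", "CG"))
  bgq <- coords(q)[bg_mask, , drop = FALSE]
  bg_resno <- q$resno[bg_mask]
  bg_global <- lapply(A, function(Ak) tf_apply(Ak, bgq))
  state_global <- lapply(rsets, function(rs)
    lapply(rs$coords, function(m) lapply(A, function(Ak) tf_apply(Ak, m))))

  pe <- function(pa, pb) {
    if (nrow(pa) == 0 || nrow(pb) == 0) return(0)
    d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
    sum(pair_potential(sqrt(pmax(as.vector(d2), 1e-12)), ef))
  }

  nodes <- list()
  for (i in seq_along(rsets)) {
    rs <- rsets[[i]]
    ns <- length(rs$coords)
    E1 <- numeric(ns)
    for (s in seq_len(ns)) {
      sc_m <- state_global[[i]][[s]][[mchain]]
      # intra: rotamer vs own-subunit background, excluding its own residue
      # and sequence neighbors (consistent with the scoring exclusions)
      own <- abs(bg_resno - rs$resno) >= 2
      e_intra <- pe(sc_m, bg_global[[mchain]][own, , drop = FALSE])
      e <- w_c * e_intra
      for (ch in names(w_k)) {
        if (w_k[[ch]] == 0) next
        e <- e + w_k[[ch]] *
          (pe(sc_m, bg_global[[ch]]) +
             pe(state_global[[i]][[s]][[ch]], bg_global[[mchain]]) +
             pe(sc_m, state_global[[i]][[s]][[ch]]))
      }
      E1[s] <- e
    }
    nodes[[i]] <- list(resno = rs$resno, E1 = E1)
  }

  edges <- list()
  if (length(rsets) >= 2) {
    for (i in seq_len(length(rsets) - 1)) for (j in (i + 1):length(rsets)) {
      ni <- length(rsets[[i]]$coords); nj <- length(rsets[[j]]$coords)
      M <- matrix(0, ni, nj)
      for (si in seq_len(ni)) for (sj in seq_len(nj)) {
        pi_m <- state_global[[i]][[si]][[mchain]]
        pj_m <- state_global[[j]][[sj]][[mchain]]
        e <- w_c * pe(pi_m, pj_m)
        for (ch in names(w_k)) {
          if (w_k[[ch]] == 0) next
          e <- e + w_k[[ch]] *
            (pe(pi_m, state_global[[j]][[sj]][[ch]]) +
               pe(pj_m, state_global[[i]][[si]][[ch]]))
        }
        M[si, sj] <- e
      }
      if (max(abs(M)) > 0)
        edges[[length(edges) + 1]] <- list(i = i, j = j, E2 = M)
    }
  }
  structure(list(nodes = nodes, edges = edges, rsets = rsets,
                 w_c = w_c, w_k = w_k),
            class = "packer_graph")
}

#' @export
print.packer_graph <- function(x, ...) {
  cat(sprintf("<packer_graph> %d node(s), %d edge(s), states: %s\n",
              length(x$nodes), length(x$edges),
              paste(vapply(x$nodes, function(n) length(n$E1), 0),
                    collapse = "x")))
  invisible(x)
}

#' Node energy of a state
#'
#' @param graph a `packer_graph`.
#' @param i node index.
#' @param s state index.
#' @return The symmetric node energy (see module notes).
#' @export
node_energy <- function(graph, i, s) graph$nodes[[i]]$E1[[s]]

#' Edge energy of a state pair
#'
#' Not generally symmetric in (s_i, s_j) — the matrix attributes all clone
#' pairings of the two positions to the one master edge — but the assignment
#' total is invariant to node ordering.
#'
#' @param graph a `packer_graph`.
#' @param i,j node indices (i < j as built).
#' @param si,sj state indices.
#' @return The symmetric edge energy.
#' @export
edge_energy <- function(graph, i, j, si, sj) {
  for (e in graph$edges) {
    if (e$i == i && e$j == j) return(e$E2[si, sj])
    if (e$i == j && e$j == i) return(e$E2[sj, si])
  }
  0
}

# total graph energy of an assignment (vector of state indices per node)
assignment_energy <- function(graph, assign) {
  tot <- 0
  for (i in seq_along(graph$nodes)) tot <- tot + graph$nodes[[i]]$E1[[assign[i]]]
  for (e in graph$edges) tot <- tot + e$E2[assign[e$i], assign[e$j]]
  tot
}

#' Simulated annealing on a packer graph
#'
#' Metropolis single-state substitutions under a geometric temperature
#' schedule (T from `t_hi` to `t_lo` over `steps_per_state` times the total
#' state count); returns the best assignment seen. Deterministic for a fixed
#' seed; ties between equal-energy states resolve to the lowest state index
#' via the strict-improvement bookkeeping.
#'
#' @param graph a `packer_graph`.
#' @param seed RNG seed.
#' @param t_hi,t_lo annealing temperature bounds, energy units.
#' @param steps_per_state Metropolis steps per rotamer state.
#' @return List with `assignment` (state index per node) and `energy`.
#' @export
anneal <- function(graph, seed = 1, t_hi = 100, t_lo = 0.3,
                   steps_per_state = 200) {
  nn <- length(graph$nodes)
  if (nn == 0) return(list(assignment = integer(), energy = 0))
  ns <- vapply(graph$nodes, function(n) length(n$E1), 0)
  set.seed(seed)
  cur <- vapply(ns, function(k) sample.int(k, 1), 0L)
  cur_e <- assignment_energy(graph, cur)
  best <- cur; best_e <- cur_e
  nsteps <- max(1L, as.integer(steps_per_state * sum(ns)))
  temps <- t_hi * (t_lo / t_hi)^(seq_len(nsteps) / nsteps)
  for (it in seq_len(nsteps)) {
    i <- sample.int(nn, 1)
    if (ns[i] < 2) next
    s_new <- sample.int(ns[i], 1)
    if (s_new == cur[i]) next
    prop <- cur; prop[i] <- s_new
    e_new <- assignment_energy(graph, prop)
    if (e_new <= cur_e ||
        stats::runif(1) < exp(-(e_new - cur_e) / temps[it])) {
      cur <- prop; cur_e <- e_new
      if (cur_e < best_e - 1e-12 ||
          (abs(cur_e - best_e) <= 1e-12 && any(cur < best))) {
        best <- cur; best_e <- cur_e
      }
    }
  }
  list(assignment = best, energy = best_e)
}

# exhaustive optimum (oracle for small graphs)
enumerate_optimum <- function(graph) {
  ns <- vapply(graph$nodes, function(n) length(n$E1), 0)
  grid <- do.call(expand.grid, lapply(ns, seq_len))
  es <- apply(grid, 1, function(a) assignment_energy(graph, as.integer(a)))
  i <- which.min(es)
  list(assignment = as.integer(grid[i, ]), energy = es[i])
}

#' Parse a residue-level packing task
#'
#' Three directives, one residue per line, applied to MASTER numbering only:
#' `NATRO` (fixed), `NATAA` (repack the native identity), `PIKAA` (repack;
#' identity design is outside this package's chemistry, so PIKAA behaves as
#' NATAA and is accepted for interface compatibility).
#'
#' @param lines character vector like `"5 NATAA"`; residues not listed
#'   default to `default` (NATRO).
#' @param default default directive.
#' @return Named character vector residue -> directive.
#' @export
parse_pack_task <- function(lines, default = "NATRO") {
  out <- character()
  for (ln in lines) {
    ln <- trimws(sub("#.*$", "", ln))
    if (ln == "") next
    toks <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(toks) < 2 || !toks[2] %in% c("NATRO", "NATAA", "PIKAA"))
      stop("malformed task line: '", ln, "'")
    out[[toks[1]]] <- toks[2]
  }
  attr(out, "default") <- default
  out
}

#' Symmetric side-chain optimization
#'
#' Builds the symmetric packer graph over the packable positions, anneals,
#' and applies the optimal assignment to the master subunit; slaves follow by
#' propagation, so all subunits end with identical chi angles. Because the
#' input conformation is always among the candidate states, the score never
#' increases.
#'
#' @param conf a `symmetric_conformation`.
#' @param ef a `symm_energy`.
#' @param positions master residues to pack; defaults to every residue with
#'   a rotatable side chain. Use master numbering — slave positions are not
#'   addressable (error).
#' @param task optional [parse_pack_task()] result restricting positions.
#' @param seed annealing seed.
#' @return The repacked conformation, with attributes `pack_energy` (graph
#'   energy of the chosen assignment) and `assignment`.
#' @export
pack <- function(conf, ef, positions = NULL, task = NULL, seed = 1) {
  q <- conf$q
  if (is.null(positions))
    positions <- unique(q$resno[q$atom == "CG"])
  if (!is.null(task)) {
    keep <- vapply(positions, function(rn) {
      d <- task[[as.character(rn)]]
      if (is.null(d)) d <- attr(task, "default")
      d %in% c("NATAA", "PIKAA")
    }, logical(1))
    positions <- positions[keep]
  }
  if (length(positions) == 0) return(conf)
  if (any(!positions %in% q$resno))
    stop("positions must use master-subunit numbering; unknown residue(s): ",
         paste(setdiff(positions, q$resno), collapse = ", "))
  graph <- build_packer_graph(conf, ef, positions)
  res <- anneal(graph, seed = seed)
  for (i in seq_along(graph$rsets)) {
    rs <- graph$rsets[[i]]
    if (length(rs$coords) < 2) next
    conf$q <- apply_state(conf$q, rs, res$assignment[i])
  }
  attr(conf, "pack_energy") <- res$energy
  attr(conf, "assignment") <- res$assignment
  conf
}

# asymmetric packer energy of a replicated assignment on an expanded complex:
# the oracle counterpart of assignment_energy (unit weights over all
# subunits). `confs` is the conformation; the assignment is replicated to
# every explicit subunit.
asym_packer_energy <- function(conf, ef, positions, assign) {
  graph0 <- build_packer_graph_asym(conf, ef, positions)
  tot <- 0
  nn <- length(positions)
  S <- nrow(conf$subunits)
  full_assign <- rep(assign, times = S)
  for (i in seq_along(graph0$nodes))
    tot <- tot + graph0$nodes[[i]]$E1[[full_assign[i]]]
  for (e in graph0$edges)
    tot <- tot + e$E2[full_assign[e$i], full_assign[e$j]]
  tot
}

# plain asymmetric interaction graph over ALL explicit subunits: every
# (subunit, position) is its own node with unit weights
build_packer_graph_asym <- function(conf, ef, positions) {
  rsets <- build_rotamers(conf, positions)
  A <- subunit_placements(conf)
  q <- conf$q
  pack_res <- vapply(rsets, `[[`, 0, "resno")
  bg_mask <- !(q$resno %in% pack_res & q$atom %in% c("CB", "CG"))
  bgq <- coords(q)[bg_mask, , drop = FALSE]
  bg_resno <- q$resno[bg_mask]
  bg_global <- lapply(A, function(Ak) tf_apply(Ak, bgq))
  chains <- names(A)

  pe <- function(pa, pb) {
    if (nrow(pa) == 0 || nrow(pb) == 0) return(0)
    d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
    sum(pair_potential(sqrt(pmax(as.vector(d2), 1e-12)), ef))
  }

  # nodes: subunit-major replication order matching asym_packer_energy
  nodes <- list(); node_meta <- list()
  for (ch in chains) for (i in seq_along(rsets)) {
    rs <- rsets[[i]]
    E1 <- numeric(length(rs$coords))
    for (s in seq_along(rs$coords)) {
      sc <- tf_apply(A[[ch]], rs$coords[[s]])
      e <- 0
      for (ch2 in chains) {
        mask <- if (ch2 == ch) abs(bg_resno - rs$resno) >= 2 else
          rep(TRUE, length(bg_resno))
        e <- e + pe(sc, bg_global[[ch2]][mask, , drop = FALSE])
      }
      E1[s] <- e
    }
    nodes[[length(nodes) + 1]] <- list(resno = rs$resno, E1 = E1)
    node_meta[[length(node_meta) + 1]] <- list(chain = ch, idx = i)
  }
  edges <- list()
  nn <- length(nodes)
  for (a in seq_len(nn - 1)) for (b in (a + 1):nn) {
    ma <- node_meta[[a]]; mb <- node_meta[[b]]
    ra <- rsets[[ma$idx]]; rb <- rsets[[mb$idx]]
    M <- matrix(0, length(ra$coords), length(rb$coords))
    for (si in seq_along(ra$coords)) for (sj in seq_along(rb$coords)) {
      pa <- tf_apply(A[[ma$chain]], ra$coords[[si]])
      pb <- tf_apply(A[[mb$chain]], rb$coords[[sj]])
      M[si, sj] <- pe(pa, pb)
    }
    if (max(abs(M)) > 0)
      edges[[length(edges) + 1]] <- list(i = a, j = b, E2 = M)
  }
  list(nodes = nodes, edges = edges)
}
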