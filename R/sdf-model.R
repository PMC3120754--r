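# Symmetry definition files (SDF): data model, parser, writer, validator.
#
# An SDF declares everything the rest of the package needs to build, score and
# perturb a symmetric system: the virtual coordinate frames, the jump tree
# connecting them, which rigid-body degrees of freedom may move, and the
# weighted energy expression that reconstructs the total system energy from
# the explicitly modeled subset of subunits.
#
# Dialect (one directive per line, '#' comments, blank lines ignored,
# directives case-sensitive):
#
#   symmetry_name NAME
#   total_subunits N
#   anchor COM | <residue number>
#   recenter
#   slide_type SEQUENTIAL|ORDERED|RANDOM
#   slide_criteria_type CONTACT|SCORE
#   slide_criteria_val <real>
#   E = 2*VRT0 + 1*(VRT0:VRT1) + ...
#   virtual_coordinates_start
#   xyz NAME <x-axis triple> <y-axis triple> <origin triple>
#   virtual_coordinates_stop
#   virtual_transforms_start
#   start <x-axis> <y-axis> <origin>
#   rot Rx|Ry|Rz <fold>
#   trans <dx,dy,dz>
#   virtual_transforms_stop
#   connect_virtual JUMPNAME START STOP     (START: ROOT or frame; STOP: frame
#                                            or SUBUNIT)
#   set_jump_group GROUP J1 J2=2 J3=3       (=w suffix: clone weight, default 1)
#   set_dof JUMP x(50) angle_x(0:360) y z(1.5)
#   full_system_frames VRT0 VRT1 ...        (frames standing for all N subunits
#                                            when only S < N are encoded)
#   lattice                                 (flag: helical/crystal system; the
#                                            E line is lattice-normalized and
#                                            full-expansion scoring oracles do
#                                            not apply)
#
# Angles are degrees in files and at all exported interfaces.

DOF_NAMES <- c("x", "y", "z", "angle_x", "angle_y", "angle_z")

## ---- domain types ----------------------------------------------------------

#' Create a virtual coordinate frame
#'
#' A virtual frame is a named right-handed coordinate system (a "virtual
#' residue" in the kinematic tree): an origin plus x and y unit axes; the z
#' axis is implied as their cross product. Axes within 1e-3 of orthonormal are
#' re-orthonormalized (Gram-Schmidt of y against x), which tolerates the
#' 7-decimal rounding of frames printed in definition files; worse axes are
#' rejected.
#'
#' @param name identifier.
#' @param origin length-3 numeric, Angstrom.
#' @param x_axis,y_axis length-3 numeric unit vectors.
#' @return An object of class `virtual_frame` with fields `name`, `origin`,
#'   `x_axis`, `y_axis`, `z_axis`.
#' @export
virtual_frame <- function(name, origin, x_axis, y_axis) {
  origin <- as.numeric(origin); x <- as.numeric(x_axis); y <- as.numeric(y_axis)
  stopifnot(length(origin) == 3, length(x) == 3, length(y) == 3)
  if (abs(vnorm(x) - 1) > 1e-3 || abs(vnorm(y) - 1) > 1e-3 ||
      abs(sum(x * y)) > 1e-3)
    stop("frame '", name, "': axes are not orthonormal within 1e-3")
  x <- unitize(x)
  y <- unitize(y - sum(y * x) * x)
  structure(list(name = name, origin = origin, x_axis = x, y_axis = y,
                 z_axis = cross3(x, y)),
            class = "virtual_frame")
}

# 3x3 basis matrix with columns x, y, z (local -> global rotation)
frame_basis <- function(f) cbind(f$x_axis, f$y_axis, f$z_axis)

# frame placement as a 4x4 transform (local coords -> global coords)
frame_tf <- function(f) tf_new(frame_basis(f), f$origin)

# build a frame from a 4x4 placement
frame_from_tf <- function(name, T) {
  R <- tf_rot(T)
  virtual_frame(name, tf_trans(T), R[, 1], R[, 2])
}

#' @export
print.virtual_frame <- function(x, ...) {
  cat(sprintf("<virtual_frame %s> origin (%s)\n", x$name,
              paste(sprintf("%.3f", x$origin), collapse = ", ")))
  invisible(x)
}

new_symmetry_definition <- function(name, frame_spec, jumps, dofs, energy,
                                    anchor = "COM", recenter = FALSE,
                                    total_subunits = NULL, slide = NULL,
                                    full_frames = NULL, lattice = FALSE) {
  sd <- structure(list(
    name = name, frame_spec = frame_spec, jumps = jumps, dofs = dofs,
    energy = energy, anchor = anchor, recenter = recenter,
    total_subunits = total_subunits, slide = slide, full_frames = full_frames,
    lattice = lattice),
    class = "symmetry_definition")
  if (is.null(sd$total_subunits))
    sd$total_subunits <- length(attachment_jumps(sd))
  sd$total_subunits <- as.integer(sd$total_subunits)
  sd
}

#' @export
print.symmetry_definition <- function(x, ...) {
  cat(sprintf("<symmetry_definition %s> N = %d total, S = %d encoded, %d frame(s), %d jump(s)\n",
              x$name, x$total_subunits, length(attachment_jumps(x)),
              length(resolve_frames(x)), nrow(x$jumps)))
  invisible(x)
}

# jumps whose stop is the subunit tag; their order defines subunit order
attachment_jumps <- function(sd) {
  which(sd$jumps$stop == "SUBUNIT")
}

# clone-group id of each jump (its own name when ungrouped)
jump_groups <- function(sd) {
  g <- sd$jumps$clone_group
  ifelse(is.na(g), sd$jumps$name, g)
}

# dof spec attached to a jump's clone group (set_dof may name any member)
group_dofs <- function(sd, group) {
  grp <- jump_groups(sd)
  members <- sd$jumps$name[grp == group]
  hits <- intersect(names(sd$dofs), members)
  if (length(hits) == 0) return(NULL)
  sd$dofs[[hits[[1]]]]
}

## ---- frame resolution ------------------------------------------------------

#' Resolve the virtual frames of a symmetry definition
#'
#' Returns the fully expanded, ordered list of [virtual_frame()]s. Explicit
#' `xyz` frames are returned as declared. A transform recipe is expanded by
#' applying its operations left to right: `rot Rz n` replaces each current
#' frame with `n` copies at 360/n-degree increments about the global z axis
#' (likewise `Rx`, `Ry`); `trans` shifts every current frame. Generated frames
#' are named `VRT0`, `VRT1`, ... in generation order.
#'
#' @param sd a `symmetry_definition`.
#' @return Named list of `virtual_frame` objects.
#' @export
resolve_frames <- function(sd) {
  fs <- sd$frame_spec
  if (fs$kind == "explicit") {
    out <- fs$frames
  } else {
    cur <- list(fs$start)
    for (op in fs$ops) {
      if (op$kind == "rot") {
        if (op$fold < 1) stop("rot fold must be >= 1")
        rotfun <- switch(op$axis, x = rot_x, y = rot_y, z = rot_z)
        nxt <- list()
        for (f in cur) {
          for (k in seq_len(op$fold) - 1) {
            R <- rotfun(360 * k / op$fold)
            nxt[[length(nxt) + 1]] <- frame_from_tf(
              "tmp", tf_new(R, c(0, 0, 0)) %*% frame_tf(f))
          }
        }
        cur <- nxt
      } else if (op$kind == "trans") {
        cur <- lapply(cur, function(f) {
          f$origin <- f$origin + op$vec
          f
        })
      } else stop("unknown transform op: ", op$kind)
    }
    for (i in seq_along(cur)) cur[[i]]$name <- paste0("VRT", i - 1)
    out <- cur
  }
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

## ---- parser ----------------------------------------------------------------

parse_triple <- function(tok, where) {
  v <- suppressWarnings(as.numeric(strsplit(tok, ",", fixed = TRUE)[[1]]))
  if (length(v) != 3 || anyNA(v))
    stop("expected a comma-separated numeric triple at ", where, ": '", tok, "'")
  v
}

parse_energy_line <- function(rhs, where) {
  terms <- strsplit(rhs, "+", fixed = TRUE)[[1]]
  intra <- NULL
  interfaces <- list()
  for (tm in trimws(terms)) {
    m <- regmatches(tm, regexec(
      "^([0-9.eE+-]+)\\*\\(([A-Za-z0-9_.-]+):([A-Za-z0-9_.-]+)\\)$", tm))[[1]]
    if (length(m) == 4) {
      interfaces[[length(interfaces) + 1]] <-
        list(a = m[3], b = m[4], mult = as.numeric(m[2]))
      next
    }
    m <- regmatches(tm, regexec("^([0-9.eE+-]+)\\*([A-Za-z0-9_.-]+)$", tm))[[1]]
    if (length(m) == 3) {
      if (!is.null(intra))
        stop("malformed E line at ", where, ": more than one intra term")
      intra <- list(frame = m[3], mult = as.numeric(m[2]))
      next
    }
    stop("malformed E line term at ", where, ": '", tm, "'")
  }
  if (is.null(intra)) stop("malformed E line at ", where, ": no intra term")
  list(intra = intra, interfaces = interfaces)
}

parse_dof_tokens <- function(toks, where) {
  allowed <- character()
  init <- numeric()
  range <- list()
  for (tok in toks) {
    m <- regmatches(tok, regexec("^(angle_[xyz]|[xyz])(\\(([^)]*)\\))?$", tok))[[1]]
    if (length(m) == 0 || m[2] == "")
      stop("malformed set_dof token at ", where, ": '", tok, "'")
    nm <- m[2]
    allowed <- union(allowed, nm)
    if (m[3] != "") {
      body <- m[4]
      if (grepl(":", body, fixed = TRUE)) {
        lohi <- suppressWarnings(as.numeric(strsplit(body, ":", fixed = TRUE)[[1]]))
        if (length(lohi) != 2 || anyNA(lohi))
          stop("malformed dof range at ", where, ": '", tok, "'")
        range[[nm]] <- lohi
      } else {
        v <- suppressWarnings(as.numeric(body))
        if (is.na(v)) stop("malformed dof init at ", where, ": '", tok, "'")
        init[[nm]] <- v
      }
    }
  }
  list(allowed = allowed, init = init, range = range)
}

#' Parse a symmetry definition file
#'
#' Accepts the textual SDF dialect documented in the package (both explicit
#' `xyz` frame blocks and implicit `virtual_transforms` recipes). Unknown
#' directives raise an error naming the offending line numbers.
#'
#' @param text an SDF document: a single string, a character vector of lines,
#'   or a file path (when `is_path = TRUE`).
#' @param is_path interpret `text` as a file path.
#' @return A validated `symmetry_definition`.
#' @seealso [write_sdf()], [validate_sdf()], [resolve_frames()]
#' @export
parse_sdf <- function(text, is_path = FALSE) {
  if (is_path) text <- readLines(text, warn = FALSE)
  if (length(text) == 1 && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(text) == 0 || all(trimws(text) == ""))
    stop("empty symmetry definition")

  name <- "unnamed"
  total_subunits <- NULL
  anchor <- "COM"
  recenter <- FALSE
  slide <- list()
  energy <- NULL
  frames <- list()
  frame_spec <- NULL
  jumps <- data.frame(name = character(), start = character(),
                      stop = character(), clone_group = character(),
                      clone_weight = numeric(), stringsAsFactors = FALSE)
  dofs <- list()
  full_frames <- NULL
  lattice <- FALSE
  mode <- "top"    # top | coords | transforms
  recipe <- NULL
  unknown <- character()

  for (i in seq_along(text)) {
    line <- sub("#.*$", "", text[[i]])
    line <- trimws(line)
    if (line == "") next
    where <- paste0("line ", i)
    toks <- strsplit(line, "[[:space:]]+")[[1]]
    key <- toks[[1]]

    if (mode == "coords") {
      if (key == "virtual_coordinates_stop") { mode <- "top"; next }
      if (key != "xyz" || length(toks) != 5)
        stop("expected 'xyz NAME x y origin' inside coordinate block at ", where)
      f <- virtual_frame(toks[2], parse_triple(toks[5], where),
                         parse_triple(toks[3], where),
                         parse_triple(toks[4], where))
      if (f$name %in% vapply(frames, `[[`, "", "name"))
        stop("duplicate frame '", f$name, "' at ", where)
      frames[[length(frames) + 1]] <- f
      next
    }
    if (mode == "transforms") {
      if (key == "virtual_transforms_stop") { mode <- "top"; next }
      if (key == "start") {
        if (length(toks) != 4) stop("malformed start line at ", where)
        recipe$start <- virtual_frame("VRTSTART",
                                      parse_triple(toks[4], where),
                                      parse_triple(toks[2], where),
                                      parse_triple(toks[3], where))
      } else if (key == "rot") {
        if (length(toks) != 3 || !toks[2] %in% c("Rx", "Ry", "Rz"))
          stop("malformed rot line at ", where)
        fold <- suppressWarnings(as.integer(toks[3]))
        if (is.na(fold) || fold < 1) stop("rot fold must be >= 1 at ", where)
        recipe$ops[[length(recipe$ops) + 1]] <-
          list(kind = "rot", axis = tolower(substr(toks[2], 2, 2)), fold = fold)
      } else if (key == "trans") {
        if (length(toks) != 2) stop("malformed trans line at ", where)
        recipe$ops[[length(recipe$ops) + 1]] <-
          list(kind = "trans", vec = parse_triple(toks[2], where))
      } else stop("unknown transform directive '", key, "' at ", where)
      next
    }

    switch(key,
      symmetry_name = { name <- toks[2] },
      total_subunits = { total_subunits <- as.integer(toks[2]) },
      anchor = {
        anchor <- if (toks[2] == "COM") "COM" else as.integer(toks[2])
      },
      recenter = { recenter <- TRUE },
      slide_type = { slide$slide_type <- toks[2] },
      slide_criteria_type = { slide$criteria_type <- toks[2] },
      slide_criteria_val = { slide$criteria_val <- as.numeric(toks[2]) },
      E = {
        rhs <- sub("^E[[:space:]]*=", "", line)
        energy <- parse_energy_line(rhs, where)
      },
      virtual_coordinates_start = { mode <- "coords" },
      virtual_transforms_start = {
        mode <- "transforms"
        recipe <- list(start = NULL, ops = list())
      },
      connect_virtual = {
        if (length(toks) != 4) stop("malformed connect_virtual at ", where)
        if (toks[2] %in% jumps$name)
          stop("duplicate jump name '", toks[2], "' at ", where)
        jumps <- rbind(jumps, data.frame(
          name = toks[2], start = toks[3], stop = toks[4],
          clone_group = NA_character_, clone_weight = 1,
          stringsAsFactors = FALSE))
      },
      set_jump_group = {
        if (length(toks) < 3) stop("malformed set_jump_group at ", where)
        grp <- toks[2]
        for (tok in toks[-(1:2)]) {
          parts <- strsplit(tok, "=", fixed = TRUE)[[1]]
          jn <- parts[1]
          w <- if (length(parts) > 1) as.numeric(parts[2]) else 1
          idx <- match(jn, jumps$name)
          if (is.na(idx))
            stop("set_jump_group references undeclared jump '", jn,
                 "' at ", where)
          jumps$clone_group[idx] <- grp
          jumps$clone_weight[idx] <- w
        }
      },
      set_dof = {
        if (length(toks) < 3) stop("malformed set_dof at ", where)
        jn <- toks[2]
        if (!jn %in% jumps$name)
          stop("set_dof on undeclared jump '", jn, "' at ", where)
        dofs[[jn]] <- parse_dof_tokens(toks[-(1:2)], where)
      },
      full_system_frames = { full_frames <- toks[-1] },
      lattice = { lattice <- TRUE },
      { unknown <- c(unknown, paste0("line ", i, ": '", key, "'")) }
    )
  }
  if (length(unknown) > 0)
    stop("unknown SDF directive(s): ", paste(unknown, collapse = "; "))
  if (mode != "top") stop("unterminated ", mode, " block")
  if (is.null(energy)) stop("SDF has no E line")

  frame_spec <-
    if (!is.null(recipe)) {
      if (is.null(recipe$start)) stop("transform recipe has no start frame")
      c(recipe, kind = "transforms")
    } else {
      if (length(frames) == 0) stop("SDF declares no virtual frames")
      names(frames) <- vapply(frames, `[[`, "", "name")
      list(kind = "explicit", frames = frames)
    }

  sd <- new_symmetry_definition(
    name = name, frame_spec = frame_spec, jumps = jumps, dofs = dofs,
    energy = energy, anchor = anchor, recenter = recenter,
    total_subunits = total_subunits,
    slide = if (length(slide)) slide else NULL, full_frames = full_frames,
    lattice = lattice)
  diags <- validate_sdf(sd)
  if (length(diags) > 0)
    stop("invalid symmetry definition:\n  ", paste(diags, collapse = "\n  "))
  sd
}

## ---- writer ----------------------------------------------------------------

fmt_triple <- function(v) paste(sprintf("%.7f", v), collapse = ",")

fmt_mult <- function(m) {
  if (abs(m - round(m)) < 1e-12) format(round(m)) else format(m, digits = 12)
}

#' Serialize a symmetry definition
#'
#' Emits the textual SDF dialect; the output re-parses to a definition equal
#' field-by-field to the input (numeric fields to within 1e-7).
#'
#' @param sd a validated `symmetry_definition`.
#' @param path optional file path; when omitted the document is returned as a
#'   character vector of lines.
#' @return The SDF lines, invisibly when written to `path`.
#' @export
write_sdf <- function(sd, path = NULL) {
  diags <- validate_sdf(sd)
  if (length(diags) > 0)
    stop("refusing to serialize an invalid symmetry definition:\n  ",
         paste(diags, collapse = "\n  "))
  out <- c(paste("symmetry_name", sd$name),
           paste("total_subunits", sd$total_subunits))
  e <- sd$energy
  terms <- c(paste0(fmt_mult(e$intra$mult), "*", e$intra$frame),
             vapply(e$interfaces, function(tm)
               paste0(fmt_mult(tm$mult), "*(", tm$a, ":", tm$b, ")"), ""))
  out <- c(out, paste("E =", paste(terms, collapse = " + ")))
  out <- c(out, paste("anchor", sd$anchor))
  if (isTRUE(sd$recenter)) out <- c(out, "recenter")
  if (!is.null(sd$slide)) {
    sl <- sd$slide
    if (!is.null(sl$slide_type)) out <- c(out, paste("slide_type", sl$slide_type))
    if (!is.null(sl$criteria_type))
      out <- c(out, paste("slide_criteria_type", sl$criteria_type))
    if (!is.null(sl$criteria_val))
      out <- c(out, paste("slide_criteria_val", format(sl$criteria_val)))
  }
  fs <- sd$frame_spec
  if (fs$kind == "explicit") {
    out <- c(out, "virtual_coordinates_start")
    for (f in fs$frames)
      out <- c(out, paste("xyz", f$name, fmt_triple(f$x_axis),
                          fmt_triple(f$y_axis), fmt_triple(f$origin)))
    out <- c(out, "virtual_coordinates_stop")
  } else {
    out <- c(out, "virtual_transforms_start",
             paste("start", fmt_triple(fs$start$x_axis),
                   fmt_triple(fs$start$y_axis), fmt_triple(fs$start$origin)))
    for (op in fs$ops) {
      if (op$kind == "rot")
        out <- c(out, paste0("rot R", op$axis, " ", op$fold))
      else out <- c(out, paste("trans", fmt_triple(op$vec)))
    }
    out <- c(out, "virtual_transforms_stop")
  }
  for (i in seq_len(nrow(sd$jumps)))
    out <- c(out, paste("connect_virtual", sd$jumps$name[i],
                        sd$jumps$start[i], sd$jumps$stop[i]))
  groups <- split(seq_len(nrow(sd$jumps)), sd$jumps$clone_group)
  for (grp in names(groups)) {
    idx <- groups[[grp]]
    toks <- ifelse(abs(sd$jumps$clone_weight[idx] - 1) < 1e-12,
                   sd$jumps$name[idx],
                   paste0(sd$jumps$name[idx], "=",
                          format(sd$jumps$clone_weight[idx], digits = 12)))
    out <- c(out, paste("set_jump_group", grp, paste(toks, collapse = " ")))
  }
  for (jn in names(sd$dofs)) {
    d <- sd$dofs[[jn]]
    toks <- vapply(d$allowed, function(nm) {
      parts <- character()
      if (nm %in% names(d$init))
        parts <- paste0(nm, "(", format(d$init[[nm]], digits = 12), ")")
      if (nm %in% names(d$range))
        parts <- c(parts, paste0(nm, "(", format(d$range[[nm]][1], digits = 12),
                                 ":", format(d$range[[nm]][2], digits = 12), ")"))
      if (length(parts) == 0) parts <- nm
      paste(parts, collapse = " ")
    }, "")
    out <- c(out, paste("set_dof", jn, paste(toks, collapse = " ")))
  }
  if (!is.null(sd$full_frames))
    out <- c(out, paste("full_system_frames",
                        paste(sd$full_frames, collapse = " ")))
  if (isTRUE(sd$lattice)) out <- c(out, "lattice")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

## ---- validator -------------------------------------------------------------

#' Validate a symmetry definition
#'
#' Checks every structural invariant: frames resolve and are orthonormal, the
#' energy expression has exactly one intra term, all multipliers are positive
#' and reference declared frames, the jumps form a directed tree rooted at a
#' single vertex whose leaves attach each encoded subunit exactly once, clone
#' weights are positive, and every degree of freedom references a declared
#' jump.
#'
#' @param sd a `symmetry_definition`.
#' @return A character vector of diagnostics; empty when the definition is
#'   valid.
#' @export
validate_sdf <- function(sd) {
  diags <- character()
  frames <- tryCatch(resolve_frames(sd), error = function(e) {
    diags <<- c(diags, paste("frame resolution failed:", conditionMessage(e)))
    NULL
  })
  if (is.null(frames)) return(diags)
  fnames <- names(frames)

  e <- sd$energy
  if (e$intra$mult <= 0)
    diags <- c(diags, "intra multiplier must be positive")
  if (!e$intra$frame %in% fnames)
    diags <- c(diags, paste0("energy intra term references undeclared frame '",
                             e$intra$frame, "'"))
  for (tm in e$interfaces) {
    if (tm$mult <= 0)
      diags <- c(diags, paste0("interface multiplier for (", tm$a, ":", tm$b,
                               ") must be positive"))
    for (fr in c(tm$a, tm$b))
      if (!fr %in% fnames)
        diags <- c(diags, paste0("energy term references undeclared frame '",
                                 fr, "'"))
  }

  J <- sd$jumps
  if (nrow(J) == 0) {
    diags <- c(diags, "no jumps declared")
    return(diags)
  }
  if (anyDuplicated(J$name))
    diags <- c(diags, paste("duplicate jump names:",
                            paste(unique(J$name[duplicated(J$name)]),
                                  collapse = ", ")))
  for (i in seq_len(nrow(J))) {
    if (J$start[i] != "ROOT" && !J$start[i] %in% fnames)
      diags <- c(diags, paste0("jump '", J$name[i],
                               "' starts at undeclared frame '", J$start[i], "'"))
    if (J$stop[i] != "SUBUNIT" && !J$stop[i] %in% fnames)
      diags <- c(diags, paste0("jump '", J$name[i],
                               "' stops at undeclared frame '", J$stop[i], "'"))
    if (J$clone_weight[i] <= 0)
      diags <- c(diags, paste0("jump '", J$name[i],
                               "' has non-positive clone weight"))
  }

  # tree structure on frames: each frame at most one incoming jump; no cycles;
  # single root
  into <- J$stop[J$stop != "SUBUNIT"]
  if (anyDuplicated(into))
    diags <- c(diags, paste("frame(s) with multiple incoming jumps:",
                            paste(unique(into[duplicated(into)]),
                                  collapse = ", ")))
  parent <- stats::setNames(J$start[J$stop != "SUBUNIT"], into)
  for (f in fnames) {
    seen <- character()
    cur <- f
    while (cur %in% names(parent)) {
      if (cur %in% seen) {
        diags <- c(diags, paste0("jump graph has a cycle through frame '", cur,
                                 "' (back edge from '",
                                 parent[[cur]], "')"))
        break
      }
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
  }
  roots <- unique(c(J$start[J$start == "ROOT"],
                    setdiff(J$start, c(into, "ROOT"))))
  used_frames <- unique(c(J$start[J$start != "ROOT"], into))
  orphan_roots <- setdiff(setdiff(fnames, into),
                          c("ROOT"))
  # frames that are referenced as jump starts but have no path to the root
  if ("ROOT" %in% J$start) {
    reach <- "ROOT"
    repeat {
      nxt <- unique(c(reach, J$stop[J$start %in% reach & J$stop != "SUBUNIT"]))
      if (length(nxt) == length(reach)) break
      reach <- nxt
    }
    bad <- setdiff(unique(J$start[J$start != "ROOT"]), reach)
    if (length(bad) > 0)
      diags <- c(diags, paste("jump start frame(s) unreachable from ROOT:",
                              paste(bad, collapse = ", ")))
  } else {
    starts <- setdiff(unique(J$start), into)
    if (length(starts) > 1)
      diags <- c(diags, paste("jump graph has multiple roots:",
                              paste(starts, collapse = ", ")))
  }

  att <- attachment_jumps(sd)
  if (length(att) < 1)
    diags <- c(diags, "no subunit attachment jumps (stop SUBUNIT)")
  if (anyDuplicated(J$start[att]))
    diags <- c(diags, "a frame attaches more than one subunit")
  if (!is.null(sd$total_subunits) && sd$total_subunits < length(att))
    diags <- c(diags, sprintf(
      "total_subunits (%d) smaller than encoded subunits (%d)",
      sd$total_subunits, length(att)))

  for (jn in names(sd$dofs)) {
    if (!jn %in% J$name) {
      diags <- c(diags, paste0("set_dof on undeclared jump '", jn, "'"))
      next
    }
    d <- sd$dofs[[jn]]
    bad <- setdiff(d$allowed, DOF_NAMES)
    if (length(bad) > 0)
      diags <- c(diags, paste0("unknown dof name(s) on jump '", jn, "': ",
                               paste(bad, collapse = ", ")))
    extra <- setdiff(union(names(d$init), names(d$range)), d$allowed)
    if (length(extra) > 0)
      diags <- c(diags, paste0("dof(s) with init/range but not allowed on '",
                               jn, "': ", paste(extra, collapse = ", ")))
    for (nm in names(d$range))
      if (d$range[[nm]][1] > d$range[[nm]][2])
        diags <- c(diags, paste0("dof range lo > hi for ", nm, " on '", jn, "'"))
  }

  if (!is.null(sd$full_frames)) {
    bad <- setdiff(sd$full_frames, fnames)
    if (length(bad) > 0)
      diags <- c(diags, paste("full_system_frames lists undeclared frame(s):",
                              paste(bad, collapse = ", ")))
  }
  if (!is.null(sd$slide) && !is.null(sd$slide$slide_type) &&
      !sd$slide$slide_type %in% c("SEQUENTIAL", "ORDERED", "RANDOM"))
    diags <- c(diags, paste0("unknown slide_type '", sd$slide$slide_type, "'"))
  diags
}

# comparison helper used by round-trip tests: field-by-field equality with a
# numeric tolerance
sdf_equal <- function(a, b, tol = 1e-7) {
  fa <- resolve_frames(a); fb <- resolve_frames(b)
  if (!identical(names(fa), names(fb))) return(FALSE)
  for (nm in names(fa)) {
    da <- c(fa[[nm]]$origin, fa[[nm]]$x_axis, fa[[nm]]$y_axis)
    db <- c(fb[[nm]]$origin, fb[[nm]]$x_axis, fb[[nm]]$y_axis)
    if (max(abs(da - db)) > tol) return(FALSE)
  }
  if (!identical(a$jumps$name, b$jumps$name)) return(FALSE)
  if (!identical(a$jumps$start, b$jumps$start)) return(FALSE)
  if (!identical(a$jumps$stop, b$jumps$stop)) return(FALSE)
  if (max(abs(a$jumps$clone_weight - b$jumps$clone_weight)) > tol) return(FALSE)
  ga <- jump_groups(a); gb <- jump_groups(b)
  if (!identical(ga, gb)) return(FALSE)
  ea <- a$energy; eb <- b$energy
  if (ea$intra$frame != eb$intra$frame) return(FALSE)
  if (abs(ea$intra$mult - eb$intra$mult) > tol) return(FALSE)
  if (length(ea$interfaces) != length(eb$interfaces)) return(FALSE)
  for (i in seq_along(ea$interfaces)) {
    ta <- ea$interfaces[[i]]; tb <- eb$interfaces[[i]]
    if (ta$a != tb$a || ta$b != tb$b || abs(ta$mult - tb$mult) > tol)
      return(FALSE)
  }
  if (!identical(sort(names(a$dofs)), sort(names(b$dofs)))) return(FALSE)
  for (jn in names(a$dofs)) {
    da <- a$dofs[[jn]]; db <- b$dofs[[jn]]
    if (!setequal(da$allowed, db$allowed)) return(FALSE)
    if (!setequal(names(da$init), names(db$init))) return(FALSE)
    if (length(da$init) &&
        max(abs(unlist(da$init)[names(da$init)] -
                unlist(db$init)[names(da$init)])) > tol) return(FALSE)
    if (!setequal(names(da$range), names(db$range))) return(FALSE)
    for (nm in names(da$range))
      if (max(abs(da$range[[nm]] - db$range[[nm]])) > tol) return(FALSE)
  }
  if (!identical(a$anchor, b$anchor)) return(FALSE)
  if (!identical(a$recenter, b$recenter)) return(FALSE)
  if (!identical(a$total_subunits, b$total_subunits)) return(FALSE)
  if (!identical(a$full_frames, b$full_frames)) return(FALSE)
  if (!identical(isTRUE(a$lattice), isTRUE(b$lattice))) return(FALSE)
  TRUE
}
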