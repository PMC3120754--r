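# Structure container and PDB I/O.
#
# A structure is a plain data.frame with one row per atom and columns
#   chain   character, single letter
#   resno   integer, 1-based residue number within the chain
#   resname character, 3-letter residue type
#   atom    character, atom name (N, CA, C, O, CB, CG, ...)
#   x, y, z numeric, Angstrom
# plus class "symm_structure" and, when present, an attribute "cryst1"
# holding list(cell = numeric(6), spacegroup = character(1)).

new_structure <- function(df, cryst1 = NULL) {
  need <- c("chain", "resno", "resname", "atom", "x", "y", "z")
  stopifnot(all(need %in% names(df)))
  df <- as.data.frame(df)[, need]
  df$resno <- as.integer(df$resno)
  class(df) <- c("symm_structure", "data.frame")
  attr(df, "cryst1") <- cryst1
  df
}

#' @export
print.symm_structure <- function(x, ...) {
  ch <- unique(x$chain)
  cat(sprintf("<symm_structure> %d atoms, %d chain(s): %s\n",
              nrow(x), length(ch), paste(ch, collapse = " ")))
  cry <- attr(x, "cryst1")
  if (!is.null(cry))
    cat(sprintf("  CRYST1 %s cell = %s\n", cry$spacegroup,
                paste(format(cry$cell), collapse = " ")))
  invisible(x)
}

coords <- function(s) as.matrix(s[, c("x", "y", "z")])

`coords<-` <- function(s, value) {
  s[, c("x", "y", "z")] <- value
  s
}

structure_chains <- function(s) unique(s$chain)

chain_atoms <- function(s, ch) s[s$chain == ch, , drop = FALSE]

# Calpha coordinate matrix of one chain (or all atoms if no CA present)
ca_coords <- function(s, ch = NULL) {
  if (!is.null(ch)) s <- s[s$chain == ch, , drop = FALSE]
  m <- s[s$atom == "CA", , drop = FALSE]
  if (nrow(m) == 0) m <- s
  as.matrix(m[, c("x", "y", "z")])
}

# apply a 4x4 transform to a whole structure (or a row subset)
transform_structure <- function(s, T, rows = NULL) {
  if (is.null(rows)) {
    coords(s) <- tf_apply(T, coords(s))
  } else {
    s[rows, c("x", "y", "z")] <- tf_apply(T, as.matrix(s[rows, c("x", "y", "z")]))
  }
  s
}

#' Read a PDB file
#'
#' Reads ATOM records through [bio3d::read.pdb()] and additionally parses the
#' CRYST1 record (unit cell + spacegroup), which feeds the crystal-symmetry
#' generator.
#'
#' @param path path to a PDB file.
#' @return A `symm_structure` data.frame (see package docs); the CRYST1
#'   content, when present, is attached as attribute `"cryst1"`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("unparseable PDB file '", path,
                                           "': ", conditionMessage(e)))
  a <- pdb$atom
  a <- a[a$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  ch <- a$chain
  ch[is.na(ch) | ch == ""] <- "A"
  cry <- NULL
  lines <- readLines(path, warn = FALSE)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl) >= 1) {
    f <- cl[[1]]
    cell <- suppressWarnings(as.numeric(c(
      substr(f, 7, 15), substr(f, 16, 24), substr(f, 25, 33),
      substr(f, 34, 40), substr(f, 41, 47), substr(f, 48, 54))))
    sg <- trimws(substr(f, 56, 66))
    if (!anyNA(cell)) cry <- list(cell = cell, spacegroup = sg)
  }
  new_structure(data.frame(
    chain = ch, resno = a$resno, resname = a$resid, atom = a$elety,
    x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE), cryst1 = cry)
}

#' Write a structure to a PDB file
#'
#' Writes through [bio3d::write.pdb()]; residue numbering, chain ids and the
#' CRYST1 record (if attached) are preserved. Coordinates are written at the
#' PDB fixed-width precision of 3 decimals.
#'
#' @param s a `symm_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  xyz <- as.vector(t(coords(s)))
  elesy <- substr(s$atom, 1, 1)
  bio3d::write.pdb(file = path, xyz = xyz, resno = s$resno, resid = s$resname,
                   chain = s$chain, elety = s$atom, elesy = elesy,
                   o = rep(1, nrow(s)), b = rep(0, nrow(s)))
  cry <- attr(s, "cryst1")
  if (!is.null(cry)) {
    line <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                    cry$cell[1], cry$cell[2], cry$cell[3],
                    cry$cell[4], cry$cell[5], cry$cell[6], cry$spacegroup)
    body <- readLines(path, warn = FALSE)
    writeLines(c(line, body), path)
  }
  invisible(path)
}

# residue table: one row per (chain, resno) with row indices of its atoms
residue_index <- function(s) {
  key <- paste(s$chain, s$resno, sep = "\r")
  split(seq_len(nrow(s)), factor(key, levels = unique(key)))
}

n_residues <- function(s, ch = NULL) {
  if (!is.null(ch)) s <- s[s$chain == ch, , drop = FALSE]
  length(unique(s$resno))
}
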