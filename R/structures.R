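# Structure toolkit ------------------------------------------------------
#
# Element-labelled Cartesian coordinates (Angstrom) with named atom
# subsets, read from XYZ or PDB. Atom correspondence between structures
# is always by list order / explicit selection; no distance-based
# assignment is attempted.

PERIODIC_TABLE <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn",
  "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr",
  "Rb", "Sr", "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
  "In", "Sn", "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu",
  "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi",
  "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am",
  "Cm", "Bk", "Cf", "Es", "Fm", "Md", "No", "Lr"
)

normalize_element <- function(el) {
  el <- trimws(el)
  paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2)))
}

#' Construct a molecular structure
#'
#' @param atoms A data frame with columns `element`, `x`, `y`, `z`
#'   (Angstrom); extra metadata columns (e.g. PDB residue info) are kept.
#' @param name Structure name.
#' @param selections Named list of 1-based atom index vectors.
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(atoms, name = "structure", selections = list()) {
  s <- structure(
    list(name = name, atoms = as_tibble(atoms), selections = selections),
    class = "structure3d"
  )
  validate_structure(s)
}

validate_structure <- function(s) {
  at <- s$atoms
  if (!all(c("element", "x", "y", "z") %in% names(at))) {
    abort("structure: atoms need columns element, x, y, z.")
  }
  at$element <- normalize_element(at$element)
  bad <- setdiff(unique(at$element), PERIODIC_TABLE)
  if (length(bad)) {
    abort(paste0("structure: unknown element symbol(s) ", toString(bad), "."))
  }
  xyz <- as.matrix(at[c("x", "y", "z")])
  if (any(!is.finite(xyz))) abort("structure: coordinates must be finite.")
  for (lab in names(s$selections)) {
    idx <- s$selections[[lab]]
    if (anyDuplicated(idx) || any(idx < 1L) || any(idx > nrow(at))) {
      abort(paste0("structure: selection '", lab,
                   "' has out-of-range or duplicate indices."))
    }
  }
  s$atoms <- at
  s
}

#' @export
print.structure3d <- function(x, ...) {
  cat("<structure3d> ", x$name, ": ", nrow(x$atoms), " atoms (",
      toString(head(sort(unique(x$atoms$element)), 8)), ")",
      if (length(x$selections)) paste0("; selections: ",
                                       toString(names(x$selections))),
      "\n", sep = "")
  invisible(x)
}

coords_matrix <- function(s, idx = NULL) {
  m <- as.matrix(s$atoms[c("x", "y", "z")])
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  unname(m)
}

#' Add or replace a named atom selection
#'
#' @param s A `structure3d`.
#' @param label Selection name.
#' @param indices Explicit 1-based atom indices, or `NULL` to build the
#'   selection from filters.
#' @param elements Keep atoms whose element is in this set.
#' @param residues For PDB-derived structures, keep atoms whose `resid`
#'   is in this set.
#' @param complement Take the complement of the filtered set.
#' @return The structure with the selection added.
#' @export
select_atoms <- function(s, label, indices = NULL, elements = NULL,
                         residues = NULL, complement = FALSE) {
  if (is.null(indices)) {
    keep <- rep(TRUE, nrow(s$atoms))
    if (!is.null(elements)) {
      keep <- keep & s$atoms$element %in% normalize_element(elements)
    }
    if (!is.null(residues)) {
      if (!"resid" %in% names(s$atoms)) {
        abort("select_atoms: structure has no residue metadata.")
      }
      keep <- keep & s$atoms$resid %in% residues
    }
    if (complement) keep <- !keep
    indices <- which(keep)
  }
  s$selections[[label]] <- as.integer(indices)
  validate_structure(s)
}

resolve_selection <- function(s, selection) {
  if (is.character(selection) && length(selection) == 1L) {
    idx <- s$selections[[selection]]
    if (is.null(idx)) {
      abort(paste0("unknown selection '", selection, "' in structure '",
                   s$name, "'."))
    }
    return(idx)
  }
  if (is.numeric(selection)) {
    idx <- as.integer(selection)
    if (any(idx < 1L) || any(idx > nrow(s$atoms))) {
      abort("selection indices out of range.")
    }
    return(idx)
  }
  abort("`selection` must be a selection label or an index vector.")
}

# --- file I/O -----------------------------------------------------------

read_xyz_file <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) abort(paste0(path, ": empty XYZ file."))
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) abort(paste0(path, ": line 1: expected an atom count."))
  if (length(lines) < n + 2L) {
    abort(paste0(path, ": expected ", n, " atom records, found ",
                 max(length(lines) - 2L, 0L), "."))
  }
  comment <- if (length(lines) >= 2L) lines[2] else ""
  recs <- lapply(seq_len(n), function(i) {
    ln <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4L) {
      abort(paste0(path, ": line ", ln, ": malformed XYZ record."))
    }
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(xyz))) {
      abort(paste0(path, ": line ", ln, ": non-numeric coordinate."))
    }
    tibble(element = tok[1], x = xyz[1], y = xyz[2], z = xyz[3])
  })
  structure3d(purrr::list_rbind(recs),
              name = if (nzchar(trimws(comment))) trimws(comment)
                     else basename(path))
}

read_pdb_file <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  alt <- at$alt
  if (!is.null(alt) && any(!is.na(alt) & nzchar(alt))) {
    # bio3d has already pruned to the first altloc; surface that policy
    warn(paste0(path, ": alternate locations present; keeping the ",
                "first altloc ('A') only."))
    at <- at[is.na(alt) | alt %in% c("", "A"), , drop = FALSE]
  }
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(!nzchar(trimws(el)))) {
    el <- gsub("[^A-Za-z].*$", "", at$elety)
    el <- substr(el, 1, 2)
    el <- ifelse(normalize_element(el) %in% PERIODIC_TABLE, el,
                 substr(el, 1, 1))
  }
  structure3d(
    tibble(
      element = normalize_element(el),
      x = at$x, y = at$y, z = at$z,
      elety = at$elety, resid = at$resid, chain = at$chain,
      resno = at$resno, insert = at$insert %||% NA_character_
    ),
    name = basename(path)
  )
}

#' Read a structure from an XYZ or PDB file
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"xyz"` or `"pdb"`.
#' @return A `structure3d` with atoms in file order; PDB residue/chain
#'   metadata is retained for selection building. For PDB files only the
#'   first alternate location is kept (with a warning).
#' @export
read_structure <- function(path, format = c("auto", "xyz", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("No such structure file: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  switch(format, xyz = read_xyz_file(path), pdb = read_pdb_file(path))
}

#' Write a structure as XYZ
#'
#' Coordinates are written with four decimals (0.0001 Angstrom), the
#' XYZ format's customary precision.
#'
#' @param s A `structure3d`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  s <- validate_structure(s)
  at <- s$atoms
  lines <- c(
    as.character(nrow(at)),
    s$name,
    sprintf("%-3s %12.4f %12.4f %12.4f", at$element, at$x, at$y, at$z)
  )
  writeLines(lines, path)
  invisible(path)
}
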