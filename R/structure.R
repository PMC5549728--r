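#' Construct a structure model
#'
#' A `habind_structure` holds an atom table, one set of coordinates in
#' nanometres, optional orthorhombic box vectors and a molecule-role tag per
#' chain (`"protein"`, `"polymer"` or `"other"`).
#'
#' @param atoms data.frame with columns `name`, `element`, `resno`,
#'   `resname`, `chain`. Row order defines the atom indexing (0-based
#'   `index` column is added).
#' @param xyz numeric matrix, one row per atom, columns x/y/z in nm.
#' @param box numeric length-3 box vectors in nm, or `NULL` (non-periodic).
#' @param roles named character vector mapping chain ids to roles; chains
#'   not named default to `"other"`.
#' @return object of class `habind_structure`.
#' @export
structure_model <- function(atoms, xyz, box = NULL, roles = NULL) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("name", "element", "resno", "resname", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(atoms) || ncol(xyz) != 3)
    stop("coordinate matrix must be n_atoms x 3")
  if (nrow(atoms) == 0L) stop("empty model: structure has zero atoms")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in structure")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
      stop("box vectors must be three positive finite lengths (nm)")
  }
  atoms$index <- seq_len(nrow(atoms)) - 1L
  chains <- unique(atoms$chain)
  role <- setNames(rep("other", length(chains)), chains)
  if (!is.null(roles)) {
    bad <- setdiff(names(roles), chains)
    if (length(bad)) stop("role given for unknown chain: ", paste(bad, collapse = ", "))
    role[names(roles)] <- unname(roles)
  }
  structure(
    list(atoms = atoms, xyz = xyz, box = box, roles = role),
    class = "habind_structure"
  )
}

#' @export
print.habind_structure <- function(x, ...) {
  cat("<habind_structure> ", nrow(x$atoms), " atoms, ",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), " residues, ",
      length(x$roles), " chain(s)\n", sep = "")
  for (ch in names(x$roles))
    cat("  chain ", ch, ": ", sum(x$atoms$chain == ch), " atoms [",
        x$roles[[ch]], "]\n", sep = "")
  invisible(x)
}

#' Number of atoms / frames
#' @param x a structure model or trajectory.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "habind_structure")) nrow(x$atoms)
  else if (inherits(x, "habind_traj")) nrow(x$model$atoms)
  else stop("unsupported type")
}

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records (through bio3d) and converts coordinates from
#' Angstrom to nanometres.
#'
#' @param path PDB file.
#' @param roles optional named character vector chain -> role
#'   ("protein"/"polymer"/"other").
#' @param resno_offset integer added to the file's residue numbers to map
#'   author numbering onto the canonical numbering (default 0).
#' @return a `habind_structure`.
#' @export
read_structure <- function(path, roles = NULL, resno_offset = 0L) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB '", path, "': ",
                                           conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop("empty model: no atoms in ", path)
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- guess_element(a$elety)
  elem[is.na(elem) | elem == ""] <- guess_element(a$elety[is.na(elem) | elem == ""])
  atoms <- data.frame(
    name = a$elety, element = elem,
    resno = a$resno + as.integer(resno_offset),
    resname = a$resid, chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
    stringsAsFactors = FALSE
  )
  xyz <- cbind(a$x, a$y, a$z) / 10  # Angstrom -> nm
  structure_model(atoms, xyz, box = NULL, roles = roles)
}

#' Write a structure as PDB
#'
#' Coordinates are converted from nm back to Angstrom.
#' @param model a `habind_structure`.
#' @param path output file.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "habind_structure"))
  a <- model$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(model$xyz * 10)),
    resno = a$resno, resid = a$resname, eleno = a$index + 1L,
    elety = a$name, chain = a$chain, elesy = a$element
  )
  invisible(path)
}

# Element from a PDB atom name when the element column is absent. First
# non-digit character; two-letter elements relevant here are handled by an
# explicit override table.
guess_element <- function(name) {
  overrides <- c(CL = "Cl", BR = "Br", NA_ = "Na", MG = "Mg", ZN = "Zn",
                 FE = "Fe", MN = "Mn", CA2 = "Ca")
  nm <- toupper(trimws(name))
  out <- character(length(nm))
  hit <- nm %in% names(overrides)
  out[hit] <- overrides[nm[hit]]
  rest <- sub("^[0-9']*", "", nm[!hit])
  out[!hit] <- substr(rest, 1, 1)
  out
}

#' Is an atom a heavy (non-hydrogen) atom?
#'
#' Uses the element column; names starting with H (after stripping leading
#' digits) are hydrogens when the element is missing.
#' @param model a `habind_structure`.
#' @return logical per atom.
#' @export
is_heavy <- function(model) {
  el <- model$atoms$element
  el[is.na(el) | el == ""] <- guess_element(model$atoms$name[is.na(el) | el == ""])
  toupper(el) != "H"
}

#' Define a named atom selection
#'
#' Selections resolve to atom indices by residue range/number, residue name,
#' chain, role and element class; they are stable across frames.
#'
#' @param name label for the selection.
#' @param resno residue numbers to keep (NULL = all).
#' @param resname residue names to keep (NULL = all).
#' @param chain chain ids to keep (NULL = all).
#' @param role chain role to keep ("protein"/"polymer"/"other", NULL = all).
#' @param atoms `"heavy"` (default) or `"all"`.
#' @export
selection_spec <- function(name, resno = NULL, resname = NULL, chain = NULL,
                           role = NULL, atoms = c("heavy", "all")) {
  atoms <- match.arg(atoms)
  structure(list(name = name, resno = resno, resname = resname,
                 chain = chain, role = role, atoms = atoms),
            class = "habind_selection")
}

#' Resolve a selection to atom row indices
#' @param model a `habind_structure`.
#' @param spec a `habind_selection` (or integer indices passed through).
#' @return integer vector of 1-based atom rows.
#' @export
resolve_selection <- function(model, spec) {
  if (is.numeric(spec)) return(as.integer(spec))
  stopifnot(inherits(spec, "habind_selection"))
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(spec$role)) {
    ch <- names(model$roles)[model$roles %in% spec$role]
    keep <- keep & a$chain %in% ch
  }
  if (!is.null(spec$chain))   keep <- keep & a$chain %in% spec$chain
  if (!is.null(spec$resno))   keep <- keep & a$resno %in% spec$resno
  if (!is.null(spec$resname)) keep <- keep & a$resname %in% spec$resname
  if (spec$atoms == "heavy")  keep <- keep & is_heavy(model)
  idx <- which(keep)
  if (!length(idx))
    stop("selection '", spec$name, "' resolves to zero atoms")
  idx
}
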