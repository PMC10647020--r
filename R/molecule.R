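#' Molecular graph
#'
#' A light-weight topology container: elements, formal charges, aromatic
#' flags and a bond table. Atom indices are 1-based and stable across all
#' conformers of the molecule. Hydrogens may be explicit or implicit; most
#' operations work on the heavy-atom graph by default.
#'
#' @param elements character vector of element symbols (e.g. `"C"`, `"O"`).
#' @param bonds data frame or matrix with columns `i`, `j`, `order`; `order`
#'   is 1, 2, 3 or 4 (aromatic). A molecule with a single atom may pass an
#'   empty bond table.
#' @param charges integer vector of formal charges, recycled to the atom
#'   count (default 0).
#' @param aromatic logical per-atom aromatic flags. If `NULL`, atoms incident
#'   to an order-4 bond are flagged.
#' @param name free-text identifier.
#' @return An object of class `mol_graph` with fields `elements`, `charges`,
#'   `aromatic`, `bonds` and `name`.
#' @examples
#' eth <- mol_graph(c("C", "C", "O"), data.frame(i = 1:2, j = 2:3, order = 1))
#' n_atoms(eth)
#' @export
mol_graph <- function(elements, bonds, charges = 0L, aromatic = NULL,
                      name = "") {
  elements <- as.character(elements)
  n <- length(elements)
  if (n < 1L) stop("a molecule needs at least one atom")
  charges <- rep_len(as.integer(charges), n)
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- data.frame(i = integer(), j = integer(), order = numeric())
  } else {
    bonds <- as.data.frame(bonds)[, c("i", "j", "order")]
    bonds$i <- as.integer(bonds$i)
    bonds$j <- as.integer(bonds$j)
    bonds$order <- as.numeric(bonds$order)
  }
  if (NROW(bonds)) {
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))
      stop("bond endpoint out of range")
    if (any(bonds$i == bonds$j)) stop("self-bonds are not allowed")
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("duplicate bonds are not allowed")
  }
  if (is.null(aromatic)) {
    aromatic <- rep(FALSE, n)
    ar <- bonds$order == 4
    aromatic[unique(c(bonds$i[ar], bonds$j[ar]))] <- TRUE
  } else {
    aromatic <- rep_len(as.logical(aromatic), n)
  }
  structure(
    list(elements = elements, charges = charges, aromatic = aromatic,
         bonds = bonds, name = as.character(name)[1]),
    class = "mol_graph"
  )
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %s: %d atoms (%d heavy), %d bonds\n",
              if (nzchar(x$name)) x$name else "<unnamed>",
              length(x$elements), length(heavy_atoms(x)), nrow(x$bonds)))
  invisible(x)
}

#' Atom count of a molecule
#' @param mol a [mol_graph].
#' @return integer atom count.
#' @export
n_atoms <- function(mol) length(mol$elements)

#' Indices of heavy (non-hydrogen) atoms
#' @param mol a [mol_graph].
#' @return integer vector of 1-based atom indices.
#' @export
heavy_atoms <- function(mol) which(mol$elements != "H")

#' Single conformer
#'
#' One 3D coordinate assignment (in Angstrom) for a molecule's atoms, with an
#' optional energy (kcal/mol, arbitrary offset) and provenance record.
#'
#' @param coords numeric matrix with one row per atom and 3 columns.
#' @param energy scalar energy or `NA` when unknown.
#' @param provenance list, e.g. `list(generator = "etkdg", minimized = TRUE,
#'   sample = 7)`.
#' @return An object of class `conformer`.
#' @export
conformer <- function(coords, energy = NA_real_, provenance = list()) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must have 3 columns")
  if (!all(is.finite(coords))) stop("coords must be finite")
  structure(list(coords = coords, energy = as.numeric(energy)[1],
                 provenance = provenance),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer> %d atoms, energy %s\n", nrow(x$coords),
              if (is.na(x$energy)) "absent" else format(x$energy)))
  invisible(x)
}

#' Conformer ensemble
#'
#' One molecule plus an ordered list of conformers (generation order is
#' meaningful). Every conformer must have as many coordinate rows as the
#' molecule has atoms.
#'
#' @param molecule a [mol_graph].
#' @param conformers list of [conformer] objects.
#' @return An object of class `conf_ensemble`.
#' @export
conf_ensemble <- function(molecule, conformers = list()) {
  stopifnot(inherits(molecule, "mol_graph"))
  n <- n_atoms(molecule)
  for (k in seq_along(conformers)) {
    cf <- conformers[[k]]
    if (!inherits(cf, "conformer")) stop("conformers must be conformer objects")
    if (nrow(cf$coords) != n)
      stop(sprintf("conformer %d has %d atoms; molecule has %d",
                   k, nrow(cf$coords), n))
  }
  structure(list(molecule = molecule, conformers = conformers),
            class = "conf_ensemble")
}

#' @export
length.conf_ensemble <- function(x) length(x$conformers)

#' @export
print.conf_ensemble <- function(x, ...) {
  cat(sprintf("<conf_ensemble> %s: %d conformers of %d atoms\n",
              if (nzchar(x$molecule$name)) x$molecule$name else "<unnamed>",
              length(x$conformers), n_atoms(x$molecule)))
  invisible(x)
}

#' Subset an ensemble by conformer index
#' @param x a [conf_ensemble].
#' @param i integer indices of conformers to keep (original order semantics
#'   of `[`).
#' @param ... ignored.
#' @return a [conf_ensemble] with the selected conformers.
#' @export
`[.conf_ensemble` <- function(x, i, ...) {
  conf_ensemble(x$molecule, x$conformers[i])
}

#' Energies of an ensemble
#' @param ens a [conf_ensemble].
#' @return numeric vector (NA where absent).
#' @export
ens_energies <- function(ens) {
  vapply(ens$conformers, function(cf) cf$energy, numeric(1))
}

# topology signature used to group identical molecules (SDF grouping rule)
mol_signature <- function(mol) {
  b <- mol$bonds
  if (NROW(b)) {
    key <- paste(pmin(b$i, b$j), pmax(b$i, b$j), b$order, sep = ":")
    key <- paste(sort(key), collapse = ",")
  } else key <- ""
  paste(mol$name, paste(mol$elements, mol$charges, sep = "_", collapse = ";"),
        key, sep = "|")
}
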