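#' Enumerate graph automorphisms of a molecule
#'
#' Finds all element-, charge- and bond-order-preserving permutations of the
#' atoms (the topological symmetries used for symmetry-corrected RMSD).
#' Enumeration runs on a colored graph via the VF2 backtracking search of
#' igraph: vertex colors encode (element, formal charge) and edge colors the
#' bond-order class, with aromatic bonds (order 4) treated as their own class
#' so that Kekule forms do not split the symmetry group.
#'
#' @param mol a [mol_graph].
#' @param heavy_only drop hydrogens before the search (default `TRUE`,
#'   matching the heavy-atom RMSD convention).
#' @param cap maximum number of mappings returned; when exceeded the result
#'   is truncated and carries `attr(, "truncated") = TRUE`.
#' @return An integer matrix with one row per automorphism; row `m` maps
#'   position `k` (in the retained atom order) to position `perm[m, k]`. The
#'   identity permutation is the first row. Attributes: `atoms` (the retained
#'   1-based atom indices of `mol`) and `truncated`.
#' @examples
#' benzene <- mol_graph(rep("C", 6),
#'   data.frame(i = 1:6, j = c(2:6, 1), order = 4))
#' nrow(find_automorphisms(benzene))  # 12: rotations + reflections
#' @export
find_automorphisms <- function(mol, heavy_only = TRUE, cap = 10000L) {
  stopifnot(inherits(mol, "mol_graph"))
  atoms <- if (heavy_only) heavy_atoms(mol) else seq_len(n_atoms(mol))
  if (length(atoms) == 0L) stop("no atoms left after hydrogen removal")
  idx <- match(seq_len(n_atoms(mol)), atoms)  # old -> new position (NA if dropped)
  k <- length(atoms)
  vcol <- as.integer(factor(paste(mol$elements[atoms], mol$charges[atoms])))
  b <- mol$bonds
  keep <- !is.na(idx[b$i]) & !is.na(idx[b$j])
  b <- b[keep, , drop = FALSE]
  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  ecol <- integer(0)
  if (NROW(b)) {
    g <- igraph::add_edges(g, rbind(idx[b$i], idx[b$j]))
    ecol <- as.integer(b$order * 2)  # 1,1.5,2,3,4 -> distinct integers
  }
  maps <- igraph::isomorphisms(
    g, g,
    vertex.color1 = vcol, vertex.color2 = vcol,
    edge.color1 = ecol, edge.color2 = ecol
  )
  perm <- do.call(rbind, lapply(maps, as.integer))
  # identity first, rest in stable order
  id_row <- which(apply(perm, 1L, function(p) all(p == seq_len(k))))
  perm <- perm[c(id_row, setdiff(seq_len(nrow(perm)), id_row)), , drop = FALSE]
  truncated <- FALSE
  if (nrow(perm) > cap) {
    perm <- perm[seq_len(cap), , drop = FALSE]
    truncated <- TRUE
  }
  attr(perm, "atoms") <- atoms
  attr(perm, "truncated") <- truncated
  perm
}

#' Kabsch superposition of two point sets
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `rotation %*% p + translation` against `Q` over all proper rigid
#' transforms. The degenerate reflection-optimal case is resolved by sign
#' flip of the smallest singular vector so that `det(rotation) = +1`. A
#' single point superposes exactly by translation (RMSD 0).
#'
#' @param P,Q numeric matrices of equal size (n x 3), rows are points in
#'   Angstrom.
#' @return A list of class `superposition` with `rotation` (3 x 3,
#'   determinant +1), `translation` (length 3) and `rmsd` (Angstrom).
#' @examples
#' P <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
#' Q <- matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)
#' kabsch_superpose(P, Q)$rmsd  # 0.5
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!is.numeric(P) || !is.numeric(Q) || ncol(P) != 3L || ncol(Q) != 3L)
    stop("P and Q must be numeric n x 3 matrices")
  if (nrow(P) != nrow(Q))
    stop(sprintf("point counts differ (%d vs %d)", nrow(P), nrow(Q)))
  res <- cpp_kabsch(P, Q)
  res$translation <- as.numeric(res$translation)
  structure(res, class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.6f A\n", x$rmsd))
  invisible(x)
}

#' Symmetry-corrected RMSD between two conformers
#'
#' The minimum RMSD over all graph automorphisms of the molecule, i.e. the
#' lowest possible RMSD of any valid atom matching. With `align = TRUE` each
#' candidate matching is first optimally superposed (Kabsch); with
#' `align = FALSE` coordinates are compared in their common frame (the
#' convention for docked poses sharing the receptor frame). The result is
#' symmetric in its two arguments and never exceeds the identity-matching
#' RMSD.
#'
#' @param a,b [conformer] objects of the same molecule.
#' @param mol the owning [mol_graph].
#' @param align superpose before comparing (default `TRUE`).
#' @param heavy_only compare heavy atoms only (default `TRUE`).
#' @param autos optional precomputed automorphism matrix from
#'   [find_automorphisms()] (must match `heavy_only`); pass it when calling
#'   in a loop.
#' @return RMSD in Angstrom, with the minimizing atom mapping in
#'   `attr(, "mapping")` (a permutation of the retained atom positions).
#' @export
symmetry_rmsd <- function(a, b, mol, align = TRUE, heavy_only = TRUE,
                          autos = NULL) {
  stopifnot(inherits(a, "conformer"), inherits(b, "conformer"),
            inherits(mol, "mol_graph"))
  n <- n_atoms(mol)
  if (nrow(a$coords) != n || nrow(b$coords) != n)
    stop("conformer atom counts do not match the molecule")
  if (is.null(autos)) autos <- find_automorphisms(mol, heavy_only = heavy_only)
  atoms <- attr(autos, "atoms")
  res <- cpp_rmsd_perms(a$coords[atoms, , drop = FALSE],
                        b$coords[atoms, , drop = FALSE],
                        autos, align)
  structure(res[1], mapping = autos[res[2], ])
}
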