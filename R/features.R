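#' The six pharmacophore feature classes
#' @return character vector of class names (Pharmit-style naming).
#' @export
feature_types <- function() {
  c("HydrogenDonor", "HydrogenAcceptor", "Hydrophobic", "Aromatic",
    "PositiveIon", "NegativeIon")
}

#' Feature detection rule table
#'
#' All heuristics used by [detect_features()] in one editable list:
#' element valences for implicit-hydrogen counting, donor/acceptor element
#' sets and exclusions, and the minimum carbon-cluster size for hydrophobic
#' features.
#'
#' @return a named list of rule parameters.
#' @export
feature_rules <- function() {
  list(
    valence = c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1,
                I = 1, B = 3),
    donor_elements = c("N", "O"),
    acceptor_elements = c("N", "O"),
    exclude_amide_n = TRUE,     # N adjacent to a carbonyl carbon
    exclude_aniline_n = TRUE,   # N attached to an aromatic atom
    hydrophobic_min_carbons = 3
  )
}

feature_row <- function(type, center, owner) {
  data.frame(type = type, x = center[1], y = center[2], z = center[3],
             owner = I(list(sort(as.integer(owner)))))
}

#' Coordinate matrix of a feature data frame
#' @param features feature data frame with `x`, `y`, `z` columns.
#' @return numeric (n x 3) matrix.
#' @export
feature_coords <- function(features) {
  as.matrix(features[, c("x", "y", "z")])
}

# neighbor list and per-atom bond-order sum (aromatic counts 1.5)
adjacency_info <- function(mol) {
  n <- n_atoms(mol)
  nb <- rep(list(integer(0)), n)
  bsum <- numeric(n)
  b <- mol$bonds
  for (r in seq_len(NROW(b))) {
    i <- b$i[r]; j <- b$j[r]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
    o <- if (b$order[r] == 4) 1.5 else b$order[r]
    bsum[i] <- bsum[i] + o; bsum[j] <- bsum[j] + o
  }
  list(nb = nb, bsum = bsum)
}

# implicit hydrogen count from default valences adjusted by formal charge
implicit_h <- function(mol, adj, rules) {
  val <- rules$valence[mol$elements]
  val[is.na(val)] <- 0
  adj_val <- ifelse(mol$elements %in% c("N", "O", "P", "S"),
                    val + mol$charges, val - abs(mol$charges))
  pmax(0, round(adj_val - adj$bsum))
}

# rings of the aromatic-bond subgraph (per-edge shortest-cycle perception)
aromatic_rings <- function(mol) {
  b <- mol$bonds[mol$bonds$order == 4, , drop = FALSE]
  if (!NROW(b)) return(list())
  verts <- sort(unique(c(b$i, b$j)))
  g <- igraph::make_empty_graph(length(verts), directed = FALSE)
  g <- igraph::add_edges(g, rbind(match(b$i, verts), match(b$j, verts)))
  rings <- list()
  seen <- character(0)
  for (e in seq_len(igraph::ecount(g))) {
    ends <- igraph::ends(g, e)
    g2 <- igraph::delete_edges(g, e)
    sp <- suppressWarnings(igraph::shortest_paths(g2, ends[1], ends[2]))$vpath[[1]]
    if (length(sp) < 2) next
    ring <- verts[sort(as.integer(sp))]
    if (length(ring) < 3 || length(ring) > 7) next
    key <- paste(ring, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    rings[[length(rings) + 1L]] <- ring
  }
  rings
}

#' Detect pharmacophore features of a conformer
#'
#' Deterministic rule-based perception over the six feature classes:
#' hydrogen-bond donors are neutral N/O with at least one (explicit or
#' implicit) hydrogen, acceptors neutral N/O with a lone pair (amide and
#' aniline-type nitrogens excluded), aromatic features sit at perceived
#' aromatic-ring centroids, ionic features at the centroids of
#' formally charged groups, and hydrophobic features at the centroids of
#' connected clusters of three or more non-aromatic carbons with no attached
#' heteroatom. All rules live in [feature_rules()].
#'
#' @param mol a [mol_graph].
#' @param conf a [conformer] of `mol`.
#' @param rules rule table, see [feature_rules()].
#' @return A data frame with columns `type`, `x`, `y`, `z` and a list column
#'   `owner` holding the generating atom indices, ordered by class then by
#'   first owner atom.
#' @export
detect_features <- function(mol, conf, rules = feature_rules()) {
  stopifnot(inherits(mol, "mol_graph"), inherits(conf, "conformer"))
  if (nrow(conf$coords) != n_atoms(mol))
    stop("conformer does not belong to this molecule")
  xyz <- conf$coords
  adj <- adjacency_info(mol)
  el <- mol$elements
  q <- mol$charges
  nH <- implicit_h(mol, adj, rules) +
    vapply(adj$nb, function(v) sum(el[v] == "H"), numeric(1))
  out <- list()
  add <- function(type, center, owner)
    out[[length(out) + 1L]] <<- feature_row(type, center, owner)

  neutral <- q == 0L
  # donors
  for (a in which(el %in% rules$donor_elements & neutral & nH >= 1)) {
    add("HydrogenDonor", xyz[a, ], a)
  }
  # acceptors
  for (a in which(el %in% rules$acceptor_elements & neutral)) {
    if (el[a] == "N") {
      if (adj$bsum[a] >= 4) next  # no lone pair (quaternary-like)
      nbrs <- adj$nb[[a]]
      if (rules$exclude_aniline_n && any(mol$aromatic[nbrs])) next
      if (mol$aromatic[a]) next
      carbonyl <- vapply(nbrs, function(c_at) {
        if (el[c_at] != "C") return(FALSE)
        b <- mol$bonds
        dbl <- (b$i == c_at & b$order == 2 & el[b$j] == "O") |
               (b$j == c_at & b$order == 2 & el[b$i] == "O")
        any(dbl)
      }, logical(1))
      if (rules$exclude_amide_n && any(carbonyl)) next
    }
    add("HydrogenAcceptor", xyz[a, ], a)
  }
  # ionic groups: connected components of same-sign charged atoms
  for (sgn in c(1, -1)) {
    atoms <- which(sign(q) == sgn)
    if (!length(atoms)) next
    comp <- components_of(atoms, adj$nb)
    for (grp in comp) {
      add(if (sgn > 0) "PositiveIon" else "NegativeIon",
          colMeans(xyz[grp, , drop = FALSE]), grp)
    }
  }
  # aromatic rings
  for (ring in aromatic_rings(mol)) {
    add("Aromatic", colMeans(xyz[ring, , drop = FALSE]), ring)
  }
  # hydrophobic carbon clusters
  hetero_free <- vapply(seq_along(el), function(a) {
    el[a] == "C" && !mol$aromatic[a] &&
      all(el[adj$nb[[a]]] %in% c("C", "H"))
  }, logical(1))
  comp <- components_of(which(hetero_free), adj$nb)
  for (grp in comp) {
    if (length(grp) >= rules$hydrophobic_min_carbons)
      add("Hydrophobic", colMeans(xyz[grp, , drop = FALSE]), grp)
  }
  if (!length(out)) {
    return(data.frame(type = character(), x = numeric(), y = numeric(),
                      z = numeric(), owner = I(list())))
  }
  feats <- do.call(rbind, out)
  ord <- order(match(feats$type, feature_types()),
               vapply(feats$owner, min, numeric(1)))
  feats <- feats[ord, , drop = FALSE]
  rownames(feats) <- NULL
  feats
}

# connected components of `atoms` within the bond graph restricted to them
components_of <- function(atoms, nb) {
  comps <- list()
  pool <- atoms
  while (length(pool)) {
    frontier <- pool[1]
    grp <- integer(0)
    while (length(frontier)) {
      a <- frontier[1]; frontier <- frontier[-1]
      if (a %in% grp) next
      grp <- c(grp, a)
      frontier <- c(frontier, intersect(nb[[a]], setdiff(pool, grp)))
    }
    comps[[length(comps) + 1L]] <- sort(grp)
    pool <- setdiff(pool, grp)
  }
  comps
}

#' Write features to the Pharmit-style JSON point format
#'
#' Schema: `{"points": [{"name": <class>, "x": .., "y": .., "z": ..,
#' "radius": ..}]}`, interoperable with Pharmit session files.
#'
#' @param features feature data frame (see [detect_features()]).
#' @param path output path.
#' @param radius tolerance radius written per point (default 1.0 A).
#' @return invisibly `path`.
#' @export
write_features_json <- function(features, path, radius = 1.0) {
  radii <- if ("radius" %in% names(features)) features$radius
           else rep(radius, nrow(features))
  pts <- lapply(seq_len(nrow(features)), function(i) {
    list(name = features$type[i], x = features$x[i], y = features$y[i],
         z = features$z[i], radius = radii[i])
  })
  jsonlite::write_json(list(points = pts), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read features from the Pharmit-style JSON point format
#' @param path JSON file with a `points` array.
#' @return feature data frame with a `radius` column.
#' @export
read_features_json <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- js$points
  if (is.null(pts) || !NROW(pts)) {
    return(data.frame(type = character(), x = numeric(), y = numeric(),
                      z = numeric(), radius = numeric(), owner = I(list())))
  }
  bad <- setdiff(unique(pts$name), feature_types())
  if (length(bad)) stop("unknown feature class: ", paste(bad, collapse = ", "))
  data.frame(type = pts$name, x = pts$x, y = pts$y, z = pts$z,
             radius = if ("radius" %in% names(pts)) pts$radius else 1.0,
             owner = I(rep(list(integer(0)), nrow(pts))))
}

# residue-level receptor feature table: atom names per residue and the
# feature class their centroid generates
.pdb_feature_table <- list(
  list(resid = c("ASP"), atoms = c("OD1", "OD2"), type = "NegativeIon"),
  list(resid = c("GLU"), atoms = c("OE1", "OE2"), type = "NegativeIon"),
  list(resid = c("LYS"), atoms = "NZ", type = "PositiveIon"),
  list(resid = c("ARG"), atoms = c("NE", "NH1", "NH2"), type = "PositiveIon"),
  list(resid = c("SER"), atoms = "OG", type = "HydrogenDonor"),
  list(resid = c("SER"), atoms = "OG", type = "HydrogenAcceptor"),
  list(resid = c("THR"), atoms = "OG1", type = "HydrogenDonor"),
  list(resid = c("THR"), atoms = "OG1", type = "HydrogenAcceptor"),
  list(resid = c("TYR"), atoms = "OH", type = "HydrogenDonor"),
  list(resid = c("ASN"), atoms = "OD1", type = "HydrogenAcceptor"),
  list(resid = c("ASN"), atoms = "ND2", type = "HydrogenDonor"),
  list(resid = c("GLN"), atoms = "OE1", type = "HydrogenAcceptor"),
  list(resid = c("GLN"), atoms = "NE2", type = "HydrogenDonor"),
  list(resid = c("HIS"), atoms = c("ND1"), type = "HydrogenDonor"),
  list(resid = c("PHE", "TYR"),
       atoms = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"), type = "Aromatic"),
  list(resid = c("HIS"),
       atoms = c("CG", "ND1", "CD2", "CE1", "NE2"), type = "Aromatic"),
  list(resid = c("TRP"),
       atoms = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"), type = "Aromatic"),
  list(resid = c("ALA", "VAL", "LEU", "ILE", "MET", "PRO"),
       atoms = c("CB", "CG", "CG1", "CG2", "CD", "CD1", "CD2", "CE", "SD"),
       type = "Hydrophobic")
)

#' Derive receptor interaction features from a PDB file
#'
#' Residue-level heuristics over protein coordinates (bio3d parser):
#' Asp/Glu carboxylates as negative centers, Lys/Arg amine/guanidinium as
#' positive, hydroxyl and amide side chains as donors/acceptors, aromatic
#' side-chain ring centroids, and aliphatic side-chain centroids as
#' hydrophobic points.
#'
#' @param path a PDB file.
#' @return feature data frame as from [detect_features()] (owners empty).
#' @export
receptor_features_from_pdb <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("receptor PDB parsing needs the bio3d package")
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  out <- list()
  for (rule in .pdb_feature_table) {
    sel <- at[at$resid %in% rule$resid & at$elety %in% rule$atoms, ]
    if (!nrow(sel)) next
    for (key in unique(paste(sel$chain, sel$resno))) {
      grp <- sel[paste(sel$chain, sel$resno) == key, ]
      if (rule$type %in% c("Aromatic", "NegativeIon", "PositiveIon",
                           "Hydrophobic") ||
          nrow(grp) == 1) {
        center <- colMeans(grp[, c("x", "y", "z")])
        out[[length(out) + 1L]] <- feature_row(rule$type, center, integer(0))
      } else {
        for (r in seq_len(nrow(grp))) {
          out[[length(out) + 1L]] <- feature_row(
            rule$type, as.numeric(grp[r, c("x", "y", "z")]), integer(0))
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(type = character(), x = numeric(), y = numeric(),
                      z = numeric(), owner = I(list())))
  }
  feats <- do.call(rbind, out)
  rownames(feats) <- NULL
  feats
}
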