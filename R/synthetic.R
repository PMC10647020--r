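#' Specification of a synthetic torsion-chain molecule
#'
#' Describes a linear heavy-atom chain with ideal bond lengths (1.54 A) and
#' tetrahedral angles (109.5 deg) whose conformational states are a discrete
#' set of dihedral angles per rotatable bond. The chain is hetero-decorated
#' (periodic O/N substitutions) so that automorphism groups stay small and
#' feature detection yields polar features; `hetero = FALSE` gives a pure
#' carbon chain for symmetry stress tests.
#'
#' @param n_torsions number of rotatable bonds (>= 1); the chain has
#'   `n_torsions + 3` heavy atoms.
#' @param states allowed dihedral angles in degrees, in `[-180, 180)`.
#' @param noise_sigma Cartesian jitter (A) applied per atom when sampling
#'   conformers.
#' @param seed integer seed for ensemble sampling.
#' @param hetero decorate the chain with O/N (default `TRUE`).
#' @return An object of class `torsion_chain_spec`.
#' @export
torsion_chain_spec <- function(n_torsions, states = c(-60, 60, -180),
                               noise_sigma = 0, seed = 1L, hetero = TRUE) {
  n_torsions <- as.integer(n_torsions)
  if (is.na(n_torsions) || n_torsions < 1L) stop("n_torsions must be >= 1")
  if (any(states < -180 | states >= 180)) stop("states must lie in [-180, 180)")
  if (length(unique(states)) < 2L) stop("need at least two torsion states")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(n_torsions = n_torsions, states = as.numeric(states),
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 hetero = isTRUE(hetero)),
            class = "torsion_chain_spec")
}

#' Cartesian coordinates of an ideal chain at given dihedrals
#'
#' Internal-to-Cartesian construction (natural extension reference frame):
#' every bond has the same length and every bond angle the same value;
#' dihedral angles are supplied per rotatable bond, placing atoms 4 onward.
#'
#' @param torsions_deg dihedral angles in degrees, one per rotatable bond;
#'   the chain has `length(torsions_deg) + 3` atoms.
#' @param bond_len bond length in Angstrom (default 1.54).
#' @param angle_deg bond angle in degrees (default 109.5).
#' @return numeric (n x 3) coordinate matrix.
#' @export
chain_coords <- function(torsions_deg, bond_len = 1.54, angle_deg = 109.5) {
  n <- length(torsions_deg) + 3L
  theta <- angle_deg * pi / 180
  xyz <- matrix(0, n, 3)
  xyz[2, ] <- c(bond_len, 0, 0)
  xyz[3, ] <- xyz[2, ] + bond_len * c(-cos(theta), sin(theta), 0)
  for (a in seq(4L, n)) {
    phi <- torsions_deg[a - 3L] * pi / 180
    A <- xyz[a - 3L, ]; B <- xyz[a - 2L, ]; C <- xyz[a - 1L, ]
    bc <- C - B; bc <- bc / sqrt(sum(bc^2))
    ab <- B - A; ab <- ab / sqrt(sum(ab^2))
    nv <- c(ab[2] * bc[3] - ab[3] * bc[2],
            ab[3] * bc[1] - ab[1] * bc[3],
            ab[1] * bc[2] - ab[2] * bc[1])
    nv <- nv / sqrt(sum(nv^2))
    mv <- c(nv[2] * bc[3] - nv[3] * bc[2],
            nv[3] * bc[1] - nv[1] * bc[3],
            nv[1] * bc[2] - nv[2] * bc[1])
    d <- bond_len * c(-cos(theta), sin(theta) * cos(phi), sin(theta) * sin(phi))
    xyz[a, ] <- C + d[1] * bc + d[2] * mv + d[3] * nv
  }
  xyz
}

#' Build a synthetic torsion-chain molecule and its reference conformer
#'
#' The reference ("bioactive") geometry places every rotatable bond at the
#' designated reference state (the last entry of `spec$states`). The
#' construction is fully deterministic given the spec.
#'
#' @param spec a [torsion_chain_spec].
#' @param name molecule name.
#' @return A list of class `torsion_chain` with `mol` ([mol_graph]),
#'   `reference` ([conformer] at the reference torsions), `ref_states`,
#'   `spec`.
#' @export
make_torsion_chain <- function(spec, name = "chain") {
  stopifnot(inherits(spec, "torsion_chain_spec"))
  n <- spec$n_torsions + 3L
  elements <- if (spec$hetero) {
    rep(c("C", "C", "O", "C", "C", "N"), length.out = n)
  } else rep("C", n)
  bonds <- data.frame(i = seq_len(n - 1L), j = seq(2L, n), order = 1)
  mol <- mol_graph(elements, bonds, name = name)
  ref_states <- rep(spec$states[length(spec$states)], spec$n_torsions)
  ref <- conformer(chain_coords(ref_states),
                   provenance = list(generator = "synthetic_reference",
                                     minimized = FALSE, sample = 0L))
  structure(list(mol = mol, reference = ref, ref_states = ref_states,
                 spec = spec),
            class = "torsion_chain")
}

# per-torsion state energies: non-reference states evenly spaced on [0, 2],
# the reference state at their mean, so that proximity to the reference
# carries no energy signal
state_energies <- function(states, ref_state) {
  nonref <- setdiff(states, ref_state)
  e <- setNames(seq(0, 2, length.out = length(nonref)), as.character(nonref))
  c(e, setNames(mean(e), as.character(ref_state)))
}

#' Sample a synthetic conformer ensemble around a torsion chain
#'
#' Each conformer is drawn by sampling torsion states and adding isotropic
#' Cartesian jitter. With probability `mixing_weight` a conformer sits at the
#' reference torsion vector ("near-reference" draw); otherwise every torsion
#' is sampled uniformly from the non-reference states, so a non-reference
#' draw never coincides with the reference geometry. Energies are a sum of
#' per-torsion potential terms whose minimum lies at a non-reference state
#' (plus Gaussian noise), making the energy ranking statistically
#' independent of distance to the reference: low energy does not mean
#' bioactive-like, by design.
#'
#' @param chain a `torsion_chain` from [make_torsion_chain()].
#' @param n_conf number of conformers (>= 1).
#' @param mixing_weight probability of a near-reference draw, in `[0, 1]`.
#' @param noise_sigma Cartesian jitter sd in A (default from the spec).
#' @param energy_noise sd of the additive Gaussian energy noise
#'   (kcal/mol-like units, default 0.2).
#' @param seed integer seed (default from the spec).
#' @return A [conf_ensemble]; each conformer's provenance records its
#'   `sample` index and whether it was an `at_reference` draw.
#' @export
make_ensemble <- function(chain, n_conf, mixing_weight = 0.1,
                          noise_sigma = NULL, energy_noise = 0.2,
                          seed = NULL) {
  stopifnot(inherits(chain, "torsion_chain"))
  n_conf <- as.integer(n_conf)
  if (n_conf < 1L) stop("n_conf must be >= 1")
  if (mixing_weight < 0 || mixing_weight > 1)
    stop("mixing_weight must lie in [0, 1]")
  spec <- chain$spec
  if (is.null(noise_sigma)) noise_sigma <- spec$noise_sigma
  if (is.null(seed)) seed <- spec$seed
  n_at <- n_atoms(chain$mol)
  e_tab <- state_energies(spec$states, chain$ref_states[1])
  confs <- with_seed_(seed, {
    lapply(seq_len(n_conf), function(s) {
      at_ref <- runif(1) < mixing_weight
      tors <- if (at_ref) chain$ref_states else {
        vapply(chain$ref_states, function(r)
          sample(setdiff(spec$states, r), 1L), numeric(1))
      }
      xyz <- chain_coords(tors)
      if (noise_sigma > 0)
        xyz <- xyz + matrix(rnorm(3 * n_at, sd = noise_sigma), n_at, 3)
      energy <- sum(e_tab[as.character(tors)]) + rnorm(1, sd = energy_noise)
      conformer(xyz, energy = energy,
                provenance = list(generator = "synthetic", minimized = FALSE,
                                  sample = s, at_reference = at_ref))
    })
  })
  conf_ensemble(chain$mol, confs)
}

#' Specification of a planted screening library
#'
#' Emulates a target-focused screening benchmark: actives carry a planted
#' 3-6-feature pharmacophore geometry in (at least) one conformer, decoys'
#' feature geometries differ from it by more than `tolerance + margin` under
#' every type-respecting correspondence, and a complementary receptor
#' feature set sits within interaction-cutoff distance of the planted
#' points.
#'
#' @param n_actives,n_decoys library composition (>= 1 each).
#' @param n_features planted feature count (3-6).
#' @param tolerance query tolerance radius in A (default 1.0).
#' @param margin separation margin in A (>= 0): actives realize the planted
#'   geometry within `tolerance - margin`, decoys miss it by more than
#'   `tolerance + margin`.
#' @param n_conf conformers per molecule.
#' @param active_jitter radius (A) of the displacement applied to actives'
#'   planted feature positions; must stay below `tolerance - margin`.
#' @param seed integer seed.
#' @return An object of class `planted_library_spec`.
#' @export
planted_library_spec <- function(n_actives = 20L, n_decoys = 80L,
                                 n_features = 4L, tolerance = 1.0,
                                 margin = 0.25, n_conf = 5L,
                                 active_jitter = 0, seed = 1L) {
  stopifnot(n_actives >= 1, n_decoys >= 1, n_features >= 3, n_features <= 6,
            tolerance > 0, margin >= 0, n_conf >= 1)
  if (active_jitter >= tolerance - margin)
    stop("active_jitter must stay below tolerance - margin")
  structure(list(n_actives = as.integer(n_actives),
                 n_decoys = as.integer(n_decoys),
                 n_features = as.integer(n_features),
                 tolerance = tolerance, margin = margin,
                 n_conf = as.integer(n_conf),
                 active_jitter = active_jitter, seed = as.integer(seed)),
            class = "planted_library_spec")
}

rand_unit <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

# k well-separated points in a bounded box: pairwise distances in about
# [4, 14] A, so a >= 16 A geometry can never be confused with them
sample_planted_points <- function(k, min_dist = 4, box = 8) {
  pts <- matrix(NA_real_, k, 3)
  pts[1, ] <- runif(3, 0, box)
  for (i in seq(2L, k)) {
    repeat {
      p <- runif(3, 0, box)
      d <- sqrt(rowSums((pts[seq_len(i - 1L), , drop = FALSE] -
                           matrix(p, i - 1L, 3, byrow = TRUE))^2))
      if (all(d >= min_dist)) {
        pts[i, ] <- p
        break
      }
    }
  }
  pts
}

# feature atom element/charge per planted class (all realizable by a single
# degree-1 substituent atom)
.planted_atom <- list(
  HydrogenDonor = list(element = "O", charge = 0L),
  HydrogenAcceptor = list(element = "O", charge = 0L),
  PositiveIon = list(element = "N", charge = 1L),
  NegativeIon = list(element = "O", charge = -1L)
)

# template molecule: per feature a C-C-C backbone block with the feature
# atom bonded to the middle carbon; blocks are chained head to tail
planted_template <- function(types, name) {
  k <- length(types)
  elements <- character(0); charges <- integer(0)
  bonds <- NULL
  feat_atoms <- integer(k)
  for (j in seq_len(k)) {
    base <- length(elements)
    spec_j <- .planted_atom[[types[j]]]
    elements <- c(elements, "C", "C", "C", spec_j$element)
    charges <- c(charges, 0L, 0L, 0L, spec_j$charge)
    blk <- data.frame(i = base + c(1L, 2L, 2L),
                      j = base + c(2L, 3L, 4L), order = 1)
    if (j > 1L) blk <- rbind(data.frame(i = base - 1L, j = base + 1L,
                                        order = 1), blk)
    bonds <- rbind(bonds, blk)
    feat_atoms[j] <- base + 4L
  }
  mol <- mol_graph(elements, bonds, charges = charges, name = name)
  list(mol = mol, feat_atoms = feat_atoms)
}

# coordinates for a template molecule with its feature atoms at `pts`
planted_conformer_coords <- function(template, pts) {
  n <- n_atoms(template$mol)
  k <- length(template$feat_atoms)
  xyz <- matrix(0, n, 3)
  for (j in seq_len(k)) {
    p <- pts[j, ]
    c2 <- p + 1.4 * rand_unit()
    c1 <- c2 + 1.54 * rand_unit()
    c3 <- c2 + 1.54 * rand_unit()
    base <- (j - 1L) * 4L
    xyz[base + 1L, ] <- c1
    xyz[base + 2L, ] <- c2
    xyz[base + 3L, ] <- c3
    xyz[base + 4L, ] <- p
  }
  xyz
}

# far-line geometry: consecutive spacings >= 19 A guarantee every pairwise
# feature distance exceeds any planted distance by > 2 (tolerance + margin)
far_line_points <- function(k) {
  d <- rand_unit()
  o <- runif(3, -5, 5)
  t(vapply(seq_len(k), function(j) o + (20 * j + runif(1)) * d, numeric(3)))
}

#' Generate a planted screening library
#'
#' Builds the planted pharmacophore geometry, a labeled library of
#' active/decoy conformer ensembles around it, the planted query and a
#' complementary receptor feature set (each receptor feature 3 A from its
#' ligand partner, within all interaction cutoffs). Every conformer gets an
#' independent synthetic energy so that energy-ranked selection policies are
#' applicable; the planted conformer sits at a random position of each
#' active's ensemble.
#'
#' @param spec a [planted_library_spec].
#' @return A list with `library` (entries `ensemble`/`active`/`name`, ready
#'   for [screen_library()]), `query` (the planted [pharm_query]),
#'   `receptor` (feature data frame), `reference` (the planted reference
#'   [conformer] of the template molecule), `template_mol`, `planted`
#'   (positions, types, per-active planted conformer index).
#' @export
make_screening_library <- function(spec) {
  stopifnot(inherits(spec, "planted_library_spec"))
  with_seed_(spec$seed, {
    k <- spec$n_features
    types <- sample(names(.planted_atom), k, replace = TRUE)
    pts <- sample_planted_points(k)
    template <- planted_template(types, "template")

    reference <- conformer(planted_conformer_coords(template, pts),
                           provenance = list(generator = "planted_reference"))
    qfeat <- data.frame(type = types, x = pts[, 1], y = pts[, 2],
                        z = pts[, 3], owner = I(as.list(template$feat_atoms)))
    query <- pharm_query(qfeat, tolerance = spec$tolerance, id = "planted")

    receptor <- do.call(rbind, lapply(seq_len(k), function(j) {
      comp <- .complementary$rec[.complementary$lig == types[j]]
      feature_row(comp, pts[j, ] + 3.0 * rand_unit(), integer(0))
    }))

    n_mol <- spec$n_actives + spec$n_decoys
    planted_at <- integer(spec$n_actives)
    library <- vector("list", n_mol)
    for (m in seq_len(n_mol)) {
      active <- m <= spec$n_actives
      tmpl <- planted_template(types, sprintf("%s%03d",
                                              if (active) "act" else "dec",
                                              m))
      confs <- vector("list", spec$n_conf)
      plant_idx <- if (active) sample.int(spec$n_conf, 1L) else 0L
      if (active) planted_at[m] <- plant_idx
      for (s in seq_len(spec$n_conf)) {
        if (active && s == plant_idx) {
          p <- pts
          if (spec$active_jitter > 0) {
            p <- p + t(vapply(seq_len(k), function(j)
              spec$active_jitter * runif(1) * rand_unit(), numeric(3)))
          }
          xyz <- planted_conformer_coords(tmpl, p)
        } else {
          xyz <- planted_conformer_coords(tmpl, far_line_points(k))
        }
        confs[[s]] <- conformer(xyz, energy = rnorm(1),
                                provenance = list(generator = "planted_library",
                                                  sample = s,
                                                  planted = active && s == plant_idx))
      }
      library[[m]] <- list(ensemble = conf_ensemble(tmpl$mol, confs),
                           active = active, name = tmpl$mol$name)
    }
    list(library = library, query = query, receptor = receptor,
         reference = reference, template_mol = template$mol,
         planted = list(positions = pts, types = types,
                        conformer_index = planted_at))
  })
}
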