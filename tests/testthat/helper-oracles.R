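# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths: superposition via the Horn quaternion
# method (closed-form eigenproblem) instead of SVD, automorphisms via plain
# enumeration of within-class permutations, matching via exhaustive
# correspondence search without pruning.

# Horn (1987) quaternion superposition: proper rotation + translation
# minimizing least-squares distance of P onto Q. Returns rotation, rmsd.
horn_superpose <- function(P, Q) {
  n <- nrow(P)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  if (n == 1) return(list(rotation = diag(3), rmsd = 0))
  M <- t(Pc) %*% Qc
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  K <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,    -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,    -Sxx-Syy+Szz), 4, 4)
  eig <- eigen(K, symmetric = TRUE)
  q <- eig$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w*w+x*x-y*y-z*z, 2*(x*y-w*z),     2*(x*z+w*y),
    2*(x*y+w*z),     w*w-x*x+y*y-z*z, 2*(y*z-w*x),
    2*(x*z-w*y),     2*(y*z+w*x),     w*w-x*x-y*y+z*z), 3, 3, byrow = TRUE)
  msd <- (sum(Pc^2) + sum(Qc^2) - 2 * eig$values[1]) / n
  list(rotation = R, rmsd = sqrt(max(msd, 0)),
       translation = cq - as.numeric(R %*% cp))
}

plain_rmsd_r <- function(A, B) sqrt(mean(rowSums((A - B)^2)))

# all permutations of 1:n (small n only)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  out <- NULL
  for (i in seq_len(n)) {
    sub <- all_perms(n - 1L)
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# enumerate every element/charge-preserving permutation and keep the ones
# preserving the bond multiset with orders
brute_valid_perms <- function(mol, heavy_only = TRUE) {
  atoms <- if (heavy_only) heavy_atoms(mol) else seq_len(n_atoms(mol))
  k <- length(atoms)
  cls <- paste(mol$elements[atoms], mol$charges[atoms])
  # adjacency with order code
  A <- matrix(0, k, k)
  b <- mol$bonds
  for (r in seq_len(NROW(b))) {
    i <- match(b$i[r], atoms); j <- match(b$j[r], atoms)
    if (is.na(i) || is.na(j)) next
    A[i, j] <- A[j, i] <- b$order[r]
  }
  groups <- split(seq_len(k), cls)
  # cartesian product of within-group permutations
  group_perms <- lapply(groups, function(g) {
    gp <- all_perms(length(g))
    matrix(g[gp], nrow(gp))
  })
  idx <- lapply(group_perms, function(m) seq_len(nrow(m)))
  combos <- expand.grid(idx)
  keep <- list()
  for (r in seq_len(nrow(combos))) {
    perm <- integer(k)
    for (gi in seq_along(groups)) {
      perm[groups[[gi]]] <- group_perms[[gi]][combos[r, gi][[1]], ]
    }
    if (all(A[perm, perm] == A)) keep[[length(keep) + 1L]] <- perm
  }
  do.call(rbind, keep)
}

# brute-force symmetry-corrected rmsd over ALL valid permutations, Horn
# superposition inside
brute_symmetry_rmsd <- function(a, b, mol, align = TRUE, heavy_only = TRUE) {
  atoms <- if (heavy_only) heavy_atoms(mol) else seq_len(n_atoms(mol))
  perms <- brute_valid_perms(mol, heavy_only)
  A <- a$coords[atoms, , drop = FALSE]
  B <- b$coords[atoms, , drop = FALSE]
  min(apply(perms, 1, function(p) {
    Bp <- B[p, , drop = FALSE]
    if (align) horn_superpose(A, Bp)$rmsd else plain_rmsd_r(A, Bp)
  }))
}

# random labeled tree molecule (n heavy atoms); sequential random attachment
random_tree_mol <- function(n, elements = c("C", "N", "O"), name = "rnd") {
  el <- sample(elements, n, replace = TRUE)
  bonds <- NULL
  if (n > 1) {
    parent <- vapply(seq(2L, n), function(i) sample.int(i - 1L, 1L), integer(1))
    bonds <- data.frame(i = parent, j = seq(2L, n), order = 1)
  }
  mol_graph(el, bonds, name = name)
}

random_conformer <- function(mol, scale = 2) {
  conformer(matrix(rnorm(3 * n_atoms(mol), sd = scale), n_atoms(mol), 3))
}

# uniform random proper rotation (normalized quaternion)
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    w*w+x*x-y*y-z*z, 2*(x*y-w*z),     2*(x*z+w*y),
    2*(x*y+w*z),     w*w-x*x+y*y-z*z, 2*(y*z-w*x),
    2*(x*z-w*y),     2*(y*z+w*x),     w*w-x*x-y*y+z*z), 3, 3, byrow = TRUE)
}

rigid_transform <- function(coords, R = random_rotation(),
                            t = rnorm(3, sd = 5)) {
  sweep(coords %*% t(R), 2, t, "+")
}

# step-by-step trace of the greedy energy-sorted RMSD filter, coded
# directly from its verbal description (independent of the C++ kernel)
greedy_trace <- function(ens, max_n, threshold) {
  e <- ens_energies(ens)
  ord <- order(e, seq_along(e))
  selected <- integer(0)
  for (cand in ord) {
    if (length(selected) >= max_n) break
    ok <- TRUE
    for (s in selected) {
      r <- symmetry_rmsd(ens$conformers[[s]], ens$conformers[[cand]],
                         ens$molecule, align = TRUE)
      if (r <= threshold) { ok <- FALSE; break }
    }
    if (ok) selected <- c(selected, cand)
  }
  selected
}

# exhaustive correspondence enumeration + Horn superposition residual test:
# the matcher oracle (no pruning, no backtracking shortcuts)
brute_match <- function(query, feats) {
  k <- nrow(query$features)
  if (!NROW(feats)) return(FALSE)
  qxyz <- as.matrix(query$features[, c("x", "y", "z")])
  fxyz <- as.matrix(feats[, c("x", "y", "z")])
  radii <- query$features$radius
  cand <- lapply(seq_len(k), function(i) which(feats$type == query$features$type[i]))
  if (any(!lengths(cand))) return(FALSE)
  assignments <- list()
  build <- function(pos, cur) {
    if (pos > k) { assignments[[length(assignments) + 1L]] <<- cur; return() }
    for (a in cand[[pos]]) if (!a %in% cur) build(pos + 1L, c(cur, a))
  }
  build(1L, integer(0))
  for (asg in assignments) {
    P <- fxyz[asg, , drop = FALSE]
    sup <- horn_superpose(P, qxyz)
    placed <- P %*% t(sup$rotation) +
      matrix(sup$translation, k, 3, byrow = TRUE)
    if (all(sqrt(rowSums((placed - qxyz)^2)) <= radii + 1e-9)) return(TRUE)
  }
  FALSE
}

# minimum over type-respecting correspondences of the maximum pairwise
# distance-matrix deviation: > 2 * tol implies no rigid placement can match
# (triangle inequality), independent of any matcher
min_correspondence_deviation <- function(query, feats) {
  k <- nrow(query$features)
  qxyz <- as.matrix(query$features[, c("x", "y", "z")])
  fxyz <- as.matrix(feats[, c("x", "y", "z")])
  cand <- lapply(seq_len(k), function(i) which(feats$type == query$features$type[i]))
  if (any(!lengths(cand))) return(Inf)
  qd <- as.matrix(dist(qxyz)); fd <- as.matrix(dist(fxyz))
  best <- Inf
  rec <- function(pos, cur) {
    if (pos > k) {
      dev <- max(abs(qd[seq_len(k), seq_len(k)] - fd[cur, cur]))
      best <<- min(best, dev)
      return()
    }
    for (a in cand[[pos]]) if (!a %in% cur) rec(pos + 1L, c(cur, a))
  }
  rec(1L, integer(0))
  best
}

# tiny valid single-record SDF text used by I/O tests
ethanol_sdf_lines <- function(name = "ethanol", energy = NULL) {
  lines <- c(
    name, "  confscreen", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5400    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.0500    1.4500    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "  2  3  1  0  0  0  0",
    "M  END")
  if (!is.null(energy)) lines <- c(lines, "> <energy>", format(energy), "")
  c(lines, "$$$$")
}
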