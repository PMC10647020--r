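#' Ensemble selection policy
#'
#' Parameterizes how a sub-ensemble is drawn from a full conformer ensemble.
#' Three policies are supported: `unbiased` (uniform random sample without
#' replacement), `lowest_energy` (the N lowest-energy conformers) and
#' `energy_rmsd_filtered` (ascending-energy greedy selection keeping only
#' conformers farther than an RMSD threshold from everything already kept).
#'
#' @param kind one of `"unbiased"`, `"lowest_energy"`,
#'   `"energy_rmsd_filtered"`.
#' @param max_n target sub-ensemble size (>= 1).
#' @param rmsd_threshold RMSD threshold in Angstrom; required (and only
#'   allowed) for `energy_rmsd_filtered`.
#' @param seed integer RNG seed; required (and only allowed) for `unbiased`.
#' @return An object of class `selection_policy`.
#' @export
selection_policy <- function(kind, max_n,
                             rmsd_threshold = NULL, seed = NULL) {
  kind <- match.arg(kind, c("unbiased", "lowest_energy",
                            "energy_rmsd_filtered"))
  max_n <- as.integer(max_n)
  if (is.na(max_n) || max_n < 1L) stop("max_n must be >= 1")
  if (kind == "energy_rmsd_filtered") {
    if (is.null(rmsd_threshold) || rmsd_threshold <= 0)
      stop("energy_rmsd_filtered needs rmsd_threshold > 0")
  } else if (!is.null(rmsd_threshold)) {
    stop("rmsd_threshold only applies to energy_rmsd_filtered")
  }
  if (kind == "unbiased") {
    if (is.null(seed)) stop("unbiased selection needs a seed")
  } else if (!is.null(seed)) {
    stop("seed only applies to unbiased selection")
  }
  structure(list(kind = kind, max_n = max_n,
                 rmsd_threshold = rmsd_threshold, seed = seed),
            class = "selection_policy")
}

#' @export
print.selection_policy <- function(x, ...) {
  extra <- switch(x$kind,
    energy_rmsd_filtered = sprintf(", threshold %.2f A", x$rmsd_threshold),
    unbiased = sprintf(", seed %d", x$seed), "")
  cat(sprintf("<selection_policy> %s, max_n %d%s\n", x$kind, x$max_n, extra))
  invisible(x)
}

#' Uniform random sub-ensemble
#'
#' Samples `min(max_n, length(ens))` conformers uniformly without
#' replacement; the output preserves original generation order. Deterministic
#' given `seed`; the caller's RNG state is untouched.
#'
#' @param ens a [conf_ensemble].
#' @param max_n sample size cap.
#' @param seed integer seed.
#' @return A [conf_ensemble].
#' @export
select_unbiased <- function(ens, max_n, seed) {
  stopifnot(inherits(ens, "conf_ensemble"))
  n <- length(ens)
  if (n == 0L) stop("cannot select from an empty ensemble")
  k <- min(as.integer(max_n), n)
  idx <- with_seed_(seed, sort(sample.int(n, k)))
  ens[idx]
}

check_energies <- function(ens) {
  e <- ens_energies(ens)
  if (anyNA(e)) {
    stop(sprintf("conformer(s) %s lack an energy; energy-based selection refuses to guess",
                 paste(which(is.na(e)), collapse = ", ")))
  }
  e
}

# ascending energy, ties by original index
energy_order <- function(e) order(e, seq_along(e))

#' Lowest-energy sub-ensemble
#'
#' The `min(max_n, length(ens))` conformers of lowest energy, in ascending
#' energy order; energy ties are broken by original generation index (lower
#' first).
#'
#' @inheritParams select_unbiased
#' @return A [conf_ensemble]; errors if any conformer lacks an energy.
#' @export
select_lowest_energy <- function(ens, max_n) {
  stopifnot(inherits(ens, "conf_ensemble"))
  if (length(ens) == 0L) stop("cannot select from an empty ensemble")
  e <- check_energies(ens)
  ens[head(energy_order(e), min(as.integer(max_n), length(ens)))]
}

#' Energy-sorted greedy RMSD-diversity sub-ensemble
#'
#' Conformers are sorted by increasing energy and greedily added to the
#' selected subset only if their symmetry-corrected RMSD to every already
#' selected conformer exceeds `threshold`. Selection stops at `max_n` or at
#' the end of the list, so the result may hold fewer than `max_n` conformers
#' (aggressive thresholds can shrink an ensemble drastically). The first
#' selected conformer is always the global energy minimum.
#'
#' @inheritParams select_unbiased
#' @param threshold RMSD threshold in Angstrom (> 0).
#' @param align use Kabsch-minimized RMSD inside the filter (default `TRUE`,
#'   the single RMSD convention used throughout).
#' @param heavy_only compare heavy atoms only (default `TRUE`).
#' @return A [conf_ensemble] in ascending energy order.
#' @export
select_energy_rmsd_filtered <- function(ens, max_n, threshold,
                                        align = TRUE, heavy_only = TRUE) {
  stopifnot(inherits(ens, "conf_ensemble"))
  if (length(ens) == 0L) stop("cannot select from an empty ensemble")
  if (threshold <= 0) stop("threshold must be > 0")
  e <- check_energies(ens)
  autos <- find_automorphisms(ens$molecule, heavy_only = heavy_only)
  atoms <- attr(autos, "atoms")
  coords <- lapply(ens$conformers,
                   function(cf) cf$coords[atoms, , drop = FALSE])
  kept <- cpp_greedy_filter(coords, energy_order(e), autos,
                            threshold, as.integer(max_n), align)
  ens[kept]
}

#' Apply a selection policy to an ensemble
#'
#' Dispatches to [select_unbiased()], [select_lowest_energy()] or
#' [select_energy_rmsd_filtered()] according to `policy$kind`. The output is
#' always a sub-multiset of the input conformers with provenance retained.
#'
#' @param ens a [conf_ensemble].
#' @param policy a [selection_policy].
#' @return A [conf_ensemble].
#' @export
apply_policy <- function(ens, policy) {
  stopifnot(inherits(policy, "selection_policy"))
  switch(policy$kind,
    unbiased = select_unbiased(ens, policy$max_n, policy$seed),
    lowest_energy = select_lowest_energy(ens, policy$max_n),
    energy_rmsd_filtered = select_energy_rmsd_filtered(
      ens, policy$max_n, policy$rmsd_threshold)
  )
}
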