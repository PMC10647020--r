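#' Best symmetry-corrected RMSD of an ensemble to a reference conformer
#'
#' The minimum over all conformers of the (by default aligned, heavy-atom)
#' symmetry-corrected RMSD to the reference, i.e. the best possible RMSD
#' across the ensemble.
#'
#' @param ens a nonempty [conf_ensemble].
#' @param ref the reference [conformer] (e.g. a crystal geometry).
#' @param align,heavy_only see [symmetry_rmsd()].
#' @return RMSD in Angstrom.
#' @export
best_rmsd <- function(ens, ref, align = TRUE, heavy_only = TRUE) {
  stopifnot(inherits(ens, "conf_ensemble"))
  if (length(ens) == 0L) stop("empty ensemble")
  autos <- find_automorphisms(ens$molecule, heavy_only = heavy_only)
  min(vapply(ens$conformers, function(cf) {
    as.numeric(symmetry_rmsd(cf, ref, ens$molecule, align = align,
                             heavy_only = heavy_only, autos = autos))
  }, numeric(1)))
}

#' Fraction of molecules retrieved within an RMSD threshold
#' @param best_rmsds numeric vector of per-molecule best RMSDs (Angstrom).
#' @param threshold RMSD cutoff in Angstrom.
#' @return the proportion with best RMSD `<= threshold`.
#' @export
retrieval_fraction <- function(best_rmsds, threshold) {
  if (!length(best_rmsds)) stop("empty input")
  mean(best_rmsds <= threshold)
}

#' Recovery curve over an RMSD threshold grid
#'
#' Pointwise [retrieval_fraction()]; non-decreasing in the threshold by
#' construction.
#'
#' @param best_rmsds numeric vector of per-molecule best RMSDs.
#' @param thresholds increasing numeric grid of cutoffs (Angstrom).
#' @return a data frame with columns `threshold` and `fraction`.
#' @export
recovery_curve <- function(best_rmsds, thresholds) {
  if (!length(best_rmsds) || !length(thresholds)) stop("empty input")
  data.frame(threshold = thresholds,
             fraction = vapply(thresholds,
                               function(t) retrieval_fraction(best_rmsds, t),
                               numeric(1)))
}

#' Confusion counts and classification metrics for a screen
#'
#' Precision and recall are taken as 0 when undefined (no predicted or no
#' actual positives); F1 is the harmonic mean of precision and recall, 0
#' when either is undefined.
#'
#' @param match_flags logical per-molecule match flags for one query.
#' @param labels logical active (TRUE) / decoy (FALSE) labels, same length.
#' @param query_id,n_features optional bookkeeping carried through to
#'   [best_f1()] tie-breaking.
#' @return An object of class `screen_metrics`: list with `tp`, `fp`, `fn`,
#'   `tn`, `precision`, `recall`, `f1`.
#' @export
confusion <- function(match_flags, labels, query_id = NA_character_,
                      n_features = NA_integer_) {
  if (length(match_flags) != length(labels))
    stop("match flags and labels differ in length")
  match_flags <- as.logical(match_flags)
  labels <- as.logical(labels)
  tp <- sum(labels & match_flags)
  fp <- sum(!labels & match_flags)
  fn <- sum(labels & !match_flags)
  tn <- sum(!labels & !match_flags)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 precision = precision, recall = recall, f1 = f1,
                 query_id = query_id, n_features = n_features),
            class = "screen_metrics")
}

#' @export
print.screen_metrics <- function(x, ...) {
  cat(sprintf("<screen_metrics> tp %d fp %d fn %d tn %d | P %.3f R %.3f F1 %.3f\n",
              x$tp, x$fp, x$fn, x$tn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Best-F1 entry across queries
#'
#' Returns the per-query metrics entry with maximal F1; ties are broken by
#' fewer query features, then lexicographically by query id (the simplest
#' query wins).
#'
#' @param per_query_metrics nonempty list of `screen_metrics`.
#' @return the winning `screen_metrics` entry.
#' @export
best_f1 <- function(per_query_metrics) {
  if (!length(per_query_metrics)) stop("no metrics to compare")
  f1 <- vapply(per_query_metrics, function(m) m$f1, numeric(1))
  nf <- vapply(per_query_metrics, function(m)
    if (is.na(m$n_features)) Inf else m$n_features, numeric(1))
  id <- vapply(per_query_metrics, function(m)
    if (is.na(m$query_id)) "" else m$query_id, character(1))
  ord <- order(-f1, nf, id)
  per_query_metrics[[ord[1]]]
}

#' Screen a library over a grid of selection policies
#'
#' For each grid cell the per-molecule ensembles are re-selected with the
#' selection module, the library is re-screened against all queries and the
#' best F1 over queries is reported (with the full per-query table
#' available).
#'
#' @param library labeled library as for [screen_library()]; every entry's
#'   full ensemble is re-subset per cell.
#' @param queries list of [pharm_query] objects.
#' @param grid data frame with columns `kind`, `max_n` and optionally
#'   `rmsd_threshold`, `seed` (per-cell [selection_policy()] arguments).
#' @param rules feature detection rules.
#' @return A data frame, one row per cell: policy columns plus `best_f1`,
#'   `precision`, `recall`, `tp`, `fp`, `fn`, `tn`, `query_id`,
#'   `n_features`. The per-cell per-query metrics are attached as
#'   `attr(, "per_query")` (a list of lists of `screen_metrics`).
#' @export
sweep_screen <- function(library, queries, grid, rules = feature_rules()) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  rows <- list()
  per_query_all <- list()
  for (g in seq_len(nrow(grid))) {
    pol <- selection_policy(
      kind = as.character(grid$kind[g]),
      max_n = grid$max_n[g],
      rmsd_threshold = if ("rmsd_threshold" %in% names(grid) &&
                           !is.na(grid$rmsd_threshold[g]))
        grid$rmsd_threshold[g] else NULL,
      seed = if ("seed" %in% names(grid) && !is.na(grid$seed[g]))
        grid$seed[g] else NULL
    )
    sub <- lapply(library, function(entry) {
      entry$ensemble <- apply_policy(entry$ensemble, pol)
      entry
    })
    flags <- screen_library(queries, sub, rules = rules)
    labels <- attr(flags, "labels")
    pq <- lapply(seq_along(queries), function(qi) {
      confusion(flags[qi, ], labels, query_id = queries[[qi]]$id,
                n_features = nrow(queries[[qi]]$features))
    })
    bst <- best_f1(pq)
    rows[[g]] <- data.frame(
      kind = pol$kind, max_n = pol$max_n,
      rmsd_threshold = if (is.null(pol$rmsd_threshold)) NA_real_
                       else pol$rmsd_threshold,
      best_f1 = bst$f1, precision = bst$precision, recall = bst$recall,
      tp = bst$tp, fp = bst$fp, fn = bst$fn, tn = bst$tn,
      query_id = bst$query_id, n_features = bst$n_features)
    per_query_all[[g]] <- pq
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_query") <- per_query_all
  out
}

#' Docking success rate at an RMSD cutoff
#'
#' The fraction of systems whose top-ranked docked pose lies within `cutoff`
#' of the reference pose. RMSD is symmetry-corrected but, by default,
#' computed without optimal alignment since docked poses and references
#' share the receptor coordinate frame.
#'
#' @param items list of entries, each a list with `pose` ([conformer]),
#'   `reference` ([conformer]) and `mol` ([mol_graph]).
#' @param cutoff RMSD cutoff in Angstrom (default 2.0).
#' @param align superpose before comparing (default `FALSE`).
#' @return the success fraction with attributes `rmsds` (per-item RMSD) and
#'   `excluded` (indices of items with mismatched atoms, reported and
#'   dropped).
#' @export
docking_success <- function(items, cutoff = 2.0, align = FALSE) {
  if (!length(items)) stop("no pose/reference pairs")
  rmsds <- rep(NA_real_, length(items))
  excluded <- integer(0)
  for (k in seq_along(items)) {
    it <- items[[k]]
    r <- tryCatch(
      as.numeric(symmetry_rmsd(it$pose, it$reference, it$mol, align = align)),
      error = function(e) NA_real_)
    if (is.na(r)) excluded <- c(excluded, k) else rmsds[k] <- r
  }
  if (length(excluded))
    message(sprintf("excluded %d pose/reference pair(s) with mismatched atoms",
                    length(excluded)))
  ok <- rmsds[!is.na(rmsds)]
  if (!length(ok)) stop("no comparable pose/reference pairs")
  structure(mean(ok < cutoff), rmsds = rmsds, excluded = excluded)
}

#' Percentile bootstrap confidence interval for a success rate
#'
#' Resamples the binary outcomes with replacement `n_boot` times and takes
#' the empirical `(1 - level)/2` and `(1 + level)/2` quantiles of the
#' success fraction. Deterministic given `seed`.
#'
#' @param outcomes nonempty logical/binary vector.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return An object of class `bootstrap_ci`: list with `point`, `lower`,
#'   `upper`, `level`, `n_boot`, `seed`.
#' @export
bootstrap_ci <- function(outcomes, n_boot = 1000L, level = 0.95, seed = 1L) {
  outcomes <- as.numeric(outcomes)
  n <- length(outcomes)
  if (n == 0L) stop("empty outcomes")
  stats <- with_seed_(seed, {
    draws <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    rowMeans(matrix(outcomes[draws], nrow = n_boot))
  })
  qs <- unname(quantile(stats, c((1 - level) / 2, (1 + level) / 2),
                        type = 7))
  structure(list(point = mean(outcomes), lower = qs[1], upper = qs[2],
                 level = level, n_boot = n_boot, seed = seed),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("<bootstrap_ci> %.4f [%.4f, %.4f] (%d%%, %d resamples)\n",
              x$point, x$lower, x$upper, round(100 * x$level), x$n_boot))
  invisible(x)
}

#' Downsample protein-ligand pairs per target
#'
#' Uniform sample without replacement of at most `max_per_target` pairs per
#' target (targets with fewer pairs are kept whole); used to avoid
#' over-weighting targets with many structures in cross-docking statistics.
#' Deterministic given `seed`.
#'
#' @param pairs_by_target named list mapping target to a vector/list of
#'   pairs.
#' @param max_per_target cap per target (default 100).
#' @param seed integer seed.
#' @return a named list with the downsampled pairs per target.
#' @export
downsample_pairs <- function(pairs_by_target, max_per_target = 100L,
                             seed = 1L) {
  if (!length(pairs_by_target)) stop("empty mapping")
  with_seed_(seed, {
    lapply(pairs_by_target, function(pairs) {
      n <- length(pairs)
      if (n <= max_per_target) return(pairs)
      pairs[sort(sample.int(n, max_per_target))]
    })
  })
}
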