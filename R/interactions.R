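#' Default ligand-receptor interaction distance cutoffs
#'
#' Center-to-center cutoffs (Angstrom) for the four complementary
#' interaction classes; all configurable.
#'
#' @return named numeric vector with entries `donor_acceptor`, `ionic`,
#'   `aromatic`, `hydrophobic`.
#' @export
interaction_cutoffs <- function() {
  c(donor_acceptor = 4.0, ionic = 5.0, aromatic = 5.0, hydrophobic = 5.0)
}

# complementary (ligand type, receptor type) -> cutoff class
.complementary <- data.frame(
  lig = c("HydrogenDonor", "HydrogenAcceptor", "Hydrophobic", "Aromatic",
          "PositiveIon", "NegativeIon"),
  rec = c("HydrogenAcceptor", "HydrogenDonor", "Hydrophobic", "Aromatic",
          "NegativeIon", "PositiveIon"),
  class = c("donor_acceptor", "donor_acceptor", "hydrophobic", "aromatic",
            "ionic", "ionic")
)

#' Detect ligand-receptor interactions between two feature sets
#'
#' Pairs every ligand feature with every receptor feature of the
#' complementary class (Donor-Acceptor, Hydrophobic-Hydrophobic,
#' Positive-Negative, Aromatic-Aromatic) whose center-center distance lies
#' within the class cutoff. A ligand feature may take part in several
#' interactions but contributes once to the query feature pool.
#'
#' @param lig ligand feature data frame (from [detect_features()]).
#' @param rec receptor feature data frame.
#' @param cutoffs named cutoff vector, see [interaction_cutoffs()].
#' @return An object of class `interaction_profile`: a list with `entries`
#'   (data frame: `lig_idx`, `rec_idx`, `lig_type`, `rec_type`, `distance`),
#'   `lig_features` and `rec_features`.
#' @export
detect_interactions <- function(lig, rec, cutoffs = interaction_cutoffs()) {
  if (!nrow(lig) || !nrow(rec)) stop("both feature sets must be nonempty")
  lc <- feature_coords(lig)
  rc <- feature_coords(rec)
  rows <- list()
  for (li in seq_len(nrow(lig))) {
    comp <- .complementary[.complementary$lig == lig$type[li], ]
    if (!nrow(comp)) next
    cand <- which(rec$type == comp$rec)
    if (!length(cand)) next
    d <- sqrt(colSums((t(rc[cand, , drop = FALSE]) - lc[li, ])^2))
    ok <- d <= cutoffs[[comp$class]]
    for (m in which(ok)) {
      rows[[length(rows) + 1L]] <- data.frame(
        lig_idx = li, rec_idx = cand[m], lig_type = lig$type[li],
        rec_type = rec$type[cand[m]], distance = d[m])
    }
  }
  entries <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lig_idx = integer(), rec_idx = integer(),
               lig_type = character(), rec_type = character(),
               distance = numeric())
  rownames(entries) <- NULL
  structure(list(entries = entries, lig_features = lig, rec_features = rec),
            class = "interaction_profile")
}

#' @export
print.interaction_profile <- function(x, ...) {
  cat(sprintf("<interaction_profile> %d interactions over %d ligand / %d receptor features\n",
              nrow(x$entries), nrow(x$lig_features), nrow(x$rec_features)))
  invisible(x)
}

#' Pharmacophore query
#'
#' At least three typed feature points (positions from a reference ligand
#' conformer) with a tolerance radius per feature and no directional
#' constraints.
#'
#' @param features feature data frame; an optional `radius` column overrides
#'   the global tolerance per feature.
#' @param tolerance global tolerance radius in Angstrom (default 1.0).
#' @param id optional identifier string.
#' @return An object of class `pharm_query`.
#' @export
pharm_query <- function(features, tolerance = 1.0, id = NULL) {
  if (nrow(features) < 3L) stop("a pharmacophore query needs >= 3 features")
  if (tolerance <= 0) stop("tolerance must be > 0")
  bad <- setdiff(unique(features$type), feature_types())
  if (length(bad)) stop("unknown feature class: ", paste(bad, collapse = ", "))
  if (!"radius" %in% names(features)) features$radius <- tolerance
  if (is.null(id)) id <- paste0("q", nrow(features), "f")
  structure(list(features = features, tolerance = tolerance, id = id),
            class = "pharm_query")
}

#' @export
print.pharm_query <- function(x, ...) {
  cat(sprintf("<pharm_query> %s: %d features (%s), tolerance %.2f A\n",
              x$id, nrow(x$features),
              paste(x$features$type, collapse = ", "), x$tolerance))
  invisible(x)
}

#' Enumerate all pharmacophore queries from an interaction profile
#'
#' The distinct interacting ligand features (deduplicated by class and owner
#' atom set) form the feature pool; one query is produced per subset of size
#' `min_features` to `max_features` (pool size when `NULL`), in
#' lexicographic order by feature index. Feature positions are those of the
#' reference ligand conformer the profile was computed from.
#'
#' @param profile an `interaction_profile` from [detect_interactions()].
#' @param min_features minimum query size (default 3).
#' @param max_features maximum query size, `NULL` for the pool size.
#' @param tolerance tolerance radius applied to every feature (default 1.0).
#' @return A list of [pharm_query] objects; empty (with a message) when the
#'   pool is smaller than `min_features`.
#' @export
enumerate_queries <- function(profile, min_features = 3L, max_features = NULL,
                              tolerance = 1.0) {
  stopifnot(inherits(profile, "interaction_profile"))
  pool_idx <- sort(unique(profile$entries$lig_idx))
  feats <- profile$lig_features[pool_idx, , drop = FALSE]
  # dedupe by (class, owner set)
  key <- paste(feats$type,
               vapply(feats$owner, function(o) paste(o, collapse = "+"),
                      character(1)))
  keep <- !duplicated(key)
  feats <- feats[keep, , drop = FALSE]
  pool <- nrow(feats)
  if (pool < min_features) {
    message(sprintf("feature pool (%d) smaller than min_features (%d); no queries",
                    pool, min_features))
    return(list())
  }
  if (is.null(max_features)) max_features <- pool
  max_features <- min(max_features, pool)
  queries <- list()
  for (k in seq(min_features, max_features)) {
    subsets <- combn(pool, k)
    for (cidx in seq_len(ncol(subsets))) {
      sel <- subsets[, cidx]
      q <- pharm_query(feats[sel, , drop = FALSE], tolerance = tolerance,
                       id = sprintf("k%d_%s", k, paste(sel, collapse = ".")))
      queries[[length(queries) + 1L]] <- q
    }
  }
  queries
}
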