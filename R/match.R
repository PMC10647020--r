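#' Match a pharmacophore query against a rigid conformer's features
#'
#' Tests whether an injective, type-respecting correspondence from query
#' features to conformer features exists together with a proper rigid
#' transform placing every matched conformer feature within the tolerance
#' radius of its query feature. Matching is rigid: no torsional change is
#' considered. Two stages: (i) backtracking over correspondences pruned by
#' pairwise-distance compatibility (`|d_query(i,j) - d_conf(a,b)| <=
#' radius_i + radius_j`, a sound triangle-inequality bound); (ii) Kabsch
#' superposition of the matched point sets with a per-feature residual test,
#' which defines the match.
#'
#' @param query a [pharm_query].
#' @param feats conformer feature data frame (from [detect_features()]).
#' @return `TRUE`/`FALSE`; on success carries `attr(, "witness")` (data
#'   frame mapping query feature to conformer feature index) and
#'   `attr(, "transform")` (the superposition placing the conformer features
#'   onto the query).
#' @export
match_query <- function(query, feats) {
  stopifnot(inherits(query, "pharm_query"))
  k <- nrow(query$features)
  if (!NROW(feats)) return(FALSE)
  qxyz <- feature_coords(query$features)
  fxyz <- feature_coords(feats)
  radii <- query$features$radius
  cand <- lapply(seq_len(k), function(i) which(feats$type == query$features$type[i]))
  if (any(!lengths(cand))) return(FALSE)
  ord <- order(lengths(cand))
  qd <- as.matrix(stats::dist(qxyz))
  fd <- as.matrix(stats::dist(fxyz))

  assign <- integer(k)  # query index -> feature index (0 = unset)
  found <- FALSE
  witness <- NULL
  transform <- NULL
  recurse <- function(pos) {
    if (found) return()
    if (pos > k) {
      P <- fxyz[assign, , drop = FALSE]
      sup <- kabsch_superpose(P, qxyz)
      placed <- P %*% t(sup$rotation) +
        matrix(sup$translation, k, 3, byrow = TRUE)
      resid <- sqrt(rowSums((placed - qxyz)^2))
      if (all(resid <= radii + 1e-9)) {
        found <<- TRUE
        witness <<- data.frame(query = seq_len(k), feature = assign)
        transform <<- sup
      }
      return()
    }
    i <- ord[pos]
    for (a in cand[[i]]) {
      if (a %in% assign) next
      ok <- TRUE
      for (prev in seq_len(pos - 1L)) {
        j <- ord[prev]
        if (abs(qd[i, j] - fd[a, assign[j]]) > radii[i] + radii[j]) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
      assign[i] <<- a
      recurse(pos + 1L)
      assign[i] <<- 0L
      if (found) return()
    }
  }
  recurse(1L)
  if (!found) return(FALSE)
  structure(TRUE, witness = witness, transform = transform)
}

#' Screen a labeled conformer library against pharmacophore queries
#'
#' A molecule matches a query iff any conformer of its (selected) ensemble
#' matches; features are detected once per conformer and reused across
#' queries. Molecules with empty ensembles never match and are reported.
#'
#' @param queries list of [pharm_query] objects.
#' @param library list of entries, each a list with `ensemble` (a
#'   [conf_ensemble]), `active` (logical label) and optionally `name`.
#' @param rules feature detection rules, see [feature_rules()].
#' @return A logical matrix (queries x molecules) of match flags with
#'   `attr(, "labels")` the active/decoy labels and `attr(, "empty")` the
#'   indices of empty ensembles.
#' @export
screen_library <- function(queries, library, rules = feature_rules()) {
  if (!length(queries) || !length(library))
    stop("queries and library must be nonempty")
  nq <- length(queries)
  nm <- length(library)
  flags <- matrix(FALSE, nq, nm)
  labels <- vapply(library, function(entry) isTRUE(entry$active), logical(1))
  empty <- integer(0)
  for (m in seq_len(nm)) {
    ens <- library[[m]]$ensemble
    if (length(ens) == 0L) {
      empty <- c(empty, m)
      next
    }
    feat_list <- lapply(ens$conformers,
                        function(cf) detect_features(ens$molecule, cf, rules))
    for (qi in seq_len(nq)) {
      for (fl in feat_list) {
        if (isTRUE(match_query(queries[[qi]], fl))) {
          flags[qi, m] <- TRUE
          break
        }
      }
    }
  }
  if (length(empty))
    message(sprintf("%d molecule(s) with empty ensembles counted as non-matching",
                    length(empty)))
  qids <- vapply(queries, function(q) q$id, character(1))
  mnames <- vapply(seq_len(nm), function(m) {
    nm_i <- library[[m]]$name
    if (is.null(nm_i)) sprintf("mol%d", m) else nm_i
  }, character(1))
  dimnames(flags) <- list(qids, mnames)
  attr(flags, "labels") <- labels
  attr(flags, "empty") <- empty
  flags
}
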