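# V2000 charge code <-> formal charge (atom-block field; 4 = radical, kept 0)
.code_to_charge <- c(0L, 3L, 2L, 1L, 0L, -1L, -2L, -3L)
charge_from_code <- function(code) .code_to_charge[as.integer(code) + 1L]
code_from_charge <- function(q) {
  ifelse(q == 0L, 0L, ifelse(q > 0L, 4L - pmin(q, 3L), 4L + pmin(-q, 3L)))
}

.ab_cols <- c("C1", "C2", "C3", "C5", "C6", "C7", "C8", "C9", "C10", "C11",
              "C12", "C13", "C14", "C15", "C16")

# minimal V2000 reader for bond-free records (single atoms), which the
# ChemmineR parser mishandles; fixed-format fields read by position
parse_record_no_bonds <- function(rec, energy_field = "energy") {
  rec <- rec[nzchar(trimws(rec)) | seq_along(rec) <= 4]
  counts <- rec[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  if (is.na(natoms) || natoms < 1L || is.na(nbonds) || nbonds != 0L)
    stop("not a bond-free V2000 record")
  atoms <- lapply(rec[5:(4 + natoms)], function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    list(xyz = as.numeric(f[1:3]), element = f[4],
         code = if (length(f) >= 6) as.integer(f[6]) else 0L)
  })
  mol <- mol_graph(vapply(atoms, `[[`, character(1), "element"), NULL,
                   charges = charge_from_code(vapply(atoms, `[[`,
                                                     integer(1), "code")),
                   name = trimws(rec[1]))
  coords <- do.call(rbind, lapply(atoms, `[[`, "xyz"))
  energy <- NA_real_
  tag <- grep(sprintf("^>.*<%s>", energy_field), rec)
  if (length(tag) == 1L && length(rec) > tag)
    energy <- suppressWarnings(as.numeric(trimws(rec[tag + 1L])))
  list(mol = mol, conformer = conformer(coords, energy = energy,
                                        provenance = list(source = "sdf")))
}

# one ChemmineR::SDF record -> list(mol = mol_graph, conformer = conformer)
sdf_record_to_parts <- function(s, energy_field = "energy") {
  ab <- ChemmineR::atomblock(s)
  elements <- sub("_.*$", "", rownames(ab))
  coords <- unname(ab[, 1:3, drop = FALSE])
  charges <- if ("C6" %in% colnames(ab)) charge_from_code(ab[, "C6"]) else 0L
  bb <- ChemmineR::bondblock(s)
  bonds <- if (NROW(bb)) {
    data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
               order = as.numeric(bb[, 3]))
  } else NULL
  name <- ChemmineR::header(s)[["Molecule_Name"]]
  if (is.null(name) || is.na(name)) name <- ""
  mol <- mol_graph(elements, bonds, charges = charges, name = name)
  mol <- perceive_aromaticity(mol, s)
  db <- ChemmineR::datablock(s)
  energy <- NA_real_
  if (length(db) && energy_field %in% names(db))
    energy <- suppressWarnings(as.numeric(db[[energy_field]]))
  list(mol = mol,
       conformer = conformer(coords, energy = energy,
                             provenance = list(source = "sdf")))
}

# mark atoms/bonds of aromatic rings (ring perception on the ChemmineR
# record) so that Kekule forms map onto a single aromatic bond class
perceive_aromaticity <- function(mol, s) {
  if (any(mol$bonds$order == 4)) return(mol)  # already flagged in the file
  r <- tryCatch(
    suppressWarnings(ChemmineR::rings(s, upper = 7, type = "all", arom = TRUE)),
    error = function(e) NULL
  )
  if (is.null(r) || !length(r$RINGS)) return(mol)
  for (k in seq_along(r$RINGS)) {
    if (!isTRUE(r$AROMATIC[[k]])) next
    atoms <- as.integer(sub("^.*_", "", r$RINGS[[k]]))
    mol$aromatic[atoms] <- TRUE
    ring_pairs <- cbind(atoms, c(atoms[-1], atoms[1]))
    for (p in seq_len(nrow(ring_pairs))) {
      hit <- (mol$bonds$i == ring_pairs[p, 1] & mol$bonds$j == ring_pairs[p, 2]) |
             (mol$bonds$i == ring_pairs[p, 2] & mol$bonds$j == ring_pairs[p, 1])
      mol$bonds$order[hit] <- 4
    }
  }
  mol
}

parts_to_sdf_record <- function(mol, cf, energy_field = "energy") {
  n <- n_atoms(mol)
  ab <- matrix(0, n, length(.ab_cols),
               dimnames = list(paste(mol$elements, seq_len(n), sep = "_"),
                               .ab_cols))
  ab[, 1:3] <- cf$coords
  ab[, "C6"] <- code_from_charge(mol$charges)
  b <- mol$bonds
  bb <- matrix(0, NROW(b), 3, dimnames = list(NULL, c("C1", "C2", "C3")))
  if (NROW(b)) {
    bb[, 1] <- b$i; bb[, 2] <- b$j; bb[, 3] <- b$order
  }
  db <- character(0)
  if (!is.na(cf$energy)) {
    db <- setNames(format(cf$energy, digits = 10, scientific = FALSE),
                   energy_field)
  }
  methods::new(methods::className("SDF", "ChemmineR"),
    header = c(Molecule_Name = mol$name, Source = "confscreen", Comment = "",
               Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                     n, NROW(b))),
    atomblock = ab, bondblock = bb, datablock = db)
}

#' Read multi-record SDF (V2000) files into conformer ensembles
#'
#' Records are parsed with ChemmineR; consecutive records with identical
#' topology (elements, charges, bond table) and name are grouped into one
#' [conf_ensemble], preserving record order. Unparsable records are skipped
#' with a warning and counted in the attached report.
#'
#' @param path SDF file path.
#' @param energy_field name of the SDF data field holding the conformer
#'   energy (default `"energy"`); records without it get `NA` energy.
#' @return A list of [conf_ensemble] objects with attribute `report`, a list
#'   with `n_records`, `n_skipped`. An empty file yields an empty list.
#' @export
read_sdf <- function(path, energy_field = "energy") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  skipped <- 0L
  parts <- list()
  if (any(nzchar(trimws(lines)))) {
    recs <- split(lines, cumsum(c(0L, head(trimws(lines) == "$$$$", -1))))
    for (rec in recs) {
      if (!any(nzchar(trimws(rec)))) next
      p <- tryCatch({
        if (length(rec) >= 4 &&
            !is.na(suppressWarnings(as.integer(substr(rec[4], 4, 6)))) &&
            as.integer(substr(rec[4], 4, 6)) == 0L) {
          parse_record_no_bonds(rec, energy_field)
        } else {
          tmp <- tempfile(fileext = ".sdf")
          on.exit(unlink(tmp), add = TRUE)
          if (!any(trimws(rec) == "$$$$")) rec <- c(rec, "$$$$")
          writeLines(rec, tmp)
          sset <- suppressWarnings(ChemmineR::read.SDFset(tmp))
          if (!ChemmineR::validSDF(sset)[1]) stop("invalid record")
          sdf_record_to_parts(sset[[1]], energy_field)
        }
      }, error = function(e) NULL)
      if (is.null(p)) skipped <- skipped + 1L else parts[[length(parts) + 1L]] <- p
    }
  }
  if (skipped > 0L)
    warning(sprintf("skipped %d unparsable SDF record(s) in %s", skipped, path))
  ensembles <- list()
  sig_last <- NULL
  for (p in parts) {
    sig <- mol_signature(p$mol)
    if (!identical(sig, sig_last)) {
      ensembles[[length(ensembles) + 1L]] <- conf_ensemble(p$mol, list(p$conformer))
      sig_last <- sig
    } else {
      k <- length(ensembles)
      ensembles[[k]]$conformers <- c(ensembles[[k]]$conformers, list(p$conformer))
    }
  }
  attr(ensembles, "report") <- list(n_records = length(parts) + skipped,
                                    n_skipped = skipped)
  ensembles
}

#' Write conformer ensembles to a multi-record SDF (V2000) file
#'
#' One record per conformer, in ensemble then conformer order. Energies (when
#' present) are written to the given data field; a round trip through
#' [read_sdf()] reproduces topology, coordinates to printed precision and
#' energies.
#'
#' @param ensembles list of [conf_ensemble] objects (a single ensemble is
#'   accepted too).
#' @param path output file path.
#' @param energy_field SDF data field name for energies.
#' @return Invisibly, the number of records written.
#' @export
write_sdf <- function(ensembles, path, energy_field = "energy") {
  if (inherits(ensembles, "conf_ensemble")) ensembles <- list(ensembles)
  recs <- list()
  ids <- character(0)
  for (ens in ensembles) {
    for (cf in ens$conformers) {
      recs[[length(recs) + 1L]] <- parts_to_sdf_record(ens$molecule, cf,
                                                       energy_field)
      ids <- c(ids, ens$molecule$name)
    }
  }
  if (!length(recs)) {
    ok <- file.create(path)
    if (!ok) stop("cannot write ", path)
    return(invisible(0L))
  }
  sset <- methods::new(methods::className("SDFset", "ChemmineR"), SDF = recs,
                       ID = sprintf("REC%d", seq_along(recs)))
  ChemmineR::write.SDF(sset, path)
  invisible(length(recs))
}

#' Parse a SMILES string into a molecular graph
#'
#' Topology-only parse (coordinates are discarded) through the Open Babel
#' backend of ChemmineR. With `strip_stereo = TRUE` all stereochemistry
#' descriptors (tetrahedral `@` marks, cis/trans slashes) are removed before
#' graph construction, since the graph deliberately carries no stereo
#' information and screening inputs often lack it.
#'
#' @param smiles a single SMILES string.
#' @param strip_stereo drop stereo descriptors first (default `FALSE`).
#' @param name molecule name for the returned graph.
#' @return A [mol_graph] of the heavy atoms.
#' @examples
#' \donttest{
#' n_atoms(parse_smiles("CCO"))  # 3
#' }
#' @export
parse_smiles <- function(smiles, strip_stereo = FALSE, name = smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  input <- smiles
  if (strip_stereo) input <- gsub("[@/\\\\]", "", input)
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("SMILES parsing needs the ChemmineOB package")
  p <- tryCatch({
    txt <- suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", input))
    tmp <- tempfile(fileext = ".sdf")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(txt, tmp)
    ens <- suppressWarnings(read_sdf(tmp))
    if (!length(ens) || n_atoms(ens[[1]]$molecule) < 1L)
      stop("empty conversion")
    list(mol = ens[[1]]$molecule)
  }, error = function(e) stop("cannot parse SMILES '", smiles, "': ",
                              conditionMessage(e), call. = FALSE))
  mol <- p$mol
  mol$name <- name
  mol
}
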