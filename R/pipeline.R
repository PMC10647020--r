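#' Default pipeline configuration
#'
#' The declarative configuration consumed by [run_recover()],
#' [run_screen()] and [run_dockstats()]; user configs (YAML via
#' [read_config()]) are merged over these defaults. The `recover` block
#' emulates a bioactive-retrieval study (ensembles of `n_conf` conformers
#' with a small near-reference mixing weight, subset by the three selection
#' policies); `screen` a planted target-focused screening benchmark;
#' `dockstats` a docking-success evaluation.
#'
#' @return a nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    recover = list(
      n_molecules = 50L,
      n_torsions = c(2L, 4L),
      n_conf = 250L,
      mixing_weight = 0.05,
      noise_sigma = 0.1,
      energy_noise = 0.2,
      thresholds = c(0.5, 1.0, 1.5, 2.0),
      eval_threshold = 1.0,
      policies = list(
        list(kind = "lowest_energy", max_n = 25L),
        list(kind = "unbiased", max_n = 25L),
        list(kind = "energy_rmsd_filtered", max_n = 25L, rmsd_threshold = 1.0)
      )
    ),
    screen = list(
      n_actives = 20L, n_decoys = 80L, n_features = 4L,
      tolerance = 1.0, margin = 0.25, n_conf = 5L, active_jitter = 0,
      min_features = 3L, max_features = NULL,
      grid = list(
        list(kind = "lowest_energy", max_n = 1L),
        list(kind = "lowest_energy", max_n = 3L),
        list(kind = "lowest_energy", max_n = 5L)
      )
    ),
    dockstats = list(
      cutoff = 2.0, n_boot = 1000L, level = 0.95,
      conditions = list(
        list(name = "single", n_systems = 100L, displacement_rate = 0.4),
        list(name = "ensemble5", n_systems = 100L, displacement_rate = 0.2)
      )
    )
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(user[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration file
#' @param path YAML file; missing entries fall back to [default_config()].
#' @return the merged configuration list.
#' @export
read_config <- function(path) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  merge_config(default_config(), user)
}

write_manifest <- function(outdir, stage, config, seeds, outputs,
                           warnings = list()) {
  manifest <- list(stage = stage, config = config, seeds = seeds,
                   outputs = outputs, warnings = warnings)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

recover_policy_label <- function(p) {
  if (p$kind == "energy_rmsd_filtered")
    sprintf("%s_%.1fA", p$kind, p$rmsd_threshold)
  else p$kind
}

#' Run the bioactive-conformer retrieval stage
#'
#' Generates synthetic torsion-chain molecules with reference geometries,
#' samples full ensembles, applies each configured selection policy and
#' reports per-molecule best RMSDs, retrieval fractions and recovery
#' curves. All randomness derives from `config$seed`, so two runs with the
#' same config produce byte-identical outputs.
#'
#' @param config configuration list (see [default_config()]; `recover`
#'   block).
#' @param output_dir directory for `retrieval.csv`, `curves.csv`,
#'   `manifest.json`.
#' @return invisibly, a list with the retrieval table, curves and summary.
#' @export
run_recover <- function(config = default_config(), output_dir) {
  rc <- config$recover
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  n_mol <- rc$n_molecules
  tor_range <- rc$n_torsions
  tor_choices <- seq(tor_range[1], tor_range[length(tor_range)])
  n_torsions <- with_seed_(config$seed,
    tor_choices[sample.int(length(tor_choices), n_mol, replace = TRUE)])
  rows <- list()
  for (i in seq_len(n_mol)) {
    spec <- torsion_chain_spec(n_torsions[i], noise_sigma = rc$noise_sigma,
                               seed = config$seed + i)
    chain <- make_torsion_chain(spec, name = sprintf("mol%04d", i))
    ens <- make_ensemble(chain, rc$n_conf, mixing_weight = rc$mixing_weight,
                         energy_noise = rc$energy_noise)
    subsets <- c(list(full = ens),
                 setNames(lapply(seq_along(rc$policies), function(pi) {
                   p <- rc$policies[[pi]]
                   pol <- selection_policy(
                     p$kind, p$max_n,
                     rmsd_threshold = p$rmsd_threshold,
                     seed = if (p$kind == "unbiased")
                       config$seed + 10000L + i else NULL)
                   apply_policy(ens, pol)
                 }), vapply(rc$policies, recover_policy_label, character(1))))
    for (lab in names(subsets)) {
      rows[[length(rows) + 1L]] <- data.frame(
        molecule = chain$mol$name, n_torsions = n_torsions[i],
        policy = lab, n_selected = length(subsets[[lab]]),
        best_rmsd = best_rmsd(subsets[[lab]], chain$reference))
    }
  }
  retrieval <- do.call(rbind, rows)
  curves <- do.call(rbind, lapply(unique(retrieval$policy), function(lab) {
    cv <- recovery_curve(retrieval$best_rmsd[retrieval$policy == lab],
                         rc$thresholds)
    cbind(policy = lab, cv)
  }))
  summary_tab <- vapply(unique(retrieval$policy), function(lab) {
    retrieval_fraction(retrieval$best_rmsd[retrieval$policy == lab],
                       rc$eval_threshold)
  }, numeric(1))
  write.csv(retrieval, file.path(output_dir, "retrieval.csv"),
            row.names = FALSE)
  write.csv(curves, file.path(output_dir, "curves.csv"), row.names = FALSE)
  write_manifest(output_dir, "recover", config,
                 seeds = list(base = config$seed),
                 outputs = list(retrieval = "retrieval.csv",
                                curves = "curves.csv",
                                retrieval_at_eval_threshold =
                                  as.list(summary_tab)))
  invisible(list(retrieval = retrieval, curves = curves,
                 summary = summary_tab))
}

#' Run the pharmacophore screening stage
#'
#' Builds the planted screening library, derives the interaction profile of
#' the reference ligand against the receptor features, enumerates all
#' queries with at least `min_features` features and sweeps the configured
#' selection-policy grid, reporting the best F1 per cell. An empty query
#' pool yields an empty table with a notice.
#'
#' @param config configuration list (`screen` block).
#' @param output_dir directory for `sweep.csv` and `manifest.json`.
#' @return invisibly, a list with the sweep table and the query count.
#' @export
run_screen <- function(config = default_config(), output_dir) {
  sc <- config$screen
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- planted_library_spec(
    n_actives = sc$n_actives, n_decoys = sc$n_decoys,
    n_features = sc$n_features, tolerance = sc$tolerance,
    margin = sc$margin, n_conf = sc$n_conf,
    active_jitter = sc$active_jitter, seed = config$seed)
  lib <- make_screening_library(spec)
  lig_feats <- detect_features(lib$template_mol, lib$reference)
  profile <- detect_interactions(lig_feats, lib$receptor)
  queries <- enumerate_queries(profile, min_features = sc$min_features,
                               max_features = sc$max_features,
                               tolerance = sc$tolerance)
  if (!length(queries)) {
    sweep_tab <- data.frame(kind = character(), max_n = integer(),
                            rmsd_threshold = numeric(), best_f1 = numeric(),
                            precision = numeric(), recall = numeric(),
                            tp = integer(), fp = integer(), fn = integer(),
                            tn = integer(), query_id = character(),
                            n_features = integer())
  } else {
    grid <- do.call(rbind, lapply(sc$grid, function(g) {
      data.frame(kind = g$kind, max_n = g$max_n,
                 rmsd_threshold = if (is.null(g$rmsd_threshold)) NA_real_
                                  else g$rmsd_threshold,
                 seed = if (is.null(g$seed)) {
                   if (g$kind == "unbiased") config$seed + 20000L else NA
                 } else g$seed)
    }))
    sweep_tab <- suppressMessages(sweep_screen(lib$library, queries, grid))
    attr(sweep_tab, "per_query") <- NULL
  }
  write.csv(sweep_tab, file.path(output_dir, "sweep.csv"), row.names = FALSE)
  write_manifest(output_dir, "screen", config,
                 seeds = list(base = config$seed),
                 outputs = list(sweep = "sweep.csv",
                                n_queries = length(queries)))
  invisible(list(sweep = sweep_tab, n_queries = length(queries)))
}

# synthetic docking condition: per system the top pose is either the
# reference geometry (plus small jitter) or a wrong-torsion geometry
synth_dock_items <- function(n_systems, displacement_rate, seed) {
  with_seed_(seed, {
    lapply(seq_len(n_systems), function(i) {
      spec <- torsion_chain_spec(3L, seed = seed + i)
      chain <- make_torsion_chain(spec, name = sprintf("sys%04d", i))
      good <- runif(1) >= displacement_rate
      pose_xyz <- if (good) {
        chain$reference$coords + matrix(rnorm(3 * n_atoms(chain$mol),
                                              sd = 0.15),
                                        n_atoms(chain$mol), 3)
      } else {
        chain_coords(vapply(chain$ref_states, function(r)
          sample(setdiff(spec$states, r), 1L), numeric(1)))
      }
      list(pose = conformer(pose_xyz,
                            provenance = list(generator = "synthetic_dock")),
           reference = chain$reference, mol = chain$mol)
    })
  })
}

# read pose/reference SDF files into docking_success() items; poses grouped
# per molecule, the top pose is the record with the smallest rank field
# (record order when absent)
dock_items_from_files <- function(poses_path, refs_path,
                                  rank_field = "rank") {
  poses <- read_sdf(poses_path, energy_field = rank_field)
  refs <- read_sdf(refs_path)
  if (length(poses) != length(refs))
    stop("pose and reference files hold different molecule counts")
  lapply(seq_along(poses), function(i) {
    ranks <- ens_energies(poses[[i]])
    top <- if (all(is.na(ranks))) 1L else which.min(ranks)
    list(pose = poses[[i]]$conformers[[top]],
         reference = refs[[i]]$conformers[[1]],
         mol = refs[[i]]$molecule)
  })
}

#' Run the docking success statistics stage
#'
#' For each condition, computes the fraction of systems whose top-ranked
#' pose lies within the RMSD cutoff of its reference (symmetry-corrected,
#' fixed-frame RMSD) together with a percentile bootstrap confidence
#' interval. Conditions either name pose/reference SDF files (`poses`,
#' `references`, optional `rank_field`) or request synthetic systems
#' (`n_systems`, `displacement_rate`).
#'
#' @param config configuration list (`dockstats` block).
#' @param output_dir directory for `dockstats.csv` and `manifest.json`.
#' @return invisibly, the dockstats table.
#' @export
run_dockstats <- function(config = default_config(), output_dir) {
  dc <- config$dockstats
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(dc$conditions), function(ci) {
    cond <- dc$conditions[[ci]]
    items <- if (!is.null(cond$poses)) {
      dock_items_from_files(cond$poses, cond$references,
                            rank_field = if (is.null(cond$rank_field)) "rank"
                                         else cond$rank_field)
    } else {
      synth_dock_items(cond$n_systems, cond$displacement_rate,
                       seed = config$seed + 1000L * ci)
    }
    rate <- docking_success(items, cutoff = dc$cutoff)
    outcomes <- attr(rate, "rmsds") < dc$cutoff
    outcomes <- outcomes[!is.na(outcomes)]
    ci_est <- bootstrap_ci(outcomes, n_boot = dc$n_boot, level = dc$level,
                           seed = config$seed + 2000L + ci)
    data.frame(condition = cond$name, n = length(outcomes),
               success = as.numeric(rate), ci_lower = ci_est$lower,
               ci_upper = ci_est$upper,
               n_excluded = length(attr(rate, "excluded")))
  })
  tab <- do.call(rbind, rows)
  write.csv(tab, file.path(output_dir, "dockstats.csv"), row.names = FALSE)
  write_manifest(output_dir, "dockstats", config,
                 seeds = list(base = config$seed),
                 outputs = list(dockstats = "dockstats.csv"))
  invisible(tab)
}

#' Write the synthetic screening inputs to disk
#'
#' Materializes a planted screening library as standard files: the labeled
#' ensembles as multi-record SDF, the planted reference as SDF, the planted
#' query and receptor features as Pharmit-style JSON and the active/decoy
#' labels as CSV.
#'
#' @param config configuration list (`screen` block drives the library).
#' @param output_dir output directory.
#' @return invisibly, the file paths written.
#' @export
run_synth <- function(config = default_config(), output_dir) {
  sc <- config$screen
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- planted_library_spec(
    n_actives = sc$n_actives, n_decoys = sc$n_decoys,
    n_features = sc$n_features, tolerance = sc$tolerance,
    margin = sc$margin, n_conf = sc$n_conf,
    active_jitter = sc$active_jitter, seed = config$seed)
  lib <- make_screening_library(spec)
  paths <- list(
    ensembles = file.path(output_dir, "ensembles.sdf"),
    reference = file.path(output_dir, "reference.sdf"),
    query = file.path(output_dir, "query.json"),
    receptor = file.path(output_dir, "receptor.json"),
    labels = file.path(output_dir, "labels.csv"))
  write_sdf(lapply(lib$library, function(e) e$ensemble), paths$ensembles)
  write_sdf(conf_ensemble(lib$template_mol, list(lib$reference)),
            paths$reference)
  write_features_json(lib$query$features, paths$query,
                      radius = lib$query$tolerance)
  write_features_json(lib$receptor, paths$receptor)
  labels <- data.frame(
    name = vapply(lib$library, function(e) e$name, character(1)),
    active = vapply(lib$library, function(e) e$active, logical(1)))
  write.csv(labels, paths$labels, row.names = FALSE)
  write_manifest(output_dir, "synth", config,
                 seeds = list(base = config$seed),
                 outputs = lapply(paths, basename))
  invisible(paths)
}
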