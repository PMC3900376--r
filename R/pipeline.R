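# End-to-end orchestration: forces -> average -> difference -> stress ->
# network -> geometry -> report, driven by a single JSON config so a run is
# reproducible from (inputs, config, seed) alone.

#' Read and validate a pipeline configuration
#'
#' The config is a JSON object with input paths (`structure`, `topology`,
#' `holo_topology`, `apo_trajectories`, `holo_trajectories`), analysis
#' constants (`cutoff_nm`, `lj_cutoff_nm`, `default_cutoff_pN`,
#' `cutoff_grid_pN`), group definitions (`sources`, `targets` residue sets;
#' atom groups come from the topology), `angle_triplets` (strings like
#' `"3-27-51"` or objects with `label` and `triplet`), optional `hbonds`
#' criteria (`donors`, `acceptors`, `d_max_A`, `angle_min_deg`, `occ_min`),
#' `output_dir`, `seed` and `log_level`.
#'
#' @param path JSON config file.
#' @return validated config list (class `fda_run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_run_config(cfg, base = dirname(path))
}

#' @rdname read_run_config
#' @param cfg config list (as from JSON).
#' @param base directory against which relative paths are resolved.
#' @export
validate_run_config <- function(cfg, base = ".") {
  resolve <- function(p) {
    ifelse(file.exists(p), p, file.path(base, p))
  }
  for (key in c("topology", "apo_trajectories", "holo_trajectories")) {
    if (is.null(cfg[[key]])) stop("config is missing '", key, "'")
  }
  cfg$topology <- resolve(cfg$topology)
  if (!is.null(cfg$holo_topology)) cfg$holo_topology <- resolve(cfg$holo_topology)
  if (!is.null(cfg$structure)) cfg$structure <- resolve(cfg$structure)
  cfg$apo_trajectories <- resolve(cfg$apo_trajectories)
  cfg$holo_trajectories <- resolve(cfg$holo_trajectories)
  missing <- c(cfg$topology, cfg$holo_topology, cfg$structure,
               cfg$apo_trajectories, cfg$holo_trajectories)
  missing <- missing[!file.exists(missing)]
  if (length(missing)) {
    stop("config references missing file(s): ", paste(missing, collapse = ", "))
  }
  cfg$cutoff_nm <- cfg$cutoff_nm %||% 1.2
  cfg$lj_cutoff_nm <- cfg$lj_cutoff_nm %||% cfg$cutoff_nm
  cfg$default_cutoff_pN <- cfg$default_cutoff_pN %||% 90
  cfg$cutoff_grid_pN <- sort(cfg$cutoff_grid_pN %||% seq(30, 240, by = 30))
  cfg$output_dir <- cfg$output_dir %||% "fda_out"
  cfg$seed <- cfg$seed %||% 1L
  cfg$log_level <- cfg$log_level %||% "info"
  # normalize angle_triplets: JSON may arrive as a data.frame, a character
  # vector of "a-b-c" strings, or a list of {label, triplet} objects
  at <- cfg$angle_triplets %||% list()
  if (is.data.frame(at)) {
    at <- lapply(seq_len(nrow(at)), function(r) as.list(at[r, , drop = FALSE]))
  } else if (is.character(at)) {
    at <- lapply(at, function(s) list(label = s, triplet = s))
  }
  cfg$angle_triplets <- at
  structure(cfg, class = c("fda_run_config", "list"))
}

#' Parse an angle-triplet spec like `"188-192-199"`
#' @param x string `"a-b-c"`, or numeric length-3 vector.
#' @return integer triplet.
#' @export
parse_triplet <- function(x) {
  if (is.character(x)) x <- as.integer(strsplit(x, "-")[[1]])
  x <- as.integer(x)
  if (length(x) != 3 || anyNA(x)) stop("triplet must be three integers, e.g. '188-192-199'")
  x
}

pipeline_log <- function(con, level, ...) {
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), level,
                  paste0(...))
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

load_state <- function(topology_path, traj_paths) {
  sys <- read_topology(topology_path)
  frames <- list()
  for (p in traj_paths) {
    tr <- read_trajectory(p)
    frames[[length(frames) + 1L]] <- tr$frames
  }
  list(system = sys, ensemble = trajectory_ensemble(frames))
}

write_unit_csv <- function(df, path, unit_note) {
  con <- file(path, "w")
  writeLines(paste0("# ", unit_note), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  path
}

#' Run the full force-distribution analysis pipeline
#'
#' Loads the apo and holo states (topology + replica trajectories), averages
#' pairwise forces per state, restricts the holo averages to the shared
#' (apo) atom set, differences the states, and derives the punctual-stress
#' profiles, the cutoff scan, the thresholded network with source-to-target
#' pathways, bending-angle and hydrogen-bond reports, and a run manifest.
#'
#' @param config an `fda_run_config` (see [read_run_config()]).
#' @return invisibly, a list with the main in-memory results and the paths
#'   of all written artifacts.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "fda_run_config")) config else
    validate_run_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(cfg$output_dir, "run.log"), "w")
  on.exit(close(logf))
  out <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      pipeline_log(logf, "ERROR", "stage '", name, "' failed: ",
                   conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    pipeline_log(logf, "info", sprintf("stage %-10s done in %.1fs", name,
                                       as.numeric(Sys.time() - t0, units = "secs")))
    res
  }
  set.seed(cfg$seed)

  apo <- stage("load", {
    a <- load_state(cfg$topology, cfg$apo_trajectories)
    a$ensemble$state <- "apo"
    a
  })
  holo <- stage("load", {
    h <- load_state(cfg$holo_topology %||% cfg$topology, cfg$holo_trajectories)
    h$ensemble$state <- "holo"
    h
  })
  n_apo <- n_atoms(apo$system)
  resmap <- residue_map(apo$system)

  avg <- stage("forces", {
    list(apo = ensemble_average_forces(apo$system, apo$ensemble,
                                       cfg$cutoff_nm,
                                       lj_cutoff = cfg$lj_cutoff_nm),
         holo = ensemble_average_forces(holo$system, holo$ensemble,
                                        cfg$cutoff_nm,
                                        lj_cutoff = cfg$lj_cutoff_nm))
  })
  paths <- c(
    avg_apo = write_unit_csv(as.data.frame(avg$apo),
                             file.path(cfg$output_dir, "avg_forces_apo.csv"),
                             "pairwise forces, mean_pn/sd_pn in pN"),
    avg_holo = write_unit_csv(as.data.frame(avg$holo),
                              file.path(cfg$output_dir, "avg_forces_holo.csv"),
                              "pairwise forces, mean_pn/sd_pn in pN"))

  diff <- stage("diff", {
    force_difference(avg$apo, restrict_pairs(avg$holo, seq_len(n_apo), n_apo))
  })
  paths["delta"] <- write_unit_csv(as.data.frame(diff),
                                   file.path(cfg$output_dir, "delta_forces.csv"),
                                   "apo - holo pairwise force difference, pN")

  stress <- stage("stress", punctual_stress(diff, resmap))
  paths["stress_atoms"] <- write_unit_csv(
    data.frame(atom = seq_len(n_apo), residue = resmap,
               stress_pn = stress$atom),
    file.path(cfg$output_dir, "stress_atoms.csv"), "punctual stress, pN")
  paths["stress_residues"] <- write_unit_csv(
    data.frame(residue = as.integer(names(stress$residue)),
               stress_pn = as.vector(stress$residue)),
    file.path(cfg$output_dir, "stress_residues.csv"),
    paste0("punctual stress per residue (", stress$mode, "), pN"))
  paths["stress_pdb"] <- file.path(cfg$output_dir, "stress.pdb")
  stage("stress_pdb", write_stress_pdb(apo$system,
                                       ensemble_frame(apo$ensemble, 1, 1),
                                       stress$atom, paths[["stress_pdb"]]))

  sources <- cfg$sources %||% sort(unique(resmap[apo$system$groups$binding]))
  targets <- cfg$targets %||% sort(unique(resmap[apo$system$groups$hinge]))
  scan <- stage("scan", scan_cutoffs(diff, resmap, sources, targets,
                                     grid = cfg$cutoff_grid_pN))
  paths["scan"] <- write_unit_csv(scan$table,
                                  file.path(cfg$output_dir, "cutoff_scan.csv"),
                                  "cutoff_pn in pN")

  cutoff_used <- if (!scan$broken) scan$recommended else cfg$default_cutoff_pN
  net <- stage("network", {
    g <- build_force_graph(diff, resmap, cutoff_used)
    lc <- largest_component(g)
    pw <- extract_pathways(lc$graph, sources, targets)
    list(graph = g, component = lc, pathways = pw)
  })
  paths["edges"] <- write_unit_csv(graph_edge_list(net$graph),
                                   file.path(cfg$output_dir, "edges.csv"),
                                   sprintf("weight_pn in pN, cutoff %.6g pN", cutoff_used))
  paths["pathways"] <- file.path(cfg$output_dir, "pathways.txt")
  writeLines(c(sprintf("# source->target pathways at cutoff %.6g pN", cutoff_used),
               vapply(net$pathways$paths, paste, character(1), collapse = " -> "),
               if (nrow(net$pathways$unreachable))
                 sprintf("# unreachable: %s -> %s",
                         net$pathways$unreachable$source,
                         net$pathways$unreachable$target)),
             paths[["pathways"]])

  angles <- stage("angles", {
    rows <- lapply(cfg$angle_triplets, function(tr) {
      triplet <- parse_triplet(if (is.list(tr)) tr$triplet else tr)
      label <- if (is.list(tr) && !is.null(tr$label))
        tr$label else paste(triplet, collapse = "-")
      pa <- angle_profile(apo$ensemble, triplet, label)
      ph <- angle_profile(holo$ensemble, triplet, label)
      dd <- angle_difference(pa, ph)
      data.frame(label = label, triplet = paste(triplet, collapse = "-"),
                 apo_mean = pa$mean, apo_sd = pa$sd,
                 holo_mean = ph$mean, holo_sd = ph$sd,
                 diff = dd$delta, diff_sd = dd$sd)
    })
    if (length(rows)) do.call(rbind, rows) else
      data.frame(label = character(), triplet = character(),
                 apo_mean = numeric(), apo_sd = numeric(),
                 holo_mean = numeric(), holo_sd = numeric(),
                 diff = numeric(), diff_sd = numeric())
  })
  paths["angles"] <- write_unit_csv(angles,
                                    file.path(cfg$output_dir, "angles.csv"),
                                    "angles in degrees")

  hb_cfg <- cfg$hbonds
  hbonds <- stage("hbonds", {
    if (is.null(hb_cfg)) {
      data.frame(donor = integer(), acceptor = integer(),
                 mean_distance_A = numeric(), occupancy = numeric(),
                 state = character())
    } else {
      rbind(
        cbind(detect_hbonds(apo$ensemble, hb_cfg$donors, hb_cfg$acceptors,
                            d_max = hb_cfg$d_max_A %||% 3.5,
                            angle_min = hb_cfg$angle_min_deg %||% 120,
                            occ_min = hb_cfg$occ_min %||% 0.5),
              state = "apo"),
        cbind(detect_hbonds(holo$ensemble, hb_cfg$donors, hb_cfg$acceptors,
                            d_max = hb_cfg$d_max_A %||% 3.5,
                            angle_min = hb_cfg$angle_min_deg %||% 120,
                            occ_min = hb_cfg$occ_min %||% 0.5),
              state = "holo"))
    }
  })
  paths["hbonds"] <- write_unit_csv(hbonds,
                                    file.path(cfg$output_dir, "hbonds.csv"),
                                    "distances in Angstrom, occupancy fraction")

  manifest <- list(
    package = "fdanet",
    version = as.character(utils::packageVersion("fdanet")),
    seed = cfg$seed,
    cutoff_nm = cfg$cutoff_nm, lj_cutoff_nm = cfg$lj_cutoff_nm,
    cutoff_grid_pN = cfg$cutoff_grid_pN,
    recommended_cutoff_pN = scan$recommended,
    cutoff_used_pN = cutoff_used,
    broken_path = scan$broken,
    n_atoms = c(apo = n_apo, holo = n_atoms(holo$system)),
    n_replicas = c(apo = length(apo$ensemble$replicas),
                   holo = length(holo$ensemble$replicas)),
    largest_component = net$component$nodes,
    artifacts = as.list(paths))
  paths["manifest"] <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  pipeline_log(logf, "info", "pipeline complete; ", length(paths),
               " artifacts in ", cfg$output_dir)
  invisible(list(config = cfg, averaged = avg, diff = diff, stress = stress,
                 scan = scan, network = net, angles = angles,
                 hbonds = hbonds, artifacts = paths))
}
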