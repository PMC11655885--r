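#' Assemble an analysis configuration
#'
#' A single configuration drives the whole comparative report. Any
#' defaulted, non-measured parameter (radii, contact-model A/B table,
#' stride, burn-in) is echoed into the run log so no result silently
#' depends on a hidden choice.
#'
#' @param topology,frames input paths (PDB topology + multi-model PDB
#'   frames); may be omitted when an `Ensemble` is handed to
#'   [run_report()] directly.
#' @param region selection expression for the region of interest (maps,
#'   network and substates are computed over it).
#' @param substate_selection selection expression for the substate
#'   clustering metric (e.g. `"calpha and resid 1-40"`; C-alphas of the
#'   region with flexible-loop residues excluded). Defaults to
#'   `"calpha"` restricted via `region` is *not* assumed: give it
#'   explicitly.
#' @param ligand optional selection expression for a ligand group; when
#'   given, ligand-receptor contacts join the interaction network.
#' @param burn_in_fraction fraction of initial frames discarded (used when
#'   reading `frames`; ensembles passed directly keep their own).
#' @param topography,flexibility,interactions,substates parameter objects
#'   ([topography_params()] etc.); defaults used when `NULL`.
#' @param stride frame stride for the substate distance matrix.
#' @param output_dir directory for exported artifacts (`NULL`: no files).
#' @param seed integer recorded in the log (analyses are deterministic).
#' @return an `AnalysisConfig` list.
#' @export
analysis_config <- function(topology = NULL, frames = NULL,
                            region = "protein",
                            substate_selection = "calpha",
                            ligand = NULL, burn_in_fraction = 0.5,
                            topography = NULL, flexibility = NULL,
                            interactions = NULL, substates = NULL,
                            stride = 1L, output_dir = NULL, seed = 0L) {
  structure(list(
    topology = topology, frames = frames, region = region,
    substate_selection = substate_selection, ligand = ligand,
    burn_in_fraction = burn_in_fraction,
    topography = topography %||% topography_params(),
    flexibility = flexibility %||% fluctuation_params(),
    interactions = interactions %||% interaction_params(),
    substates = substates %||% cluster_params(),
    stride = as.integer(stride), output_dir = output_dir,
    seed = as.integer(seed)), class = "AnalysisConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an analysis configuration from YAML or JSON
#'
#' @param path configuration file (`.yaml`/`.yml` needs the yaml package;
#'   `.json` uses jsonlite).
#' @return an `AnalysisConfig`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), c(known, "params"))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  pb <- function(ctor, block) if (is.null(block)) NULL else do.call(ctor, block)
  raw$topography <- pb(topography_params, raw$topography)
  raw$flexibility <- pb(fluctuation_params, raw$flexibility)
  raw$interactions <- pb(interaction_params, raw$interactions)
  raw$substates <- pb(cluster_params, raw$substates)
  do.call(analysis_config, raw)
}

#' Run the full comparative-dynamics report
#'
#' Executes topography, flexibility, interaction-network and substate
#' analyses on one analyzed frame set and collects the results, run
#' metadata (parameter digests, frame counts) and any stage failures. A
#' stage that errors (e.g. the flexibility width, undefined on a 1-frame
#' ensemble) is recorded as missing in `errors` while the remaining
#' stages still run. With `output_dir` set, CSV/TSV/JSON artifacts and
#' B-factor-encoded PDB heatmaps are written alongside a JSON log.
#'
#' @param config an [analysis_config()].
#' @param ensemble optional `Ensemble` (bypasses reading
#'   `config$topology`/`config$frames`).
#' @return a `ComparativeReport`: list with `topography`, `flexibility`
#'   (ResidueScalarMaps), `network` (InteractionNetwork), `substates`
#'   (SubstatePartition), `errors`, `metadata`.
#' @export
run_report <- function(config, ensemble = NULL) {
  stopifnot(inherits(config, "AnalysisConfig"))
  if (is.null(ensemble)) {
    if (is.null(config$topology) || is.null(config$frames))
      stop("config must name topology and frames (or pass an ensemble)")
    ensemble <- read_ensemble(config$topology, config$frames,
                              burn_in_fraction = config$burn_in_fraction)
  }
  topo <- ensemble$topology
  region <- select_atoms(topo, config$region)
  sub_sel <- select_atoms(topo, config$substate_selection)
  lig <- if (!is.null(config$ligand)) select_atoms(topo, config$ligand)

  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      warning("stage '", name, "' failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
  }
  res_topography <- stage("topography",
    topography_map(ensemble, region, config$topography))
  res_flex <- stage("flexibility",
    fluctuation_map(ensemble, region, config$flexibility))
  pairs <- list(list(a = region, b = region))
  if (!is.null(lig)) pairs <- c(pairs, list(list(a = region, b = lig)))
  res_net <- stage("interactions",
    persistence_network(ensemble, pairs, config$interactions))
  res_sub <- stage("substates",
    find_substates(ensemble, sub_sel, config$substates, config$stride))

  metadata <- list(
    n_frames = n_frames(ensemble),
    n_frames_analyzed = length(analyzed_frames(ensemble)),
    burn_in_fraction = ensemble$burn_in_fraction,
    region = config$region,
    substate_selection = config$substate_selection,
    ligand = config$ligand,
    seed = config$seed,
    params_digests = list(
      topography = params_digest(config$topography),
      flexibility = params_digest(config$flexibility),
      interactions = params_digest(config$interactions),
      substates = params_digest(config$substates)),
    defaults_note = paste(
      "neighborhood/environment radii and the topography A/B table are",
      "configuration defaults, not measured values"),
    partial = length(errors) > 0)
  report <- structure(list(topography = res_topography,
                           flexibility = res_flex, network = res_net,
                           substates = res_sub, errors = errors,
                           metadata = metadata),
                      class = "ComparativeReport")
  if (!is.null(config$output_dir))
    export_report(report, topo, config$output_dir)
  report
}

#' @export
print.ComparativeReport <- function(x, ...) {
  ok <- function(v) if (is.null(v)) "MISSING" else "ok"
  cat("ComparativeReport over", x$metadata$n_frames_analyzed,
      "analyzed frames\n")
  cat("  topography:", ok(x$topography), " flexibility:", ok(x$flexibility),
      " network:", ok(x$network), " substates:", ok(x$substates), "\n")
  if (length(x$errors))
    cat("  failed stages:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

export_report <- function(report, topology, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wmap <- function(map, stem) {
    if (is.null(map)) return()
    utils::write.csv(as.data.frame(map), file.path(dir, paste0(stem, ".csv")),
                     row.names = FALSE)
    map_to_bfactor_pdb(topology, map, file.path(dir, paste0(stem, ".pdb")))
  }
  wmap(report$topography, "topography")
  wmap(report$flexibility, "flexibility")
  if (!is.null(report$network))
    utils::write.table(report$network$edges, file.path(dir, "network.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$substates)) {
    p <- report$substates
    jsonlite::write_json(
      list(substates = lapply(p$substates, function(s)
        list(centroid_frame = s$centroid_frame, density = s$density,
             member_frames = s$member_frames)),
        noise_frames = p$noise_frames, n_frames = p$n_frames,
        params_digest = p$params_digest),
      file.path(dir, "substates.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(report$metadata, file.path(dir, "report_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a residue map into the B-factor column of a PDB
#'
#' Encodes per-residue values as atomic B-factors for molecular-surface
#' heatmap rendering in external viewers; atoms of residues absent from
#' the map get 0.
#'
#' @param structure the topology `Structure`.
#' @param map a `ResidueScalarMap`.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
map_to_bfactor_pdb <- function(structure, map, path) {
  key <- atom_residue_key(structure)
  mkey <- paste(map$chain, map$resid, sep = ":")
  val <- map$value[match(key, mkey)]
  val[is.na(val)] <- 0
  write_structure(structure, path, bfactor = val)
}

#' Compare two comparative reports residue by residue
#'
#' Aligns the per-residue maps of two reports by `(chain, residue
#' number)` and tabulates differences (`b - a`), the core
#' ligand-versus-ligand readout. Residues present in only one report are
#' marked missing, never treated as zero. A parameter-digest mismatch
#' between the reports triggers a warning.
#'
#' @param report_a,report_b `ComparativeReport`s.
#' @return list of data.frames (`topography`, `flexibility`, where
#'   available) with columns `chain`, `resid`, `value_a`, `value_b`,
#'   `difference`, `missing_in`.
#' @export
compare_reports <- function(report_a, report_b) {
  out <- list()
  for (metric in c("topography", "flexibility")) {
    ma <- report_a[[metric]]
    mb <- report_b[[metric]]
    if (is.null(ma) || is.null(mb)) next
    da <- attr(ma, "params_digest"); db <- attr(mb, "params_digest")
    if (!identical(da, db))
      warning("parameter digests differ for ", metric,
              "; comparison may not be like-for-like", call. = FALSE)
    ka <- paste(ma$chain, ma$resid, sep = ":")
    kb <- paste(mb$chain, mb$resid, sep = ":")
    if (length(intersect(ka, kb)) == 0L)
      stop("reports share no residues for ", metric)
    keys <- union(ka, kb)
    va <- ma$value[match(keys, ka)]
    vb <- mb$value[match(keys, kb)]
    missing_in <- ifelse(is.na(va) & is.na(vb), "both",
                         ifelse(is.na(va), "a", ifelse(is.na(vb), "b", "")))
    tab <- data.frame(
      chain = sub(":.*", "", keys),
      resid = as.integer(sub(".*:", "", keys)),
      value_a = va, value_b = vb, difference = vb - va,
      missing_in = missing_in, stringsAsFactors = FALSE)
    tab <- tab[order(tab$chain, tab$resid), , drop = FALSE]
    rownames(tab) <- NULL
    out[[metric]] <- tab
  }
  if (length(out) == 0L) stop("reports have no comparable residue maps")
  out
}
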