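#' Assemble a pipeline configuration
#'
#' Collects every tunable of the landscape-to-flux pipeline with the
#' standard defaults: 300 K, 400 insertions per voxel, saddle-pair cutoff
#' 40 kJ/mol, water reference 8.30 kJ/mol, 50%-of-maximum pathway
#' retention. Fields left `NULL` disable the optional stages that need
#' them.
#'
#' @param grid a [grid_spec()] (required).
#' @param frames a [frameset()], or a path readable by [read_frameset()];
#'   `NULL` generates the synthetic cavity ensemble.
#' @param n_frames,jitter synthetic-ensemble parameters used when `frames`
#'   is `NULL`.
#' @param ligand a [diatomic_model()]. Default [default_o2_model()].
#' @param temperature K. Default 300.
#' @param insertions insertions per voxel. Default 400.
#' @param saddle_cutoff kJ/mol. Default 40.
#' @param water_reference kJ/mol subtracted from the vacuum landscape.
#'   Default [water_reference()] = 8.30; set 0 for ensembles with a vacuum
#'   exterior such as the synthetic cavity.
#' @param fraction pathway retention fraction. Default 0.5.
#' @param contact_distance product-basin contact distance, Å. Default 3.32.
#' @param targets data.frame with x, y, z of target atoms (product-basin
#'   selection), or path to a TSV with those columns.
#' @param structure optional residue-annotated data.frame (or PDB path) for
#'   residue mapping.
#' @param walk optional list(n_ligands, n_steps) to run the explicit-ligand
#'   density stage on a Metropolis walk over the final landscape.
#' @param seed integer seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(grid, frames = NULL, n_frames = 200, jitter = 0.2,
                            ligand = default_o2_model(), temperature = 300,
                            insertions = 400, saddle_cutoff = 40,
                            water_reference = ilsflux::water_reference(),
                            fraction = 0.5, contact_distance = 3.32,
                            targets = NULL, structure = NULL, walk = NULL,
                            seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"))
  cfg <- list(grid = grid, frames = frames, n_frames = n_frames,
              jitter = jitter, ligand = ligand, temperature = temperature,
              insertions = insertions, saddle_cutoff = saddle_cutoff,
              water_reference = water_reference, fraction = fraction,
              contact_distance = contact_distance, targets = targets,
              structure = structure, walk = walk, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full landscape-to-flux pipeline
#'
#' Executes ensemble preparation, the implicit-ligand-sampling landscape,
#' water referencing, the energy cutoff mask, watershed basins, saddles and
#' the minima network, the basin Markov model with solvent coarse-graining,
#' the stationary distribution, product-basin targeting, transition path
#' theory and pathway decomposition, plus the optional explicit-ligand
#' density and residue-mapping stages. All artifacts (OpenDX maps, TSV
#' tables, a JSON summary with total flux and per-pathway fluxes and
#' percentages, and the resolved configuration) are written under
#' `out_dir`. Deterministic stages rerun bit-identically for the same
#' config and seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with every stage result (`landscape`,
#'   `basins`, `network`, `model`, `pi`, `tpt`, `pathways`, optional
#'   `density`/`internalization`/`residues`) and `summary`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  thermo <- thermo_params(config$temperature)

  frames <- stage("frames", {
    f <- config$frames
    if (is.null(f)) make_cavity_frames(config$n_frames, jitter = config$jitter,
                                       seed = config$seed)
    else if (is.character(f)) {
      if (!file.exists(f)) stop("frames file not found: ", f)
      read_frameset(f)
    } else f
  })

  land <- stage("ils", {
    ils_landscape(frames, config$ligand, config$grid,
                  insertions_per_voxel = config$insertions, thermo = thermo,
                  seed = config$seed)
  })
  land <- stage("reference", reference_to_water(land, config$water_reference))
  land <- stage("cutoff", apply_energy_cutoff(land, config$saddle_cutoff))
  write_volumetric(land, file.path(out_dir, "landscape.dx"))

  basins <- stage("basins", watershed(land, thermo))
  saddles <- stage("saddles", find_saddles(land, basins))
  network <- stage("network", build_network(land, basins, saddles))
  write_basin_labels(basins, file.path(out_dir, "basins.dx"))
  write_network_edges(network, config$grid, file.path(out_dir, "network_edges.tsv"))

  model <- stage("markov", {
    m <- build_markov_model(land, basins, saddles, config$saddle_cutoff, thermo)
    solvent <- identify_solvent_basins(basins)
    coarse_grain_solvent(m, solvent)
  })
  ## the Eq-2-style construction is in detailed balance with Z, so Z/sum(Z)
  ## is the analytic equilibrium; starting the chain iteration there makes
  ## the invariance check immediate even when near-isolated basins give the
  ## chain an extremely long relaxation time from a solvent start
  pi_hat <- stage("stationary",
                  suppressWarnings(stationary_distribution(
                    model, p0 = model$Z / sum(model$Z))))
  utils::write.table(
    data.frame(state = model$states, pi = as.numeric(pi_hat)),
    file.path(out_dir, "stationary.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)

  result <- NULL; pathways <- NULL
  if (!is.null(config$targets)) {
    targets_df <- stage("targets", {
      tg <- config$targets
      if (is.character(tg)) {
        if (!file.exists(tg)) stop("targets file not found: ", tg)
        tg <- utils::read.table(tg, sep = "\t", header = TRUE)
      }
      tg
    })
    products <- stage("products", {
      ids <- select_product_basins(basins, targets_df,
                                   contact_distance = config$contact_distance)
      ids <- intersect(as.character(ids), model$states)
      if (!length(ids)) stop("no product basin survives coarse-graining")
      ids
    })
    result <- stage("tpt", tpt_analysis(model, "solvent", products))
    pathways <- stage("pathways", top_pathways(result, config$fraction))
    write_tpt_result(result, file.path(out_dir, "tpt"))
    write_pathway_report(pathways, file.path(out_dir, "pathway_report.tsv"),
                         groups = group_product_basins(pathways))
  }

  res <- list(landscape = land, basins = basins, saddles = saddles,
              network = network, model = model, pi = pi_hat,
              tpt = result, pathways = pathways)

  if (!is.null(config$walk)) {
    res$walk <- stage("walk", {
      make_ligand_walk(land, n_ligands = config$walk$n_ligands,
                       n_steps = config$walk$n_steps,
                       temperature = config$temperature,
                       seed = config$seed + 1L)
    })
    res$density <- stage("density", pdf_map(res$walk, config$grid))
    write_volumetric(res$density, file.path(out_dir, "density.dx"))
    write_walk(res$walk, file.path(out_dir, "walk.tsv"))
  }

  if (!is.null(config$structure) && !is.null(pathways)) {
    res$residues <- stage("residues", {
      struct <- config$structure
      if (is.character(struct)) struct <- read_structure_pdb(struct)
      traces <- pathway_traces_from(pathways, basins, network, land)
      lining_residues(traces, struct,
                      contact_distance = config$contact_distance,
                      flux_fraction = config$fraction)
    })
    utils::write.table(res$residues, file.path(out_dir, "lining_residues.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  summary <- list(
    n_basins = basins$n_basins,
    n_states = length(model$states),
    total_flux = if (is.null(result)) NA_real_ else result$total_flux,
    pathway_fluxes = if (is.null(pathways)) NULL else pathways$groups$flux,
    pathway_percent = if (is.null(pathways)) NULL else pathways$groups$percent,
    product_basins = if (is.null(pathways)) NULL else pathways$groups$product,
    seed = config$seed)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_echo <- config
  cfg_echo$frames <- if (is.character(config$frames)) config$frames
                     else if (is.null(config$frames)) "synthetic cavity ensemble"
                     else "in-memory frameset"
  cfg_echo$structure <- if (is.character(config$structure)) config$structure
                        else if (is.null(config$structure)) NULL
                        else "in-memory structure"
  jsonlite::write_json(cfg_echo, file.path(out_dir, "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  res$summary <- summary
  invisible(res)
}

#' Geometric traces of decomposed pathways
#'
#' Converts each retained pathway (a sequence of basin states) into a
#' [pathway_trace()] polyline by concatenating, for every consecutive
#' basin pair, the steepest-descent traces linking the two minima through
#' their saddle; every segment carries the pathway's flux.
#'
#' @param pathways a [top_pathways()] result.
#' @param basins the underlying [watershed()] decomposition.
#' @param network the [build_network()] result.
#' @param field the landscape [scalar_field()].
#' @return List of [pathway_trace()] objects (pathways whose state pairs
#'   have no saddle edge — e.g. hops through the merged solvent state —
#'   contribute only their resolvable legs).
#' @export
pathway_traces_from <- function(pathways, basins, network, field) {
  ed <- network$edges
  out <- list()
  for (p in seq_along(pathways$paths)) {
    st <- pathways$paths[[p]]
    pts <- NULL
    for (k in seq_len(length(st) - 1L)) {
      a <- suppressWarnings(as.integer(st[k]))
      b <- suppressWarnings(as.integer(st[k + 1L]))
      if (is.na(a) || is.na(b)) next  # merged solvent state has no voxels
      lo <- min(a, b); hi <- max(a, b)
      r <- which(ed$basin_i == lo & ed$basin_j == hi)
      if (!length(r)) next
      tr <- network$traces[[r[1L]]]
      leg_a <- if (a == lo) tr$to_i else tr$to_j
      leg_b <- if (b == lo) tr$to_i else tr$to_j
      seg <- rbind(leg_a[rev(seq_len(nrow(leg_a))), , drop = FALSE],
                   leg_b[-1L, , drop = FALSE])
      pts <- rbind(pts, seg)
    }
    if (!is.null(pts) && nrow(pts) >= 2L)
      out[[length(out) + 1L]] <- pathway_trace(
        pts, flux = pathways$pathways$flux[p],
        id = sprintf("pathway_%d", pathways$pathways$rank[p]))
  }
  out
}

#' Literature reactive-flux table for the two hydrogenases
#'
#' Returns the reported per-product-basin reactive fluxes (per unitless
#' lag step) of the \[NiFe\]- and \[NiFeSe\]-hydrogenase O2 permeation study
#' shipped with the package, the input of the worked percentage example.
#'
#' @return data.frame: enzyme, pathway_group, product_basin, flux.
#' @export
hydrogenase_fluxes <- function() {
  utils::read.table(system.file("extdata", "hydrogenase_fluxes.tsv",
                                package = "ilsflux"),
                    sep = "\t", header = TRUE)
}
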