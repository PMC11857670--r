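## Pipeline orchestration: screen -> occurrences -> evaluate -> ensemble ->
## contribute -> multi-species stack, from one declarative JSON config, with
## a machine-readable run report capturing every seed and threshold.

#' Default pipeline configuration
#'
#' @return named list of defaults; every field can be overridden by the
#'   config file. There are no hidden defaults outside this list.
#' @export
default_config <- function() {
  list(stack_manifest = NULL, occurrences = NULL, status = NULL,
       output_dir = "esdm_out",
       r_max = 0.7, vif_max = 10, auc_cutoff = 0.85, strict_cutoff = FALSE,
       replicates = 20L, holdout = 0.2,
       algorithms = SDM_ALGORITHMS, seed = 1L, dedupe = TRUE)
}

read_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(default_config(), config)
  stopifnot(cfg$holdout > 0, cfg$holdout < 1, cfg$replicates >= 1)
  cfg$algorithms <- match.arg(cfg$algorithms, SDM_ALGORITHMS, several.ok = TRUE)
  cfg
}

#' Read an environmental stack from a manifest
#'
#' The manifest is a JSON array of `{name, path, kind}` records pointing at
#' ASCII grid rasters; relative paths resolve against the manifest's
#' directory. All rasters must already share one grid (use [align_stack()]
#' upstream otherwise).
#'
#' @param path manifest path.
#' @return an [env_stack()].
#' @export
read_stack_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("name", "path", "kind") %in% names(man)))
    stop("stack manifest needs fields name, path, kind")
  base <- dirname(path)
  layers <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    read_ascii_raster(p, name = man$name[i], kind = man$kind[i])
  })
  env_stack(layers)
}

stage_error <- function(stage, e) {
  stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
}

#' Run the full multi-species pipeline
#'
#' Stages: collinearity screen; occurrence loading and pseudo-absence
#' sampling; replicate evaluation; AUC-weighted ensemble; jackknife
#' contributions; conservation-weighted multi-species overlay. Species with
#' no admissible model (all AUC below the cutoff) are excluded from the
#' overlay and the remaining weights renormalised. Idempotent given an
#' identical config.
#'
#' @param config path to a JSON config file or an equivalent named list;
#'   see [default_config()] for the recognised fields.
#' @return the run report (also written to `report.json` in the output
#'   directory), invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- read_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  stack <- tryCatch(read_stack_manifest(cfg$stack_manifest),
                    error = function(e) stage_error("stack", e))
  scr <- tryCatch(screen_stack(stack, cfg$r_max, cfg$vif_max),
                  error = function(e) stage_error("screen", e))
  occs <- tryCatch(load_occurrences(cfg$occurrences, stack$grid,
                                    stack$valid_mask, cfg$dedupe),
                   error = function(e) stage_error("occurrences", e))
  sp_seeds <- derive_seeds(cfg$seed, length(occs))
  names(sp_seeds) <- names(occs)
  species_out <- list(); maps <- list()
  for (sp in names(occs)) {
    res <- tryCatch({
      occ <- add_pseudo_absences(occs[[sp]], stack, seed = sp_seeds[sp])
      ens <- build_ensemble(occ, stack, cfg$algorithms,
                            n_rep = cfg$replicates, holdout = cfg$holdout,
                            seed = sp_seeds[sp], layers = scr$kept,
                            cutoff = cfg$auc_cutoff, strict = cfg$strict_cutoff)
      contrib <- jackknife_contribution(ens, occ, stack, scr$kept)
      map_path <- file.path(cfg$output_dir, paste0(gsub("\\W+", "_", sp), "_suitability.asc"))
      write_ascii_raster(ens$map, map_path)
      list(status = "ok", seed = unname(sp_seeds[sp]),
           n_presence = nrow(occ$presences), n_absence = length(occ$absences),
           weights = as.list(ens$weights), h = ens$h,
           mean_auc = as.list(ens$mean_auc), metrics = ens$metrics,
           contributions = as.list(contrib), map = map_path, ens = ens)
    }, error = function(e) {
      if (grepl("no admissible model", conditionMessage(e)))
        list(status = "unmodellable", seed = unname(sp_seeds[sp]),
             message = conditionMessage(e))
      else stage_error(paste0("ensemble:", sp), e)
    })
    if (identical(res$status, "ok")) maps[[sp]] <- res$ens$map
    res$ens <- NULL
    species_out[[sp]] <- res
  }
  overlay <- NULL; weights_out <- NULL
  if (!is.null(cfg$status) && length(maps)) {
    ct <- tryCatch(conservation_table(cfg$status),
                   error = function(e) stage_error("status", e))
    modelled <- ct[ct$species %in% names(maps), , drop = FALSE]
    if (nrow(modelled)) {
      # renormalise over the modellable species (logged in the report)
      w <- species_weights(modelled$I)
      overlay <- stack_multispecies(maps[modelled$species], w)
      overlay_path <- file.path(cfg$output_dir, "multispecies_suitability.asc")
      write_ascii_raster(overlay, overlay_path)
      weights_out <- list(species = modelled$species,
                          I = modelled$I, weight = w,
                          weight_rounded = round_weights(w),
                          excluded = setdiff(ct$species, modelled$species),
                          path = overlay_path)
      jsonlite::write_json(weights_out, file.path(cfg$output_dir, "weights.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  report <- list(config = cfg[setdiff(names(cfg), "algorithms")],
                 algorithms = cfg$algorithms,
                 screening = list(kept = scr$kept, dropped = scr$dropped),
                 species_seeds = as.list(sp_seeds),
                 species = species_out, overlay = weights_out)
  jsonlite::write_json(report, file.path(cfg$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

#' Write a complete synthetic fixture to disk
#'
#' Emits the artefacts a real study would supply: the raster stack (+
#' manifest), an occurrence CSV, a species status CSV, the true-suitability
#' raster(s), and the generating spec — all plain text.
#'
#' @param dir output directory.
#' @param spec a [landscape_spec()].
#' @param species named list of `list(vs = virtual_species, n_presence =,
#'   status = c(national_level, redlist, cites))`.
#' @param seed integer seed for presence sampling.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(dir, spec, species, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stack <- generate_landscape(spec)
  man <- data.frame(name = layer_names(stack),
                    path = paste0(layer_names(stack), ".asc"),
                    kind = vapply(stack$layers, `[[`, "", "kind"))
  for (l in stack$layers) write_ascii_raster(l, file.path(dir, paste0(l$name, ".asc")))
  jsonlite::write_json(man, file.path(dir, "stack.json"), auto_unbox = TRUE)
  occ_rows <- list(); status_rows <- list()
  sp_seeds <- derive_seeds(seed, length(species))
  for (i in seq_along(species)) {
    sp <- names(species)[i]
    s <- species[[i]]
    occ <- sample_virtual_occurrences(s$vs, stack, s$n_presence, sp_seeds[i], sp)
    occ_rows[[sp]] <- data.frame(species = sp, x = occ$presences$x, y = occ$presences$y)
    status_rows[[sp]] <- data.frame(species = sp,
                                    national_level = s$status[1],
                                    redlist = s$status[2], cites = s$status[3])
    write_ascii_raster(true_suitability(s$vs, stack),
                       file.path(dir, paste0(gsub("\\W+", "_", sp), "_truth.asc")))
  }
  utils::write.csv(do.call(rbind, occ_rows), file.path(dir, "occurrences.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, status_rows), file.path(dir, "status.csv"),
                   row.names = FALSE)
  invisible(dir)
}
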