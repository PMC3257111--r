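#' Default pipeline configuration
#'
#' All modelling defaults equal the standard CoMFA/CoMSIA settings: lattice
#' spacing 2 Angstrom with 4 Angstrom margin, CoMSIA attenuation factor 0.3,
#' CoMFA cutoff 30 kcal/mol with distance-dependent dielectric and 2.0
#' kcal/mol minimum-sigma column filter, contour levels 80%/20%, training
#' set of 81 compounds.
#'
#' @param ... Named overrides of any default (nested lists merged one level
#'   deep, e.g. `grid = list(spacing = 1)`).
#' @return A nested list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    paths = list(structures = NULL, activities = NULL, maps_dir = NULL,
                 output_dir = "qsar3d_run"),
    template_id = NULL,
    grid = list(spacing = 2.0, margin = 4.0),
    comsia = list(alpha = 0.3),
    comfa = list(cutoff = 30, dielectric = "distance", min_sigma = 2.0),
    pls = list(max_components = 10L),
    contours = list(high = 0.80, low = 0.20),
    split = list(n_train = 81L, seed = 1L),
    fields = paste0("comsia_", PROPERTY_KINDS))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Any key absent from the file falls back to [default_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(default_config, raw)
}

pipeline_log <- function(con, stage, fmt, ...) {
  line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
  message(line)
  if (!is.null(con)) writeLines(line, con)
  invisible(line)
}

#' Run the full ligand-based 3D-QSAR pipeline
#'
#' Chains the package's stages end-to-end: load structures, assign PEOE
#' charges where missing, read activities and convert Ki to pKi, perform the
#' activity-stratified train/test split, align all molecules onto the
#' template via their atom maps, build the lattice, compute the configured
#' molecular fields, search all field combinations by leave-one-out Q2,
#' compute the best model's fit and external-prediction statistics, and
#' extract stdev*coeff contours per field of the best model. All outputs
#' (ranked model table, statistics JSON, contour CSV/DX exports, aligned
#' structures, log) are written to the configured output directory;
#' re-running with the same configuration reproduces them exactly.
#'
#' @param config A `run_config` (or path to a YAML file).
#' @param molecules Optional list of [molecule()] objects to use instead of
#'   reading `config$paths$structures` (e.g. from [generate_dataset()]).
#' @param activities Optional activity data.frame (`id`, `ki_nM`) replacing
#'   `config$paths$activities`.
#' @param maps Optional named list of atom maps replacing
#'   `config$paths$maps_dir`; the default `"identity"` maps molecules with a
#'   shared scaffold.
#' @return Invisibly, a list with `config`, `activities` (with split),
#'   `alignment`, `grid`, `search` (the [model_search()] result), `best`
#'   (model name, fit, statistics), `contours`, `output_dir`.
#' @export
run_pipeline <- function(config = default_config(), molecules = NULL,
                         activities = NULL, maps = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$paths$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(out_dir, "log.txt"), "w")
  on.exit(close(log_con))
  yaml::write_yaml(unclass(config), file.path(out_dir, "run_config.yaml"))
  lg <- function(stage, fmt, ...) pipeline_log(log_con, stage, fmt, ...)

  # -- load ------------------------------------------------------------
  if (is.null(molecules)) {
    if (is.null(config$paths$structures))
      stop("[load] no structures supplied (config$paths$structures)")
    molecules <- load_structures(config$paths$structures)
    errs <- attr(molecules, "errors")
    for (e in errs) lg("load", "skipped %s", e)
  }
  ids <- vapply(molecules, `[[`, character(1L), "id")
  lg("load", "%d molecules", length(molecules))

  # -- charges ---------------------------------------------------------
  need <- !vapply(molecules, has_charges, logical(1L))
  if (any(need)) {
    molecules[need] <- lapply(molecules[need], assign_charges)
    lg("charges", "assigned PEOE charges to %d molecule(s)", sum(need))
  } else lg("charges", "all molecules carry charges")

  # -- weights ---------------------------------------------------------
  noww <- vapply(molecules, function(m) is.null(m$weights), logical(1L))
  if (any(noww)) {
    molecules[noww] <- lapply(molecules[noww], comsia_atom_weights)
    lg("weights", "derived CoMSIA property weights for %d molecule(s)",
       sum(noww))
  }

  # -- activities ------------------------------------------------------
  if (is.null(activities)) {
    if (is.null(config$paths$activities))
      stop("[activities] no activity table supplied")
    activities <- read_activities(config$paths$activities)
  } else {
    activities <- as.data.frame(activities)
    activities$id <- as.character(activities$id)
    if (!("pki" %in% names(activities)))
      activities$pki <- ki_to_pki(activities$ki_nM)
  }
  missing_act <- setdiff(ids, activities$id)
  if (length(missing_act))
    stop("[activities] no activity for structure id(s): ",
         paste(missing_act, collapse = ", "))
  activities <- activities[match(ids, activities$id), , drop = FALSE]
  n_train <- min(config$split$n_train, nrow(activities))
  activities <- split_train_test(activities, n_train,
                                 seed = config$split$seed)
  lg("split", "%d train / %d test compounds (seed %d)",
     sum(activities$subset == "train"), sum(activities$subset == "test"),
     config$split$seed)

  # -- alignment -------------------------------------------------------
  template_id <- config$template_id
  if (is.null(template_id))
    template_id <- activities$id[which.max(activities$pki)]
  if (is.null(maps)) {
    maps <- if (!is.null(config$paths$maps_dir)) {
      mapfiles <- list.files(config$paths$maps_dir, pattern = "\\.map$",
                             full.names = TRUE)
      stats::setNames(lapply(mapfiles, read_atom_map),
                      sub("\\.map$", "", basename(mapfiles)))
    } else "identity"
  }
  al <- align_set(molecules, template_id, maps)
  for (id in names(al$failures))
    lg("align", "FAILED %s: %s", id, al$failures[[id]])
  if (length(al$failures))
    stop("[align] alignment failed for: ",
         paste(names(al$failures), collapse = ", "))
  molecules <- al$molecules[ids]
  lg("align", "template %s; max rmsd %.3f A", template_id, max(al$rmsd))
  write_structures(molecules, file.path(out_dir, "aligned.sdf"))

  # -- grid + fields ---------------------------------------------------
  grid <- build_grid(molecules, spacing = config$grid$spacing,
                     margin = config$grid$margin)
  lg("grid", "%d x %d x %d lattice, spacing %.2f A",
     grid$dims[1L], grid$dims[2L], grid$dims[3L], config$grid$spacing)
  blocks <- compute_field_blocks(molecules, grid, config$fields,
                                 alpha = config$comsia$alpha,
                                 cutoff = config$comfa$cutoff,
                                 dielectric = config$comfa$dielectric)
  lg("fields", "computed %d field block(s): %s", length(blocks),
     paste(config$fields, collapse = ", "))

  # -- model search on the training set --------------------------------
  train <- activities$subset == "train"
  min_sigma <- c(comfa = config$comfa$min_sigma, comsia = 0)
  train_blocks <- lapply(blocks, function(b) {
    b$values <- b$values[train, , drop = FALSE]; b
  })
  search <- model_search(train_blocks, activities$pki[train],
                         max_components = config$pls$max_components,
                         min_sigma = min_sigma)
  utils::write.csv(search$table, file.path(out_dir, "model_search.csv"),
                   row.names = FALSE)
  best_name <- search$table$model[1L]
  best_fields <- strsplit(search$table$fields[1L], ",")[[1L]]
  lg("search", "%d combinations; best %s (ncomp %d, Q2 %.3f)",
     nrow(search$table), best_name, search$table$ncomp[1L],
     search$table$q2[1L])

  # -- best-model statistics -------------------------------------------
  dm_all <- assemble_descriptor_matrix(blocks[best_fields],
                                       min_sigma = min_sigma,
                                       fit_rows = train)
  fit <- pls_fit(dm_rows(dm_all, train), activities$pki[train],
                 search$table$ncomp[1L])
  st <- fit_statistics(fit, dm_rows(dm_all, train), activities$pki[train])
  stats_out <- list(model = best_name, fields = best_fields,
                    ncomp = search$table$ncomp[1L],
                    q2 = search$table$q2[1L], sep = search$table$sep[1L],
                    r2_ncv = st$r2_ncv, see = st$see, f = st$f,
                    contributions = as.list(field_contributions(fit)))
  if (any(!train)) {
    yhat <- predict(fit, dm_rows(dm_all, !train))
    stats_out$r2_pred <- r2_pred(activities$pki[!train], yhat,
                                 mean(activities$pki[train]))
    lg("stats", "R2_ncv %.3f, SEE %.3f, F %.1f, R2_pred %.3f",
       st$r2_ncv, st$see, st$f, stats_out$r2_pred)
  } else {
    lg("stats", "R2_ncv %.3f, SEE %.3f, F %.1f (no test set)",
       st$r2_ncv, st$see, st$f)
  }
  jsonlite::write_json(stats_out, file.path(out_dir, "best_model.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(
    data.frame(id = activities$id, subset = activities$subset,
               pki = activities$pki,
               predicted = predict(fit, dm_all)),
    file.path(out_dir, "predictions.csv"), row.names = FALSE)

  # -- contours --------------------------------------------------------
  contours <- list()
  for (k in best_fields) {
    sc <- stdev_coeff_field(fit, kind = k)
    ct <- suppressWarnings(
      extract_contours(sc, grid = grid, high = config$contours$high,
                       low = config$contours$low, kind = k))
    contours[[k]] <- ct
    write_contours_csv(ct, file.path(out_dir, paste0("contours_", k, ".csv")))
    write_dx(sc, grid, file.path(out_dir, paste0("stdev_coeff_", k, ".dx")))
    lg("contours", "%s: %d favored / %d disfavored points", k,
       nrow(ct$favored), nrow(ct$disfavored))
  }
  utils::write.csv(activities, file.path(out_dir, "activities.csv"),
                   row.names = FALSE)
  lg("done", "outputs in %s", out_dir)
  invisible(list(config = config, activities = activities, alignment = al,
                 grid = grid, search = search,
                 best = list(name = best_name, fields = best_fields,
                             fit = fit, stats = stats_out),
                 contours = contours, output_dir = out_dir))
}
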