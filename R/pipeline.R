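#' Pipeline run configuration
#'
#' Exactly one of `inputs` (paths to real data) or `synth` (a [synth_config()])
#' must be supplied. Defaults are desk-scale smoke values; study-scale values
#' (5000 trees, 100 topologies, 100 downsampling replicates) are one argument
#' away.
#'
#' @param inputs Named list of paths: `predictors` (trait CSV), `materials`
#'   (either raw source records with a `descriptors` column, to be coded, or an
#'   already-coded profile table), `trees` (multi-Newick).
#' @param synth A [synth_config()] for a fully synthetic run.
#' @param n_trees Decision trees per forest.
#' @param n_topologies Topologies used by the phylogenetic null (and the
#'   consensus tree).
#' @param n_downsample_reps Downsampling replicates.
#' @param include_mixed Keep the `mixed` class in the primary model.
#' @param contribution_families Model families for [contribution_analysis()].
#' @param pglm_candidates Named list of candidate predictor subsets for
#'   [select_model()] (over the columns `PC1`, `PC2`, `hand_wing_index` made
#'   available to the confirmatory track).
#' @param seed Integer master seed.
#' @param output_dir Directory for the result bundle.
#' @return A `run_config` list.
#' @export
run_config <- function(inputs = NULL, synth = NULL, n_trees = 200,
                       n_topologies = 20, n_downsample_reps = 20,
                       include_mixed = TRUE,
                       contribution_families = "primary",
                       pglm_candidates = default_pglm_candidates(),
                       seed = 1L, output_dir = "beaknest_run") {
  if (is.null(inputs) == is.null(synth)) {
    stop("supply exactly one of 'inputs' (real data paths) or 'synth' (synthetic config)")
  }
  if (!is.null(inputs)) {
    need <- c("predictors", "materials", "trees")
    if (!all(need %in% names(inputs))) {
      stop("inputs must name paths: ", paste(need, collapse = ", "))
    }
  }
  stopifnot(n_trees >= 1, n_topologies >= 1, n_downsample_reps >= 1)
  structure(list(inputs = inputs, synth = synth, n_trees = as.integer(n_trees),
                 n_topologies = as.integer(n_topologies),
                 n_downsample_reps = as.integer(n_downsample_reps),
                 include_mixed = include_mixed,
                 contribution_families = contribution_families,
                 pglm_candidates = pglm_candidates,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' @rdname run_config
#' @export
default_pglm_candidates <- function() {
  list("(intercept)" = character(0),
       "PC1" = "PC1",
       "PC2" = "PC2",
       "PC1+PC2" = c("PC1", "PC2"),
       "PC1+PC2+hand_wing_index" = c("PC1", "PC2", "hand_wing_index"))
}

load_pipeline_data <- function(config) {
  if (!is.null(config$synth)) {
    ds <- generate_dataset(config$synth)
    return(list(predictors = ds$predictors, profiles = ds$profiles,
                trees = ds$trees))
  }
  paths <- config$inputs
  for (p in unlist(paths)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  predictors <- utils::read.csv(paths$predictors, stringsAsFactors = TRUE)
  predictors$species_id <- as.character(predictors$species_id)
  materials <- utils::read.csv(paths$materials, stringsAsFactors = FALSE)
  profiles <- if ("descriptors" %in% names(materials)) {
    code_materials(materials)
  } else {
    class(materials) <- c("material_profiles", "data.frame")
    materials
  }
  trees <- read_newick(paths$trees)
  list(predictors = predictors, profiles = profiles, trees = as_multiphylo(trees))
}

write_report_csvs <- function(report, name, dir) {
  utils::write.csv(as.data.frame(unclass(report$confusion)),
                   file.path(dir, paste0("confusion_", name, ".csv")))
  utils::write.csv(
    data.frame(class = names(report$per_class_accuracy),
               n = as.integer(report$n),
               accuracy = report$per_class_accuracy,
               row.names = NULL),
    file.path(dir, paste0("per_class_", name, ".csv")), row.names = FALSE)
}

#' Row-normalized confusion heat map
#'
#' Observed classes as rows, model-assigned classes as columns; darker cells
#' mark the popular guesses for each observed class.
#'
#' @param report A `classifier_report`.
#' @param path Optional PDF path; when `NULL`, draws on the current device.
#' @export
plot_confusion <- function(report, path = NULL) {
  prop <- report$confusion_prop
  if (!is.null(path)) {
    grDevices::pdf(path, width = 6, height = 5.5)
    on.exit(grDevices::dev.off())
  }
  k <- nrow(prop)
  pal <- grDevices::colorRampPalette(c("white", "#c6dbef", "#2171b5", "#08306b"))(100)
  op <- graphics::par(mar = c(6, 6, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::image(seq_len(ncol(prop)), seq_len(k), t(prop[rev(seq_len(k)), , drop = FALSE]),
                  col = pal, zlim = c(0, 1), axes = FALSE, xlab = "", ylab = "")
  graphics::axis(1, at = seq_len(ncol(prop)), labels = colnames(prop), las = 2)
  graphics::axis(2, at = seq_len(k), labels = rev(rownames(prop)), las = 1)
  graphics::mtext("model-assigned", side = 1, line = 4.5)
  graphics::mtext("observed", side = 2, line = 4.5)
  graphics::box()
  invisible(report)
}

#' Run the full analysis pipeline
#'
#' Orchestrates material coding, the three random-forest model families, the
#' phylogenetic-simulation and downsampling nulls, the predictor-contribution
#' decomposition and the confirmatory phylogenetic logistic regressions, and
#' writes a result bundle: coded profiles, per-model confusion matrices and
#' per-class accuracies (CSV), confusion heat maps (PDF), null replicate
#' tables, a five-column per-material summary table (material / sample size /
#' accuracy rate / phylogenetic simulation accuracy rate / downsampled
#' predictive power), model-selection and coefficient tables for the
#' phylogenetic GLMs, and a machine-readable manifest. Reruns with the same
#' config and seed are byte-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`reports`, `nulls`,
#'   `summary`, `contributions`, `pglm`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- "load-inputs"
  result <- tryCatch({
    dat <- load_pipeline_data(config)
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- config$output_dir
    rf_cfg <- rf_config(n_trees = config$n_trees, seed = config$seed)
    cats <- material_categories()

    stage <- "material-coding"
    write_material_profiles(dat$profiles, file.path(out, "material_profiles.csv"))
    al <- align_profiles(dat$profiles, dat$predictors)

    stage <- "random-forest-models"
    binary <- run_binary_models(dat$profiles, dat$predictors, rf_cfg)
    primary <- run_primary_model(dat$profiles, dat$predictors, rf_cfg,
                                 include_mixed = config$include_mixed)
    specialist <- run_specialist_model(dat$profiles, dat$predictors, rf_cfg)
    for (nm in names(binary)) write_report_csvs(binary[[nm]], paste0("binary_", nm), out)
    write_report_csvs(primary, "primary", out)
    write_report_csvs(specialist, "specialist", out)
    plot_confusion(primary, file.path(out, "confusion_primary.pdf"))
    plot_confusion(specialist, file.path(out, "confusion_specialist.pdf"))

    stage <- "phylogenetic-null"
    sims <- simulate_phylo_predictors(al$predictors, dat$trees,
                                      n_topologies = config$n_topologies,
                                      seed = config$seed)
    null_acc <- function(labels, sims_list) {
      acc <- vapply(sims_list, function(sp) {
        sp <- sp[match(names(labels), sp$species_id), , drop = FALSE]
        fit_family_forest(sp, labels, rf_cfg)
      }, numeric(1))
      null_report(unname(acc), "phylogenetic")
    }
    phylo_nulls <- list()
    for (cat in names(binary)) {
      lab <- family_labels(al$profiles, cat)
      labels <- stats::setNames(lab$y, al$profiles$species_id[lab$keep])
      phylo_nulls[[cat]] <- null_acc(labels, sims)
    }
    lab <- family_labels(al$profiles, "primary", config$include_mixed)
    primary_labels <- stats::setNames(lab$y, al$profiles$species_id[lab$keep])
    phylo_nulls$primary <- null_acc(primary_labels,
                                    lapply(sims, function(sp) sp[lab$keep, , drop = FALSE]))
    lab_sp <- family_labels(al$profiles, "specialist")
    specialist_labels <- stats::setNames(lab_sp$y, al$profiles$species_id[lab_sp$keep])
    phylo_nulls$specialist <- null_acc(specialist_labels,
                                       lapply(sims, function(sp) sp[lab_sp$keep, , drop = FALSE]))

    stage <- "downsampling-null"
    down_nulls <- list()
    for (cat in names(binary)) {
      lab <- family_labels(al$profiles, cat)
      labels <- stats::setNames(lab$y, al$profiles$species_id[lab$keep])
      down_nulls[[cat]] <- downsample_null(labels, al$predictors, rf_cfg,
                                           n_reps = config$n_downsample_reps,
                                           seed = config$seed)
    }
    down_nulls$primary <- downsample_null(primary_labels, al$predictors, rf_cfg,
                                          n_reps = config$n_downsample_reps,
                                          seed = config$seed)
    down_nulls$specialist <- downsample_null(specialist_labels, al$predictors,
                                             rf_cfg,
                                             n_reps = config$n_downsample_reps,
                                             seed = config$seed)
    null_rows <- do.call(rbind, lapply(names(phylo_nulls), function(nm) {
      data.frame(model = nm,
                 null_kind = c("phylogenetic", "downsampled"),
                 median = c(phylo_nulls[[nm]]$summary$median,
                            down_nulls[[nm]]$summary$median),
                 iqr_lower = c(phylo_nulls[[nm]]$summary$iqr["lower"],
                               down_nulls[[nm]]$summary$iqr["lower"]),
                 iqr_upper = c(phylo_nulls[[nm]]$summary$iqr["upper"],
                               down_nulls[[nm]]$summary$iqr["upper"]),
                 n_replicates = c(phylo_nulls[[nm]]$n_replicates,
                                  down_nulls[[nm]]$n_replicates))
    }))
    utils::write.csv(null_rows, file.path(out, "null_summaries.csv"), row.names = FALSE)

    stage <- "summary-table"
    summary_tab <- data.frame(
      material = names(binary),
      `sample size` = vapply(names(binary), function(cat) {
        sum(al$profiles[[paste0("used_", cat)]] == 1)
      }, numeric(1)),
      `accuracy rate` = vapply(binary, `[[`, numeric(1), "overall_accuracy"),
      `phylogenetic simulation accuracy rate` = vapply(
        names(binary), function(nm) phylo_nulls[[nm]]$summary$median, numeric(1)),
      `downsampled predictive power` = vapply(
        names(binary), function(nm) down_nulls[[nm]]$summary$median, numeric(1)),
      check.names = FALSE)
    utils::write.csv(summary_tab, file.path(out, "summary_table.csv"),
                     row.names = FALSE)

    stage <- "contribution-analysis"
    contribs <- list()
    for (fam in config$contribution_families) {
      tab <- contribution_analysis(dat$profiles, dat$predictors, rf_cfg, fam)
      tab <- cbind(model = fam, tab,
                   full_accuracy = attr(tab, "full_accuracy"),
                   baseline_accuracy = attr(tab, "baseline_accuracy"))
      contribs[[fam]] <- tab
    }
    contrib_tab <- do.call(rbind, contribs)
    utils::write.csv(contrib_tab, file.path(out, "contributions.csv"),
                     row.names = FALSE)

    stage <- "phylogenetic-glm"
    cons <- consensus_tree(dat$trees[seq_len(min(config$n_topologies,
                                                 length(dat$trees)))])
    cons <- prune_to_taxa(cons, al$profiles$species_id)
    cont <- standardize(al$predictors[continuous_predictors()])
    pca <- beak_pca(al$predictors[beak_predictors()])
    pg_pred <- data.frame(PC1 = pca$scores[, 1], PC2 = pca$scores[, 2],
                          hand_wing_index = cont[, "hand_wing_index"])
    rownames(pg_pred) <- al$predictors$species_id
    pglm <- list()
    coef_rows <- list()
    for (cat in cats) {
      y <- stats::setNames(al$profiles[[paste0("used_", cat)]],
                           al$profiles$species_id)
      if (length(unique(y)) < 2) next
      sel <- select_model(config$pglm_candidates, y, pg_pred, cons)
      utils::write.csv(sel, file.path(out, paste0("pglm_selection_", cat, ".csv")),
                       row.names = FALSE)
      best <- attr(sel, "fits")[[sel$model[1]]]
      coef_rows[[cat]] <- data.frame(material = cat, model = sel$model[1],
                                     term = names(best$coefficients),
                                     estimate = best$coefficients,
                                     se = best$se, z = best$zscore,
                                     alpha = best$alpha, aic = best$aic,
                                     row.names = NULL)
      pglm[[cat]] <- sel
    }
    utils::write.csv(do.call(rbind, c(coef_rows, list(make.row.names = FALSE))),
                     file.path(out, "pglm_coefficients.csv"), row.names = FALSE)

    stage <- "manifest"
    cfg_json <- jsonlite::toJSON(config_for_manifest(config), auto_unbox = TRUE,
                                 digits = NA)
    cfg_file <- file.path(out, "config.json")
    writeLines(cfg_json, cfg_file)
    manifest <- list(seed = config$seed,
                     package_version = as.character(utils::packageVersion("beaknest")),
                     r_version = R.version.string,
                     config_hash = unname(tools::md5sum(cfg_file)),
                     outputs = sort(setdiff(list.files(out), "manifest.json")))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    list(reports = c(binary, list(primary = primary, specialist = specialist)),
         nulls = list(phylogenetic = phylo_nulls, downsampled = down_nulls),
         summary = summary_tab, contributions = contrib_tab, pglm = pglm,
         manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

config_for_manifest <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- NULL  # hash the scientific config, not the destination
  if (!is.null(cfg$synth)) {
    cfg$synth <- lapply(unclass(cfg$synth), function(v) {
      if (is.matrix(v)) as.data.frame(v) else v
    })
  }
  cfg
}

#' Read a run configuration from JSON or YAML
#'
#' @param path Path to a `.json` or `.yaml`/`.yml` file with fields matching
#'   the arguments of [run_config()] (and, optionally, a `synth` block with
#'   [synth_config()] fields).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required for YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$synth)) {
    syn <- raw$synth
    if (!is.null(syn$effect_matrix)) {
      syn$effect_matrix <- as.matrix(syn$effect_matrix)
    }
    raw$synth <- do.call(synth_config, syn)
  }
  do.call(run_config, raw)
}
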