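#' Random-forest model configuration
#'
#' @param n_trees Number of decision trees in the ensemble (default 5000, the
#'   study-scale value; reduce for smoke runs).
#' @param mtry Features tried per split; default `floor(sqrt(p))`, the
#'   conventional classification default.
#' @param seed Integer seed applied before every fit for reproducibility.
#' @return An `rf_config` list.
#' @export
rf_config <- function(n_trees = 5000, mtry = NULL, seed = 1L) {
  stopifnot(n_trees >= 1, is.null(mtry) || mtry >= 1)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 seed = as.integer(seed)),
            class = "rf_config")
}

#' The naive beak-only predictor subset
#'
#' The four beak measurements plus body mass, used for the baseline models
#' that ask how far beak morphology alone predicts material use.
#' @return Character vector of 5 predictor names.
#' @export
beak_predictors <- function() {
  c("bill_length_total", "bill_length_nares", "bill_width_nares",
    "bill_depth_nares", "body_mass")
}

prepare_predictor_frame <- function(predictors, predictor_cols = NULL) {
  stopifnot(is.data.frame(predictors), "species_id" %in% names(predictors))
  x <- predictors[setdiff(names(predictors), "species_id")]
  if (!is.null(predictor_cols)) {
    missing <- setdiff(predictor_cols, names(x))
    if (length(missing) > 0) {
      stop("predictor columns not found: ", paste(missing, collapse = ", "))
    }
    x <- x[predictor_cols]
  }
  for (nm in names(x)) {
    if (is.character(x[[nm]])) x[[nm]] <- factor(x[[nm]])
  }
  rownames(x) <- predictors$species_id
  x
}

#' Fit a random-forest classifier with out-of-bag predictions
#'
#' Bootstrap-aggregated classification trees (via the randomForest package,
#' with native categorical splits for factor predictors). Every species
#' receives an out-of-bag (OOB) predicted class — the majority vote over
#' trees whose bootstrap sample excluded it — which is the basis of all
#' accuracy reporting; no separate test split is used.
#'
#' @param predictors Data frame with a `species_id` column plus predictor
#'   columns (numeric or factor). Rows with missing values are dropped with a
#'   logged count.
#' @param labels Class label per species: a vector aligned with `predictors`
#'   rows, or named by `species_id`.
#' @param config An [rf_config()].
#' @param predictor_cols Optional character vector restricting the predictor
#'   columns used (e.g. [beak_predictors()]).
#' @return A `beaknest_forest` list: `forest`, `oob` (OOB predicted classes,
#'   `NA` for species never out of bag), `observed`, `species_id`, `config`,
#'   `encoding`, `n_dropped`.
#' @export
fit_forest <- function(predictors, labels, config = rf_config(),
                       predictor_cols = NULL) {
  stopifnot(inherits(config, "rf_config"))
  x <- prepare_predictor_frame(predictors, predictor_cols)
  if (!is.null(names(labels))) {
    missing <- setdiff(rownames(x), names(labels))
    if (length(missing) > 0) stop("labels missing for: ", paste(missing, collapse = ", "))
    labels <- labels[rownames(x)]
  } else if (length(labels) != nrow(x)) {
    stop("labels length must match predictor rows")
  }
  y <- droplevels(factor(labels))
  keep <- stats::complete.cases(x) & !is.na(y)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " species dropped for missing predictor or label values")
    x <- x[keep, , drop = FALSE]
    y <- droplevels(y[keep])
  }
  if (nlevels(y) < 2) stop("labels contain a single class; nothing to classify")
  small <- table(y) < 2
  if (any(small)) {
    warning("classes with < 2 members: ",
            paste(names(which(small)), collapse = ", "))
  }
  mtry <- if (is.null(config$mtry)) max(1, floor(sqrt(ncol(x)))) else config$mtry
  set.seed(config$seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = config$n_trees,
                                   mtry = mtry)
  structure(list(forest = rf, oob = rf$predicted, observed = y,
                 species_id = rownames(x), config = config,
                 encoding = "factor", n_dropped = n_dropped),
            class = "beaknest_forest")
}

#' Out-of-bag accuracy report for a fitted forest
#'
#' @param fitted A `beaknest_forest` from [fit_forest()].
#' @return A `classifier_report` list: `overall_accuracy` (percent of species
#'   whose OOB prediction matches the observed class), `per_class_accuracy`
#'   (percent, named by class), `confusion` (counts, rows = observed, columns
#'   = predicted), `confusion_prop` (row-normalized), `n` (per-class sample
#'   sizes), `n_total`, `n_excluded` (species without an OOB prediction,
#'   excluded with a warning), and `metadata`.
#' @export
oob_report <- function(fitted) {
  stopifnot(inherits(fitted, "beaknest_forest"))
  obs <- fitted$observed
  pred <- fitted$oob
  has_oob <- !is.na(pred)
  n_excluded <- sum(!has_oob)
  if (n_excluded > 0) {
    warning(n_excluded, " species lack an out-of-bag prediction ",
            "(increase n_trees); excluded from accuracy")
    obs <- obs[has_oob]
    pred <- pred[has_oob]
  }
  lev <- levels(fitted$observed)
  confusion <- table(observed = factor(obs, lev), predicted = factor(pred, lev))
  confusion <- unclass(confusion)
  n <- rowSums(confusion)
  prop <- sweep(confusion, 1, pmax(n, 1), "/")
  overall <- 100 * sum(diag(confusion)) / sum(confusion)
  per_class <- 100 * diag(confusion) / pmax(n, 1)
  structure(list(overall_accuracy = overall,
                 per_class_accuracy = per_class,
                 confusion = confusion, confusion_prop = prop,
                 n = n, n_total = sum(confusion), n_excluded = n_excluded,
                 metadata = list(encoding = fitted$encoding,
                                 n_trees = fitted$config$n_trees,
                                 seed = fitted$config$seed)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("Classifier report (out-of-bag)\n")
  cat(sprintf("  overall accuracy: %.1f%% (n = %d)\n",
              x$overall_accuracy, x$n_total))
  cat("  per-class accuracy (%):\n")
  print(round(x$per_class_accuracy, 1))
  invisible(x)
}

# Align profiles and predictors on shared species, excluding species flagged
# for omission during material coding.
align_profiles <- function(profiles, predictors) {
  stopifnot(is.data.frame(profiles), "species_id" %in% names(profiles))
  if ("omit" %in% names(profiles)) {
    profiles <- profiles[!profiles$omit, , drop = FALSE]
  }
  common <- intersect(profiles$species_id, predictors$species_id)
  if (length(common) == 0) stop("profiles and predictors share no species")
  list(profiles = profiles[match(common, profiles$species_id), , drop = FALSE],
       predictors = predictors[match(common, predictors$species_id), , drop = FALSE])
}

#' Binary per-material random-forest models
#'
#' One two-class model per material category: does the species use that
#' material or not, over all coded species.
#'
#' @param profiles A `material_profiles` data frame.
#' @param predictors Predictor data frame (`species_id` + columns).
#' @param config An [rf_config()].
#' @param predictor_cols Optional predictor subset.
#' @return Named list of up to 7 `classifier_report`s; categories used by all
#'   or no species are skipped with a warning.
#' @export
run_binary_models <- function(profiles, predictors, config = rf_config(),
                              predictor_cols = NULL) {
  al <- align_profiles(profiles, predictors)
  out <- list()
  for (cat in material_categories()) {
    used <- al$profiles[[paste0("used_", cat)]]
    if (length(unique(used)) < 2) {
      warning("category '", cat, "' used by all or no species; skipped")
      next
    }
    y <- factor(ifelse(used == 1, "user", "non-user"),
                levels = c("non-user", "user"))
    fit <- fit_forest(al$predictors, y, config, predictor_cols)
    out[[cat]] <- oob_report(fit)
  }
  out
}

#' Primary-material random-forest model
#'
#' Multiclass model of each species' primary material (7 categories plus the
#' `mixed` sentinel for species whose sources disagree; `mixed` can be
#' excluded since it carries no ecological meaning).
#'
#' @inheritParams run_binary_models
#' @param include_mixed Keep species whose primary material is `mixed` as an
#'   eighth class (default `TRUE`).
#' @return A `classifier_report`.
#' @export
run_primary_model <- function(profiles, predictors, config = rf_config(),
                              include_mixed = TRUE, predictor_cols = NULL) {
  al <- align_profiles(profiles, predictors)
  keep <- if (include_mixed) rep(TRUE, nrow(al$profiles)) else al$profiles$primary != "mixed"
  fit <- fit_forest(al$predictors[keep, , drop = FALSE],
                    al$profiles$primary[keep], config, predictor_cols)
  oob_report(fit)
}

#' Specialist-only random-forest model
#'
#' The primary-material model restricted to material specialists (species
#' using exactly one category).
#'
#' @inheritParams run_binary_models
#' @return A `classifier_report`.
#' @export
run_specialist_model <- function(profiles, predictors, config = rf_config(),
                                 predictor_cols = NULL) {
  al <- align_profiles(profiles, predictors)
  keep <- al$profiles$specialist %in% TRUE
  if (sum(keep) < 4) stop("too few specialists to model")
  y <- al$profiles$primary[keep]
  tab <- table(y)
  if (sum(tab >= 2) < 2) stop("need >= 2 specialist classes with >= 2 members")
  fit <- fit_forest(al$predictors[keep, , drop = FALSE], y, config,
                    predictor_cols)
  oob_report(fit)
}

family_labels <- function(profiles, model_family, include_mixed = TRUE) {
  if (model_family == "primary") {
    keep <- if (include_mixed) rep(TRUE, nrow(profiles)) else profiles$primary != "mixed"
    list(keep = keep, y = profiles$primary[keep])
  } else if (model_family == "specialist") {
    keep <- profiles$specialist %in% TRUE
    list(keep = keep, y = profiles$primary[keep])
  } else if (model_family %in% material_categories()) {
    used <- profiles[[paste0("used_", model_family)]]
    list(keep = rep(TRUE, nrow(profiles)),
         y = factor(ifelse(used == 1, "user", "non-user"),
                    levels = c("non-user", "user")))
  } else {
    stop("unknown model family: ", model_family)
  }
}

#' Marginal and independent predictor contributions
#'
#' For each predictor, refits the model (same seed policy) with that predictor
#' removed (`marginal` contribution = full-model accuracy minus the reduced
#' accuracy) and with only that predictor included (`independent` contribution
#' = accuracy of the one-predictor model). The majority-class frequency is
#' reported alongside as the chance baseline.
#'
#' @inheritParams run_binary_models
#' @param model_family One of `"primary"`, `"specialist"`, or a material
#'   category name (its binary model).
#' @return Data frame with columns `predictor`, `marginal`, `independent`
#'   (percent accuracy points); attributes `full_accuracy` and
#'   `baseline_accuracy`.
#' @export
contribution_analysis <- function(profiles, predictors, config = rf_config(),
                                  model_family = "primary",
                                  predictor_cols = NULL) {
  al <- align_profiles(profiles, predictors)
  lab <- family_labels(al$profiles, model_family)
  px <- al$predictors[lab$keep, , drop = FALSE]
  y <- lab$y
  cols <- if (is.null(predictor_cols)) {
    setdiff(names(px), "species_id")
  } else predictor_cols
  acc_for <- function(use_cols) {
    oob_report(fit_forest(px, y, config, predictor_cols = use_cols))$overall_accuracy
  }
  full <- acc_for(cols)
  marg <- ind <- numeric(length(cols))
  for (i in seq_along(cols)) {
    marg[i] <- full - acc_for(setdiff(cols, cols[i]))
    ind[i] <- acc_for(cols[i])
  }
  baseline <- 100 * max(table(droplevels(factor(y)))) / length(y)
  out <- data.frame(predictor = cols, marginal = marg, independent = ind,
                    stringsAsFactors = FALSE)
  attr(out, "full_accuracy") <- full
  attr(out, "baseline_accuracy") <- baseline
  out
}
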