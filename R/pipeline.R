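#' Run the full analysis pipeline
#'
#' Orchestrates generate/load -> optical characterization -> PARAFAC ->
#' kinetics inversion -> association from a single configuration: a named
#' list (or YAML file path) with any of
#' \describe{
#'   \item{dataset_dir}{directory to load with [read_dataset()]; when absent
#'     a synthetic dataset is generated from `synthetic` parameters (passed
#'     to [generate_dataset()]).}
#'   \item{parafac}{list of [fit_parafac()] options (`n_components`,
#'     `n_restarts`, `tol`, `max_iter`, `scatter_halfwidths`).}
#'   \item{constants}{named [rate_constants()] overrides.}
#'   \item{hix_form}{HIX definition variant (`"classic"` or `"ohno"`).}
#'   \item{assoc}{list: `responses` (default `"ln_phi_1O2"`), `gbt_search`,
#'     `nfold`.}
#'   \item{seed}{global seed; all stage seeds derive from it.}
#'   \item{out_dir}{when set, stage tables are written there as CSV/JSON.}
#' }
#' Association models are fitted in cross-validation-only mode when fewer
#' than 20 samples are available. Every stage is a pure function of (inputs,
#' config, seed), so re-running a configuration reproduces all numbers
#' exactly.
#'
#' @param config named list or path to a YAML file.
#' @return An object of class `photox_report`: list with `config`, `samples`,
#'   `indices`, `parafac`, `fractions`, `oxidants`, `features`,
#'   `correlations`, `mlr`, `gbt`, `truth_comparison` (when truth is
#'   available), `warnings` (per stage), `files` (when `out_dir` was set).
#' @export
#' @examples
#' \donttest{
#' report <- run_pipeline(list(seed = 1,
#'                             synthetic = list(include_eems = FALSE),
#'                             parafac = list(skip = TRUE)))
#' report$oxidants
#' }
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  stage_warnings <- list()
  run_stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        abort(paste0("stage '", name, "': ", conditionMessage(e)))
      }),
      warning = function(w) {
        stage_warnings[[name]] <<- c(stage_warnings[[name]],
                                     conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }

  constants <- do.call(rate_constants, as.list(config$constants %||% list()))

  dataset <- run_stage("data", {
    if (!is.null(config$dataset_dir)) {
      read_dataset(config$dataset_dir)
    } else {
      args <- as.list(config$synthetic %||% list())
      args$seed <- derive_seed(seed, "dataset")
      args$constants <- constants
      do.call(generate_dataset, args)
    }
  })

  indices <- run_stage("indices", {
    purrr::map_dfr(dataset$samples$sample_id, function(id) {
      sp <- dataset$absorbance[[id]]
      if (is.null(sp)) abort(paste0("no absorbance spectrum for ", id))
      doc <- dataset$samples$doc_mgC_L[dataset$samples$sample_id == id]
      if (!is.null(dataset$eems[[id]])) {
        dplyr::bind_cols(tibble::tibble(sample_id = id),
                         optical_indices(sp, dataset$eems[[id]], doc,
                                         hix_form = config$hix_form %||%
                                           "classic"))
      } else {
        e23 <- suppressWarnings(e2_e3(sp))
        tibble::tibble(sample_id = id, e2_e3 = e23,
                       suva254 = suva254(sp, doc),
                       e2_e3_defined = is.finite(e23), suva254_defined = TRUE)
      }
    })
  })

  pf_cfg <- config$parafac %||% list()
  parafac_model <- NULL
  fractions <- NULL
  if (!isTRUE(pf_cfg$skip) && !is.null(dataset$eems)) {
    parafac_model <- run_stage("parafac", {
      cube <- eem_cube(dataset$eems)
      hw <- pf_cfg$scatter_halfwidths
      if (!is.null(hw)) cube <- excise_scatter(cube, hw[1], hw[2])
      fit <- fit_parafac(cube,
                         n_components = pf_cfg$n_components %||% 6L,
                         n_restarts = pf_cfg$n_restarts %||% 10L,
                         tol = pf_cfg$tol %||% 1e-8,
                         max_iter = pf_cfg$max_iter %||% 2000L,
                         seed = derive_seed(seed, "parafac"))
      if (!is.null(dataset$library)) {
        fit <- match_components(fit, dataset$library)
      }
      fit
    })
    fractions <- run_stage("fractions", component_fractions(parafac_model))
  }

  oxidants <- run_stage("photokin", {
    oxidant_results(dataset, constants = constants)
  })

  features <- run_stage("features", {
    build_feature_table(dataset$samples, indices, fractions, oxidants)
  })

  assoc_cfg <- config$assoc %||% list()
  responses <- assoc_cfg$responses %||% "ln_phi_1O2"
  predictor_cols <- intersect(
    c("e2_e3", "suva254", "bix", "fix", "hix",
      grep("^frac_", names(features), value = TRUE),
      "protein_mg_L", "polysaccharide_mg_L"),
    names(features))

  correlations <- run_stage("correlations", {
    resp_cols <- intersect(c(paste0("ln_phi_", oxidant_channels()),
                             paste0("ln_riss_", oxidant_channels())),
                           names(features))
    spearman_matrix(features, vars = c(predictor_cols, resp_cols))
  })

  mlr <- list(); gbt <- list()
  for (resp in responses) {
    if (!resp %in% names(features)) next
    mlr[[resp]] <- run_stage(paste0("mlr_", resp), {
      fit_mlr(features, resp, predictors = predictor_cols,
              nfold = assoc_cfg$nfold %||% 5L,
              seed = derive_seed(seed, paste0("mlr_", resp)))
    })
    gbt[[resp]] <- run_stage(paste0("gbt_", resp), {
      fit_gbt(features, resp, features = predictor_cols,
              search_config = as.list(assoc_cfg$gbt_search %||% list()),
              nfold = assoc_cfg$nfold %||% 5L,
              seed = derive_seed(seed, paste0("gbt_", resp)))
    })
  }

  truth_comparison <- NULL
  if (!is.null(dataset$truth)) {
    truth_comparison <- run_stage("truth_comparison", {
      compare_to_truth(oxidants, dataset$truth)
    })
  }

  report <- structure(list(
    config = config, samples = dataset$samples, indices = indices,
    parafac = parafac_model, fractions = fractions, oxidants = oxidants,
    features = features, correlations = correlations, mlr = mlr, gbt = gbt,
    truth_comparison = truth_comparison, warnings = stage_warnings,
    seed = seed
  ), class = "photox_report")

  if (!is.null(config$out_dir)) {
    report$files <- write_report(report, config$out_dir)
  }
  report
}

#' Compare recovered oxidant quantities to generator truth
#'
#' @param oxidants [oxidant_results()] tibble.
#' @param truth a dataset `truth` tibble with `phi_*` and `riss_*` columns.
#' @return A tibble per sample x channel with recovered and true `phi` and
#'   `riss` and their relative errors.
#' @export
compare_to_truth <- function(oxidants, truth) {
  purrr::map_dfr(oxidant_channels(), function(ch) {
    sub <- oxidants[oxidants$channel == ch, ]
    tr <- truth[match(sub$sample_id, truth$sample_id), ]
    tibble::tibble(
      sample_id = sub$sample_id, channel = ch,
      phi = sub$phi, phi_true = tr[[paste0("phi_", ch)]],
      riss = sub$riss, riss_true = tr[[paste0("riss_", ch)]],
      rel_err_phi = abs(sub$phi - tr[[paste0("phi_", ch)]]) /
        tr[[paste0("phi_", ch)]],
      rel_err_riss = abs(sub$riss - tr[[paste0("riss_", ch)]]) /
        tr[[paste0("riss_", ch)]]
    )
  })
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  save_csv <- function(x, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(x, path)
    files <<- c(files, path)
  }
  save_csv(report$indices, "indices.csv")
  if (!is.null(report$fractions)) save_csv(report$fractions, "fractions.csv")
  save_csv(report$oxidants, "oxidants.csv")
  save_csv(tidy(report$correlations), "correlations.csv")
  if (!is.null(report$truth_comparison)) {
    save_csv(report$truth_comparison, "truth_comparison.csv")
  }
  if (!is.null(report$parafac)) {
    path <- file.path(out_dir, "parafac_model.json")
    jsonlite::write_json(list(
      n_components = report$parafac$n_components,
      explained_variance = report$parafac$explained_variance,
      converged = report$parafac$converged,
      labels = report$parafac$labels,
      scores = report$parafac$scores,
      ex_loadings = report$parafac$ex_loadings,
      em_loadings = report$parafac$em_loadings
    ), path, digits = NA, matrix = "rowmajor", auto_unbox = TRUE)
    files <- c(files, path)
  }
  for (resp in names(report$mlr)) {
    path <- file.path(out_dir, paste0("mlr_", resp, ".json"))
    m <- report$mlr[[resp]]
    jsonlite::write_json(list(response = m$response, selected = m$selected,
                              coefficients = m$coefficients,
                              metrics = m$metrics),
                         path, digits = NA, auto_unbox = TRUE)
    files <- c(files, path)
  }
  for (resp in names(report$gbt)) {
    path <- file.path(out_dir, paste0("gbt_", resp, ".json"))
    g <- report$gbt[[resp]]
    jsonlite::write_json(list(response = g$response,
                              hyperparameters = g$hyperparameters,
                              metrics = g$metrics, importance = g$importance),
                         path, digits = NA, auto_unbox = TRUE)
    files <- c(files, path)
  }
  files
}

#' @export
print.photox_report <- function(x, ...) {
  cat("<photox_report> ", nrow(x$samples), " samples, seed ", x$seed, "\n",
      sep = "")
  if (!is.null(x$parafac)) {
    cat("  PARAFAC: ", x$parafac$n_components, " components, ",
        signif(100 * x$parafac$explained_variance, 4), "% variance\n",
        sep = "")
  }
  cat("  oxidant channels: ",
      paste(unique(x$oxidants$channel), collapse = ", "), "\n", sep = "")
  if (!is.null(x$truth_comparison)) {
    cat("  max |rel err| Phi vs truth: ",
        signif(max(x$truth_comparison$rel_err_phi), 3), "\n", sep = "")
  }
  if (length(x$warnings)) {
    cat("  warnings in stages: ", paste(names(x$warnings), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
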