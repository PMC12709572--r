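#' Write and read a dataset directory
#'
#' `write_dataset()` serializes a [generate_dataset()] object (or any dataset
#' with the same structure) to a plain-text directory layout:
#' \preformatted{
#'   samples.csv                 metadata + composition features
#'   absorbance/<sample>.csv     wavelength_nm, absorbance_per_cm
#'   eem/<sample>.csv            ex_nm column, emission-grid header
#'   lamp.csv                    wavelength_nm, photon_flux
#'   kinetics/<sample>_<probe>.csv  time_s, concentration_M, replicate, ...
#'   truth.json                  ground truth (synthetic datasets only)
#'   config.yaml                 generator configuration echo
#' }
#' `read_dataset()` reconstructs the dataset from such a directory; numeric
#' values round-trip to full double precision.
#'
#' @param dataset a `photox_dataset`.
#' @param dir target directory (created if needed).
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()`
#'   returns a `photox_dataset` (with `library = NULL` and `truth` present
#'   only if `truth.json` exists).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("absorbance", "eem", "kinetics")) {
    dir.create(file.path(dir, sub), showWarnings = FALSE)
  }
  readr::write_csv(dataset$samples, file.path(dir, "samples.csv"))
  write_flux(dataset$lamp, file.path(dir, "lamp.csv"))
  for (id in names(dataset$absorbance)) {
    write_absorbance(dataset$absorbance[[id]],
                     file.path(dir, "absorbance", paste0(id, ".csv")))
  }
  for (id in names(dataset$eems %||% list())) {
    write_eem(dataset$eems[[id]], file.path(dir, "eem", paste0(id, ".csv")))
  }
  kin <- dataset$kinetics
  for (key in unique(paste(kin$sample_id, kin$probe, sep = "_"))) {
    part <- kin[paste(kin$sample_id, kin$probe, sep = "_") == key, ]
    readr::write_csv(
      part[, c("time_s", "concentration_M", "replicate", "initial_M",
               "analyte")],
      file.path(dir, "kinetics", paste0(key, ".csv")))
  }
  if (!is.null(dataset$truth)) {
    jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                         digits = NA, dataframe = "columns")
  }
  cfg <- dataset$config %||% list()
  cfg$scatter <- cfg$scatter %||% NULL
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  if (!dir.exists(dir)) abort(paste0("dataset directory not found: ", dir))
  samples <- readr::read_csv(file.path(dir, "samples.csv"),
                             show_col_types = FALSE, progress = FALSE)
  lamp_path <- file.path(dir, "lamp.csv")
  lamp <- if (file.exists(lamp_path)) read_flux(lamp_path) else NULL

  read_per_sample <- function(sub, reader) {
    files <- list.files(file.path(dir, sub), pattern = "\\.csv$",
                        full.names = TRUE)
    out <- purrr::map(files, reader)
    names(out) <- sub("\\.csv$", "", basename(files))
    out[intersect(samples$sample_id, names(out))]
  }
  absorbance <- read_per_sample("absorbance", read_absorbance)
  eems <- read_per_sample("eem", read_eem)
  if (!length(eems)) eems <- NULL

  kin_files <- list.files(file.path(dir, "kinetics"), pattern = "\\.csv$",
                          full.names = TRUE)
  kinetics <- purrr::map_dfr(kin_files, function(f) {
    key <- sub("\\.csv$", "", basename(f))
    probe <- sub("^.*_", "", key)
    id <- sub(paste0("_", probe, "$"), "", key)
    df <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
    dplyr::mutate(df, sample_id = id, probe = probe, .before = 1)
  })

  truth <- NULL
  truth_path <- file.path(dir, "truth.json")
  if (file.exists(truth_path)) {
    truth <- tibble::as_tibble(jsonlite::fromJSON(truth_path))
  }
  config <- NULL
  cfg_path <- file.path(dir, "config.yaml")
  if (file.exists(cfg_path)) config <- yaml::read_yaml(cfg_path)

  structure(list(samples = samples, truth = truth, library = NULL,
                 absorbance = absorbance, lamp = lamp, eems = eems,
                 kinetics = kinetics, constants = rate_constants(),
                 config = config, seed = config$seed %||% NA_integer_),
            class = "photox_dataset")
}
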