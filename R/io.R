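# CSV readers/writers for pig tables and JSON (de)serialization of fitted
# models. CSVs are UTF-8 with dot decimals and an exact header; unknown
# columns survive a round-trip untouched.

PIG_REQUIRED_COLUMNS <- c("pig_id", "farm_id", "carcass_weight_kg",
                          "backfat_mm")
PIG_NUMERIC_COLUMNS <- c("carcass_weight_kg", "backfat_mm",
                         paste0(PRIMAL_CUTS, "_kg"))

#' Read a pig table from CSV
#'
#' Requires columns `pig_id`, `farm_id`, `carcass_weight_kg`, `backfat_mm`;
#' the five `<cut>_kg` columns and `quality_grade` are optional and any
#' further columns are preserved. Malformed numeric cells are reported with
#' their row numbers.
#'
#' @param path CSV file.
#' @return data.frame, one row per pig, in file order.
#' @export
read_pig_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pigs <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing <- setdiff(PIG_REQUIRED_COLUMNS, names(pigs))
  if (length(missing)) {
    stop("pig CSV misses required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(pigs) == 0) {
    warning("empty pig table: ", path)
  }
  for (col in intersect(PIG_NUMERIC_COLUMNS, names(pigs))) {
    parsed <- suppressWarnings(as.numeric(pigs[[col]]))
    bad <- which(is.na(parsed) & !(is.na(pigs[[col]]) | pigs[[col]] == ""))
    if (length(bad)) {
      stop(sprintf("column '%s': malformed numeric cell(s) in row(s) %s",
                   col, paste(utils::head(bad, 10), collapse = ", ")))
    }
    pigs[[col]] <- parsed
  }
  if (nrow(pigs) > 0 && any(pigs$carcass_weight_kg <= 0, na.rm = TRUE)) {
    stop("carcass_weight_kg must be > 0 for every pig")
  }
  pigs
}

#' Write a pig table to CSV
#'
#' @param pigs pig data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pig_csv <- function(pigs, path) {
  utils::write.csv(pigs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

MODEL_JSON_VERSION <- 1L

#' Serialize a fitted model to JSON
#'
#' Writes a versioned JSON document carrying the standardization
#' parameters, ordered centroids, fit configuration, seed, inertia and
#' group map, so a fitted model can be reloaded and applied to new pigs or
#' farms. Training-point assignments are not serialized.
#'
#' @param model fitted, relabeled `kmeans_model` with params.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "kmeans_model"))
  if (!isTRUE(model$relabeled) || is.null(model$params)) {
    stop("only relabeled models with standardization params are serialized")
  }
  doc <- list(
    format = "farmgrade-kmeans-model",
    version = MODEL_JSON_VERSION,
    params = unclass(model$params),
    centroids = lapply(seq_len(nrow(model$centroids)),
                       function(i) as.numeric(model$centroids[i, ])),
    k = model$k, n_init = model$n_init, max_iter = model$max_iter,
    tol = model$tol, seed = model$seed, inertia = model$inertia,
    group_map = as.list(model$group_map))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a fitted model from JSON
#'
#' @param path JSON file written by [write_model_json()].
#' @return a `kmeans_model` ready for [assign_cluster()] /
#'   [assign_farm_grades()].
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "farmgrade-kmeans-model")) {
    stop("not a farmgrade model file: ", path)
  }
  if (doc$version > MODEL_JSON_VERSION) {
    stop("model file version ", doc$version, " is newer than supported")
  }
  centroids <- do.call(rbind, if (is.list(doc$centroids)) doc$centroids
                       else list(doc$centroids))
  if (is.matrix(doc$centroids)) centroids <- doc$centroids
  rownames(centroids) <- paste0("cluster", seq_len(nrow(centroids)))
  colnames(centroids) <- c("z_cw", "z_bf")
  structure(list(
    centroids = centroids,
    cluster = NULL,
    inertia = doc$inertia,
    inertia_trace = numeric(0),
    k = doc$k, n_init = doc$n_init, max_iter = doc$max_iter,
    tol = doc$tol, seed = doc$seed,
    relabeled = TRUE,
    group_map = setNames(unlist(doc$group_map), names(doc$group_map)),
    params = standardization_params(doc$params$mu_cw, doc$params$sigma_cw,
                                    doc$params$mu_bf, doc$params$sigma_bf)),
    class = "kmeans_model")
}
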