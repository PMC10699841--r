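# File I/O: delimited matrices, prior-effect tables, model serialization.
#
# Matrix dialect: header row required, first column holds sample or feature
# identifiers, tab- or comma-separated (sniffed from the header line), UTF-8,
# '.' decimal. gzip is handled transparently by R's connections.

sniff_sep <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a delimited numeric matrix
#'
#' Expects a header row and an identifier first column; returns a numeric
#' matrix with identifiers as row names. `.tsv`/`.csv`/gzipped files are
#' all accepted.
#'
#' @param path file path.
#' @return Numeric matrix with row and column names.
#' @export
read_matrix_file <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_input("non-numeric entries in ", path)
  rownames(m) <- ids
  m
}

#' Read a response vector
#'
#' One value per row, optionally with an identifier column. Binomial
#' responses may be 0/1 or two string labels; with string labels the
#' lexicographically larger label is mapped to 1 (reported via a message).
#'
#' @param path file path.
#' @param family `"gaussian"` or `"binomial"`.
#' @return Numeric vector, named if identifiers were present.
#' @export
read_response_file <- function(path, family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  col <- df[[ncol(df)]]
  ids <- if (ncol(df) > 1) as.character(df[[1]]) else NULL
  if (family == "binomial" && is.character(col)) {
    labs <- sort(unique(col))
    if (length(labs) != 2)
      stop_input("binomial response must have exactly 2 labels, found ",
                 length(labs))
    message("mapping response labels: '", labs[2], "' -> 1, '",
            labs[1], "' -> 0")
    col <- as.numeric(col == labs[2])
  }
  y <- as.numeric(col)
  if (!is.null(ids)) names(y) <- ids
  y
}

#' Match a prior-effect table to a feature matrix
#'
#' Aligns the rows of a feature-by-source prior table to the columns of the
#' target feature matrix by identifier. Features without a prior entry get
#' 0 in every source (reported); prior rows without a matching feature are
#' dropped.
#'
#' @param z matrix of prior effects with feature identifiers as row names.
#' @param feature_names column names of the target feature matrix.
#' @return p x m numeric matrix aligned to `feature_names`.
#' @export
match_priors <- function(z, feature_names) {
  if (is.null(rownames(z))) stop_input("prior table needs feature identifiers")
  out <- matrix(0, length(feature_names), ncol(z),
                dimnames = list(feature_names, colnames(z)))
  hit <- intersect(feature_names, rownames(z))
  out[hit, ] <- z[hit, , drop = FALSE]
  n_missing <- length(feature_names) - length(hit)
  if (n_missing > 0)
    message(n_missing, " feature(s) had no prior entry; imputed as 0")
  out
}

MODEL_FORMAT_VERSION <- "1"

#' Serialize a fitted model to JSON
#'
#' Writes a versioned JSON document holding everything needed for
#' prediction and interpretation: family, calibration and stacking modes,
#' feature and source names, combined coefficients, meta-weights, selected
#' co-data-free coefficients, and the per-source calibration parameters.
#' Numbers are written at full precision, so a read-back reproduces the
#' coefficients bit-exactly.
#'
#' @param model a `"priorstack"` fit.
#' @param path output file.
#' @return `path`, invisibly.
#' @seealso [read_model_json()]
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "priorstack"))
  cal <- lapply(model$calibrations, function(cc)
    list(source = cc$source, method = cc$method, alpha = cc$alpha,
         gamma = cc$gamma, theta = cc$theta, tau = cc$tau,
         inverted = cc$inverted, retained = isTRUE(cc$retained),
         filter_pvalue = cc$filter_pvalue))
  doc <- list(
    format = "priorstack-model", format_version = MODEL_FORMAT_VERSION,
    package_version = model$version,
    family = model$family, calibration = model$calibration,
    stacking = model$stacking, alpha = model$alpha,
    nfolds = model$nfolds,
    feature_names = model$feature_names, source_names = model$source_names,
    beta0_star = model$beta0_star, beta_star = model$beta_star,
    omega0 = model$omega0, omega = model$omega,
    lambda_min = model$base$lambda_min, lambda_1se = model$base$lambda_1se,
    a0_min = model$base$a0_min, beta_min = as.numeric(model$base$beta_min),
    a0_1se = model$base$a0_1se, beta_1se = as.numeric(model$base$beta_1se),
    calibrations = cal)
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' Restore a serialized model
#'
#' Reads a document written by [write_model_json()] and returns a
#' `"priorstack"` object suitable for [predict.priorstack()] and
#' [coef.priorstack()] (fit internals such as the cv path object are not
#' round-tripped).
#'
#' @param path JSON file.
#' @return A `"priorstack"` model.
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "priorstack-model"))
    stop_input("not a priorstack model file: ", path)
  if (!identical(as.character(doc$format_version), MODEL_FORMAT_VERSION))
    stop_input("model format version ", doc$format_version,
               " not supported (expected ", MODEL_FORMAT_VERSION, ")")
  num <- function(v) as.numeric(unlist(v))   # JSON integers back to doubles
  cal <- NULL
  if (length(doc$calibrations)) {
    cal <- lapply(seq_len(nrow(doc$calibrations)), function(i) {
      cc <- lapply(doc$calibrations, function(col)
        if (is.list(col)) col[[i]] else col[i])
      cc$gamma <- num(cc$gamma)
      class(cc) <- "calibrated_prior"
      cc
    })
  }
  structure(
    list(family = doc$family, calibration = doc$calibration,
         stacking = doc$stacking, alpha = doc$alpha, nfolds = doc$nfolds,
         calibrations = cal,
         retained = vapply(cal %||% list(), function(cc) isTRUE(cc$retained),
                           logical(1)),
         base = list(lambda_min = num(doc$lambda_min),
                     lambda_1se = num(doc$lambda_1se),
                     a0_min = num(doc$a0_min), beta_min = num(doc$beta_min),
                     a0_1se = num(doc$a0_1se), beta_1se = num(doc$beta_1se)),
         omega0 = num(doc$omega0), omega = num(doc$omega),
         beta0_star = num(doc$beta0_star), beta_star = num(doc$beta_star),
         feature_names = doc$feature_names,
         source_names = doc$source_names,
         version = doc$package_version),
    class = "priorstack")
}

#' Write predictions to a delimited file
#'
#' @param pred numeric predictions (probabilities for binomial models).
#' @param ids sample identifiers (defaults to `1..n`).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, ids = NULL, path) {
  df <- data.frame(id = ids %||% seq_along(pred), prediction = pred)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write simulation results as TSV
#'
#' @param results output of [run_study()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
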