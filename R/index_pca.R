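#' Fit a PCA refinement of the raw residue indices
#'
#' The seven raw graph-derived indices covary strongly (e.g. reach with
#' forking index), so the working residue encoding uses their principal
#' component scores instead.  Because the indices carry incommensurate units
#' (Angstrom, elementary charge, dimensionless tallies) the PCA is performed
#' on the correlation structure: columns are z-scored before
#' eigen-decomposition.  Component signs are fixed deterministically so the
#' encoding is reproducible: within each loading column the entry of largest
#' magnitude is made positive (ties broken by the earliest row).
#'
#' @param table A 20 x 7 raw index matrix from [compute_raw_index_table()].
#' @return An object of class `index_pca`: list with `means`, `scales`
#'   (7-vectors), `loadings` (orthonormal 7 x 7, columns PC1..PC7 ordered by
#'   decreasing explained variance) and `explained_variance` (eigenvalues,
#'   summing to 7).
#' @export
#' @examples
#' mod <- fit_index_pca(compute_raw_index_table())
#' sum(mod$explained_variance)  # 7 under correlation PCA
fit_index_pca <- function(table) {
  stopifnot(is.matrix(table), ncol(table) == 7)
  means <- colMeans(table)
  scales <- apply(table, 2, stats::sd)
  if (any(scales == 0))
    stop("zero-variance index column(s): ",
         paste(colnames(table)[scales == 0], collapse = ", "),
         "; correlation PCA undefined")
  z <- scale(table, center = means, scale = scales)
  eg <- eigen(stats::cor(table), symmetric = TRUE)
  load <- eg$vectors
  # deterministic sign convention
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(table), paste0("PC", seq_len(ncol(load))))
  ev <- pmax(eg$values, 0)
  names(ev) <- colnames(load)
  structure(list(means = means, scales = scales, loadings = load,
                 explained_variance = ev),
            class = "index_pca")
}

#' Project a raw index table onto the fitted principal components
#'
#' @param table A raw index matrix with the same seven columns the model was
#'   fitted on.
#' @param model An [fit_index_pca()] model.
#' @return Score matrix (rows as in `table`, columns PC1..PC7), the
#'   PCA-refined residue index table.  "The first 5 indices" downstream means
#'   columns PC1..PC5 of this table.
#' @export
project_indices <- function(table, model) {
  stopifnot(inherits(model, "index_pca"))
  if (ncol(table) != length(model$means) ||
      !identical(colnames(table), names(model$means)))
    stop("table columns do not match the fitted model")
  z <- scale(table, center = model$means, scale = model$scales)
  z %*% model$loadings
}

#' Invert a projection back to standardized index values
#'
#' Utility for round-trip checks: maps PC scores back through the orthonormal
#' loadings to the z-scored raw indices.
#'
#' @param scores Score matrix from [project_indices()].
#' @param model The fitted model.
#' @param unstandardize If `TRUE`, also undo the z-scoring.
#' @return Matrix of (standardized) raw index values.
#' @export
unproject_indices <- function(scores, model, unstandardize = FALSE) {
  z <- scores %*% t(model$loadings)
  if (unstandardize)
    z <- sweep(sweep(z, 2, model$scales, `*`), 2, model$means, `+`)
  colnames(z) <- names(model$means)
  z
}

#' Serialize / restore a PCA model as plain text
#'
#' Writes means, scales, explained variance and loadings in a TSV-style block
#' format so residue encodings are bit-reproducible across runs and machines.
#'
#' @param model An `index_pca` model.
#' @param path File path.
#' @return `write_pca_model` returns `path` invisibly; `read_pca_model` the
#'   restored model.
#' @export
write_pca_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  dump_vec <- function(tag, v)
    writeLines(paste(c(tag, names(v), sprintf("%.17g", v)),
                     collapse = "\t"), con)
  writeLines("# ugtregio index_pca model v1", con)
  dump_vec("means", model$means)
  dump_vec("scales", model$scales)
  dump_vec("explained_variance", model$explained_variance)
  for (j in seq_len(ncol(model$loadings)))
    dump_vec(paste0("loading_", colnames(model$loadings)[j]),
             stats::setNames(model$loadings[, j],
                             rownames(model$loadings)))
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  grab <- function(tag) {
    p <- parts[[which(vapply(parts, `[[`, "", 1L) == tag)]]
    k <- (length(p) - 1L) / 2L
    stats::setNames(as.numeric(p[(k + 2L):length(p)]), p[2:(k + 1L)])
  }
  means <- grab("means")
  load <- sapply(paste0("loading_PC", 1:7), grab)
  colnames(load) <- paste0("PC", 1:7)
  structure(list(means = means, scales = grab("scales"), loadings = load,
                 explained_variance = grab("explained_variance")),
            class = "index_pca")
}

#' The default PCA-refined residue encoding
#'
#' Convenience wrapper: raw table from the shipped chemistry, correlation PCA,
#' projected scores.  Memoized per session for speed.
#'
#' @param chemistry Optional chemistry parameter set.
#' @return List with `raw` (20 x 7 raw table), `model` (`index_pca`) and
#'   `scores` (20 x 7 PC-score table used as the residue encoding).
#' @export
default_residue_encoding <- local({
  cache <- NULL
  function(chemistry = NULL) {
    if (is.null(chemistry) && !is.null(cache)) return(cache)
    chem <- if (is.null(chemistry)) load_chemistry() else chemistry
    raw <- compute_raw_index_table(chem)
    model <- fit_index_pca(raw)
    out <- list(raw = raw, model = model,
                scores = project_indices(raw, model))
    if (is.null(chemistry)) cache <<- out
    out
  }
})
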