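#' Dynamic time warping distance between two index series
#'
#' Unconstrained DTW with per-step cost `|x_i - y_j|` and the symmetric step
#' pattern (up, right, diagonal); with this step pattern the cost is
#' symmetric in its arguments.
#'
#' @param x,y Non-empty numeric series.
#' @return Warping cost, `>= 0`; 0 iff the warped series match pointwise.
#' @export
#' @examples
#' dtw_distance(c(0, 1, 2), c(0, 2))
dtw_distance <- function(x, y) dtw_cpp(as.numeric(x), as.numeric(y))

#' LCSS distance between two index series
#'
#' Longest common subsequence under numeric tolerance: positions `i` of `x`
#' and `j` of `y` may match when `|x_i - y_j| <= epsilon` and
#' `|i - j| <= delta`.  The distance is one minus the ratio of the longest
#' common subsequence length to the longer series length, hence lies in
#' `[0, 1]`.
#'
#' @inheritParams dtw_distance
#' @param epsilon Positive similarity threshold.
#' @param delta Integer warping window; `NULL` (default) means unconstrained.
#' @return Distance in `[0, 1]`.
#' @export
lcss_distance <- function(x, y, epsilon, delta = NULL) {
  if (is.null(delta)) delta <- max(length(x), length(y))
  lcss_cpp(as.numeric(x), as.numeric(y), epsilon, as.integer(delta))
}

#' Minimal variance matching distance
#'
#' Embeds the shorter series into the longer by a strictly increasing index
#' map minimizing the summed absolute differences, combining subsequence
#' selection with warping-style flexibility.  The wrapper symmetrizes the
#' inherently one-sided definition by always mapping the shorter series into
#' the longer (equal lengths admit only the identity map, so order is then
#' irrelevant).
#'
#' @inheritParams dtw_distance
#' @return Matching cost, `>= 0`; 0 when the shorter series occurs exactly
#'   (as a not necessarily contiguous subsequence) in the longer.
#' @export
mvm_distance <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) <= length(y)) mvm_cpp(x, y) else mvm_cpp(y, x)
}

#' Specify a loop/index-restricted protein distance
#'
#' A distance specification names the elastic metric, the subset of loops and
#' the subset of index components over which per-series distances are summed.
#' Restricting the sums is how individual loop or index combinations are
#' isolated for the combinatorial search.
#'
#' @param metric `"DTW"`, `"LCSS"` or `"MVM"`.
#' @param loops Character subset of `letters[1:7]`.
#' @param indices Integer subset of 1..7 (PC components).
#' @param lcss_epsilon Similarity threshold for LCSS, either a scalar or a
#'   vector named/positioned by index; `NULL` defers to a data-driven default
#'   (half the pooled standard deviation of each index's residue scores).
#' @param lcss_delta LCSS warping window (`NULL` = unconstrained).
#' @return Object of class `distance_spec`.
#' @export
distance_spec <- function(metric = c("DTW", "LCSS", "MVM"),
                          loops = letters[1:7], indices = 1:7,
                          lcss_epsilon = NULL, lcss_delta = NULL) {
  metric <- match.arg(toupper(metric[1L]), c("DTW", "LCSS", "MVM"))
  loops <- sort(match.arg(loops, letters[1:7], several.ok = TRUE))
  indices <- sort(unique(as.integer(indices)))
  if (!length(loops) || !length(indices))
    stop("loops and indices must be non-empty")
  if (any(indices < 1 | indices > 7)) stop("indices must lie in 1..7")
  if (metric == "LCSS" && !is.null(lcss_epsilon) &&
      any(lcss_epsilon <= 0))
    stop("lcss_epsilon must be positive")
  structure(list(metric = metric, loops = loops, indices = indices,
                 lcss_epsilon = lcss_epsilon, lcss_delta = lcss_delta),
            class = "distance_spec")
}

#' Default LCSS epsilon per index component
#'
#' Half the pooled standard deviation of each PC score over the 20 residue
#' types of the supplied encoding.
#'
#' @param scores Residue score table.
#' @return Numeric 7-vector.
#' @export
default_lcss_epsilon <- function(scores = default_residue_encoding()$scores) {
  0.5 * apply(scores, 2, stats::sd)
}

resolve_epsilon <- function(spec, n_indices = 7L) {
  if (is.null(spec$lcss_epsilon)) return(default_lcss_epsilon())
  eps <- spec$lcss_epsilon
  if (length(eps) == 1L) rep(eps, n_indices) else eps
}

series_metric_fun <- function(spec, eps_by_index) {
  switch(spec$metric,
         DTW = function(x, y, idx) dtw_distance(x, y),
         MVM = function(x, y, idx) mvm_distance(x, y),
         LCSS = function(x, y, idx)
           lcss_distance(x, y, epsilon = eps_by_index[idx],
                         delta = spec$lcss_delta))
}

#' Protein-level distance between two encoded records
#'
#' Sums the per-series elastic distances over the loops and index components
#' named by the supplied [distance_spec()]: first over the chosen indices
#' within a loop, then
#' over the chosen loops.  The restriction is therefore exactly additive over
#' disjoint loop (or index) subsets.
#'
#' @param u,v `index_series_set` objects from [encode_record()].
#' @param spec A [distance_spec()].
#' @return Non-negative distance.
#' @export
protein_distance <- function(u, v, spec = distance_spec()) {
  stopifnot(inherits(u, "index_series_set"),
            inherits(v, "index_series_set"))
  missing_lp <- setdiff(spec$loops, intersect(names(u), names(v)))
  if (length(missing_lp))
    stop("loop(s) absent from a record: ",
         paste(missing_lp, collapse = ", "))
  eps <- resolve_epsilon(spec)
  f <- series_metric_fun(spec, eps)
  tot <- 0
  for (lp in spec$loops)
    for (ix in spec$indices)
      tot <- tot + f(u[[lp]][, ix], v[[lp]][, ix], ix)
  tot
}

#' Per-(loop, index) distance terms for all record pairs
#'
#' Computes, once, the elastic distance between every pair of records for
#' every loop and every index component.  Any loop/index-restricted distance
#' matrix is then a sum of slices of this array, which is what makes the
#' exhaustive loop-by-index search cheap.
#'
#' @param sets List of `index_series_set` objects.
#' @param spec A [distance_spec()]; its `loops`/`indices` bound the slices
#'   computed.
#' @return Numeric array `[n, n, loops, indices]` with record ids on the
#'   first two dimnames.
#' @export
series_distance_terms <- function(sets, spec = distance_spec()) {
  n <- length(sets)
  ids <- vapply(sets, attr, "", "id")
  eps <- resolve_epsilon(spec)
  f <- series_metric_fun(spec, eps)
  out <- array(0, dim = c(n, n, length(spec$loops), length(spec$indices)),
               dimnames = list(ids, ids, spec$loops,
                               paste0("PC", spec$indices)))
  for (li in seq_along(spec$loops)) {
    lp <- spec$loops[li]
    for (xi in seq_along(spec$indices)) {
      ix <- spec$indices[xi]
      for (i in seq_len(n - 1)) {
        for (j in seq.int(i + 1, n)) {
          d <- f(sets[[i]][[lp]][, ix], sets[[j]][[lp]][, ix], ix)
          out[i, j, li, xi] <- d
          out[j, i, li, xi] <- d
        }
      }
    }
  }
  out
}

#' Pairwise protein distance matrix
#'
#' @param sets List of encoded records (`index_series_set`).
#' @param spec A [distance_spec()].
#' @param terms Optional precomputed [series_distance_terms()] array (must
#'   cover `spec`'s loops and indices); when supplied the matrix is a pure
#'   slice-sum.
#' @return Object of class `distance_matrix`: symmetric non-negative matrix
#'   with zero diagonal and record ids as dimnames.
#' @export
distance_matrix <- function(sets, spec = distance_spec(), terms = NULL) {
  if (length(sets) < 2L) stop("need at least two records")
  if (is.null(terms)) terms <- series_distance_terms(sets, spec)
  m <- terms_to_matrix(terms, spec$loops, paste0("PC", spec$indices))
  structure(m, class = c("distance_matrix", class(m)))
}

# sum the [n, n, loop, index] slices selected by name
terms_to_matrix <- function(terms, loops, index_names) {
  sl <- terms[, , loops, index_names, drop = FALSE]
  apply(sl, c(1, 2), sum)
}

#' Write / read a distance matrix as TSV (ids in header row and column)
#' @param m Distance matrix.
#' @param path File path.
#' @return `write_distance_matrix` returns `path` invisibly.
#' @export
write_distance_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m),
                   formatC(m, format = "g", digits = 12),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$id
  structure(m, class = c("distance_matrix", class(m)))
}
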