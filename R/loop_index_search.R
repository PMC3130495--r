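#' Enumerate all loop-subset by index-subset combinations
#'
#' Every non-empty subset of the loop labels crossed with every non-empty
#' subset of the index components, in a deterministic order (loop subsets by
#' size then lexicographically, likewise index subsets).  With the full 7
#' loops and the first 5 index components this yields
#' `(2^7 - 1) * (2^5 - 1) = 3937` combinations, and each loop subset is
#' paired with `2^5 - 1 = 31` index choices.
#'
#' @param loop_labels Loop universe (default `a`..`g`).
#' @param index_labels Index universe (default components 1..5; the search
#'   restricts itself to the first five principal components).
#' @return Data frame with list-columns `loops` and `indices` and string
#'   keys `loop_key` / `index_key`.
#' @export
enumerate_combos <- function(loop_labels = letters[1:7],
                             index_labels = 1:5) {
  subsets <- function(x) {
    out <- list()
    for (size in seq_along(x)) {
      cmb <- utils::combn(x, size, simplify = FALSE)
      out <- c(out, cmb)
    }
    out
  }
  ls <- subsets(loop_labels)
  is <- subsets(index_labels)
  grid <- expand.grid(li = seq_along(ls), xi = seq_along(is))
  # loops vary slowest: all index subsets of one loop subset are contiguous
  grid <- grid[order(grid$li, grid$xi), ]
  data.frame(loop_key = vapply(ls[grid$li], paste, "", collapse = ""),
             index_key = vapply(is[grid$xi], paste, "", collapse = ""),
             loops = I(ls[grid$li]), indices = I(is[grid$xi]),
             stringsAsFactors = FALSE)
}

#' Exhaustive loop-index-specific kNN crossvalidation
#'
#' Runs one leave-one-out kNN crossvalidation per loop/index combination,
#' with the distance restricted to that combination.  All per-(loop, index)
#' series distances are computed once via [series_distance_terms()]; each
#' combination's distance matrix is then a sum of cached slices, so the
#' 3937-combination sweep costs one pass over the series pairs.
#'
#' @param sets Encoded records.
#' @param labels Named logical truth.
#' @param metric Elastic metric (default DTW).
#' @param k Neighbourhood size (default 3).
#' @param combos Combination table from [enumerate_combos()].
#' @param terms Optional precomputed distance-term array.
#' @return Object of class `combo_results`: list with the `combos` table
#'   augmented by `n_errors` and `missed`, the per-combo loss patterns
#'   (`losses`), and bookkeeping (`ids`, `labels`, `metric`, `k`).
#' @export
run_search <- function(sets, labels, metric = "DTW", k = 3L,
                       combos = enumerate_combos(), terms = NULL) {
  ids <- vapply(sets, attr, "", "id")
  spec_all <- distance_spec(metric, loops = letters[1:7], indices = 1:7)
  if (is.null(terms)) terms <- series_distance_terms(sets, spec_all)
  n <- length(ids)
  plan <- cv_plan(ids, "L1O")
  # flatten slices once: rows = (loop, index) term, cols = n*n entries
  flat <- matrix(aperm(terms, c(3, 4, 1, 2)),
                 nrow = dim(terms)[3] * dim(terms)[4])
  term_key <- as.vector(outer(dimnames(terms)[[3]],
                              dimnames(terms)[[4]], paste0))
  losses <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    keys <- as.vector(outer(combos$loops[[i]],
                            paste0("PC", combos$indices[[i]]), paste0))
    rows <- match(keys, term_key)
    D <- matrix(if (length(rows) > 1L) colSums(flat[rows, , drop = FALSE])
                else flat[rows, ], n, n, dimnames = list(ids, ids))
    losses[[i]] <- knn_crossvalidate(D, labels, plan, k = k)
  }
  res <- combos
  res$n_errors <- vapply(losses, `[[`, 0L, "n_errors")
  res$missed <- vapply(losses, format_loss_pattern, "")
  structure(list(combos = res, losses = losses, ids = ids,
                 labels = labels, metric = metric, k = k),
            class = "combo_results")
}

#' @export
print.combo_results <- function(x, ...) {
  cat("<combo_results> ", nrow(x$combos), " combos (", x$metric, " ",
      x$k, "NN L1O); best loss ", min(x$combos$n_errors), "\n", sep = "")
  invisible(x)
}

#' Per-record miss frequency across all loop-index classifiers
#'
#' For each record, the number of loop-index-specific classifiers whose loss
#' pattern contains it.  Summed over records this equals the summed loss
#' sizes over combinations (each miss is counted exactly once on each side).
#'
#' @param results A [run_search()] result.
#' @return Named integer vector over all record ids (zeros included).
#' @export
miss_frequency_by_record <- function(results) {
  counts <- stats::setNames(integer(length(results$ids)), results$ids)
  for (lp in results$losses)
    counts[lp$missed] <- counts[lp$missed] + 1L
  counts
}

#' Frequency spectrum of distinct loss patterns
#'
#' Groups identical loss patterns across combinations and tabulates their
#' frequencies, sorted by frequency (descending), then pattern size
#' (ascending), then lexicographically.
#'
#' @param results A [run_search()] result.
#' @return Data frame with columns `pattern` (formatted ids), `size`,
#'   `frequency`.
#' @export
loss_pattern_spectrum <- function(results) {
  keys <- vapply(results$losses, loss_key, "")
  tab <- table(keys)
  first <- results$losses[!duplicated(keys)]
  names(first) <- keys[!duplicated(keys)]
  df <- data.frame(pattern = vapply(first[names(tab)],
                                    format_loss_pattern, ""),
                   size = vapply(first[names(tab)], `[[`, 0L, "n_errors"),
                   frequency = as.integer(tab),
                   key = names(tab), stringsAsFactors = FALSE)
  df <- df[order(-df$frequency, df$size, df$key), , drop = FALSE]
  rownames(df) <- NULL
  df[, c("pattern", "size", "frequency")]
}

#' Modal loss pattern per loop combination
#'
#' Groups the search results by loop subset; within each group (its up-to-31
#' index subsets) finds the modal loss pattern (most frequent; ties broken by
#' smaller loss then lexicographically) and flags loop subsets whose mode is
#' both small and dominant.  This is the screen for loop combinations whose
#' classification behaviour is stable across index choices - the signature of
#' genuine loop-confined signal rather than crossvalidation artifact.
#'
#' @param results A [run_search()] result.
#' @param max_loss Qualifying modes must miss strictly fewer than this many
#'   records (default 4, i.e. "a loss under 4").
#' @param min_frequency Qualifying modes must occur at least this many times
#'   among the group's index subsets (default 10, i.e. "higher than 9" -
#'   roughly a third of the 31 index choices).
#' @return Data frame with one row per loop subset: `loop_key`,
#'   `modal_pattern`, `modal_size`, `mode_frequency`, `n_index_subsets`,
#'   `qualifies`; ordered qualifying-first, then by modal size and
#'   descending frequency.
#' @export
mode_analysis <- function(results, max_loss = 4L, min_frequency = 10L) {
  combos <- results$combos
  groups <- split(seq_len(nrow(combos)), combos$loop_key)
  rows <- lapply(names(groups), function(gk) {
    idx <- groups[[gk]]
    keys <- vapply(results$losses[idx], loss_key, "")
    sizes <- vapply(results$losses[idx], `[[`, 0L, "n_errors")
    tab <- table(keys)
    cand <- names(tab)[tab == max(tab)]
    cand_size <- sizes[match(cand, keys)]
    pick <- cand[order(cand_size, cand)][1L]
    modal <- results$losses[idx][[match(pick, keys)]]
    data.frame(loop_key = gk,
               modal_pattern = format_loss_pattern(modal),
               modal_size = modal$n_errors,
               mode_frequency = as.integer(tab[pick]),
               n_index_subsets = length(idx),
               qualifies = modal$n_errors < max_loss &&
                 tab[pick] >= min_frequency,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(-df$qualifies, df$modal_size, -df$mode_frequency,
                 df$loop_key), , drop = FALSE]
  rownames(df) <- NULL
  df
}
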