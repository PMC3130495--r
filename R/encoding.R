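#' Construct a UGT record
#'
#' Bundles one protein: its identifier, sequence, the seven acceptor-pocket
#' loop annotations (1-based inclusive intervals labeled `a`..`g`, ordered and
#' non-overlapping along the sequence), the binary class label for the current
#' problem, optional per-record excluded positions (e.g. the conserved
#' histidine in loop a, identical in every UGT and therefore uninformative)
#' and free-form metadata.
#'
#' @param id Record identifier (unique within a dataset).
#' @param sequence Residue string (one-letter codes).
#' @param loops Data frame with columns `loop` (letters a..g), `start`, `end`.
#' @param label Logical class label (`TRUE` = positive), or `NA` if unknown.
#' @param exclusions Integer vector of 1-based sequence positions dropped
#'   before encoding.
#' @param metadata Named list (organism, acceptor, accession, ...).
#' @return An object of class `ugt_record`.
#' @export
ugt_record <- function(id, sequence, loops, label = NA,
                       exclusions = integer(), metadata = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L)
  loops <- as.data.frame(loops)
  if (!all(c("loop", "start", "end") %in% names(loops)))
    stop("loops needs columns loop/start/end (record ", id, ")")
  loops <- loops[order(match(loops$loop, letters[1:7])), , drop = FALSE]
  if (!identical(loops$loop, letters[1:7]))
    stop("record ", id, " must annotate exactly loops a-g")
  n <- nchar(sequence)
  if (any(loops$start < 1 | loops$end > n))
    stop("loop interval out of sequence bounds in record ", id)
  if (any(loops$end < loops$start))
    stop("empty loop interval in record ", id)
  if (any(loops$start[-1] <= loops$end[-7]))
    stop("loops overlap or are out of order in record ", id)
  exclusions <- sort(unique(as.integer(exclusions)))
  if (length(exclusions) && (min(exclusions) < 1 || max(exclusions) > n))
    stop("exclusion position out of bounds in record ", id)
  structure(list(id = id, sequence = sequence, loops = loops,
                 label = label, exclusions = exclusions,
                 metadata = metadata),
            class = "ugt_record")
}

#' @export
print.ugt_record <- function(x, ...) {
  cat("<ugt_record ", x$id, "> ", nchar(x$sequence), " aa, label = ",
      x$label, "\n", sep = "")
  invisible(x)
}

loop_residues <- function(rec, loop) {
  row <- rec$loops[rec$loops$loop == loop, ]
  pos <- seq.int(row$start, row$end)
  pos <- setdiff(pos, rec$exclusions)
  list(pos = pos,
       chars = strsplit(substr(rec$sequence, 1, nchar(rec$sequence)),
                        "")[[1]][pos])
}

# score rows for a character vector of residues; non-standard codes (X/B/Z
# and padding) encode as all-zero rows with a warning for real ambiguity
score_rows <- function(chars, scores, warn = TRUE) {
  out <- matrix(0, nrow = length(chars), ncol = ncol(scores),
                dimnames = list(NULL, colnames(scores)))
  known <- chars %in% rownames(scores)
  out[known, ] <- scores[chars[known], , drop = FALSE]
  odd <- setdiff(unique(chars[!known]), c("X", "B", "Z", "-"))
  if (length(odd))
    stop("unresolvable residue code(s): ", paste(odd, collapse = ", "))
  if (warn && any(!known & chars != "-"))
    warning("ambiguous residue(s) ",
            paste(unique(chars[!known & chars != "-"]), collapse = ", "),
            " encoded as zero scores")
  out
}

#' Encode one record's loops as multidimensional index series
#'
#' Maps each loop's residues through the PCA-refined residue index table,
#' yielding, per loop, a (loop length) x 7 matrix whose columns PC1..PC7 are
#' the 1-D index series compared by the elastic distances.  Positions in the
#' record's exclusion set are dropped before encoding.
#'
#' @param rec A [ugt_record()].
#' @param scores 20 x 7 PCA-refined index table (rows = residue codes); the
#'   default is the shipped encoding.
#' @return Object of class `index_series_set`: named list (`a`..`g`) of
#'   series matrices, with attribute `id`.
#' @export
#' @examples
#' enc <- default_residue_encoding()
#' rec <- ugt_record("demo", "MAGTKLS",
#'                   data.frame(loop = letters[1:7], start = 1:7, end = 1:7))
#' encode_record(rec, enc$scores)$a
encode_record <- function(rec, scores = default_residue_encoding()$scores) {
  stopifnot(inherits(rec, "ugt_record"))
  out <- lapply(letters[1:7], function(lp) {
    lr <- loop_residues(rec, lp)
    if (!length(lr$pos))
      stop("loop ", lp, " of record ", rec$id,
           " is empty after exclusions")
    score_rows(lr$chars, scores)
  })
  names(out) <- letters[1:7]
  structure(out, class = "index_series_set", id = rec$id)
}

#' Build uniform-length covering windows around each loop
#'
#' For each loop label, finds one window per record, of a single common
#' length, that contains that record's loop.  The common length is the
#' maximum loop length across records plus a per-loop margin.  Window
#' placements are regularized by a gapless sum-of-pairs local alignment:
#' starting from loop-centred placements, records are updated one at a time
#' to the admissible offset maximizing the summed substitution-matrix
#' similarity against all other records' current windows (ties broken by the
#' smallest offset), sweeping until no placement changes (at most
#' `max_sweeps`).  A window that would overrun a sequence end is shifted
#' inward; if the sequence is too short even then, it is padded with a
#' neutral `-` token that encodes to all-zero scores.
#'
#' @param records List of [ugt_record()]s (at least two).
#' @param margins Integer vector of length 1 or 7: extra positions added to
#'   each loop's maximal length.
#' @param scoring Substitution matrix (default BLOSUM62).
#' @param max_sweeps Sweep cap for the iterative refinement.
#' @return Object of class `covering_windows`: list with `window_length`
#'   (named 7-vector), `starts` (records x loops matrix of window start
#'   positions), `L_total` (sum of window lengths) and `ids`.
#' @export
build_covering_windows <- function(records, margins = 4L,
                                   scoring = blosum62(),
                                   max_sweeps = 50L) {
  if (length(records) < 2L) stop("need at least two records")
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate record ids")
  if (length(margins) == 1L) margins <- rep(margins, 7L)
  stopifnot(length(margins) == 7L, all(margins >= 0))
  chars <- lapply(records, function(r) strsplit(r$sequence, "")[[1]])
  lens <- vapply(chars, length, 0L)

  wlen <- integer(7)
  starts <- matrix(NA_integer_, nrow = length(records), ncol = 7,
                   dimnames = list(ids, letters[1:7]))
  for (j in 1:7) {
    lp <- letters[j]
    ls <- vapply(records, function(r) r$loops$start[j], 0)
    le <- vapply(records, function(r) r$loops$end[j], 0)
    W <- max(le - ls + 1) + margins[j]
    wlen[j] <- W
    # admissible start range per record: cover the loop, stay in bounds,
    # shifting inward at the ends; pad on the right if unavoidable
    smin <- pmax(le - W + 1, 1)
    smax <- pmin(ls, lens - W + 1)
    smax <- pmax(smax, smin)  # padding case: only smin remains admissible
    cur <- pmin(pmax(round(ls - (W - (le - ls + 1)) / 2), smin), smax)

    win_chars <- function(i, s) {
      idx <- seq.int(s, s + W - 1)
      out <- rep("-", W)
      ok <- idx >= 1 & idx <= lens[i]
      out[ok] <- chars[[i]][idx[ok]]
      out
    }
    # sum-of-pairs score of record i's candidate window vs the others
    sp_score <- function(i, s, mats) {
      cand <- win_chars(i, s)
      tot <- 0
      for (k in seq_along(records)) {
        if (k == i) next
        tot <- tot + sum(scoring[cbind(cand, mats[[k]])])
      }
      tot
    }
    mats <- lapply(seq_along(records), function(i) win_chars(i, cur[i]))
    for (sweep in seq_len(max_sweeps)) {
      changed <- FALSE
      for (i in seq_along(records)) {
        cand_s <- seq.int(smin[i], smax[i])
        sc <- vapply(cand_s, function(s) sp_score(i, s, mats), 0)
        best <- cand_s[which.max(sc)]  # which.max takes the first maximum
        if (best != cur[i]) {
          cur[i] <- best
          mats[[i]] <- win_chars(i, best)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    starts[, j] <- cur
  }
  names(wlen) <- letters[1:7]
  structure(list(window_length = wlen, starts = starts,
                 L_total = sum(wlen), ids = ids),
            class = "covering_windows")
}

#' @export
print.covering_windows <- function(x, ...) {
  cat("<covering_windows> ", length(x$ids), " records, window lengths ",
      paste(x$window_length, collapse = "/"),
      ", L_total = ", x$L_total, "\n", sep = "")
  invisible(x)
}

#' BLOSUM62 substitution matrix
#'
#' Thin accessor for the matrix shipped with Biostrings, including the
#' neutral `-` row/column (scored 0 against everything) used for padded
#' window positions.
#' @return Integer matrix with residue codes as dimnames.
#' @export
blosum62 <- function() {
  B62 <- get(utils::data("BLOSUM62", package = "Biostrings",
                         envir = environment()))
  if (!"-" %in% rownames(B62)) {
    B62 <- rbind(cbind(B62, `-` = 0L), `-` = 0L)
  } else {
    B62["-", ] <- 0L; B62[, "-"] <- 0L
  }
  B62
}

windowed_chars <- function(rec, windows, loop) {
  j <- match(loop, letters[1:7])
  s <- windows$starts[rec$id, j]
  W <- windows$window_length[j]
  idx <- seq.int(s, s + W - 1)
  ch <- strsplit(rec$sequence, "")[[1]]
  out <- rep("-", W)
  ok <- idx >= 1 & idx <= length(ch)
  out[ok] <- ch[idx[ok]]
  out
}

#' Flatten a record's covering windows into one fixed-length vector
#'
#' Concatenates, loop `a` through `g` and position left to right, the seven
#' PC scores of every residue in the record's covering windows.  All records
#' of a dataset share one vector length, `L_total * 7`; with the 86-position
#' windows used for the real UGT panel this is the 602-input representation
#' consumed by the Bayesian neural network.
#'
#' @param rec A [ugt_record()].
#' @param windows A [build_covering_windows()] result containing `rec$id`.
#' @param scores PCA-refined residue index table.
#' @return Numeric vector of length `windows$L_total * ncol(scores)`.
#' @export
flatten_to_vector <- function(rec, windows,
                              scores = default_residue_encoding()$scores) {
  if (!rec$id %in% rownames(windows$starts))
    stop("record ", rec$id, " has no covering windows")
  pieces <- lapply(letters[1:7], function(lp) {
    m <- score_rows(windowed_chars(rec, windows, lp), scores, warn = FALSE)
    as.vector(t(m))  # position-major, PC1..PC7 within a position
  })
  unlist(pieces, use.names = FALSE)
}

#' Flatten every record of a dataset into a feature matrix
#'
#' @param records List of records.
#' @param windows Covering windows over those records.
#' @param scores Residue index table.
#' @return Numeric matrix, rows = records (named by id).
#' @export
flatten_dataset <- function(records, windows,
                            scores = default_residue_encoding()$scores) {
  m <- t(vapply(records, flatten_to_vector, windows = windows,
                scores = scores,
                FUN.VALUE = numeric(windows$L_total * ncol(scores))))
  rownames(m) <- vapply(records, `[[`, "", "id")
  m
}
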