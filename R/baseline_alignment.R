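#' Global pairwise alignment score
#'
#' Needleman-Wunsch global alignment with affine gap costs, scored with a
#' standard substitution matrix (default BLOSUM62, gap opening 10, gap
#' extension 0.5).  This pairwise scorer, not a progressive multiple-
#' alignment pipeline, backs the alignment-score distance baseline; the
#' substitution is recorded in output metadata wherever the baseline is
#' written out.
#'
#' @param seq_a,seq_b Non-empty residue strings.
#' @param matrix Substitution matrix name or matrix (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Non-negative gap penalties; a gap of length L
#'   costs `gap_open + L * gap_extend`.
#' @return Optimal global alignment score.
#' @export
pairwise_alignment_score <- function(seq_a, seq_b, matrix = "BLOSUM62",
                                     gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  stopifnot(gap_open >= 0, gap_extend >= 0)
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
}

#' Specify an alignment-score distance
#'
#' @param scope `"full"` (whole sequences), `"concatenated_loops"` (loops
#'   a..g joined into one string per record) or `"per_loop_sum"` (sum of the
#'   per-loop reciprocal-score distances, optionally restricted to a loop
#'   subset, making the baseline comparable to loop-restricted elastic
#'   distances).
#' @param loops Loop subset used by `per_loop_sum`.
#' @param matrix,gap_open,gap_extend Passed to
#'   [pairwise_alignment_score()].
#' @return Object of class `alignment_distance_spec`.
#' @export
alignment_distance_spec <- function(scope = c("full", "concatenated_loops",
                                              "per_loop_sum"),
                                    loops = letters[1:7],
                                    matrix = "BLOSUM62",
                                    gap_open = 10, gap_extend = 0.5) {
  scope <- match.arg(scope)
  loops <- sort(match.arg(loops, letters[1:7], several.ok = TRUE))
  structure(list(scope = scope, loops = loops, matrix = matrix,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_distance_spec")
}

# sentinel for non-positive alignment scores; reciprocal undefined there
ALIGN_SENTINEL <- 1e6

recip_score <- function(score) {
  if (score <= 0) {
    warning("non-positive alignment score ", score,
            "; using sentinel distance ", ALIGN_SENTINEL)
    return(ALIGN_SENTINEL)
  }
  1 / score
}

loop_seq <- function(rec, lp) {
  row <- rec$loops[rec$loops$loop == lp, ]
  substr(rec$sequence, row$start, row$end)
}

#' Alignment-score distance between two records
#'
#' The reciprocal of the global alignment score: a simple decreasing
#' function of similarity.  For the `per_loop_sum` scope the distance is the
#' sum over the chosen loops of the per-loop reciprocal scores, mirroring
#' the per-loop additivity of the elastic protein distance.
#'
#' @param rec_a,rec_b [ugt_record()]s.
#' @param spec An [alignment_distance_spec()].
#' @return Positive distance.
#' @export
alignment_distance <- function(rec_a, rec_b,
                               spec = alignment_distance_spec()) {
  score1 <- function(a, b)
    pairwise_alignment_score(a, b, spec$matrix, spec$gap_open,
                             spec$gap_extend)
  switch(spec$scope,
    full = recip_score(score1(rec_a$sequence, rec_b$sequence)),
    concatenated_loops = {
      cat_a <- paste(vapply(letters[1:7], loop_seq, "", rec = rec_a),
                     collapse = "")
      cat_b <- paste(vapply(letters[1:7], loop_seq, "", rec = rec_b),
                     collapse = "")
      recip_score(score1(cat_a, cat_b))
    },
    per_loop_sum = sum(vapply(spec$loops, function(lp)
      recip_score(score1(loop_seq(rec_a, lp), loop_seq(rec_b, lp))), 0)))
}

#' Pairwise alignment-distance matrix over a record set
#'
#' Same format as the elastic [distance_matrix()], so kNN and SVM
#' classifiers consume either interchangeably.
#'
#' @param records List of records.
#' @param spec An [alignment_distance_spec()].
#' @return A `distance_matrix` (zero diagonal, symmetric).
#' @export
alignment_distance_matrix <- function(records,
                                      spec = alignment_distance_spec()) {
  if (length(records) < 2L) stop("need at least two records")
  ids <- vapply(records, `[[`, "", "id")
  n <- length(records)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      d <- alignment_distance(records[[i]], records[[j]], spec)
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  structure(m, class = c("distance_matrix", class(m)))
}
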