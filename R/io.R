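#' Load the packaged metadata for the 23-UGT reference panel
#'
#' The panel's numeric ids, labels, acceptor substrate classes, organisms,
#' sequence database accessions and experimentally determined
#' regioselectivity classes ship as plain TSV.  Sequences are deliberately
#' not bundled: obtaining them requires an accession download, which is an
#' optional workflow, never a test dependency.
#'
#' @return Data frame with columns id, label, acceptor, organism, accession,
#'   class.
#' @export
#' @examples
#' meta <- load_ugt_metadata()
#' nrow(meta)  # 23
load_ugt_metadata <- function() {
  utils::read.delim(system.file("extdata", "ugt23_metadata.tsv",
                                package = "ugtregio"),
                    colClasses = "character")
}

#' Resolve multi-position class strings to binary problem labels
#'
#' A class string lists the acceptor positions an enzyme glucosylates, e.g.
#' `"3"`, `"5, 3"` or `"4', 7"`.  A primed position label is a distinct
#' class from its unprimed counterpart (`3'` is not `3`).  A record is
#' positive for problem `"3-O"` exactly when its class set contains `"3"`;
#' `"NA"` (no verified class among those considered) is negative for every
#' problem.
#'
#' @param class_strings Character vector of class strings.
#' @param problem `"3-O"` or `"7-O"` (any position label plus `-O` works).
#' @return Logical vector of binary labels.
#' @export
resolve_problem_labels <- function(class_strings, problem = "3-O") {
  target <- sub("-O$", "", problem)
  vapply(strsplit(class_strings, ","), function(parts)
    target %in% trimws(parts), NA)
}

parse_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Read a dataset (sequences, loop annotations, labels) for one problem
#'
#' Validates and joins the three plain-text inputs: a FASTA of sequences, a
#' loop-annotation TSV (columns `id`, `loop` = a..g, `start`, `end`,
#' optional `exclude` with comma-separated excluded positions), and a label
#' TSV (columns `id`, `class`).  Multi-position class strings are resolved
#' to binary labels via [resolve_problem_labels()].
#'
#' @param fasta,loops_tsv,labels_tsv File paths.
#' @param problem Binary problem, e.g. `"3-O"`.
#' @return Object of class `ugt_dataset`: list with `records` (list of
#'   [ugt_record()]), `labels` (named logical), `problem` and `provenance`
#'   (the input paths).
#' @export
read_dataset <- function(fasta, loops_tsv, labels_tsv, problem = "3-O") {
  for (f in c(fasta, loops_tsv, labels_tsv))
    if (!file.exists(f)) stop("input file not found: ", f)
  seqs <- parse_fasta(fasta)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence id: ",
         names(seqs)[duplicated(names(seqs))][1L])
  loops <- utils::read.delim(loops_tsv, colClasses = "character",
                             comment.char = "#")
  labels <- utils::read.delim(labels_tsv, colClasses = "character",
                              comment.char = "#")
  if (!all(c("id", "loop", "start", "end") %in% names(loops)))
    stop("loop annotation file needs columns id/loop/start/end")
  if (!all(c("id", "class") %in% names(labels)))
    stop("label file needs columns id/class")
  if (anyDuplicated(labels$id))
    stop("duplicate id in label file: ",
         labels$id[duplicated(labels$id)][1L])
  ids <- names(seqs)
  for (where in list(c("loop annotation", loops$id),
                     c("label", labels$id))) {
    odd <- setdiff(unique(where[-1]), ids)
    if (length(odd))
      stop(where[1L], " file names unknown id: ", odd[1L])
  }
  missing_lab <- setdiff(ids, labels$id)
  if (length(missing_lab))
    stop("record without label: ", missing_lab[1L])
  y <- resolve_problem_labels(labels$class, problem)
  names(y) <- labels$id
  records <- lapply(ids, function(i) {
    li <- loops[loops$id == i, , drop = FALSE]
    if (nrow(li) != 7L)
      stop("record ", i, " has ", nrow(li),
           " loop annotations; expected 7 (a-g)")
    excl <- integer()
    if ("exclude" %in% names(li)) {
      raw <- unlist(strsplit(li$exclude[nzchar(li$exclude)], ","))
      excl <- as.integer(trimws(raw))
    }
    ugt_record(i, seqs[[i]],
               data.frame(loop = li$loop, start = as.integer(li$start),
                          end = as.integer(li$end)),
               label = y[[i]], exclusions = excl)
  })
  names(records) <- ids
  structure(list(records = records, labels = y[ids], problem = problem,
                 provenance = list(fasta = fasta, loops = loops_tsv,
                                   labels = labels_tsv)),
            class = "ugt_dataset")
}

#' @export
print.ugt_dataset <- function(x, ...) {
  cat("<ugt_dataset> ", length(x$records), " records, problem ", x$problem,
      " (", sum(x$labels), " positive)\n", sep = "")
  invisible(x)
}

#' Encode every record of a dataset
#'
#' @param dataset A [read_dataset()] result or plain list of records.
#' @param scores Residue index table.
#' @return Named list of `index_series_set`s.
#' @export
encode_dataset <- function(dataset,
                           scores = default_residue_encoding()$scores) {
  records <- if (inherits(dataset, "ugt_dataset")) dataset$records
             else dataset
  lapply(records, encode_record, scores = scores)
}
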