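#' Configuration for the synthetic UGT-like data generator
#'
#' The generator emulates the shape of the real 23-UGT panel so that every
#' pipeline stage is testable without sequence downloads: record count,
#' sequence length range (446-511), the seven per-loop length ranges
#' (3-6, 2-18, 7-24, 2-3, 1-4, 2-9, 2-9) and the 10-of-23 positive class
#' balance.  Class-correlated signal is confined to the chosen loops and
#' index components: positive-class residues inside signal loops are drawn
#' with sampling weights tilted towards residue types scoring high on the
#' signal indices, so the planted effect travels the full residue-graph /
#' PCA / encoding path rather than being injected numerically.
#'
#' @param n_records Number of records.
#' @param length_range Sequence length range (inclusive).
#' @param loop_length_ranges 7 x 2 matrix of per-loop length ranges.
#' @param signal_loops Loops carrying class signal.
#' @param signal_indices PC components (1..5) defining the signal direction.
#' @param effect_size Strength of the sampling tilt for positives, in units
#'   of standardized index score (0 = null data).
#' @param noise_rate Per-residue probability of substituting a uniformly
#'   random residue after planting (applied everywhere).
#' @param n_positive Number of positive records.
#' @param seed Integer seed; the same config yields bit-identical data.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_records = 23L,
                       length_range = c(446L, 511L),
                       loop_length_ranges = default_loop_length_ranges(),
                       signal_loops = c("b", "e"),
                       signal_indices = c(1L, 2L),
                       effect_size = 2,
                       noise_rate = 0.02,
                       n_positive = 10L,
                       seed = 1L) {
  stopifnot(n_records >= 2, length_range[1] <= length_range[2],
            nrow(loop_length_ranges) == 7L,
            all(loop_length_ranges[, 1] >= 1),
            all(loop_length_ranges[, 1] <= loop_length_ranges[, 2]),
            noise_rate >= 0, noise_rate <= 1,
            n_positive >= 1, n_positive < n_records)
  signal_loops <- sort(match.arg(signal_loops, letters[1:7],
                                 several.ok = TRUE))
  signal_indices <- sort(unique(as.integer(signal_indices)))
  if (effect_size > 0 &&
      (!length(signal_loops) || !length(signal_indices)))
    stop("signal loops/indices must be non-empty when effect_size > 0")
  structure(list(n_records = as.integer(n_records),
                 length_range = as.integer(length_range),
                 loop_length_ranges = loop_length_ranges,
                 signal_loops = signal_loops,
                 signal_indices = signal_indices,
                 effect_size = effect_size, noise_rate = noise_rate,
                 n_positive = as.integer(n_positive),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Per-loop length ranges of the acceptor-pocket loops
#'
#' The observed length variation of loops a-g across the reference panel:
#' 3-6, 2-18, 7-24, 2-3, 1-4, 2-9 and 2-9 residues.
#' @return 7 x 2 integer matrix with loop letters as rownames.
#' @export
default_loop_length_ranges <- function() {
  m <- matrix(c(3L, 6L, 2L, 18L, 7L, 24L, 2L, 3L, 1L, 4L, 2L, 9L, 2L, 9L),
              ncol = 2, byrow = TRUE,
              dimnames = list(letters[1:7], c("min", "max")))
  m
}

#' Generate a synthetic UGT-like dataset with known ground truth
#'
#' Sequences are drawn uniformly over the 20 residue types; the seven loops
#' are placed non-overlapping in order a-g at random positions.  In
#' positive-class records, residues inside the signal loops are sampled with
#' weight `exp(effect_size * z(r))` where `z(r)` is the residue's mean
#' standardized score over the signal indices, biasing those loops towards
#' high-scoring residue types.  Substitution noise is then applied at
#' `noise_rate` per residue.  The manifest records every planted parameter.
#'
#' @param config A [sim_config()].
#' @param scores Residue score table defining the signal direction.
#' @return List with `records` (list of labeled [ugt_record()]s, ids
#'   `"ugt01"`...) and `manifest` (config echo plus planted truth).
#' @export
simulate_ugt_data <- function(config = sim_config(),
                              scores =
                                default_residue_encoding()$scores) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    res20 <- rownames(scores)
    z <- scale(scores[, config$signal_indices, drop = FALSE])
    # signal score per residue type: mean over the signal components,
    # restandardized so effect_size is in per-residue sd units whatever the
    # number of components
    sig <- drop(scale(rowMeans(z)))
    tilt <- exp(config$effect_size * sig)
    labels <- c(rep(TRUE, config$n_positive),
                rep(FALSE, config$n_records - config$n_positive))
    labels <- sample(labels)
    ids <- sprintf("ugt%02d", seq_len(config$n_records))
    names(labels) <- ids
    records <- vector("list", config$n_records)
    for (r in seq_len(config$n_records)) {
      L <- sample(seq.int(config$length_range[1], config$length_range[2]),
                  1L)
      lens <- vapply(1:7, function(j)
        sample(seq.int(config$loop_length_ranges[j, 1],
                       config$loop_length_ranges[j, 2]), 1L), 0L)
      # place loops in order with at least one spacer residue between and
      # around them: distribute the slack among the 8 gaps
      slack <- L - sum(lens) - 8L
      if (slack < 0) stop("loops cannot be placed: sequence too short")
      extra <- tabulate(sample.int(8L, slack, replace = TRUE), nbins = 8L)
      gaps <- 1L + extra
      starts <- cumsum(c(gaps[1] + 1L,
                         utils::head(lens, -1) + gaps[2:7]))
      ends <- starts + lens - 1L
      chars <- sample(res20, L, replace = TRUE)
      if (labels[r] && config$effect_size > 0) {
        for (j in match(config$signal_loops, letters[1:7])) {
          pos <- seq.int(starts[j], ends[j])
          chars[pos] <- sample(res20, length(pos), replace = TRUE,
                               prob = tilt)
        }
      }
      if (config$noise_rate > 0) {
        flip <- stats::runif(L) < config$noise_rate
        chars[flip] <- sample(res20, sum(flip), replace = TRUE)
      }
      records[[r]] <- ugt_record(ids[r], paste(chars, collapse = ""),
                                 data.frame(loop = letters[1:7],
                                            start = starts, end = ends),
                                 label = labels[[r]])
    }
    names(records) <- ids
    list(records = records,
         manifest = list(config = config, labels = labels,
                         signal_loops = config$signal_loops,
                         signal_indices = config$signal_indices,
                         seed = config$seed))
  })
}

#' Generate a warping-noise dataset of class-templated loops
#'
#' Companion generator emulating the regime elastic distances are designed
#' for: each class has a fixed residue template per loop, and every record
#' realizes its class templates through random *time warping* - each
#' template position is deleted or duplicated with probability
#' `warp_rate / 2` each (respecting the loop length ranges) - followed by
#' substitution noise.  Records of one class are therefore warped,
#' noise-corrupted copies of a common prototype, differing mostly by local
#' compression, dilation and phase rather than by composition.
#'
#' @param n_records,n_positive,noise_rate,seed As in [sim_config()].
#' @param warp_rate Per-position probability of a warping event
#'   (split evenly between deletion and duplication).
#' @param signal_loops Loops whose templates differ between the classes;
#'   the remaining loops share one template, so class signal stays
#'   loop-confined.
#' @param scores Residue score table (only used downstream; templates are
#'   drawn uniformly over residue types).
#' @return Same shape as [simulate_ugt_data()].
#' @export
simulate_warped_data <- function(n_records = 23L, n_positive = 10L,
                                 warp_rate = 0.3, noise_rate = 0.05,
                                 signal_loops = c("b", "e"), seed = 1L,
                                 scores =
                                   default_residue_encoding()$scores) {
  ranges <- default_loop_length_ranges()
  res20 <- rownames(scores)
  sig <- match(signal_loops, letters[1:7])
  with_local_seed(seed, {
    shared <- lapply(1:7, function(j)
      sample(res20, round(mean(ranges[j, ])), replace = TRUE))
    tmpl <- lapply(c(pos = 1, neg = 2), function(cls) {
      tm <- shared
      for (j in sig)
        tm[[j]] <- sample(res20, round(mean(ranges[j, ])),
                          replace = TRUE)
      tm
    })
    labels <- sample(c(rep(TRUE, n_positive),
                       rep(FALSE, n_records - n_positive)))
    ids <- sprintf("ugt%02d", seq_len(n_records))
    names(labels) <- ids
    warp <- function(x, lo, hi) {
      out <- character()
      for (ch in x) {
        u <- stats::runif(1)
        if (u < warp_rate / 2) next                   # deletion
        out <- c(out, ch)
        if (u > 1 - warp_rate / 2) out <- c(out, ch)  # duplication
      }
      if (length(out) < lo)
        out <- c(out, sample(x, lo - length(out), replace = TRUE))
      if (length(out) > hi) out <- out[seq_len(hi)]
      out
    }
    records <- vector("list", n_records)
    for (r in seq_len(n_records)) {
      tm <- if (labels[r]) tmpl$pos else tmpl$neg
      loops_chars <- lapply(1:7, function(j)
        warp(tm[[j]], ranges[j, 1], ranges[j, 2]))
      lens <- vapply(loops_chars, length, 0L)
      L <- sample(446:511, 1L)
      slack <- L - sum(lens) - 8L
      extra <- tabulate(sample.int(8L, slack, replace = TRUE),
                        nbins = 8L)
      gaps <- 1L + extra
      starts <- cumsum(c(gaps[1] + 1L,
                         utils::head(lens, -1) + gaps[2:7]))
      ends <- starts + lens - 1L
      chars <- sample(res20, L, replace = TRUE)
      for (j in 1:7)
        chars[seq.int(starts[j], ends[j])] <- loops_chars[[j]]
      flip <- stats::runif(L) < noise_rate
      chars[flip] <- sample(res20, sum(flip), replace = TRUE)
      records[[r]] <- ugt_record(ids[r], paste(chars, collapse = ""),
                                 data.frame(loop = letters[1:7],
                                            start = starts, end = ends),
                                 label = labels[[r]])
    }
    names(records) <- ids
    list(records = records,
         manifest = list(labels = labels, warp_rate = warp_rate,
                         noise_rate = noise_rate, seed = seed))
  })
}

#' Write a simulated dataset as a plain-text fixture
#'
#' Produces the same three files [read_dataset()] consumes - `sequences.fa`,
#' `loops.tsv`, `labels.tsv` (positives get class `"3"`, negatives `"NA"`,
#' so the fixture reads back under problem `"3-O"`) - plus a `manifest.txt`
#' recording the generator parameters.
#'
#' @param sim A [simulate_ugt_data()] result.
#' @param directory Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(sim, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create ", directory)
  paths <- c(fasta = file.path(directory, "sequences.fa"),
             loops = file.path(directory, "loops.tsv"),
             labels = file.path(directory, "labels.tsv"),
             manifest = file.path(directory, "manifest.txt"))
  fa <- unlist(lapply(sim$records, function(r)
    c(paste0(">", r$id), r$sequence)))
  writeLines(fa, paths["fasta"])
  loops <- do.call(rbind, lapply(sim$records, function(r)
    data.frame(id = r$id, r$loops,
               exclude = "", stringsAsFactors = FALSE)))
  utils::write.table(loops, paths["loops"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  labels <- data.frame(id = names(sim$manifest$labels),
                       class = ifelse(sim$manifest$labels, "3", "NA"))
  utils::write.table(labels, paths["labels"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- sim$manifest$config
  writeLines(c(paste0("seed=", cfg$seed),
               paste0("n_records=", cfg$n_records),
               paste0("n_positive=", cfg$n_positive),
               paste0("effect_size=", cfg$effect_size),
               paste0("noise_rate=", cfg$noise_rate),
               paste0("signal_loops=",
                      paste(cfg$signal_loops, collapse = "")),
               paste0("signal_indices=",
                      paste(cfg$signal_indices, collapse = ""))),
             paths["manifest"])
  invisible(paths)
}
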