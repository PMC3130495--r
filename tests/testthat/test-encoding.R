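mk_rec <- function(seq, starts, ends, id = "r1", excl = integer())
  ugt_record(id, seq, data.frame(loop = letters[1:7], start = starts,
                                 end = ends), exclusions = excl)

test_that("record validation catches malformed loop annotations", {
  seq60 <- paste(rep("A", 60), collapse = "")
  starts <- c(3, 10, 18, 27, 34, 42, 50)
  ends <- starts + 1
  expect_s3_class(mk_rec(seq60, starts, ends), "ugt_record")
  expect_error(mk_rec(seq60, starts, replace(ends, 7, 70)), "bounds")
  expect_error(mk_rec(seq60, starts, replace(ends, 2, 5)), "empty loop")
  expect_error(mk_rec(seq60, replace(starts, 2, 4), ends), "overlap")
  expect_error(ugt_record("x", seq60,
                          data.frame(loop = letters[1:6],
                                     start = starts[1:6],
                                     end = ends[1:6])),
               "exactly loops a-g")
})

test_that("encode_record maps loop residues through the score table", {
  seq <- paste0("MM", "AG", "XXXXXX",
                strrep("K", 52))
  rec <- ugt_record("r1", seq,
                    data.frame(loop = letters[1:7],
                               start = c(3, 11, 15, 20, 25, 30, 35),
                               end = c(4, 12, 16, 21, 26, 31, 36)))
  sets <- suppressWarnings(encode_record(rec, enc$scores))
  expect_equal(sets$a, enc$scores[c("A", "G"), ], ignore_attr = TRUE)
  expect_equal(nrow(sets$a), 2L)
  # all series in a loop share its length
  for (lp in letters[1:7])
    expect_equal(nrow(sets[[lp]]), 2L)
})

test_that("excluded positions are dropped before encoding", {
  base <- strrep("C", 60)
  mk <- function(s, excl = integer())
    ugt_record("r", s, data.frame(loop = letters[1:7],
                                  start = c(3, 10, 18, 27, 34, 42, 50),
                                  end = c(5, 11, 19, 28, 35, 43, 51)),
               exclusions = excl)
  s_hag <- paste0("CC", "HAG", substr(base, 6, 60))
  s_ag <- paste0("CC", "AG", substr(base, 6, 60))
  rec_hag <- mk(s_hag, excl = 3L)     # drop the conserved His
  enc_hag <- encode_record(rec_hag, enc$scores)
  expect_equal(enc_hag$a, enc$scores[c("A", "G"), ], ignore_attr = TRUE)

  # positional locality: a change outside every loop never alters series
  s2 <- paste0("WW", substr(s_hag, 3, 60))
  enc2 <- encode_record(mk(s2, excl = 3L), enc$scores)
  for (lp in letters[1:7])
    expect_identical(enc_hag[[lp]], enc2[[lp]])
})

test_that("ambiguous residues encode to zero with a warning", {
  seq <- paste0("CC", "XA", strrep("C", 56))
  rec <- mk_rec(seq, c(3, 10, 18, 27, 34, 42, 50),
                c(4, 11, 19, 28, 35, 43, 51))
  expect_warning(sets <- encode_record(rec, enc$scores), "ambiguous")
  expect_equal(unname(sets$a[1, ]), rep(0, 7))
  expect_equal(sets$a[2, ], enc$scores["A", ], ignore_attr = TRUE)
})

test_that("covering windows cover every loop at uniform length", {
  recs <- make_toy_records(5)
  win <- build_covering_windows(recs, margins = 3L)
  expect_equal(win$L_total, sum(win$window_length))
  for (r in recs) {
    for (j in 1:7) {
      s <- win$starts[r$id, j]
      e <- s + win$window_length[j] - 1
      expect_lte(s, r$loops$start[j])
      expect_gte(e, r$loops$end[j])
    }
  }
  # identical records give identical windows
  recs2 <- lapply(1:3, function(i) {
    r <- recs[[1]]
    ugt_record(paste0("dup", i), r$sequence, r$loops)
  })
  win2 <- build_covering_windows(recs2, margins = 2L)
  expect_true(all(apply(win2$starts, 2, function(col)
    length(unique(col)) == 1L)))
})

test_that("window placement maximizes sum-of-pairs score (brute force)", {
  # plant a shared motif near loop b at different offsets; the one-loop
  # optimum is verified by exhaustive enumeration over admissible offsets
  motif <- "WWYFWW"
  mk <- function(id, pre) {
    seq <- paste0(strrep("A", pre), motif,
                  strrep("A", 40 - pre - nchar(motif)), strrep("G", 25))
    starts <- c(2, pre + 2, 45, 50, 54, 58, 62)
    ends <- starts + c(0, 2, 1, 1, 1, 1, 1)
    ugt_record(id, seq, data.frame(loop = letters[1:7], start = starts,
                                   end = ends))
  }
  recs <- list(mk("a1", 8), mk("a2", 10), mk("a3", 12))
  win <- build_covering_windows(recs, margins = 4L)
  B62 <- blosum62()
  chars <- lapply(recs, function(r) strsplit(r$sequence, "")[[1]])
  W <- win$window_length[["b"]]
  sp_total <- function(ss) {
    mats <- lapply(1:3, function(i)
      chars[[i]][seq.int(ss[i], ss[i] + W - 1)])
    sum(B62[cbind(mats[[1]], mats[[2]])]) +
      sum(B62[cbind(mats[[1]], mats[[3]])]) +
      sum(B62[cbind(mats[[2]], mats[[3]])])
  }
  ranges <- lapply(1:3, function(i) {
    ls <- recs[[i]]$loops$start[2]; le <- recs[[i]]$loops$end[2]
    seq.int(max(le - W + 1, 1), ls)
  })
  grid <- expand.grid(ranges)
  best <- max(apply(grid, 1, sp_total))
  got <- sp_total(win$starts[, "b"])
  expect_equal(got, best)
})

test_that("flattened vectors share one length with the stated layout", {
  recs <- make_toy_records(4)
  win <- build_covering_windows(recs, margins = 2L)
  vecs <- lapply(recs, flatten_to_vector, windows = win,
                 scores = enc$scores)
  lens <- vapply(vecs, length, 0L)
  expect_true(all(lens == win$L_total * 7))

  # single 1-residue window flattens to that residue's scores
  one <- flatten_dataset(recs, win, enc$scores)
  expect_equal(dim(one), c(4L, win$L_total * 7L))

  # identical windowed residues -> identical vectors
  r <- recs[[1]]
  dup <- ugt_record("dup", r$sequence, r$loops)
  win2 <- build_covering_windows(list(r, dup), margins = 2L)
  expect_identical(flatten_to_vector(r, win2, enc$scores),
                   flatten_to_vector(dup, win2, enc$scores))

  # layout: first 7 entries are the scores of the first window position
  v <- flatten_to_vector(r, win, scores = enc$scores)
  first_char <- substr(r$sequence, win$starts[r$id, 1],
                       win$starts[r$id, 1])
  expect_equal(v[1:7], unname(enc$scores[first_char, ]))
})

test_that("windows wider than a whole sequence are padded neutrally", {
  # a record much shorter than the loop-c window (forced wide by the
  # other record's 24-residue loop) cannot fit it even after shifting
  # inward, so its window is padded with the neutral token
  short <- ugt_record("short", "AKAKAKAGAGAGAGAGAGAG",
                      data.frame(loop = letters[1:7],
                                 start = c(2, 4, 6, 9, 12, 15, 18),
                                 end = c(2, 4, 7, 10, 13, 16, 19)))
  long_chars <- paste(rep(c("K", "W"), 30), collapse = "")
  long <- ugt_record("long", long_chars,
                     data.frame(loop = letters[1:7],
                                start = c(2, 5, 8, 35, 40, 46, 52),
                                end = c(2, 5, 31, 36, 41, 47, 53)))
  win <- build_covering_windows(list(short, long), margins = 1L)
  expect_gt(win$window_length[["c"]], nchar(short$sequence))
  v <- flatten_to_vector(short, win, enc$scores)
  expect_equal(length(v), win$L_total * 7)
  expect_true(all(is.finite(v)))
  # the overhanging positions of loop c encode to zeros
  offset <- sum(win$window_length[c("a", "b")]) * 7
  cwin <- v[(offset + 1):(offset + win$window_length[["c"]] * 7)]
  tail7 <- cwin[(length(cwin) - 6):length(cwin)]
  expect_equal(unname(tail7), rep(0, 7))
})
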