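# shared fixtures, built in code at test time

chem <- load_chemistry()
enc <- default_residue_encoding()

# a small deterministic panel of toy records with seven 2-4 residue loops
make_toy_records <- function(n = 4, seed = 42) {
  with_seed_local <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    expr
  }
  with_seed_local({
    lapply(seq_len(n), function(i) {
      chars <- sample(standard_residues(), 60, replace = TRUE)
      starts <- c(3, 10, 18, 27, 34, 42, 50)
      ends <- starts + c(1, 2, 3, 1, 0, 2, 1)
      ugt_record(sprintf("toy%02d", i), paste(chars, collapse = ""),
                 data.frame(loop = letters[1:7], start = starts,
                            end = ends),
                 label = i %% 2 == 0)
    })
  })
}

toy_labels <- function(records)
  vapply(records, function(r) r$label, NA) |>
    stats::setNames(vapply(records, `[[`, "", "id"))

# independent unit-hop BFS distances from CA using only the bonds table
bfs_hops_from_tables <- function(residue) {
  bd <- chem$bonds[chem$bonds$residue == residue, ]
  verts <- unique(c(bd$atom1, bd$atom2, "CA"))
  d <- stats::setNames(rep(Inf, length(verts)), verts)
  d["CA"] <- 0
  frontier <- "CA"
  while (length(frontier)) {
    nxt <- character()
    for (v in frontier) {
      nb <- c(bd$atom2[bd$atom1 == v], bd$atom1[bd$atom2 == v])
      new <- nb[d[nb] == Inf]
      d[new] <- d[v] + 1
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  d
}
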