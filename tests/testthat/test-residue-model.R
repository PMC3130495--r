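test_that("side-chain graphs have the expected structure", {
  g <- build_residue_graph("G", chem)
  expect_setequal(igraph::V(g)$name, c("CA", "HA2"))

  p <- build_residue_graph("P", chem)
  expect_gt(igraph::girth(p)$girth, 0)           # cyclic
  cyc <- igraph::girth(p)$circle
  expect_true("CA" %in% attr(cyc, "names") ||
                "CA" %in% igraph::V(p)$name[as.integer(cyc)])

  a <- build_residue_graph("A", chem)
  expect_equal(igraph::vcount(a), 5L)            # CA + CB + 3 H
  expect_true(igraph::is_tree(a))

  for (r in standard_residues()) {
    g <- build_residue_graph(r, chem)
    expect_true(igraph::is_connected(g))
    d <- igraph::distances(g, v = "CA")
    expect_true(all(is.finite(d)))               # all reachable from root
  }

  expect_error(build_residue_graph("B", chem), "unknown residue")
  expect_error(build_residue_graph("ALA", chem), "unknown residue")
})

test_that("reach equals a brute-force all-simple-paths oracle", {
  expect_equal(reach(build_residue_graph("G", chem)), 1.09)
  for (r in c("A", "S", "K", "W", "P", "H")) {
    g <- build_residue_graph(r, chem)
    # oracle: enumerate every simple path from the root, min cost per
    # target then max over targets
    best <- stats::setNames(rep(Inf, igraph::vcount(g)),
                            igraph::V(g)$name)
    best["CA"] <- 0
    for (v in setdiff(igraph::V(g)$name, "CA")) {
      paths <- igraph::all_simple_paths(g, from = "CA", to = v)
      for (p in paths) {
        ep <- igraph::E(g, path = p)
        best[v] <- min(best[v], sum(ep$length))
      }
    }
    expect_equal(reach(g), max(best), info = r)
    expect_gte(reach(g), max(igraph::E(g)$length))
  }
})

test_that("branching density matches an independent degree census", {
  # census straight from the bonds table, no igraph
  for (r in c("L", "G", "F")) {
    bd <- chem$bonds[chem$bonds$residue == r, ]
    deg <- table(c(bd$atom1, bd$atom2))
    internal <- deg[deg >= 2]
    expected <- if (length(internal)) mean(internal) else 0
    expect_equal(branching_density(build_residue_graph(r, chem)),
                 expected, info = r)
  }
  expect_equal(branching_density(build_residue_graph("L", chem)), 4)
  expect_equal(branching_density(build_residue_graph("G", chem)), 0)
  # bounds whenever an internal node exists
  for (r in standard_residues()) {
    g <- build_residue_graph(r, chem)
    b <- branching_density(g)
    if (b > 0) {
      expect_gte(b, 2)
      expect_lte(b, max(igraph::degree(g)))
    }
  }
})

test_that("forking index matches a BFS-layer census", {
  for (r in c("V", "K", "Y")) {
    hops <- bfs_hops_from_tables(r)
    bd <- chem$bonds[chem$bonds$residue == r, ]
    deg <- table(c(bd$atom1, bd$atom2))
    internal <- names(deg)[deg >= 2]
    keep <- setdiff(internal, "CA")
    expected <- sum(1 / hops[keep])
    expect_equal(forking_index(build_residue_graph(r, chem)), expected,
                 info = r)
  }
  expect_equal(forking_index(build_residue_graph("G", chem)), 0)
})

test_that("charge-based indices match direct table computations", {
  # net partial charge: plain column sums of the chemistry table
  for (r in c("D", "K", "A")) {
    at <- chem$atoms[chem$atoms$residue == r, ]
    expect_equal(net_partial_charge(build_residue_graph(r, chem)),
                 sum(at$charge), info = r)
  }
  expect_equal(net_partial_charge(build_residue_graph("D", chem)), -1)

  # average polarity: per-bond |dq| * length by hand
  for (r in c("S", "N")) {
    at <- chem$atoms[chem$atoms$residue == r, ]
    q <- stats::setNames(at$charge, at$atom)
    bd <- chem$bonds[chem$bonds$residue == r, ]
    expected <- mean(abs(q[bd$atom1] - q[bd$atom2]) * bd$length)
    expect_equal(average_polarity(build_residue_graph(r, chem)),
                 expected, info = r)
  }
})

test_that("hydrogen-bond indices enumerate qualifying atoms correctly", {
  en <- pauling_electronegativity()
  # asparagine acceptor: only the carbonyl oxygen carries counted pairs
  hops <- bfs_hops_from_tables("N")
  at <- chem$atoms[chem$atoms$residue == "N", ]
  acc <- at[at$lone_pairs > 0, ]
  expected <- sum(acc$lone_pairs * en[acc$element] /
                    (1 + hops[acc$atom]))
  expect_equal(hb_acceptor_index(build_residue_graph("N", chem)),
               expected)

  # lysine donors: three ammonium hydrogens share the nitrogen's weight
  hopsK <- bfs_hops_from_tables("K")
  expect_equal(hb_donor_index(build_residue_graph("K", chem)),
               3 * en[["N"]] / (1 + hopsK[["NZ"]]))

  # alanine has no side-chain N/O/S at all
  expect_equal(hb_acceptor_index(build_residue_graph("A", chem)), 0)
  expect_equal(hb_donor_index(build_residue_graph("A", chem)), 0)
  expect_equal(hb_acceptor_index(build_residue_graph("F", chem)), 0)
})

test_that("indices are invariant under relabeling of node identifiers", {
  relabel <- function(chm, residue) {
    at <- chm$atoms
    bd <- chm$bonds
    sel_a <- at$residue == residue & at$atom != "CA"
    at$atom[sel_a] <- paste0("x_", at$atom[sel_a])
    for (cn in c("atom1", "atom2")) {
      sel_b <- bd$residue == residue & bd[[cn]] != "CA"
      bd[[cn]][sel_b] <- paste0("x_", bd[[cn]][sel_b])
    }
    structure(list(atoms = at, bonds = bd), class = "residue_chemistry")
  }
  for (r in c("W", "K")) {
    g1 <- build_residue_graph(r, chem)
    g2 <- build_residue_graph(r, relabel(chem, r))
    vals1 <- c(reach(g1), branching_density(g1), forking_index(g1),
               net_partial_charge(g1), average_polarity(g1),
               hb_acceptor_index(g1), hb_donor_index(g1))
    vals2 <- c(reach(g2), branching_density(g2), forking_index(g2),
               net_partial_charge(g2), average_polarity(g2),
               hb_acceptor_index(g2), hb_donor_index(g2))
    expect_equal(vals1, vals2, info = r)
  }
})

test_that("the raw index table is complete, finite and deterministic", {
  tab <- compute_raw_index_table(chem)
  expect_equal(dim(tab), c(20L, 7L))
  expect_true(all(is.finite(tab)))
  expect_identical(tab, compute_raw_index_table(chem))
  expect_identical(rownames(tab), standard_residues())
  # rows reproduce the per-residue operations
  g <- build_residue_graph("Q", chem)
  expect_equal(unname(tab["Q", ]),
               c(reach(g), branching_density(g), forking_index(g),
                 net_partial_charge(g), average_polarity(g),
                 hb_acceptor_index(g), hb_donor_index(g)))
  # TSV round trip
  f <- withr::local_tempfile(fileext = ".tsv")
  write_index_table(tab, f)
  expect_equal(read_index_table(f), tab, tolerance = 1e-12)
})
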