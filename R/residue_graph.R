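#' Build the labeled side-chain graph for one residue
#'
#' Models a residue's side chain (plus the alpha-carbon root) as a labeled
#' graph: atoms are nodes carrying element, partial charge, electronegativity,
#' lone-pair count and donor-hydrogen flag; bonds are edges weighted by bond
#' length in Angstrom.  Proline's graph contains the ring closure through the
#' backbone nitrogen and is therefore cyclic through the root.
#'
#' @param residue One-letter code of a standard residue.
#' @param chemistry A [load_chemistry()] parameter set.
#' @return An `igraph` graph with vertex attributes `element`, `charge`,
#'   `electronegativity`, `lone_pairs`, `donor_h`, edge attribute `length`
#'   (also mirrored to `weight`), and graph attributes `residue` and `root`
#'   (the alpha-carbon's vertex name, always `"CA"`).
#' @export
#' @examples
#' g <- build_residue_graph("A", load_chemistry())
#' igraph::vcount(g)   # CA + CB + 3 methyl hydrogens
build_residue_graph <- function(residue, chemistry = load_chemistry()) {
  stopifnot(inherits(chemistry, "residue_chemistry"))
  if (!is.character(residue) || length(residue) != 1L ||
      !residue %in% standard_residues())
    stop("unknown residue code: ", deparse(residue),
         " (expected one of the 20 standard one-letter codes)")
  at <- chemistry$atoms[chemistry$atoms$residue == residue, , drop = FALSE]
  bd <- chemistry$bonds[chemistry$bonds$residue == residue, , drop = FALSE]
  if (!"CA" %in% at$atom) stop("chemistry table for ", residue,
                               " lacks the CA root")
  if (any(bd$atom1 == bd$atom2)) stop("self-bond in chemistry for ", residue)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = bd$atom1, to = bd$atom2, length = bd$length,
                   weight = bd$length),
    directed = FALSE,
    vertices = data.frame(name = at$atom, element = at$element,
                          charge = at$charge,
                          electronegativity = at$electronegativity,
                          lone_pairs = at$lone_pairs, donor_h = at$donor_h))
  if (!igraph::is_connected(g))
    stop("side-chain graph for ", residue, " is not connected")
  g <- igraph::set_graph_attr(g, "residue", residue)
  igraph::set_graph_attr(g, "root", "CA")
}

root_vertex <- function(g) igraph::graph_attr(g, "root")

#' Reach: bond-length-weighted eccentricity of the alpha-carbon
#'
#' The maximum over atoms of the shortest-path distance from the alpha-carbon,
#' using bond lengths as edge weights.  Measures the side chain's size in
#' Angstrom.
#'
#' @param g A side-chain graph from [build_residue_graph()].
#' @return Length in Angstrom (0 for a single-node graph).
#' @export
reach <- function(g) {
  if (igraph::vcount(g) == 1L) return(0)
  d <- igraph::distances(g, v = root_vertex(g), weights =
                           igraph::E(g)$length)
  max(d)
}

#' Branching density: mean degree of the internal nodes
#'
#' Internal nodes are those of degree two or more; their average degree
#' measures the leafiness of the side-chain graph.  Graphs with no internal
#' node (e.g. glycine's) score 0.
#'
#' @inheritParams reach
#' @return Dimensionless mean degree.
#' @export
branching_density <- function(g) {
  deg <- igraph::degree(g)
  internal <- deg[deg >= 2]
  if (!length(internal)) return(0)
  mean(internal)
}

#' Forking index: reciprocal-distance tally of internal nodes
#'
#' With unit edge weights, counts the internal nodes (degree two or more,
#' evaluated on the whole graph) at each hop distance d >= 1 from the
#' alpha-carbon and sums count/d.  The root itself is excluded (distance 0).
#' Measures the presence of lengthy branches.
#'
#' @inheritParams reach
#' @return Dimensionless tally.
#' @export
forking_index <- function(g) {
  deg <- igraph::degree(g)
  hop <- igraph::distances(g, v = root_vertex(g), weights = NA)[1, ]
  keep <- deg >= 2 & hop >= 1
  if (!any(keep)) return(0)
  sum(1 / hop[keep])
}

#' Net partial charge of a residue graph
#'
#' @inheritParams reach
#' @return Sum of atomic partial charges, elementary-charge units.
#' @export
net_partial_charge <- function(g) {
  sum(igraph::V(g)$charge)
}

#' Average polarity: mean unsigned bond dipole
#'
#' Each bond contributes |difference in partial charge between its endpoints|
#' times its bond length; the index is the mean over bonds (0 for a graph
#' with no bonds).  The absolute value is used so that arbitrary bond
#' orientation cannot cancel dipoles.
#'
#' @inheritParams reach
#' @return Average bond dipole in charge * Angstrom.
#' @export
average_polarity <- function(g) {
  if (igraph::ecount(g) == 0L) return(0)
  el <- igraph::as_edgelist(g, names = TRUE)
  q <- igraph::V(g)$charge
  names(q) <- igraph::V(g)$name
  mean(abs(q[el[, 1]] - q[el[, 2]]) * igraph::E(g)$length)
}

# Bounded decreasing distance weight used by the two hydrogen-bond indices:
# 1 / (1 + unit-hop distance from the root).  Configurable via the
# `distance_weight` argument of the index functions.
default_distance_weight <- function(hops) 1 / (1 + hops)

#' Hydrogen-bond acceptor index
#'
#' A weighted tally of the lone electron pairs on N, O or S atoms that accept
#' hydrogen bonds (atoms recorded with `lone_pairs = 0` take no part).  Each
#' qualifying pair contributes the bearing atom's electronegativity times a
#' decreasing function of that atom's unit-hop bond distance from the
#' alpha-carbon (default `1/(1+hops)`).
#'
#' @inheritParams reach
#' @param distance_weight Function mapping a vector of unit-hop distances to
#'   multiplicative weights.
#' @return Dimensionless tally (0 when no atom bears qualifying pairs).
#' @export
hb_acceptor_index <- function(g, distance_weight = default_distance_weight) {
  lp <- igraph::V(g)$lone_pairs
  if (!any(lp > 0)) return(0)
  hop <- igraph::distances(g, v = root_vertex(g), weights = NA)[1, ]
  en <- igraph::V(g)$electronegativity
  sum(lp * en * distance_weight(hop))
}

#' Hydrogen-bond donor index
#'
#' A weighted tally of hydrogens that donate hydrogen bonds and are bound to
#' an N, O or S atom.  Each such hydrogen contributes its heavy partner's
#' electronegativity times a decreasing function of the heavy atom's unit-hop
#' bond distance from the alpha-carbon (default `1/(1+hops)`), so e.g. the
#' three ammonium hydrogens of lysine share one nitrogen's weight.
#'
#' @inheritParams hb_acceptor_index
#' @return Dimensionless tally (0 when the side chain has no N/O/S-bound
#'   donor hydrogen).
#' @export
hb_donor_index <- function(g, distance_weight = default_distance_weight) {
  don <- which(igraph::V(g)$donor_h == 1)
  if (!length(don)) return(0)
  hop <- igraph::distances(g, v = root_vertex(g), weights = NA)[1, ]
  en <- igraph::V(g)$electronegativity
  el <- igraph::V(g)$element
  total <- 0
  for (h in don) {
    nbr <- as.integer(igraph::neighbors(g, h))
    heavy <- nbr[el[nbr] %in% c("N", "O", "S")]
    if (!length(heavy))
      stop("donor hydrogen ", igraph::V(g)$name[h], " in ",
           igraph::graph_attr(g, "residue"), " is not bound to N/O/S")
    heavy <- heavy[1L]
    total <- total + en[heavy] * distance_weight(hop[heavy])
  }
  unname(total)
}

#' Names of the seven raw graph-derived indices, in canonical column order
#' @return Character vector of length 7.
#' @export
index_names <- function() {
  c("reach", "branching_density", "forking_index", "net_partial_charge",
    "average_polarity", "hb_acceptor_index", "hb_donor_index")
}

#' Compute the 20 x 7 raw residue index table
#'
#' Builds each residue's side-chain graph and evaluates the seven
#' graph-derived indices, yielding the raw numerical encoding of residue
#' types.  Deterministic given the chemistry parameters.
#'
#' @inheritParams build_residue_graph
#' @param distance_weight Distance weighting hook passed to the two
#'   hydrogen-bond indices.
#' @return A 20 x 7 numeric matrix, rows named by one-letter residue code
#'   (alphabetical), columns by [index_names()].
#' @export
#' @examples
#' tab <- compute_raw_index_table()
#' tab["K", "hb_donor_index"] > 0
compute_raw_index_table <- function(chemistry = load_chemistry(),
                                    distance_weight =
                                      default_distance_weight) {
  res <- standard_residues()
  out <- matrix(NA_real_, nrow = length(res), ncol = 7,
                dimnames = list(res, index_names()))
  for (r in res) {
    g <- build_residue_graph(r, chemistry)
    out[r, ] <- c(reach(g), branching_density(g), forking_index(g),
                  net_partial_charge(g), average_polarity(g),
                  hb_acceptor_index(g, distance_weight),
                  hb_donor_index(g, distance_weight))
  }
  if (any(!is.finite(out))) stop("non-finite index value computed")
  out
}

#' Write / read an index table as TSV
#'
#' @param table A 20 x 7 matrix as from [compute_raw_index_table()] or
#'   [project_indices()].
#' @param path File path.
#' @return `write_index_table` returns `path` invisibly; `read_index_table`
#'   returns the matrix.
#' @export
write_index_table <- function(table, path) {
  df <- data.frame(residue = rownames(table), table, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_index_table
#' @export
read_index_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$residue
  m
}
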