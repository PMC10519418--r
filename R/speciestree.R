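## Quartet-agreement species-tree estimation: exhaustive enumeration for
## small taxon sets (the oracle) and seeded greedy insertion plus NNI hill
## climbing otherwise. Trees are manipulated as undirected edge lists over a
## fixed taxon universe (leaves 1..N, internal nodes N+1..), and scored by
## the total number of gene-tree quartets agreeing with the topology.

## distance matrix of an edge-list tree over the taxon universe;
## absent taxa get -1 rows/columns (including the diagonal)
edges_to_dist <- function(edges, n_univ, present) {
  n_nodes <- max(edges)
  D <- topo_dist_cpp(edges, n_nodes, n_univ)
  absent <- setdiff(seq_len(n_univ), present)
  if (length(absent)) {
    D[absent, ] <- -1L
    D[, absent] <- -1L
  }
  D
}

## gene trees -> list of unit-length leaf distance matrices over `taxa`;
## gene-tree leaves outside `taxa` are ignored (only 4-subsets present in
## both trees can ever be scored)
gene_dist_matrices <- function(gene_trees, taxa) {
  n <- length(taxa)
  lapply(gene_trees, function(gt) {
    Dg <- topo_distances(gt)
    shared <- intersect(gt$tip.label, taxa)
    D <- matrix(-1L, n, n)
    D[match(shared, taxa), match(shared, taxa)] <-
      Dg[shared, shared, drop = FALSE]
    storage.mode(D) <- "integer"
    D
  })
}

## star tree on three leaves; internal nodes start at n_univ + 1
start_edges <- function(leaves, n_univ) {
  ctr <- n_univ + 1L
  matrix(c(ctr, leaves[1L], ctr, leaves[2L], ctr, leaves[3L]),
         ncol = 2L, byrow = TRUE)
}

## attach `leaf` in the middle of edge `k`, creating one internal node
insert_leaf <- function(edges, k, leaf, n_univ) {
  m <- max(c(edges, n_univ)) + 1L
  a <- edges[k, 1L]
  b <- edges[k, 2L]
  rbind(edges[-k, , drop = FALSE],
        matrix(c(a, m, m, b, m, leaf), ncol = 2L, byrow = TRUE))
}

## canonical Newick of an edge-list tree (children sorted by smallest
## descendant label); basal trifurcation at the internal node adjacent to
## the smallest present leaf
edges_to_newick <- function(edges, taxa, present = NULL) {
  if (is.null(present)) present <- sort(intersect(unique(c(edges)), seq_along(taxa)))
  n_univ <- length(taxa)
  adj <- split(c(edges[, 2L], edges[, 1L]), c(edges[, 1L], edges[, 2L]))
  names(adj) <- as.character(as.integer(names(adj)))
  rec <- function(v, parent) {
    if (v <= n_univ) return(list(min = taxa[v], str = taxa[v]))
    kids <- setdiff(adj[[as.character(v)]], parent)
    subs <- lapply(kids, rec, parent = v)
    ord <- order(vapply(subs, `[[`, "", "min"))
    subs <- subs[ord]
    list(min = subs[[1L]]$min,
         str = paste0("(", paste(vapply(subs, `[[`, "", "str"),
                                 collapse = ","), ")"))
  }
  first_leaf <- present[order(taxa[present])[1L]]
  root <- adj[[as.character(first_leaf)]][1L]
  kids <- adj[[as.character(root)]]
  subs <- lapply(kids, rec, parent = root)
  ord <- order(vapply(subs, `[[`, "", "min"))
  paste0("(", paste(vapply(subs[ord], `[[`, "", "str"), collapse = ","), ");")
}

#' Quartet agreement score of a topology
#'
#' Sums, over gene trees and over the 4-leaf subsets present in both the
#' topology and the gene tree, the indicator that both trees induce the same
#' quartet topology. Quartets unresolved in a gene tree contribute nothing.
#'
#' @param topology `phylo`; its leaves define the scored taxa.
#' @param gene_trees list of `phylo`, leaf sets subsets of the topology's.
#' @return non-negative integer (as double).
#' @export
quartet_agreement_score <- function(topology, gene_trees) {
  taxa <- sort(topology$tip.label)
  n <- length(taxa)
  Dt <- matrix(-1L, n, n)
  idx <- match(topology$tip.label, taxa)
  Dt[idx, idx] <- topo_distances(topology)
  storage.mode(Dt) <- "integer"
  quartet_score_cpp(Dt, gene_dist_matrices(gene_trees, taxa))
}

## internal: score an edge-list candidate against precomputed gene matrices
score_edges <- function(edges, present, n_univ, gene_D) {
  quartet_score_cpp(edges_to_dist(edges, n_univ, present), gene_D)
}

## enumerate all unrooted binary topologies on leaves 1..k by stepwise
## leaf addition (k = 3 -> 1 tree, k = n -> (2n-5)!! trees)
enumerate_topologies <- function(leaves, n_univ) {
  stopifnot(length(leaves) >= 3L)
  trees <- list(start_edges(leaves[1:3], n_univ))
  for (leaf in leaves[-(1:3)]) {
    trees <- unlist(lapply(trees, function(ed)
      lapply(seq_len(nrow(ed)), function(k)
        insert_leaf(ed, k, leaf, n_univ))), recursive = FALSE)
  }
  trees
}

#' Exhaustive quartet-agreement species-tree search
#'
#' Enumerates every unrooted binary topology on the taxon set (by stepwise
#' leaf addition) and returns a maximum-score topology. Ties are broken by
#' the lexicographically smallest canonical Newick string; all co-optima are
#' reported.
#'
#' @param gene_trees list of `phylo`.
#' @param taxa taxon labels (default: sorted union of gene-tree leaves);
#'   at most 8.
#' @return list with `tree` (`phylo`), `newick`, `score`, and `co_optima`
#'   (canonical Newick strings of all maximum-score topologies).
#' @export
exhaustive_search <- function(gene_trees, taxa = NULL) {
  if (is.null(taxa))
    taxa <- sort(unique(unlist(lapply(gene_trees, `[[`, "tip.label"))))
  taxa <- sort(taxa)
  n <- length(taxa)
  if (n < 4L) stop("need at least 4 taxa")
  if (n > 8L) stop("exhaustive search is capped at 8 taxa")
  gene_D <- gene_dist_matrices(gene_trees, taxa)
  trees <- enumerate_topologies(seq_len(n), n)
  scores <- vapply(trees, score_edges, numeric(1L),
                   present = seq_len(n), n_univ = n, gene_D = gene_D)
  best <- max(scores)
  opt <- which(scores == best)
  nwk <- vapply(trees[opt], edges_to_newick, "", taxa = taxa,
                present = seq_len(n))
  nwk <- sort(unique(nwk))
  list(tree = ape::read.tree(text = nwk[1L]), newick = nwk[1L],
       score = best, co_optima = nwk)
}

## the two NNI neighbours across internal edge k of a binary edge list
nni_neighbors <- function(edges, k, n_univ) {
  u <- edges[k, 1L]
  v <- edges[k, 2L]
  if (u <= n_univ || v <= n_univ) return(list())
  iu <- which((edges[, 1L] == u | edges[, 2L] == u) & seq_len(nrow(edges)) != k)
  iv <- which((edges[, 1L] == v | edges[, 2L] == v) & seq_len(nrow(edges)) != k)
  other <- function(i, node) if (edges[i, 1L] == node) edges[i, 2L] else edges[i, 1L]
  b <- other(iu[2L], u) # swap u's second neighbour with each of v's
  lapply(iv, function(ic) {
    c_ <- other(ic, v)
    e2 <- edges
    e2[iu[2L], ] <- c(u, c_)
    e2[ic, ] <- c(v, b)
    e2
  })
}

#' Greedy quartet-agreement species-tree search
#'
#' Seeded stepwise insertion: taxa are added in random order, each at the
#' edge maximising the quartet-agreement score of the partial tree, followed
#' by nearest-neighbour-interchange (NNI) hill climbing to a local optimum.
#' Deterministic given the seed; the NNI phase never decreases the score.
#'
#' @param gene_trees list of `phylo`.
#' @param taxa taxon labels (default: sorted union of gene-tree leaves).
#' @param seed integer seed controlling the insertion order.
#' @return list with `tree` (`phylo`), `newick`, `score`.
#' @export
greedy_search <- function(gene_trees, taxa = NULL, seed = 1L) {
  if (is.null(taxa))
    taxa <- sort(unique(unlist(lapply(gene_trees, `[[`, "tip.label"))))
  taxa <- sort(taxa)
  n <- length(taxa)
  if (n < 4L) stop("need at least 4 taxa")
  gene_D <- gene_dist_matrices(gene_trees, taxa)
  set.seed(as.integer(seed))
  ord <- sample.int(n)
  edges <- start_edges(ord[1:3], n)
  present <- ord[1:3]
  for (leaf in ord[-(1:3)]) {
    present2 <- c(present, leaf)
    cand <- lapply(seq_len(nrow(edges)), function(k)
      insert_leaf(edges, k, leaf, n))
    sc <- vapply(cand, score_edges, numeric(1L),
                 present = present2, n_univ = n, gene_D = gene_D)
    edges <- cand[[which.max(sc)]]
    present <- present2
  }
  best <- score_edges(edges, present, n, gene_D)
  repeat {
    improved <- FALSE
    internal <- which(edges[, 1L] > n & edges[, 2L] > n)
    for (k in internal) {
      for (nb in nni_neighbors(edges, k, n)) {
        s <- score_edges(nb, present, n, gene_D)
        if (s > best) {
          stopifnot(s >= best) # hill climbing never decreases the score
          edges <- nb
          best <- s
          improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) break
  }
  nwk <- edges_to_newick(edges, taxa, present)
  list(tree = ape::read.tree(text = nwk), newick = nwk, score = best)
}
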