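## Tree comparison and per-branch concordance statistics: Robinson-Foulds
## distance, clade recovery, gene concordance factor, and quartet support.

## leaf-label sets for every node (tips + internal), by postorder traversal
node_leaf_sets <- function(tree) {
  n <- length(tree$tip.label)
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- tree$tip.label[i]
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1L]
    ch <- ord$edge[e, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

## canonical key of the bipartition side_set | complement over `taxa`:
## the side not containing the alphabetically first taxon, sorted
split_key <- function(side, taxa) {
  ref <- min(taxa)
  if (ref %in% side) side <- setdiff(taxa, side)
  paste(sort(side), collapse = "\r")
}

## non-trivial unrooted bipartition keys of a tree
unrooted_split_keys <- function(tree) {
  taxa <- tree$tip.label
  n <- length(taxa)
  if (n < 4L) return(character(0))
  sets <- node_leaf_sets(tree)
  root <- n + 1L
  keys <- character(0)
  for (v in seq_along(sets)) {
    if (v == root) next
    k <- length(sets[[v]])
    if (k < 2L || k > n - 2L) next
    keys <- c(keys, split_key(sets[[v]], taxa))
  }
  unique(keys)
}

## non-root clade keys (rooted interpretation), clades of 2..n-1 leaves
rooted_clade_keys <- function(tree) {
  n <- length(tree$tip.label)
  sets <- node_leaf_sets(tree)
  root <- n + 1L
  internal <- setdiff(seq.int(n + 1L, n + tree$Nnode), root)
  keys <- vapply(internal, function(v) paste(sort(sets[[v]]), collapse = "\r"), "")
  unique(keys[vapply(internal, function(v)
    length(sets[[v]]) < n, logical(1L))])
}

#' Robinson-Foulds distance between two trees
#'
#' Unrooted mode counts the symmetric difference of the non-trivial
#' bipartition sets; rooted mode counts the symmetric difference of the
#' non-root clade sets. With `prune_to_common`, both trees are first pruned
#' to their shared leaves.
#'
#' @param t1,t2 `phylo` objects.
#' @param mode `"unrooted"` (default) or `"rooted"`.
#' @param prune_to_common prune both trees to their shared leaf set.
#' @return non-negative integer; 0 iff the trees are topologically identical.
#' @export
rf_distance <- function(t1, t2, mode = c("unrooted", "rooted"),
                        prune_to_common = FALSE) {
  mode <- match.arg(mode)
  l1 <- t1$tip.label
  l2 <- t2$tip.label
  if (!setequal(l1, l2)) {
    if (!prune_to_common)
      stop("trees have different leaf sets; set prune_to_common = TRUE")
    common <- intersect(l1, l2)
    need <- if (mode == "rooted") 3L else 4L
    if (length(common) < need)
      stop(sprintf("fewer than %d shared leaves", need))
    t1 <- ape::keep.tip(t1, common)
    t2 <- ape::keep.tip(t2, common)
  }
  if (mode == "unrooted") {
    k1 <- unrooted_split_keys(t1)
    k2 <- unrooted_split_keys(t2)
  } else {
    k1 <- rooted_clade_keys(t1)
    k2 <- rooted_clade_keys(t2)
  }
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Which reference clades occur in a rooted tree
#'
#' @param tree rooted `phylo`.
#' @param reference_clades list of character vectors (leaf sets).
#' @return logical vector, one entry per reference clade: `TRUE` iff the
#'   leaf set is exactly the leaf set of some node (tips and root included).
#' @export
clade_recovery <- function(tree, reference_clades) {
  taxa <- tree$tip.label
  for (cl in reference_clades)
    if (!all(cl %in% taxa))
      stop(sprintf("clade contains unknown leaf '%s'",
                   setdiff(cl, taxa)[1L]))
  sets <- node_leaf_sets(tree)
  keys <- unique(vapply(sets, function(s) paste(sort(s), collapse = "\r"), ""))
  vapply(reference_clades, function(cl)
    paste(sort(cl), collapse = "\r") %in% keys, logical(1L))
}

## species-tree internal branches as lists of (side, key) over its taxa
species_branches <- function(species_tree) {
  taxa <- species_tree$tip.label
  n <- length(taxa)
  sets <- node_leaf_sets(species_tree)
  root <- n + 1L
  seen <- character(0)
  branches <- list()
  for (v in seq_along(sets)) {
    if (v == root) next
    k <- length(sets[[v]])
    if (k < 2L || k > n - 2L) next
    key <- split_key(sets[[v]], taxa)
    if (key %in% seen) next
    seen <- c(seen, key)
    branches[[length(branches) + 1L]] <- list(side = sets[[v]], key = key)
  }
  branches
}

split_label <- function(side, taxa) {
  other <- setdiff(taxa, side)
  small <- if (length(side) <= length(other)) side else other
  paste(sort(small), collapse = ",")
}

#' Gene concordance factor per species-tree branch
#'
#' For each internal branch (bipartition `A|B`) of the species tree, each
#' gene tree is restricted to its own leaf set; the gene tree is decisive
#' when both restricted sides keep at least two leaves, and concordant when
#' the restricted bipartition occurs among the gene tree's bipartitions
#' (a polytomy is non-concordant but still decisive). The factor is
#' `100 * concordant / decisive`, undefined (`NA`) when no gene tree is
#' decisive.
#'
#' @param species_tree `phylo`.
#' @param gene_trees list of `phylo`, possibly missing taxa.
#' @return data.frame with columns `branch` (label of the smaller side),
#'   `n_decisive`, `n_concordant`, `gcf_pct`.
#' @export
gene_concordance_factor <- function(species_tree, gene_trees) {
  taxa <- species_tree$tip.label
  branches <- species_branches(species_tree)
  gene_info <- lapply(gene_trees, function(gt) {
    if (!all(gt$tip.label %in% taxa))
      stop(sprintf("gene tree leaf '%s' is not in the species tree",
                   setdiff(gt$tip.label, taxa)[1L]))
    list(leaves = gt$tip.label, keys = unrooted_split_keys(gt))
  })
  res <- lapply(branches, function(br) {
    A <- br$side
    dec <- 0L
    con <- 0L
    for (gi in gene_info) {
      L <- gi$leaves
      A2 <- intersect(A, L)
      B2 <- setdiff(L, A2)
      if (length(A2) < 2L || length(B2) < 2L) next
      dec <- dec + 1L
      if (split_key(A2, L) %in% gi$keys) con <- con + 1L
    }
    data.frame(branch = split_label(A, taxa), n_decisive = dec,
               n_concordant = con,
               gcf_pct = if (dec > 0L) 100 * con / dec else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

## unit-branch-length leaf distance matrix of a tree
topo_distances <- function(tree) {
  n <- length(tree$tip.label)
  D <- topo_dist_cpp(tree$edge, n + tree$Nnode, n)
  dimnames(D) <- list(tree$tip.label, tree$tip.label)
  D
}

## the four leaf clusters around each internal branch of a binary tree
branch_clusters <- function(species_tree) {
  tr <- species_tree
  n <- length(tr$tip.label)
  sets <- node_leaf_sets(tr)
  root <- n + 1L
  children <- split(tr$edge[, 2L], tr$edge[, 1L])
  parent <- setNames(tr$edge[, 1L], tr$edge[, 2L])
  taxa <- tr$tip.label
  root_children <- children[[as.character(root)]]
  out <- list()
  for (v in seq.int(n + 1L, n + tr$Nnode)) {
    if (v == root) next
    kids <- children[[as.character(v)]]
    if (length(kids) != 2L)
      stop("quartet support requires a binary species tree")
    p <- parent[[as.character(v)]]
    below <- list(sets[[kids[1L]]], sets[[kids[2L]]])
    if (p == root) {
      others <- setdiff(root_children, v)
      if (length(others) == 1L) {
        ## basal bifurcation: the two root edges are one unrooted branch,
        ## whose far side is the sibling's two child subtrees
        sib <- others
        if (sib <= n) next # pendant edge: not an internal branch
        sibkids <- children[[as.character(sib)]]
        if (length(sibkids) != 2L)
          stop("quartet support requires a binary species tree")
        above <- list(sets[[sibkids[1L]]], sets[[sibkids[2L]]])
      } else if (length(others) == 2L) {
        above <- list(sets[[others[1L]]], sets[[others[2L]]])
      } else stop("quartet support requires a binary species tree")
    } else {
      sib <- setdiff(children[[as.character(p)]], v)
      if (length(sib) != 1L)
        stop("quartet support requires a binary species tree")
      above <- list(sets[[sib]], setdiff(taxa, sets[[p]]))
    }
    if (any(lengths(above) == 0L)) next
    out[[length(out) + 1L]] <-
      list(side = sets[[v]], key = split_key(sets[[v]], taxa),
           below = below, above = above)
  }
  ## deduplicate branches (a basal bifurcation induces one split twice)
  keys <- vapply(out, `[[`, "", "key")
  out[!duplicated(keys)]
}

#' Quartet support per species-tree branch
#'
#' For each internal branch, the four adjacent subtree clusters define the
#' quartets (one leaf per cluster). Over the gene trees containing all four
#' sampled leaves, the three possible quartet topologies are tallied: `q1` is
#' the fraction concordant with the species tree, `q2` and `q3` the two
#' alternatives. All quartets are enumerated when their number is at most
#' `max_quartets_per_branch`; otherwise that many are drawn uniformly (with
#' replacement) under the given seed. Quartets unresolved in a gene tree are
#' skipped.
#'
#' @param species_tree binary `phylo`.
#' @param gene_trees list of `phylo`.
#' @param max_quartets_per_branch cap on quartets per branch (default 1000).
#' @param seed integer seed for quartet sampling.
#' @return data.frame with columns `branch`, `n_quartets`, `n_decisive`
#'   (gene trees contributing at least one resolved quartet), `q1`, `q2`,
#'   `q3`.
#' @export
quartet_support <- function(species_tree, gene_trees,
                            max_quartets_per_branch = 1000L, seed = 1L) {
  branches <- branch_clusters(species_tree)
  taxa <- species_tree$tip.label
  gene_D <- lapply(gene_trees, topo_distances)
  set.seed(as.integer(seed))
  res <- lapply(branches, function(br) {
    cl <- c(br$below, br$above)
    sizes <- lengths(cl)
    n_q <- prod(sizes)
    if (n_q <= max_quartets_per_branch) {
      grid <- expand.grid(a = cl[[1L]], b = cl[[2L]], c = cl[[3L]],
                          d = cl[[4L]], stringsAsFactors = FALSE)
    } else {
      grid <- data.frame(
        a = sample(cl[[1L]], max_quartets_per_branch, replace = TRUE),
        b = sample(cl[[2L]], max_quartets_per_branch, replace = TRUE),
        c = sample(cl[[3L]], max_quartets_per_branch, replace = TRUE),
        d = sample(cl[[4L]], max_quartets_per_branch, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    tallies <- c(0, 0, 0)
    contributing <- 0L
    for (D in gene_D) {
      ia <- match(grid$a, rownames(D))
      ib <- match(grid$b, rownames(D))
      ic <- match(grid$c, rownames(D))
      id <- match(grid$d, rownames(D))
      okq <- !(is.na(ia) | is.na(ib) | is.na(ic) | is.na(id))
      if (!any(okq)) next
      s1 <- D[cbind(ia[okq], ib[okq])] + D[cbind(ic[okq], id[okq])]
      s2 <- D[cbind(ia[okq], ic[okq])] + D[cbind(ib[okq], id[okq])]
      s3 <- D[cbind(ia[okq], id[okq])] + D[cbind(ib[okq], ic[okq])]
      t1 <- sum(s1 < s2 & s1 < s3)
      t2 <- sum(s2 < s1 & s2 < s3)
      t3 <- sum(s3 < s1 & s3 < s2)
      if (t1 + t2 + t3 > 0L) contributing <- contributing + 1L
      tallies <- tallies + c(t1, t2, t3)
    }
    tot <- sum(tallies)
    q <- if (tot > 0) tallies / tot else rep(NA_real_, 3L)
    data.frame(branch = split_label(br$side, taxa), n_quartets = nrow(grid),
               n_decisive = contributing, q1 = q[1L], q2 = q[2L], q3 = q[3L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Combined per-branch concordance table
#'
#' Joins [gene_concordance_factor()] and [quartet_support()] on the branch
#' label.
#'
#' @inheritParams quartet_support
#' @return data.frame with gCF and quartet-support columns per branch.
#' @export
branch_concordance <- function(species_tree, gene_trees,
                               max_quartets_per_branch = 1000L, seed = 1L) {
  g <- gene_concordance_factor(species_tree, gene_trees)
  q <- quartet_support(species_tree, gene_trees, max_quartets_per_branch, seed)
  names(g)[names(g) == "n_decisive"] <- "gcf_n_decisive"
  names(q)[names(q) == "n_decisive"] <- "quartet_n_trees"
  merge(g, q, by = "branch", sort = TRUE)
}
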