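## Synthetic inputs with known ground truth: birth-process species trees,
## multispecies-coalescent gene trees, codon sequences evolved along them,
## and injected contamination artifacts with a manifest, so that the filter,
## concordance and subsampling machinery can be tested without any real data.

## deterministic per-unit substream seeds derived from one user seed
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(counter) * 16807) %%
               2147483647)
}

## stable small-integer hash of a string (for id-keyed substreams)
id_hash <- function(id) {
  h <- 0
  for (v in utf8ToInt(id)) h <- (h * 131 + v) %% 2147483647
  as.integer(h)
}

#' Simulate a species tree
#'
#' A pure-birth (Yule) tree with `n_species` tips labelled `sp1..spN`;
#' branch lengths are interpreted downstream as coalescent units. Internal
#' branches can optionally be rescaled so the shortest one reaches
#' `min_internal`, which controls the expected level of incomplete lineage
#' sorting.
#'
#' @param n_species number of species (at least 3).
#' @param birth_rate speciation rate of the birth process.
#' @param seed integer seed.
#' @param depth optional root age: the tree is rescaled so the root sits at
#'   this many coalescent units before the present.
#' @param min_internal optional lower bound for internal branch lengths; the
#'   whole tree is scaled up if the shortest internal branch falls below it
#'   (applied after `depth`).
#' @return rooted binary `phylo` with positive branch lengths.
#' @export
simulate_species_tree <- function(n_species, birth_rate = 1, seed = 1L,
                                  depth = NULL, min_internal = NULL) {
  stopifnot(n_species >= 3L)
  set.seed(as.integer(seed))
  tr <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  tr$tip.label <- paste0("sp", seq_len(n_species))
  if (!is.null(depth)) {
    cur <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * (depth / cur)
  }
  if (!is.null(min_internal)) {
    n <- n_species
    internal <- tr$edge[, 2L] > n
    shortest <- min(tr$edge.length[internal])
    if (shortest < min_internal)
      tr$edge.length <- tr$edge.length * (min_internal / shortest)
  }
  tr
}

## coalesce lineages within one species-tree branch between times t0 < t1;
## each lineage is list(str = newick fragment, h = node height)
coalesce_interval <- function(lineages, t0, t1) {
  t <- t0
  while (length(lineages) >= 2L) {
    j <- length(lineages)
    w <- rexp(1L, rate = j * (j - 1) / 2)
    if (t + w > t1) break
    t <- t + w
    pick <- sample.int(j, 2L)
    a <- lineages[[pick[1L]]]
    b <- lineages[[pick[2L]]]
    merged <- list(
      str = sprintf("(%s:%.10g,%s:%.10g)", a$str, t - a$h, b$str, t - b$h),
      h = t)
    lineages <- c(lineages[-pick], list(merged))
  }
  lineages
}

#' Simulate gene trees under the multispecies coalescent
#'
#' Within each species-tree branch, gene lineages coalesce with exponential
#' waiting times at rate `choose(j, 2)` per coalescent unit; lineages
#' surviving at the root coalesce freely. Branch lengths of the species tree
#' are coalescent units. With `samples_per_species > 1`, tips are labelled
#' `<species>_<k>`.
#'
#' @param species_tree rooted `phylo` with branch lengths.
#' @param n_genes number of gene trees to draw.
#' @param samples_per_species haploid lineages sampled per species.
#' @param seed integer seed; gene `g` uses an independent derived substream.
#' @return list of `phylo` gene trees with branch lengths in coalescent
#'   units.
#' @export
simulate_gene_trees <- function(species_tree, n_genes,
                                samples_per_species = 1L, seed = 1L) {
  tr <- species_tree
  n <- length(tr$tip.label)
  depth <- ape::node.depth.edgelength(tr)
  age <- max(depth) - depth # time before present per node
  children <- split(tr$edge[, 2L], tr$edge[, 1L])
  root <- n + 1L
  ## children before parents (ages can tie when branches have length zero)
  node_order <- unique(ape::reorder.phylo(tr, "postorder")$edge[, 1L])
  lapply(seq_len(n_genes), function(g) {
    set.seed(derive_seed(seed, g))
    pools <- vector("list", n + tr$Nnode)
    for (i in seq_len(n)) {
      labs <- if (samples_per_species == 1L) tr$tip.label[i]
              else paste0(tr$tip.label[i], "_", seq_len(samples_per_species))
      pools[[i]] <- lapply(labs, function(l) list(str = l, h = age[i]))
    }
    for (v in node_order) {
      incoming <- list()
      for (ch in children[[as.character(v)]]) {
        incoming <- c(incoming,
                      coalesce_interval(pools[[ch]], age[ch], age[v]))
      }
      pools[[v]] <- incoming
    }
    lin <- coalesce_interval(pools[[root]], age[root], Inf)
    stopifnot(length(lin) == 1L)
    ape::read.tree(text = paste0(lin[[1L]]$str, ";"))
  })
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

## apply n point substitutions to a char vector, rejecting any mutation
## that creates an in-frame stop codon
mutate_chars <- function(chars, n_mut) {
  bases <- c("A", "C", "G", "T")
  len <- length(chars)
  for (i in seq_len(n_mut)) {
    for (attempt in 1:100) {
      pos <- sample.int(len, 1L)
      new <- sample(setdiff(bases, chars[pos]), 1L)
      cs <- 3L * ((pos - 1L) %/% 3L) + 1L
      codon <- chars[cs:(cs + 2L)]
      codon[pos - cs + 1L] <- new
      if (!(paste(codon, collapse = "") %in% STOP_CODONS)) {
        chars[pos] <- new
        break
      }
    }
  }
  chars
}

#' Simulate codon sequences along a gene tree
#'
#' The root sequence is `n_codons` random sense codons; along each branch a
#' Poisson number of point substitutions (mean
#' `3 * n_codons * subst_rate * branch length`) is applied under an
#' equal-rates model, resampling any mutation that would create an in-frame
#' stop codon. Every output passes [check_and_translate()] with status `ok`.
#'
#' @param gene_tree `phylo` with branch lengths (coalescent units).
#' @param n_codons sequence length in codons.
#' @param subst_rate expected substitutions per site per coalescent unit.
#' @param seed integer seed.
#' @param cluster_id id for the returned cluster.
#' @return an [ortho_cluster()] with one CDS per gene-tree tip.
#' @export
simulate_codon_sequences <- function(gene_tree, n_codons, subst_rate,
                                     seed = 1L, cluster_id = "cluster1") {
  set.seed(as.integer(seed))
  sense <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
  root_seq <- unlist(strsplit(sample(sense, n_codons, replace = TRUE), ""))
  tr <- ape::reorder.phylo(gene_tree, "cladewise") # parents before children
  n <- length(tr$tip.label)
  seqs <- vector("list", n + tr$Nnode)
  seqs[[n + 1L]] <- root_seq
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]
    ch <- tr$edge[e, 2L]
    n_mut <- rpois(1L, 3 * n_codons * subst_rate * tr$edge.length[e])
    seqs[[ch]] <- mutate_chars(seqs[[p]], n_mut)
  }
  out <- vapply(seq_len(n), function(i) paste(seqs[[i]], collapse = ""), "")
  names(out) <- tr$tip.label
  ortho_cluster(cluster_id, out)
}

#' Contamination specification
#'
#' Per-record probabilities of injecting at most one artifact, and the
#' artifact effect sizes. The defaults emulate moderate contamination:
#' paralogs carry 1.5 expected extra substitutions per site (about 65%
#' uncorrected distance, far beyond the default distance threshold), masking
#' hits 60% of sites and truncation removes half the codons.
#'
#' @param p_paralog,p_frameshift,p_truncate,p_mask per-record probabilities
#'   (their sum must not exceed 1).
#' @param paralog_extra_divergence expected extra substitutions per site.
#' @param mask_frac fraction of sites set to `N`.
#' @param truncate_frac fraction of trailing codons removed.
#' @return list of class `contamination_spec`.
#' @export
contamination_spec <- function(p_paralog = 0.05, p_frameshift = 0.05,
                               p_truncate = 0.05, p_mask = 0.05,
                               paralog_extra_divergence = 1.5,
                               mask_frac = 0.6, truncate_frac = 0.5) {
  p <- c(p_paralog, p_frameshift, p_truncate, p_mask)
  stopifnot(all(p >= 0), all(p <= 1),
            paralog_extra_divergence > 0, mask_frac > 0, truncate_frac > 0)
  if (sum(p) > 1) stop("artifact probabilities sum to more than 1")
  structure(list(p_paralog = p_paralog, p_frameshift = p_frameshift,
                 p_truncate = p_truncate, p_mask = p_mask,
                 paralog_extra_divergence = paralog_extra_divergence,
                 mask_frac = mask_frac, truncate_frac = truncate_frac),
            class = "contamination_spec")
}

#' Inject artifacts into clean clusters
#'
#' Per record, at most one artifact is drawn according to the specification:
#' `paralog` adds `paralog_extra_divergence` expected substitutions per site
#' (stop codons rejected), emulating a diverged duplicate assigned to the
#' wrong cluster; `frameshift` deletes one base at a random position;
#' `truncate` removes the trailing fraction of codons; `mask` sets one
#' contiguous interior block of sites to `N` (emulating a coverage gap),
#' keeping the first and last codon intact so terminal-N trimming does not
#' disturb the reading frame. A manifest records every action.
#'
#' @param clusters named list of [ortho_cluster()] objects.
#' @param spec a [contamination_spec()].
#' @param seed integer seed; each cluster uses a derived substream.
#' @return list with `clusters` (corrupted) and `manifest` (data.frame with
#'   `cluster_id`, `sample_id`, `artifact`, `param`).
#' @export
inject_artifacts <- function(clusters, spec = contamination_spec(),
                             seed = 1L) {
  stopifnot(inherits(spec, "contamination_spec"))
  probs <- c(none = 1 - spec$p_paralog - spec$p_frameshift -
               spec$p_truncate - spec$p_mask,
             paralog = spec$p_paralog, frameshift = spec$p_frameshift,
             truncate = spec$p_truncate, mask = spec$p_mask)
  manifest <- list()
  out <- clusters
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    ## substream keyed by the cluster id: corruption does not depend on the
    ## iteration order or on which other clusters are present
    set.seed(derive_seed(seed, id_hash(cl$cluster_id)))
    for (id in names(cl$seq)) {
      art <- sample(names(probs), 1L, prob = probs)
      if (art == "none") {
        manifest[[length(manifest) + 1L]] <-
          data.frame(cluster_id = cl$cluster_id, sample_id = id,
                     artifact = "none", param = NA_real_,
                     stringsAsFactors = FALSE)
        next
      }
      s <- cl$seq[[id]]
      chars <- strsplit(s, "", fixed = TRUE)[[1L]]
      len <- length(chars)
      param <- NA_real_
      if (art == "paralog") {
        n_mut <- rpois(1L, len * spec$paralog_extra_divergence)
        chars <- mutate_chars(chars, n_mut)
        param <- spec$paralog_extra_divergence
      } else if (art == "frameshift") {
        pos <- sample.int(len, 1L)
        chars <- chars[-pos]
        param <- pos
      } else if (art == "truncate") {
        n_rm <- max(1L, round(spec$truncate_frac * len / 3)) * 3L
        chars <- chars[seq_len(len - n_rm)]
        param <- spec$truncate_frac
      } else if (art == "mask") {
        ## one contiguous interior block, as left by a coverage gap; the
        ## first and last codon stay intact so terminal-N trimming does not
        ## disturb the reading frame
        n_mask <- min(floor(spec$mask_frac * len), len - 6L)
        start <- sample.int(len - 6L - n_mask + 1L, 1L) + 3L
        chars[seq.int(start, start + n_mask - 1L)] <- "N"
        param <- spec$mask_frac
      }
      out[[ci]]$seq[[id]] <- paste(chars, collapse = "")
      manifest[[length(manifest) + 1L]] <-
        data.frame(cluster_id = cl$cluster_id, sample_id = id,
                   artifact = art, param = param, stringsAsFactors = FALSE)
    }
  }
  list(clusters = out, manifest = do.call(rbind, manifest))
}

#' Simulate a complete synthetic dataset
#'
#' Species tree, coalescent gene trees, codon sequences per gene, and
#' injected artifacts — the full set of inputs the filtering and
#' concordance machinery consumes, with ground truth.
#'
#' @param n_species number of species.
#' @param n_genes number of ortholog clusters (one gene tree each).
#' @param n_codons codons per sequence.
#' @param subst_rate substitutions per site per coalescent unit.
#' @param contamination a [contamination_spec()], or `NULL` for clean data.
#' @param seed integer seed.
#' @param birth_rate,depth,min_internal passed to
#'   [simulate_species_tree()]; the default depth of 3 coalescent units with
#'   rate 0.01 yields within-cluster divergences of a few percent, typical
#'   of congeneric ortholog sets.
#' @return list with `species_tree`, `gene_trees`, `clusters`, `manifest`
#'   (`NULL` when clean).
#' @export
simulate_dataset <- function(n_species = 8L, n_genes = 20L, n_codons = 120L,
                             subst_rate = 0.01,
                             contamination = contamination_spec(),
                             seed = 1L, birth_rate = 1, depth = 3,
                             min_internal = NULL) {
  sp <- simulate_species_tree(n_species, birth_rate, derive_seed(seed, 1e6),
                              depth = depth, min_internal = min_internal)
  gts <- simulate_gene_trees(sp, n_genes, seed = derive_seed(seed, 2e6))
  clusters <- lapply(seq_len(n_genes), function(g)
    simulate_codon_sequences(gts[[g]], n_codons, subst_rate,
                             seed = derive_seed(seed, 3e6 + g),
                             cluster_id = sprintf("cluster%03d", g)))
  names(clusters) <- vapply(clusters, `[[`, "", "cluster_id")
  manifest <- NULL
  if (!is.null(contamination)) {
    inj <- inject_artifacts(clusters, contamination,
                            seed = derive_seed(seed, 4e6))
    clusters <- inj$clusters
    manifest <- inj$manifest
  }
  list(species_tree = sp, gene_trees = gts, clusters = clusters,
       manifest = manifest)
}
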