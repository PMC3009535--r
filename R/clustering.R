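# The grouping process: similarity-based hierarchical agglomerative
# clustering on the pair scores, automatic stopping when no remaining
# cluster pair has positive linkage similarity, collapse of insignificant
# caterpillar structure, and module extraction (one module per surviving
# internal node).
#
# Trees are nested lists: a leaf is a character scalar (the node id); an
# internal node is list(height = <merge score>, children = list(...)).

is_leaf <- function(x) is.character(x)

tree_leaves <- function(tree) {
  if (is_leaf(tree)) return(tree)
  unlist(lapply(tree$children, tree_leaves), use.names = FALSE)
}

#' Agglomerate scored node pairs into a dendrogram forest
#'
#' Standard agglomerative clustering on a similarity, seeded with the pair
#' scores: the two clusters with the highest linkage similarity are merged
#' repeatedly, where single linkage takes the maximum and complete linkage
#' the minimum score over cross-pairs (pairs absent from the score table
#' have similarity 0). Merging stops as soon as the best available linkage
#' similarity is 0 — exactly when every remaining candidate pair shares no
#' more neighbours than expected by chance, so the procedure needs no
#' threshold parameter. Nodes never merged remain singleton trees.
#'
#' Ties in merge order are broken deterministically towards the cluster pair
#' whose smallest member ids sort first.
#'
#' @param scores data frame from [score_all_pairs()] (columns `a`, `b`, `r`).
#' @param linkage `"complete"` (default) or `"single"`.
#' @param nodes optional character vector of all network nodes; nodes absent
#'   from `scores` are carried as singleton leaves.
#' @return An object of class `nemo_dendrogram`: a list with `trees` (forest,
#'   ordered by smallest member id) and `linkage`.
#' @export
agglomerate <- function(scores, linkage = c("complete", "single"), nodes = NULL) {
  linkage <- match.arg(linkage)
  scored <- radix_sort(unique(c(scores$a, scores$b)))
  extra <- radix_sort(setdiff(unique(trimws(as.character(nodes %||% character()))), scored))
  m <- length(scored)

  trees <- as.list(scored)
  if (m >= 2L && nrow(scores) > 0L) {
    M <- matrix(0, m, m)
    ia <- match(scores$a, scored)
    ib <- match(scores$b, scored)
    M[cbind(ia, ib)] <- scores$r
    M[cbind(ib, ia)] <- scores$r
    diag(M) <- -Inf
    minrank <- seq_len(m) # rank of each cluster's smallest member id
    active <- rep(TRUE, m)

    repeat {
      best <- max(M)
      if (best <= 0) break
      cand <- which(M == best, arr.ind = TRUE)
      cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
      k1 <- pmin(minrank[cand[, 1L]], minrank[cand[, 2L]])
      k2 <- pmax(minrank[cand[, 1L]], minrank[cand[, 2L]])
      sel <- order(k1, k2)[1L]
      i <- cand[sel, 1L]
      j <- cand[sel, 2L]
      if (minrank[j] < minrank[i]) { tmp <- i; i <- j; j <- tmp }

      trees[[i]] <- list(height = best, children = list(trees[[i]], trees[[j]]))
      minrank[i] <- min(minrank[i], minrank[j])
      merged <- if (linkage == "single") pmax(M[i, ], M[j, ]) else pmin(M[i, ], M[j, ])
      M[i, ] <- merged
      M[, i] <- merged
      M[i, i] <- -Inf
      M[j, ] <- -Inf
      M[, j] <- -Inf
      active[j] <- FALSE
    }
    trees <- trees[active]
  }

  trees <- c(trees, as.list(extra))
  first <- vapply(trees, function(t) tree_leaves(t)[1L], character(1L))
  trees <- trees[radix_order(first)]
  structure(list(trees = trees, linkage = linkage), class = "nemo_dendrogram")
}

#' @export
print.nemo_dendrogram <- function(x, ...) {
  sizes <- vapply(x$trees, function(t) length(tree_leaves(t)), integer(1L))
  cat(sprintf("nemo_dendrogram (%s linkage): %d tree(s), %d leaves (%d singletons)\n",
              x$linkage, length(x$trees), sum(sizes), sum(sizes == 1L)))
  invisible(x)
}

collapse_node <- function(tree) {
  if (is_leaf(tree)) return(tree)
  tree$children <- lapply(tree$children, collapse_node)
  # splice out an internal child paired with a single leaf sibling, to fixpoint
  repeat {
    if (length(tree$children) == 2L) {
      leafy <- vapply(tree$children, is_leaf, logical(1L))
      if (sum(leafy) == 1L) {
        inner <- tree$children[[which(!leafy)]]
        tree$children <- c(tree$children[which(leafy)], inner$children)
        next
      }
    }
    break
  }
  tree
}

#' Collapse insignificant dendrogram structure
#'
#' Wherever an internal node has exactly two children, one a leaf and one an
#' internal node, the internal child is spliced out (its children are
#' promoted), applied bottom-up to a fixpoint. This removes caterpillar
#' chains that would otherwise emit a nested module for every single-node
#' accretion; the descendant leaf set of every tree is unchanged.
#'
#' @param dend a `nemo_dendrogram` from [agglomerate()].
#' @return A collapsed `nemo_dendrogram` (internal nodes may be n-ary).
#' @export
collapse_tree <- function(dend) {
  dend$trees <- lapply(dend$trees, collapse_node)
  dend
}

#' Extract putative modules from a dendrogram
#'
#' One module per internal node: its descendant leaf set. Modules smaller
#' than `min_size` are dropped (singleton leaves are never reported).
#' Nested modules are allowed — an internal node's module contains those of
#' its internal descendants.
#'
#' @param dend a (collapsed) `nemo_dendrogram`.
#' @param min_size smallest module size reported (default 2, i.e. every
#'   internal node).
#' @return A [module_set()] with ids `M1`, `M2`, ... ordered by decreasing
#'   size, ties broken lexicographically on the member list.
#' @export
extract_modules <- function(dend, min_size = 2L) {
  mods <- list()
  walk <- function(tree) {
    if (is_leaf(tree)) return(invisible())
    mods[[length(mods) + 1L]] <<- radix_sort(unique(tree_leaves(tree)))
    for (ch in tree$children) walk(ch)
  }
  for (t in dend$trees) walk(t)
  mods <- mods[lengths(mods) >= min_size]
  if (length(mods) == 0L) return(module_set())
  key <- vapply(mods, paste, character(1L), collapse = SEP)
  ord <- radix_order(-lengths(mods), key)
  mods <- mods[ord]
  module_set(stats::setNames(mods, sprintf("M%d", seq_along(mods))))
}

#' Identify network modules (full pipeline)
#'
#' Runs the whole parameterless pipeline: score all node pairs by the
#' shared-neighbour log-odds ([score_all_pairs()]), agglomerate on the scores
#' with automatic stopping ([agglomerate()]), collapse insignificant tree
#' structure ([collapse_tree()]) and report one putative module per
#' surviving internal node ([extract_modules()]). Deterministic for a fixed
#' input network. Because the score only needs shared neighbours, not direct
#' adjacency, both clique-like and dense-bipartite groups (e.g. a ligand
#' family touching common receptors while forming an independent set) are
#' recovered.
#'
#' @param net an [interaction_network()].
#' @param linkage `"complete"` (default) or `"single"`.
#' @param direction_policy passed to [score_all_pairs()].
#' @param min_size smallest module size reported.
#' @return A [module_set()] of putative modules.
#' @examples
#' # two sides of a complete bipartite graph are recovered as modules
#' left <- c("a", "b"); right <- c("w", "x", "y", "z")
#' edges <- expand.grid(left, right, stringsAsFactors = FALSE)
#' net <- interaction_network(undirected = as.matrix(edges))
#' run_nemo(net)
#' @export
run_nemo <- function(net, linkage = c("complete", "single"),
                     direction_policy = c("symmetrize", "split"),
                     min_size = 2L) {
  linkage <- match.arg(linkage)
  direction_policy <- match.arg(direction_policy)
  scores <- score_all_pairs(net, direction_policy)
  dend <- agglomerate(scores, linkage, nodes = net$nodes)
  extract_modules(collapse_tree(dend), min_size = min_size)
}

newick_node <- function(tree) {
  if (is_leaf(tree)) return(gsub("[,():;]", "_", tree))
  paste0("(", paste(vapply(tree$children, newick_node, character(1L)), collapse = ","), ")")
}

#' Export a dendrogram forest in Newick format
#'
#' One Newick string per tree (topology only), for inspection in standard
#' tree viewers.
#'
#' @param dend a `nemo_dendrogram`.
#' @return Character vector of Newick strings, each terminated by `;`.
#' @export
as_newick <- function(dend) {
  vapply(dend$trees, function(t) paste0(newick_node(t), ";"), character(1L))
}
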