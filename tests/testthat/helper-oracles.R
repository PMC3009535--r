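# Shared fixtures and independent oracles. The oracles deliberately avoid
# the code paths they check: pair scoring by explicit per-pair set
# intersection instead of sparse matrix products, AUC by Mann-Whitney pair
# counting instead of the trapezoid sweep.

pair_ids <- function(n) sprintf("n%03d", seq_len(n))

# Erdos-Renyi undirected network on n labelled nodes (isolated nodes kept).
make_gnp <- function(n, p) {
  ids <- pair_ids(n)
  pr <- which(upper.tri(diag(n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pr)) < p
  interaction_network(undirected = cbind(ids[pr[keep, 1L]], ids[pr[keep, 2L]]),
                      nodes = ids)
}

make_clique <- function(ids) {
  pr <- t(utils::combn(ids, 2L))
  interaction_network(undirected = pr)
}

make_bipartite <- function(left, right) {
  ed <- as.matrix(expand.grid(left, right, stringsAsFactors = FALSE))
  interaction_network(undirected = ed)
}

square_net <- function() {
  interaction_network(undirected = rbind(c("a", "c"), c("a", "d"),
                                         c("b", "c"), c("b", "d")))
}

# Brute-force scorer over every unordered node pair.
bf_scores <- function(net) {
  nodes <- net$nodes
  if (length(nodes) < 2L || net$e == 0L) {
    return(data.frame(a = character(), b = character(), s_ab = integer(),
                      lambda0 = numeric(), r = numeric()))
  }
  deg <- vapply(nodes, function(v) degree(net, v), integer(1L))
  rows <- list()
  for (i in seq_len(length(nodes) - 1L)) {
    for (j in seq.int(i + 1L, length(nodes))) {
      a <- nodes[[i]]
      b <- nodes[[j]]
      s <- length(setdiff(intersect(neighbours(net, a), neighbours(net, b)), c(a, b)))
      rest <- sum(vapply(setdiff(nodes, c(a, b)),
                         function(c) deg[[c]] * (deg[[c]] - 1), numeric(1L)))
      l0 <- deg[[a]] * deg[[b]] * rest / (2 * net$e)^2
      r <- if (s > 0 && s > l0) s * log(s / l0) - s + l0 else 0
      if (r > 0) {
        rows[[length(rows) + 1L]] <-
          data.frame(a = a, b = b, s_ab = s, lambda0 = l0, r = r,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(a = character(), b = character(), s_ab = integer(),
                      lambda0 = numeric(), r = numeric()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$r, out$a, out$b, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Mann-Whitney AUC: fraction of (real, random) pairs ranked correctly,
# ties counting one half.
mw_auc <- function(score, label) {
  re <- score[label == "real"]
  ra <- score[label == "random"]
  cmp <- outer(re, ra, function(x, y) (x > y) + 0.5 * (x == y))
  mean(cmp)
}

# Member sets created by every merge of an hclust tree, as sorted key strings.
hclust_merge_sets <- function(hc, labels) {
  sets <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    grab <- function(x) if (x < 0) labels[-x] else sets[[x]]
    sets[[k]] <- sort(c(grab(hc$merge[k, 1L]), grab(hc$merge[k, 2L])), method = "radix")
  }
  vapply(sets, paste, character(1L), collapse = "|")
}

module_keys <- function(ms) {
  sort(vapply(ms, paste, character(1L), collapse = "|"), method = "radix")
}
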