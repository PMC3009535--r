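# Shared-neighbour log-odds scoring.
#
# For a node pair (a, b) with observed shared-neighbour count s_ab, the score
# is the Poisson log-likelihood ratio between the maximum-likelihood
# alternative (rate = s_ab) and a degree-preserving random-network null with
# rate lambda0_ab:
#
#   r_ab = s_ab * ln(s_ab / lambda0_ab) - s_ab + lambda0_ab
#
# zeroed whenever s_ab <= lambda0_ab (no more sharing than expected by
# chance). lambda0_ab is the configuration-model expectation
#
#   lambda0_ab = n_a * n_b * sum_{c != a,b} n_c (n_c - 1) / (2e)^2
#
# with n_v the combined-mode degree and e the stored edge count.

#' Shared-neighbour count of a node pair
#'
#' A shared neighbour of `a` and `b` is a third node `c` adjacent to both.
#' Under the `symmetrize` policy every edge is treated as bidirectional and
#' the count is the size of the intersection of the combined neighbour sets.
#' Under the `split` policy shared out-neighbours and shared in-neighbours
#' are counted separately and summed, with undirected edges contributing to
#' both; this keeps, e.g., co-regulation (shared targets) and co-regulated
#' (shared regulators) evidence distinct in directed networks. `a` and `b`
#' themselves are never counted.
#'
#' @param net an [interaction_network()].
#' @param a,b distinct node ids present in `net`.
#' @param direction_policy `"symmetrize"` (default) or `"split"`.
#' @return Non-negative integer count.
#' @export
shared_neighbour_count <- function(net, a, b,
                                   direction_policy = c("symmetrize", "split")) {
  direction_policy <- match.arg(direction_policy)
  check_node(net, a)
  check_node(net, b)
  if (a == b) stop("a and b must be distinct nodes", call. = FALSE)
  if (direction_policy == "symmetrize") {
    shared <- intersect(net$adj$combined[[a]], net$adj$combined[[b]])
    length(setdiff(shared, c(a, b)))
  } else {
    out_shared <- setdiff(intersect(net$adj$out[[a]], net$adj$out[[b]]), c(a, b))
    in_shared <- setdiff(intersect(net$adj[["in"]][[a]], net$adj[["in"]][[b]]), c(a, b))
    length(out_shared) + length(in_shared)
  }
}

#' Null expectation of the shared-neighbour count
#'
#' Expected number of shared neighbours of `a` and `b` in a random network
#' that preserves all node degrees (configuration model):
#' `n_a * n_b * sum_{c != a,b} n_c (n_c - 1) / (2e)^2`, where degrees are
#' combined-mode neighbour-set sizes and `e` is the total stored edge count.
#'
#' @inheritParams shared_neighbour_count
#' @return Non-negative real `lambda0_ab`; symmetric in `a` and `b`.
#' @export
null_expectation <- function(net, a, b) {
  check_node(net, a)
  check_node(net, b)
  if (a == b) stop("a and b must be distinct nodes", call. = FALSE)
  if (net$e == 0L) stop("empty network: e = 0", call. = FALSE)
  deg <- lengths(net$adj$combined)
  two_e <- 2 * net$e
  tot <- sum(deg * (deg - 1))
  rest <- tot - deg[[a]] * (deg[[a]] - 1) - deg[[b]] * (deg[[b]] - 1)
  deg[[a]] * deg[[b]] * rest / two_e^2
}

#' Poisson log-odds pair score
#'
#' Log-likelihood ratio of `Poisson(s)` (the maximum-likelihood alternative)
#' to `Poisson(lambda0)` evaluated at the observed count `s`:
#' `s * ln(s / lambda0) - s + lambda0`, in natural log units. The score is
#' set to 0 whenever `s <= lambda0` or `s == 0` (pairs with no excess
#' sharing carry no significance), so it is always non-negative. Vectorised
#' over `s` and `lambda0`.
#'
#' The scoring pipeline never produces `lambda0 = 0` together with `s > 0`
#' (a shared neighbour forces positive degrees on `a`, `b` and the shared
#' node); as a guard, such a pair is scored with `lambda0` floored at
#' `lambda_floor` when that is positive, and yields `Inf` otherwise.
#'
#' @param s non-negative integer count(s) of shared neighbours.
#' @param lambda0 non-negative null expectation(s).
#' @param lambda_floor optional positive floor substituted for a zero
#'   `lambda0` when `s > 0` (the pipeline passes `1 / (2e)^2`).
#' @return Non-negative numeric score(s).
#' @export
pair_score <- function(s, lambda0, lambda_floor = 0) {
  if (any(s < 0) || any(lambda0 < 0)) {
    stop("s and lambda0 must be non-negative", call. = FALSE)
  }
  n <- max(length(s), length(lambda0))
  s <- rep_len(as.numeric(s), n)
  l0 <- rep_len(as.numeric(lambda0), n)
  if (lambda_floor > 0) l0[l0 == 0 & s > 0] <- lambda_floor
  r <- numeric(n)
  pos <- s > l0 & s > 0
  r[pos] <- s[pos] * log(s[pos] / l0[pos]) - s[pos] + l0[pos]
  r
}

# Sparse 0/1 combined adjacency matrix over net$nodes (symmetric, no loops).
combined_adjacency <- function(net) {
  n <- length(net$nodes)
  pairs <- rbind(net$und, net$dir)
  if (nrow(pairs) > 0L) {
    i <- match(pairs[, 1L], net$nodes)
    j <- match(pairs[, 2L], net$nodes)
    key <- paste(pmin(i, j), pmax(i, j))
    keep <- !duplicated(key)
    i <- i[keep]
    j <- j[keep]
    Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1, dims = c(n, n))
  } else {
    Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(), dims = c(n, n))
  }
}

# Directed-aware adjacency: row v has 1 in column c when c is reachable from v
# in the given mode ("out"/"in"), undirected edges counting in both.
mode_adjacency <- function(net, mode) {
  n <- length(net$nodes)
  nb <- net$adj[[mode]]
  deg <- lengths(nb)
  i <- rep(seq_len(n), deg)
  j <- match(unlist(nb, use.names = FALSE), net$nodes)
  Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
}

#' Score all node pairs with excess shared neighbours
#'
#' Computes `s_ab`, `lambda0_ab` and the log-odds score `r_ab` for every
#' unordered node pair sharing at least one neighbour, and keeps the pairs
#' with positive score (`s_ab > lambda0_ab`). Candidate pairs are enumerated
#' through sparse adjacency products, never the full pair grid, so runtime
#' scales with the number of length-two paths.
#'
#' @param net an [interaction_network()].
#' @param direction_policy `"symmetrize"` (default) treats all edges as
#'   bidirectional; `"split"` sums shared out-neighbour and shared
#'   in-neighbour counts (see [shared_neighbour_count()]). The null
#'   expectation uses combined-mode degrees under both policies.
#' @return A data frame with columns `a`, `b` (with `a < b`), `s_ab`,
#'   `lambda0`, `r`, sorted by decreasing `r` with ties broken
#'   lexicographically on (`a`, `b`).
#' @export
score_all_pairs <- function(net, direction_policy = c("symmetrize", "split")) {
  direction_policy <- match.arg(direction_policy)
  empty <- data.frame(a = character(), b = character(), s_ab = integer(),
                      lambda0 = numeric(), r = numeric(), stringsAsFactors = FALSE)
  if (length(net$nodes) == 0L || net$e == 0L) return(empty)

  if (direction_policy == "symmetrize") {
    A <- combined_adjacency(net)
    S <- Matrix::crossprod(A)
  } else {
    S <- Matrix::tcrossprod(mode_adjacency(net, "out")) +
      Matrix::tcrossprod(mode_adjacency(net, "in"))
  }
  S <- methods::as(Matrix::triu(S, k = 1L), "TsparseMatrix")
  keep <- S@x > 0
  if (!any(keep)) return(empty)
  ii <- S@i[keep] + 1L
  jj <- S@j[keep] + 1L
  s <- S@x[keep]

  deg <- lengths(net$adj$combined)
  two_e <- 2 * net$e
  tot <- sum(deg * (deg - 1))
  l0 <- deg[ii] * deg[jj] *
    (tot - deg[ii] * (deg[ii] - 1) - deg[jj] * (deg[jj] - 1)) / two_e^2
  r <- pair_score(s, l0, lambda_floor = 1 / two_e^2)

  pos <- r > 0
  out <- data.frame(
    a = net$nodes[ii[pos]], b = net$nodes[jj[pos]],
    s_ab = as.integer(s[pos]), lambda0 = l0[pos], r = r[pos],
    stringsAsFactors = FALSE
  )
  out <- out[radix_order(-out$r, out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a pair-score table as TSV
#'
#' @param scores data frame from [score_all_pairs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pair_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
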