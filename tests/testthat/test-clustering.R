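# Agglomeration, dendrogram collapse and module extraction.

leaf_sets <- function(dend) lapply(dend$trees, nemor:::tree_leaves)

test_that("agglomerate builds the hand-traced forests", {
  sq <- score_all_pairs(square_net())
  dend <- agglomerate(sq, "complete")
  expect_equal(length(dend$trees), 2L)
  expect_setequal(vapply(leaf_sets(dend), paste, "", collapse = ","), c("a,b", "c,d"))

  one <- data.frame(a = "x", b = "y", s_ab = 2L, lambda0 = 0.1, r = 1.5)
  d1 <- agglomerate(one, "single")
  expect_equal(length(d1$trees), 1L)
  expect_equal(d1$trees[[1L]]$height, 1.5)
  expect_setequal(leaf_sets(d1)[[1L]], c("x", "y"))

  # all ten 5-clique scores are equal: both linkages end in one tree
  cl <- score_all_pairs(make_clique(letters[1:5]))
  for (lk in c("single", "complete")) {
    d <- agglomerate(cl, lk)
    expect_equal(length(d$trees), 1L)
    expect_setequal(leaf_sets(d)[[1L]], letters[1:5])
  }

  # empty score list: forest of singletons, no error
  d0 <- agglomerate(sq[0, ], "complete", nodes = c("p", "q"))
  expect_equal(length(d0$trees), 2L)
})

test_that("unscored nodes survive as singleton leaves outside every module", {
  sq <- score_all_pairs(square_net())
  dend <- agglomerate(sq, "complete", nodes = c("a", "b", "c", "d", "iso"))
  sizes <- lengths(leaf_sets(dend))
  expect_equal(sort(sizes), c(1L, 2L, 2L))
  mods <- extract_modules(collapse_tree(dend))
  expect_false("iso" %in% unlist(mods))
})

test_that("collapse splices single-leaf/internal pairs to a fixpoint", {
  leaf <- function(x) x
  node <- function(h, ...) list(height = h, children = list(...))
  wrap <- function(tr) structure(list(trees = list(tr), linkage = "complete"),
                                 class = "nemo_dendrogram")

  caterpillar <- node(1, node(2, node(3, leaf("a"), leaf("b")), leaf("c")), leaf("d"))
  got <- collapse_tree(wrap(caterpillar))$trees[[1L]]
  expect_equal(length(got$children), 4L)
  expect_true(all(vapply(got$children, is.character, TRUE)))
  expect_setequal(unlist(got$children), c("a", "b", "c", "d"))

  balanced <- node(1, node(2, leaf("a"), leaf("b")), node(2, leaf("c"), leaf("d")))
  expect_identical(collapse_tree(wrap(balanced))$trees[[1L]], balanced)

  pairtree <- node(1, leaf("a"), leaf("b"))
  expect_identical(collapse_tree(wrap(pairtree))$trees[[1L]], pairtree)
})

test_that("collapse preserves every tree's descendant leaf set", {
  set.seed(19)
  for (trial in 1:10) {
    net <- make_gnp(sample(10:30, 1L), runif(1, 0.15, 0.5))
    dend <- agglomerate(score_all_pairs(net), sample(c("single", "complete"), 1L),
                        nodes = net$nodes)
    key <- function(d) sort(vapply(leaf_sets(d),
                                   function(l) paste(sort(l), collapse = "|"), ""))
    before <- key(dend)
    after <- key(collapse_tree(dend))
    expect_identical(after, before)
  }
})

test_that("merge heights never increase from leaves toward the root", {
  # scores are processed in descending order, so merges nearer the leaves
  # happen at higher similarity: every internal child's height >= its parent's
  heights_ok <- function(tree) {
    if (is.character(tree)) return(TRUE)
    all(vapply(tree$children, function(ch) {
      is.character(ch) || (ch$height >= tree$height - 1e-12 && heights_ok(ch))
    }, TRUE))
  }
  set.seed(23)
  for (trial in 1:10) {
    net <- make_gnp(sample(10:30, 1L), runif(1, 0.15, 0.5))
    for (lk in c("single", "complete")) {
      dend <- agglomerate(score_all_pairs(net), lk)
      expect_true(all(vapply(dend$trees, heights_ok, TRUE)))
    }
  }
})

test_that("extract_modules returns one module per internal node", {
  node <- function(h, ...) list(height = h, children = list(...))
  balanced <- node(1, node(2, "a", "b"), node(2, "c", "d"))
  dend <- structure(list(trees = list(balanced), linkage = "complete"),
                    class = "nemo_dendrogram")
  mods <- extract_modules(dend)
  expect_equal(names(mods), c("M1", "M2", "M3"))
  expect_equal(mods$M1, c("a", "b", "c", "d")) # largest first
  expect_setequal(vapply(mods[2:3], paste, "", collapse = ","), c("a,b", "c,d"))

  pair <- structure(list(trees = list(node(1, "x", "y")), linkage = "complete"),
                    class = "nemo_dendrogram")
  expect_equal(length(extract_modules(pair)), 1L)

  singles <- structure(list(trees = list("a", "b"), linkage = "complete"),
                       class = "nemo_dendrogram")
  expect_equal(length(extract_modules(singles)), 0L)
})

test_that("agglomeration reproduces hclust merges when every pair is scored", {
  set.seed(71)
  for (lk in c("single", "complete")) {
    ids <- letters[1:8]
    pr <- t(utils::combn(ids, 2L))
    r <- sample(seq(0.1, 0.9, length.out = nrow(pr))) # distinct positive scores
    scores <- data.frame(a = pr[, 1L], b = pr[, 2L], s_ab = 1L, lambda0 = 0.01, r = r)
    dend <- agglomerate(scores, lk)
    expect_equal(length(dend$trees), 1L)

    C <- max(r) + 1
    D <- matrix(0, 8, 8, dimnames = list(ids, ids))
    D[cbind(pr[, 1L], pr[, 2L])] <- C - r
    D <- D + t(D)
    hc <- stats::hclust(stats::as.dist(D), method = if (lk == "single") "single" else "complete")

    ours <- extract_modules(dend) # uncollapsed: every merge is an internal node
    expect_setequal(module_keys(ours), hclust_merge_sets(hc, ids))

    collect_heights <- function(tr) {
      if (is.character(tr)) return(numeric())
      c(tr$height, unlist(lapply(tr$children, collect_heights)))
    }
    expect_equal(sort(collect_heights(dend$trees[[1L]])), sort(C - hc$height),
                 tolerance = 1e-12)
  }
})

test_that("the full pipeline recovers bipartite sides, cliques and determinism", {
  # both sides of K_{2,4}: the right side is an independent set, still a module
  k24 <- make_bipartite(c("a", "b"), c("w", "x", "y", "z"))
  mods <- run_nemo(k24)
  expect_setequal(module_keys(mods), c("a|b", "w|x|y|z"))

  # two 5-cliques joined by a bridge: exactly the two cliques, never merged
  cl <- rbind(t(utils::combn(letters[1:5], 2L)), t(utils::combn(letters[6:10], 2L)),
              c("a", "f"))
  twocl <- interaction_network(undirected = cl)
  for (lk in c("complete", "single")) {
    m2 <- run_nemo(twocl, linkage = lk)
    expect_setequal(module_keys(m2), c("a|b|c|d|e", "f|g|h|i|j"))
  }

  # empty network
  expect_equal(length(run_nemo(interaction_network(nodes = c("a", "b")))), 0L)

  # byte-identical output across reruns
  set.seed(3)
  net <- make_gnp(40, 0.12)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_module_set(run_nemo(net), f1)
  write_module_set(run_nemo(net), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("modules from one network are laminar and stay inside the node set", {
  set.seed(41)
  for (trial in 1:8) {
    net <- make_gnp(sample(15:35, 1L), runif(1, 0.1, 0.35))
    mods <- run_nemo(net, linkage = sample(c("single", "complete"), 1L))
    expect_true(all(unlist(mods) %in% net$nodes))
    if (length(mods) >= 2L) {
      for (i in seq_len(length(mods) - 1L)) {
        for (j in seq.int(i + 1L, length(mods))) {
          ov <- length(intersect(mods[[i]], mods[[j]]))
          expect_true(ov == 0L || ov == min(length(mods[[i]]), length(mods[[j]])))
        }
      }
    }
  }
})

test_that("newick export writes one rooted tree per forest component", {
  sq <- score_all_pairs(square_net())
  nwk <- as_newick(collapse_tree(agglomerate(sq, "complete")))
  expect_equal(nwk, c("(a,b);", "(c,d);"))
})
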