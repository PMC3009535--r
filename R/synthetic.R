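# Planted-module synthetic benchmark: networks of 5-10 embedded clusters of
# 5-10 nodes each, cluster-specific within density drawn from a uniform
# range and one between-cluster density per network.

# Run code under a seeded RNG, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Generate one planted-module synthetic network
#'
#' Draws a network of `k` disjoint planted clusters covering all nodes:
#' `k` uniform on 5..10, each cluster size uniform on 5..10, each cluster's
#' within density uniform on `within_range`, and a single between-cluster
#' density for the whole network uniform on `between_range`. Every
#' within-cluster node pair receives an undirected edge with its cluster's
#' density and every cross-cluster pair with the between density.
#'
#' The default density ranges leave planted clusters no denser than the
#' background; `within_range = c(0.5, 0.8)` is the documented dense-module
#' variant under which planted clusters are recoverable (see the package
#' vignette for the rationale).
#'
#' @param seed integer seed; the same seed reproduces the instance exactly.
#' @param n_clusters optional fixed cluster count (default: drawn 5..10).
#' @param size_range inclusive integer range of cluster sizes.
#' @param within_range within-cluster edge-density range.
#' @param between_range between-cluster edge-density range.
#' @return An object of class `synthetic_instance`: list with `network`
#'   (an [interaction_network()]), `planted` (a [module_set()], disjoint and
#'   covering all nodes) and `params`.
#' @export
generate_instance <- function(seed,
                              n_clusters = NULL,
                              size_range = c(5L, 10L),
                              within_range = c(0.05, 0.08),
                              between_range = c(0.05, 0.10)) {
  with_seed(seed, {
    k <- n_clusters %||% sample(size_range[1L]:size_range[2L], 1L)
    sizes <- sample(size_range[1L]:size_range[2L], k, replace = TRUE)
    p_within <- stats::runif(k, within_range[1L], within_range[2L])
    p_between <- stats::runif(1L, between_range[1L], between_range[2L])

    n <- sum(sizes)
    membership <- rep(seq_len(k), sizes)
    ids <- sprintf("v%03d", seq_len(n))

    pair <- which(upper.tri(diag(n)), arr.ind = TRUE)
    same <- membership[pair[, 1L]] == membership[pair[, 2L]]
    p <- ifelse(same, p_within[membership[pair[, 1L]]], p_between)
    keep <- stats::runif(nrow(pair)) < p
    edges <- cbind(ids[pair[keep, 1L]], ids[pair[keep, 2L]])

    planted <- module_set(stats::setNames(
      split(ids, membership), sprintf("planted%d", seq_len(k))
    ))
    structure(
      list(
        network = interaction_network(undirected = edges, nodes = ids),
        planted = planted,
        params = list(k = k, sizes = sizes, p_within = p_within,
                      p_between = p_between, seed = as.integer(seed),
                      within_range = within_range, between_range = between_range)
      ),
      class = "synthetic_instance"
    )
  })
}

#' @export
print.synthetic_instance <- function(x, ...) {
  cat(sprintf(
    "synthetic_instance (seed %d): %d clusters, %d nodes, %d edges, p_between = %.3f\n",
    x$params$seed, x$params$k, length(x$network$nodes), x$network$e, x$params$p_between
  ))
  invisible(x)
}

#' Run the planted-module recovery benchmark
#'
#' Generates `n_networks` synthetic instances, runs the module-identification
#' pipeline on each under the requested linkages, and records per planted
#' module the best-Jaccard reconstruction fidelity and per network the
#' putative-module count.
#'
#' @param n_networks number of networks.
#' @param linkages character vector of linkages to run.
#' @param seed master seed; per-instance seeds are derived from it, so the
#'   whole benchmark is reproducible from `(n_networks, seed)`.
#' @param ... further arguments passed to [generate_instance()] (e.g. the
#'   `within_range` density override).
#' @return An object of class `nemo_benchmark`: list with `fidelity` (data
#'   frame: network, linkage, module, size, fidelity), `counts` (data frame:
#'   network, linkage, n_modules) and `seed`.
#' @export
run_benchmark <- function(n_networks, linkages = c("complete", "single"),
                          seed = 1L, ...) {
  stopifnot(n_networks >= 1L)
  linkages <- match.arg(linkages, c("complete", "single"), several.ok = TRUE)
  inst_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_networks))

  fid_rows <- vector("list", n_networks * length(linkages))
  cnt_rows <- vector("list", n_networks * length(linkages))
  row <- 0L
  for (i in seq_len(n_networks)) {
    inst <- generate_instance(inst_seeds[[i]], ...)
    scores <- score_all_pairs(inst$network)
    for (lk in linkages) {
      dend <- agglomerate(scores, lk, nodes = inst$network$nodes)
      mods <- extract_modules(collapse_tree(dend))
      fid <- vapply(inst$planted, reconstruction_fidelity, numeric(1L),
                    putative = mods)
      row <- row + 1L
      fid_rows[[row]] <- data.frame(
        network = i, linkage = lk, module = names(inst$planted),
        size = lengths(inst$planted), fidelity = unname(fid),
        row.names = NULL, stringsAsFactors = FALSE
      )
      cnt_rows[[row]] <- data.frame(network = i, linkage = lk,
                                    n_modules = length(mods),
                                    stringsAsFactors = FALSE)
    }
  }
  structure(
    list(
      fidelity = do.call(rbind, fid_rows),
      counts = do.call(rbind, cnt_rows),
      seed = as.integer(seed)
    ),
    class = "nemo_benchmark"
  )
}

#' Summarize a benchmark run
#'
#' Per linkage: mean putative-module count per network, percentage of
#' planted modules recovered exactly (reconstruction error 0) and percentage
#' recovered with fidelity at least 0.8 (error at most 0.2).
#'
#' @param object a `nemo_benchmark` from [run_benchmark()].
#' @param ... unused.
#' @return Data frame with columns `linkage`, `mean_modules`, `pct_perfect`,
#'   `pct_fid80`.
#' @export
summary.nemo_benchmark <- function(object, ...) {
  lks <- unique(object$counts$linkage)
  do.call(rbind, lapply(lks, function(lk) {
    fid <- object$fidelity$fidelity[object$fidelity$linkage == lk]
    cnt <- object$counts$n_modules[object$counts$linkage == lk]
    data.frame(
      linkage = lk,
      mean_modules = mean(cnt),
      pct_perfect = 100 * mean(fid >= 1 - 1e-9),
      pct_fid80 = 100 * mean(fid >= 0.8 - 1e-9),
      stringsAsFactors = FALSE
    )
  }))
}

#' @export
print.nemo_benchmark <- function(x, ...) {
  n <- max(x$counts$network)
  cat(sprintf("nemo_benchmark: %d network(s), %d planted-module evaluations\n",
              n, nrow(x$fidelity)))
  print(summary(x))
  invisible(x)
}
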