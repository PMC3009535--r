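# Network container: opaque string node ids, undirected and directed edges
# coexisting, with cached neighbour sets. All string ordering uses radix
# sorting so results are locale-independent.

SEP <- "\x1f" # unit separator; cannot occur in whitespace-stripped ids read from TSV/SIF

radix_sort <- function(x) sort(x, method = "radix")
radix_order <- function(...) order(..., method = "radix")

normalize_edge_matrix <- function(x) {
  if (is.null(x)) return(matrix(character(), 0L, 2L))
  if (is.data.frame(x)) x <- as.matrix(x)
  if (length(x) == 0L) return(matrix(character(), 0L, 2L))
  if (is.null(dim(x))) x <- matrix(x, ncol = 2L, byrow = TRUE)
  if (ncol(x) != 2L) stop("edge table must have exactly two columns")
  storage.mode(x) <- "character"
  x[] <- trimws(x)
  x
}

#' Construct an interaction network
#'
#' Builds the network container used throughout the package: a set of node
#' identifiers (opaque, case-sensitive strings) together with undirected and
#' directed edges, which may coexist in one network (e.g. protein-protein
#' plus protein-DNA interactions). Self-loops are dropped and duplicate edges
#' are stored once (an undirected pair once regardless of input order; a
#' directed pair once per orientation). Reciprocal directed edges are kept as
#' two directed edges. Neighbour sets are cached per node.
#'
#' @param undirected two-column character matrix or data frame of undirected
#'   edges (one row per edge), or `NULL`.
#' @param directed two-column character matrix or data frame of directed
#'   edges (source, target), or `NULL`.
#' @param nodes optional character vector of node ids to include even when
#'   isolated (no incident edges).
#' @return An object of class `interaction_network` with elements `nodes`
#'   (sorted character vector), `und` and `dir` (edge matrices), `e` (total
#'   stored edge count) and cached neighbour lists.
#' @examples
#' net <- interaction_network(undirected = rbind(c("a", "b"), c("b", "c")))
#' net$e
#' neighbours(net, "b")
#' @export
interaction_network <- function(undirected = NULL, directed = NULL, nodes = NULL) {
  und <- normalize_edge_matrix(undirected)
  dir <- normalize_edge_matrix(directed)

  n_loops <- sum(und[, 1L] == und[, 2L]) + sum(dir[, 1L] == dir[, 2L])
  und <- und[und[, 1L] != und[, 2L], , drop = FALSE]
  dir <- dir[dir[, 1L] != dir[, 2L], , drop = FALSE]

  # canonical order for undirected pairs, then dedup both tables
  if (nrow(und) > 0L) {
    swap <- und[, 1L] > und[, 2L]
    und[swap, ] <- und[swap, 2:1, drop = FALSE]
  }
  key_u <- paste(und[, 1L], und[, 2L], sep = SEP)
  key_d <- paste(dir[, 1L], dir[, 2L], sep = SEP)
  n_dup <- sum(duplicated(key_u)) + sum(duplicated(key_d))
  und <- und[!duplicated(key_u), , drop = FALSE]
  dir <- dir[!duplicated(key_d), , drop = FALSE]

  all_nodes <- radix_sort(unique(c(
    trimws(as.character(nodes %||% character())),
    und[, 1L], und[, 2L], dir[, 1L], dir[, 2L]
  )))
  all_nodes <- all_nodes[nzchar(all_nodes)]

  adj <- build_adjacency(all_nodes, und, dir)

  structure(
    list(
      nodes = all_nodes,
      und = und,
      dir = dir,
      e = nrow(und) + nrow(dir),
      adj = adj,
      dropped = c(self_loops = n_loops, duplicates = n_dup)
    ),
    class = "interaction_network"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

build_adjacency <- function(nodes, und, dir) {
  empty <- stats::setNames(rep(list(character()), length(nodes)), nodes)
  grow <- function(base, from, to) {
    if (length(from) == 0L) return(base)
    add <- split(to, factor(from, levels = nodes))
    got <- lengths(add) > 0L
    base[got] <- Map(function(old, new) radix_sort(unique(c(old, new))),
                     base[got], add[got])
    base
  }
  und_n <- grow(grow(empty, und[, 1L], und[, 2L]), und[, 2L], und[, 1L])
  out_n <- grow(und_n, dir[, 1L], dir[, 2L])
  in_n <- grow(und_n, dir[, 2L], dir[, 1L])
  comb <- Map(function(a, b) radix_sort(unique(c(a, b))), out_n, in_n)
  list(out = out_n, "in" = in_n, combined = comb)
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf(
    "interaction_network: %d nodes, %d undirected + %d directed edges (e = %d)\n",
    length(x$nodes), nrow(x$und), nrow(x$dir), x$e
  ))
  invisible(x)
}

check_node <- function(net, v) {
  if (length(v) != 1L || !v %in% net$nodes) {
    stop(sprintf("unknown node: '%s'", paste(v, collapse = ",")), call. = FALSE)
  }
}

#' Neighbour set of a node
#'
#' `combined` mode treats every edge as bidirectional; `out` follows
#' undirected edges plus directed edges leaving `v`; `in` follows undirected
#' edges plus directed edges entering `v`.
#'
#' @param net an [interaction_network()].
#' @param v a node id present in `net`.
#' @param mode one of `"combined"`, `"out"`, `"in"`.
#' @return Character vector of neighbouring node ids (sorted).
#' @export
neighbours <- function(net, v, mode = c("combined", "out", "in")) {
  mode <- match.arg(mode)
  check_node(net, v)
  net$adj[[mode]][[v]]
}

#' Node degree
#'
#' The number of distinct neighbours of `v` under the given mode (the
#' `n_a`, `n_b` of the pair-scoring null model).
#'
#' @inheritParams neighbours
#' @return Integer degree.
#' @export
degree <- function(net, v, mode = c("combined", "out", "in")) {
  length(neighbours(net, v, mode))
}

strip_comment_lines <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  lines[!startsWith(trimws(lines), "#")]
}

#' Read an interaction network from an edge-list file
#'
#' Supports two plain-text formats:
#' \describe{
#'   \item{TSV}{two or three tab-separated columns: source, target and an
#'     optional directed flag (`1` = directed source to target, `0` or absent
#'     = undirected).}
#'   \item{SIF}{Cytoscape simple interaction format: source, interaction
#'     type, one or more targets per line (tab- or space-delimited; a line
#'     with a single token declares an isolated node). All SIF edges are
#'     read as undirected.}
#' }
#' Lines starting with `#` are comments. Self-loops and duplicate edges are
#' dropped with a message reporting the counts.
#'
#' @param path path to the file.
#' @param format `"auto"` (SIF when the file extension is `.sif`, TSV
#'   otherwise), `"tsv"` or `"sif"`.
#' @return An [interaction_network()].
#' @export
read_edge_list <- function(path, format = c("auto", "tsv", "sif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  kept <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(kept) == 0L) stop(sprintf("no edges in '%s'", path), call. = FALSE)

  und <- list()
  dir <- list()
  lone <- character()
  for (ln in kept) {
    raw <- lines[[ln]]
    fields <- if (format == "tsv" || grepl("\t", raw)) {
      strsplit(raw, "\t", fixed = TRUE)[[1L]]
    } else {
      strsplit(trimws(raw), "[[:space:]]+")[[1L]]
    }
    fields <- trimws(fields)
    if (format == "tsv") {
      if (length(fields) < 2L) {
        stop(sprintf("%s: line %d has fewer than 2 columns", path, ln), call. = FALSE)
      }
      is_dir <- length(fields) >= 3L && fields[[3L]] == "1"
      rec <- c(fields[[1L]], fields[[2L]])
      if (is_dir) dir[[length(dir) + 1L]] <- rec else und[[length(und) + 1L]] <- rec
    } else {
      if (length(fields) == 1L) {
        lone <- c(lone, fields)
        next
      }
      if (length(fields) == 2L) {
        stop(sprintf("%s: line %d names an interaction type but no target", path, ln),
             call. = FALSE)
      }
      for (tgt in fields[-(1:2)]) {
        und[[length(und) + 1L]] <- c(fields[[1L]], tgt)
      }
    }
  }
  net <- interaction_network(
    undirected = if (length(und)) do.call(rbind, und),
    directed = if (length(dir)) do.call(rbind, dir),
    nodes = lone
  )
  if (sum(net$dropped) > 0L) {
    message(sprintf("read_edge_list: dropped %d self-loop(s) and %d duplicate edge(s)",
                    net$dropped[["self_loops"]], net$dropped[["duplicates"]]))
  }
  if (net$e == 0L && length(lone) == 0L) stop(sprintf("no edges in '%s'", path), call. = FALSE)
  net
}

#' Write a network as a three-column TSV edge list
#'
#' Columns are source, target and the directed flag (0 undirected,
#' 1 directed). Reading the file back with [read_edge_list()] reproduces the
#' network.
#'
#' @param net an [interaction_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  rows <- character()
  if (nrow(net$und) > 0L) {
    rows <- c(rows, paste(net$und[, 1L], net$und[, 2L], "0", sep = "\t"))
  }
  if (nrow(net$dir) > 0L) {
    rows <- c(rows, paste(net$dir[, 1L], net$dir[, 2L], "1", sep = "\t"))
  }
  writeLines(rows, path)
  invisible(path)
}

#' Construct a module set
#'
#' A module set is an ordered collection of named node sets: putative modules
#' emitted by the clustering step, planted modules of a synthetic benchmark,
#' or a gold-standard complex catalogue.
#'
#' @param modules named list of character vectors (members). Names must be
#'   unique and every member set non-empty; members are deduplicated and
#'   sorted.
#' @return An object of class `module_set`.
#' @export
module_set <- function(modules = list()) {
  if (length(modules) == 0L) {
    return(structure(stats::setNames(list(), character()), class = "module_set"))
  }
  if (is.null(names(modules)) || anyNA(names(modules)) || any(!nzchar(names(modules)))) {
    stop("every module needs a non-empty id", call. = FALSE)
  }
  if (anyDuplicated(names(modules))) stop("module ids must be unique", call. = FALSE)
  modules <- lapply(modules, function(m) radix_sort(unique(as.character(m))))
  if (any(lengths(modules) == 0L)) stop("modules must be non-empty", call. = FALSE)
  structure(modules, class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d module(s)\n", length(x)))
  show <- utils::head(seq_along(x), 10L)
  for (i in show) {
    cat(sprintf("  %s (%d): %s\n", names(x)[i], length(x[[i]]),
                paste(utils::head(x[[i]], 8L), collapse = ", ")))
  }
  if (length(x) > 10L) cat(sprintf("  ... and %d more\n", length(x) - 10L))
  invisible(x)
}

#' Read a module set from a TSV file
#'
#' Accepts `id TAB members`, `id TAB size TAB members` (members
#' comma-separated), or one whitespace/comma-separated node set per line
#' (ids are then generated as `M1`, `M2`, ...).
#'
#' @param path path to the file.
#' @return A [module_set()].
#' @export
read_module_set <- function(path) {
  lines <- strip_comment_lines(readLines(path, encoding = "UTF-8", warn = FALSE))
  ids <- character()
  members <- list()
  for (i in seq_along(lines)) {
    fields <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]])
    if (length(fields) == 1L) {
      ids <- c(ids, sprintf("M%d", i))
      members[[length(members) + 1L]] <- strsplit(trimws(fields), "[,[:space:]]+")[[1L]]
    } else {
      memb_field <- if (length(fields) >= 3L && grepl("^[0-9]+$", fields[[2L]])) {
        fields[[3L]]
      } else {
        fields[[2L]]
      }
      ids <- c(ids, fields[[1L]])
      members[[length(members) + 1L]] <- strsplit(memb_field, ",", fixed = TRUE)[[1L]]
    }
  }
  module_set(stats::setNames(members, ids))
}

#' Write a module set as TSV (id, size, comma-separated members)
#'
#' @param ms a [module_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_module_set <- function(ms, path) {
  rows <- vapply(seq_along(ms), function(i) {
    paste(names(ms)[i], length(ms[[i]]), paste(ms[[i]], collapse = ","), sep = "\t")
  }, character(1L))
  writeLines(rows, path)
  invisible(path)
}
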