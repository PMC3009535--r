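# Module-recovery evaluation: Jaccard reconstruction fidelity, fidelity
# threshold curves, size-matched randomized complexes, and ROC / precision-
# recall scoring of putative module sets.

#' Jaccard coefficient between two node sets
#'
#' @param A,B character vectors of node ids (treated as sets); at least one
#'   must be non-empty.
#' @return `|A ∩ B| / |A ∪ B|` in `[0, 1]`.
#' @export
jaccard <- function(A, B) {
  A <- unique(A)
  B <- unique(B)
  u <- length(union(A, B))
  if (u == 0L) stop("jaccard undefined for two empty sets", call. = FALSE)
  length(intersect(A, B)) / u
}

#' Reconstruction fidelity of a gold module
#'
#' The Jaccard coefficient between the gold-standard node set and the most
#' similar putative module; 0 if the putative set is empty. Reconstruction
#' error is one minus reconstruction fidelity. Note fidelity is monotone
#' non-decreasing in the putative set: methods returning more modules can
#' only gain, which is why the ROC protocol against randomized complexes
#' exists.
#'
#' @param gold non-empty character vector of node ids.
#' @param putative a [module_set()] (or list of character vectors).
#' @return Fidelity in `[0, 1]`.
#' @export
reconstruction_fidelity <- function(gold, putative) {
  if (length(gold) == 0L) stop("gold module must be non-empty", call. = FALSE)
  if (length(putative) == 0L) return(0)
  max(vapply(putative, function(m) jaccard(gold, m), numeric(1L)))
}

#' Fidelity-threshold curve
#'
#' Fraction of gold modules recovered with reconstruction error at most each
#' threshold (the benchmark figure's cumulative curve): at threshold 0 the
#' fraction recovered exactly, at threshold 1 all modules.
#'
#' @param fidelities numeric vector of per-module fidelities in `[0, 1]`.
#' @param thresholds error thresholds (default a 0.01 grid).
#' @return Data frame with columns `error_threshold` and `fraction`.
#' @export
fidelity_curve <- function(fidelities, thresholds = seq(0, 1, by = 0.01)) {
  err <- 1 - fidelities
  frac <- vapply(thresholds, function(t) mean(err <= t + 1e-9), numeric(1L))
  data.frame(error_threshold = thresholds, fraction = frac)
}

#' Generate size-matched randomized complexes
#'
#' Null modules for the ROC protocol: node labels of the universe are
#' permuted by one global random permutation and every gold module is mapped
#' through it, preserving the module size distribution exactly. With
#' `method = "resample"` each null module is instead drawn independently
#' without replacement from the universe.
#'
#' @param gold a [module_set()] of gold-standard modules.
#' @param universe character vector of node ids covering all gold members.
#' @param seed integer seed.
#' @param method `"permute"` (default, one global label permutation) or
#'   `"resample"`.
#' @return A [module_set()] with ids `<gold id>_rand`.
#' @export
permute_complexes <- function(gold, universe, seed, method = c("permute", "resample")) {
  method <- match.arg(method)
  universe <- radix_sort(unique(universe))
  members <- unique(unlist(gold, use.names = FALSE))
  if (!all(members %in% universe)) {
    stop("universe must contain every gold-module member", call. = FALSE)
  }
  if (any(lengths(gold) > length(universe))) {
    stop("a gold module is larger than the universe", call. = FALSE)
  }
  out <- with_seed(seed, {
    if (method == "permute") {
      perm <- stats::setNames(sample(universe), universe)
      lapply(gold, function(m) unname(perm[m]))
    } else {
      lapply(gold, function(m) sample(universe, length(m)))
    }
  })
  module_set(stats::setNames(out, paste0(names(gold), "_rand")))
}

#' ROC, AUC and precision-recall from fidelity-ranked test modules
#'
#' Implements the randomized-complex protocol: real and randomized test
#' modules are ranked by a score (reconstruction fidelity against one
#' putative module set) and swept from high to low score. Tied scores are
#' grouped — all items at one score value enter together — so ties between
#' real and random modules are treated neither optimistically nor
#' pessimistically. AUC is computed by the trapezoidal rule, which under tie
#' grouping equals the Mann-Whitney statistic with the usual 1/2 tie
#' correction.
#'
#' @param score numeric vector of scores (higher = more complex-like).
#' @param label vector labelling each score `"real"` or `"random"` (logical
#'   `TRUE` for real also accepted). Both classes must be present.
#' @return An object of class `evaluation_report`: list with `roc`
#'   (`threshold`, `fpr`, `tpr`), `pr` (`threshold`, `recall`, `precision`)
#'   and `auc`.
#' @export
roc_and_auc <- function(score, label) {
  if (is.logical(label)) label <- ifelse(label, "real", "random")
  label <- as.character(label)
  if (!all(label %in% c("real", "random"))) {
    stop("labels must be 'real' or 'random'", call. = FALSE)
  }
  if (length(score) != length(label)) stop("score/label length mismatch", call. = FALSE)
  n_real <- sum(label == "real")
  n_rand <- sum(label == "random")
  if (n_real == 0L || n_rand == 0L) {
    stop("need at least one real and one random module", call. = FALSE)
  }

  ord <- order(-score)
  score <- score[ord]
  label <- label[ord]
  grp_last <- which(!duplicated(score, fromLast = TRUE)) # last index of each tie group
  tp <- cumsum(label == "real")[grp_last]
  fp <- cumsum(label == "random")[grp_last]
  roc <- data.frame(
    threshold = c(Inf, score[grp_last]),
    fpr = c(0, fp / n_rand),
    tpr = c(0, tp / n_real)
  )
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  pr <- data.frame(
    threshold = score[grp_last],
    recall = tp / n_real,
    precision = tp / (tp + fp)
  )
  structure(list(roc = roc, pr = pr, auc = auc), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: AUC = %.4f (%d ROC points)\n", x$auc, nrow(x$roc)))
  invisible(x)
}

#' Evaluate a putative module set against gold-standard modules
#'
#' Convenience wrapper for the full protocol: per-gold-module reconstruction
#' fidelity, the fidelity-threshold curve and, when randomized complexes are
#' requested, the ROC/AUC and precision-recall of real-vs-random
#' discrimination.
#'
#' @param gold a [module_set()] of gold-standard modules.
#' @param putative a [module_set()] of putative modules.
#' @param universe node universe for randomization (default: union of gold
#'   members and putative members).
#' @param n_random number of randomized complex sets is fixed at one per
#'   gold module (size-matched); set `n_random = 0` to skip the ROC.
#' @param seed integer seed for the randomization.
#' @return List with `fidelity` (data frame: module, size, fidelity, error),
#'   `curve`, and optionally `report` (an `evaluation_report`).
#' @export
evaluate_modules <- function(gold, putative, universe = NULL, n_random = 1L, seed = 1L) {
  fid <- vapply(gold, reconstruction_fidelity, numeric(1L), putative = putative)
  fidelity <- data.frame(
    module = names(gold), size = lengths(gold),
    fidelity = unname(fid), error = 1 - unname(fid),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- list(fidelity = fidelity, curve = fidelity_curve(fidelity$fidelity))
  if (n_random > 0L && length(gold) > 0L) {
    universe <- universe %||% radix_sort(unique(c(
      unlist(gold, use.names = FALSE), unlist(putative, use.names = FALSE)
    )))
    rand <- permute_complexes(gold, universe, seed = seed)
    rand_fid <- vapply(rand, reconstruction_fidelity, numeric(1L), putative = putative)
    out$report <- roc_and_auc(
      score = c(fidelity$fidelity, unname(rand_fid)),
      label = rep(c("real", "random"), c(length(fid), length(rand_fid)))
    )
  }
  out
}
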