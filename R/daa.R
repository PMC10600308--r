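# Welch two-sample t statistics for every column of L, class 1 = idx1.
welch_t <- function(L, idx1) {
  L1 <- L[idx1, , drop = FALSE]
  L2 <- L[!idx1, , drop = FALSE]
  n1 <- nrow(L1); n2 <- nrow(L2)
  m1 <- colMeans(L1); m2 <- colMeans(L2)
  v1 <- colSums(sweep(L1, 2L, m1)^2) / (n1 - 1L)
  v2 <- colSums(sweep(L2, 2L, m2)^2) / (n2 - 1L)
  t <- (m1 - m2) / sqrt(v1 / n1 + v2 / n2)
  t[is.nan(t)] <- 0   # both groups constant and equal
  t
}

#' Differential activation analysis
#'
#' Per-atom Welch two-sample t-tests on pathway activity scores with
#' permutation p-values: the geneset-level analog of differential expression
#' analysis. One label shuffle is evaluated on all atoms per iteration, so
#' permutations are shared across atoms. The two-sided p-value uses the
#' add-one estimator `(1 + #permuted |t*| >= |t|) / (n_perm + 1)`, which is
#' never zero. When `n_perm` is at least the number of distinct label
#' assignments, all assignments are enumerated instead and the p-value is
#' the exact permutation p `count / total` (the observed assignment counts
#' itself).
#'
#' @param L Score matrix (samples x atoms) from [pasl_transform()], atom
#'   names as column names.
#' @param labels Two-class label vector aligned with the rows of `L` (or
#'   named by sample id when `L` has rownames). Each class needs >= 2
#'   samples.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Seed for the label shuffles.
#' @param adjust If `TRUE`, append Benjamini-Hochberg adjusted p-values.
#' @return A `pasl_daa` data frame with columns `atom`, `geneset` (NA for
#'   discovery atoms when provenance is available), `t`, `p`, `rank`,
#'   sorted by ascending p (ties: larger |t| first). Attributes: `n_perm`
#'   (effective count), `exhaustive`, `seed`.
#' @export
differential_activation <- function(L, labels, n_perm = 10000, seed = NULL,
                                    adjust = FALSE) {
  L <- as.matrix(L)
  if (!is.null(names(labels)) && !is.null(rownames(L))) {
    if (!all(rownames(L) %in% names(labels))) {
      stop("labels missing for some samples in the score matrix")
    }
    labels <- labels[rownames(L)]
  }
  if (length(labels) != nrow(L)) stop("labels must align with the rows of L")
  f <- factor(labels)
  if (nlevels(f) != 2L) stop("exactly two classes are required")
  if (min(table(f)) < 2L) stop("each class needs at least 2 samples")
  idx1 <- f == levels(f)[1L]
  n <- nrow(L); n1 <- sum(idx1)

  t_obs <- welch_t(L, idx1)
  abs_obs <- abs(t_obs)
  counts <- numeric(ncol(L))

  n_distinct <- choose(n, n1)
  exhaustive <- is.finite(n_distinct) && n_perm >= n_distinct
  if (exhaustive) {
    combs <- utils::combn(n, n1)
    for (b in seq_len(ncol(combs))) {
      idx <- logical(n); idx[combs[, b]] <- TRUE
      counts <- counts + (abs(welch_t(L, idx)) >= abs_obs)
    }
    p <- counts / n_distinct
    n_eff <- n_distinct
  } else {
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        idx <- logical(n); idx[sample.int(n, n1)] <- TRUE
        counts <- counts + (abs(welch_t(L, idx)) >= abs_obs)
      }
    })
    p <- (1 + counts) / (n_perm + 1)
    n_eff <- n_perm
  }

  meta <- attr(L, "atom_meta")
  atom <- colnames(L) %||% paste0("atom", seq_len(ncol(L)))
  geneset <- if (!is.null(meta)) meta$geneset[match(atom, meta$atom)]
             else rep(NA_character_, length(atom))
  res <- data.frame(atom = atom, geneset = geneset, t = t_obs, p = p,
                    stringsAsFactors = FALSE)
  res <- res[order(res$p, -abs(res$t), seq_len(nrow(res))), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  if (adjust) res$p_adj <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  attr(res, "n_perm") <- n_eff
  attr(res, "exhaustive") <- exhaustive
  attr(res, "seed") <- seed
  class(res) <- c("pasl_daa", "data.frame")
  res
}

#' Top-k attribution curve between two significance rankings
#'
#' Ranks the geneset universe by the pooled p-value (each geneset's smallest
#' p across the two methods) and, for each cutoff x, counts how many of the
#' top-x genesets each method identified — i.e. on how many it attains the
#' pooled minimum. A method compared with itself yields the identity curve
#' y = x; when the two methods' findings are disjoint (no ties), the two
#' curves sum to x at every x. The method with the higher statistical power
#' (smaller p-values on the jointly top-ranked genesets) has the higher
#' curve.
#'
#' @param p_method_a,p_method_b Named numeric vectors of p-values. The
#'   universes are aligned on the union of names; a geneset missing from one
#'   method is treated as unranked (p = Inf). Pooled-rank ties are broken by
#'   name; a geneset on which both methods tie counts for both.
#' @return Data frame with columns `x`, `a`, `b` for `x = 1..N`.
#' @export
topk_overlap_curve <- function(p_method_a, p_method_b) {
  if (length(p_method_a) == 0L || length(p_method_b) == 0L) {
    return(data.frame(x = integer(0), a = integer(0), b = integer(0)))
  }
  if (is.null(names(p_method_a)) || is.null(names(p_method_b))) {
    stop("p-value vectors must be named by geneset")
  }
  universe <- sort(union(names(p_method_a), names(p_method_b)))
  pa <- p_method_a[universe]; pa[is.na(pa)] <- Inf
  pb <- p_method_b[universe]; pb[is.na(pb)] <- Inf
  ord <- order(pmin(pa, pb), universe)
  data.frame(
    x = seq_along(universe),
    a = cumsum((pa <= pb)[ord]),
    b = cumsum((pb <= pa)[ord])
  )
}
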