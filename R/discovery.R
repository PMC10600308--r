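#' Discovery-phase configuration
#'
#' @param a2 Number of unconstrained sparse atoms to extract (>= 0).
#' @param nz Number of non-zero coefficients per atom (must not exceed the
#'   number of features). The package default of 2000 targets full microarray
#'   platforms; set `nz` explicitly on smaller matrices.
#' @param max_iter Maximum truncated-power iterations per atom.
#' @param tol Relative-change convergence tolerance.
#' @param subsample_rows Optional number of rows to subsample (seeded) before
#'   extraction, for large cohorts; `NULL` uses all rows.
#' @param seed Seed for the row subsample (unused otherwise).
#' @return A `discovery_config` list.
#' @export
discovery_config <- function(a2, nz = 2000, max_iter = 500L, tol = 1e-6,
                             subsample_rows = NULL, seed = NULL) {
  stopifnot(a2 >= 0, nz >= 1, max_iter >= 1, tol > 0)
  structure(list(a2 = as.integer(a2), nz = as.integer(nz),
                 max_iter = as.integer(max_iter), tol = tol,
                 subsample_rows = subsample_rows, seed = seed),
            class = "discovery_config")
}

# One cardinality-constrained leading sparse component by truncated power
# iteration: alternate the covariance action with hard thresholding to the
# top-nz magnitudes (ties by lower index), renormalize. Initialized at the
# dense leading right singular vector.
sparse_leading_component <- function(R, nz, max_iter, tol) {
  p <- ncol(R)
  v <- svd(R, nu = 0L, nv = 1L)$v[, 1L]
  v <- hard_threshold(v, nz)
  for (it in seq_len(max_iter)) {
    w <- crossprod(R, R %*% v)   # t(R) %*% R %*% v without forming t(R)%*%R
    w <- hard_threshold(as.numeric(w), nz)
    if (sum(w^2) == 0) break
    delta <- sqrt(sum((w - v)^2))
    v <- w
    if (delta < tol) break
  }
  fix_sign(v)
}

hard_threshold <- function(w, nz) {
  p <- length(w)
  if (nz < p) {
    keep <- order(-abs(w), seq_len(p))[seq_len(nz)]
    out <- numeric(p)
    out[keep] <- w[keep]
    w <- out
  }
  nrm <- sqrt(sum(w^2))
  if (nrm > 0) w / nrm else w
}

#' Discovery phase: sparse atoms on the inference residual
#'
#' Extracts `a2` unconstrained atoms from the residual left by the inference
#' phase, each with at most `nz` non-zero coefficients (exactly `nz` whenever
#' the residual's numerical support allows), using cardinality-constrained
#' sparse PCA by truncated power iteration, with the same deflation operator
#' as the inference phase between atoms. With `nz = p` this reduces to
#' ordinary PCA of the residual.
#'
#' @param residual Residual matrix from [inference_phase()] (or any centered
#'   matrix).
#' @param cfg A [discovery_config()].
#' @return List of `pasl_atom`s with `phase = "discovery"` and
#'   `geneset_index = NA`; empty (with a warning) when the residual is
#'   numerically zero. The final deflated residual is attached as the
#'   `"residual"` attribute.
#' @export
discovery_phase <- function(residual, cfg) {
  stopifnot(inherits(cfg, "discovery_config"))
  p <- ncol(residual)
  if (cfg$nz > p) stop("nz (", cfg$nz, ") exceeds the number of features (", p, ")")
  if (cfg$a2 == 0L) return(structure(list(), residual = residual))
  R <- residual
  if (!is.null(cfg$subsample_rows) && cfg$subsample_rows < nrow(R)) {
    rows <- with_seed(cfg$seed, sample.int(nrow(R), cfg$subsample_rows))
    R <- R[rows, , drop = FALSE]
  }
  total0 <- sum(residual^2)
  if (total0 <= RANK_GUARD) {
    warning("residual is numerically zero; no discovery atoms extracted")
    return(structure(list(), residual = residual))
  }
  atoms <- vector("list", cfg$a2)
  k <- 0L
  for (j in seq_len(cfg$a2)) {
    if (sum(R^2) <= RANK_GUARD * max(total0, 1)) {
      warning("residual exhausted after ", k, " discovery atoms")
      break
    }
    v <- sparse_leading_component(R, cfg$nz, cfg$max_iter, cfg$tol)
    if (sum(v^2) == 0) break
    vr <- sum((residual %*% v)^2)
    k <- k + 1L
    atoms[[k]] <- structure(
      list(coeffs = v, geneset_index = NA_integer_, phase = "discovery",
           variance_removed = vr),
      class = "pasl_atom"
    )
    R <- deflate(R, v)
    residual <- deflate(residual, v)
  }
  structure(atoms[seq_len(k)], residual = residual)
}
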