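#' Column-wise standardization
#'
#' Centers and scales each feature to zero mean and unit standard deviation
#' (n - 1 denominator). Constant features are mapped to all-zero columns and
#' their scale recorded as 1, so the parameters stay reusable on future data.
#'
#' @param X Numeric matrix, samples x features, `n >= 2`.
#' @return List with `Xz` (standardized matrix) and `params` (list `mu`,
#'   `sigma`), both of length p.
#' @export
standardize <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("standardization needs at least 2 samples")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, "-")
  sigma <- sqrt(colSums(Xc^2) / (n - 1L))
  zero <- sigma <= 0 | !is.finite(sigma)
  sigma[zero] <- 1
  Xz <- sweep(Xc, 2L, sigma, "/")
  if (any(zero)) Xz[, zero] <- 0
  list(Xz = Xz, params = list(mu = mu, sigma = sigma))
}

#' Apply stored standardization parameters to new data
#'
#' @param X Numeric matrix whose columns align with `params`.
#' @param params The `params` component returned by [standardize()].
#' @return Standardized matrix.
#' @export
apply_standardization <- function(X, params) {
  X <- as.matrix(X)
  if (ncol(X) != length(params$mu)) {
    stop("column count does not match standardization parameters")
  }
  sweep(sweep(X, 2L, params$mu, "-"), 2L, params$sigma, "/")
}

#' Box-Cox power transform
#'
#' `(y^lambda - 1) / lambda` for `lambda != 0`, `log(y)` for `lambda == 0`;
#' the two branches are continuous in lambda at 0. Used here to penalize
#' geneset size when ranking explained variance.
#'
#' @param y Positive numeric vector.
#' @param lam Power parameter lambda.
#' @return Transformed values.
#' @export
box_cox <- function(y, lam) {
  if (any(y <= 0)) stop("box_cox requires y > 0")
  if (lam == 0) log(y) else (y^lam - 1) / lam
}

#' Size-normalize an explained variance
#'
#' Divides a raw explained variance by the Box-Cox transform of the geneset
#' size, so that, for `lam > 0`, larger genesets are penalized when competing
#' for the next dictionary atom. The divisor is floored at 1e-12 (a size-1
#' geneset has Box-Cox transform 0).
#'
#' @param v Non-negative explained variance(s).
#' @param geneset_size Number of member features (>= 1).
#' @param lam Box-Cox parameter; `lam = 1` is an affine function of raw size
#'   (effectively unnormalized ranking), the default used elsewhere in the
#'   package is 1/3.
#' @return Normalized variance `v / max(box_cox(size, lam), 1e-12)`.
#' @export
normalize_variance <- function(v, geneset_size, lam) {
  if (any(geneset_size < 1)) stop("geneset_size must be >= 1")
  v / pmax(box_cox(geneset_size, lam), 1e-12)
}

# Deterministic eigenvector sign: largest-|coefficient| entry positive
# (which.max takes the lowest index on ties).
fix_sign <- function(u) {
  i <- which.max(abs(u))
  if (length(i) && u[i] < 0) -u else u
}

# Relative threshold under which a component is considered numerically null.
RANK_GUARD <- 1e-10

#' PCA spectrum restricted to a geneset
#'
#' Singular value decomposition of the (already centered) standardized data
#' restricted to the columns in `g`; no per-geneset re-centering is done, so
#' the spectrum refers to the same matrix that deflation acts on. Components
#' with squared singular value below `1e-10` of the restricted total are
#' dropped as numerical rank noise.
#'
#' @param Xz Standardized (centered) data matrix.
#' @param g Integer vector of feature column indices (non-empty).
#' @param mode `"full"` (all components) or `"first"` (leading only).
#' @return List with `values` (variances, squared singular values divided by
#'   n - 1, descending), `sqnorm` (squared singular values, the squared-norm
#'   units used in the variance ledger), and `vectors` (|g| x k matrix of
#'   unit-norm eigenvectors, sign-fixed).
#' @export
geneset_pca_spectrum <- function(Xz, g, mode = c("full", "first")) {
  mode <- match.arg(mode)
  if (length(g) == 0L) stop("empty geneset support")
  sub <- Xz[, g, drop = FALSE]
  n <- nrow(sub)
  k <- min(dim(sub))
  nv <- if (mode == "first") 1L else k
  s <- svd(sub, nu = 0L, nv = nv)
  sq <- s$d[seq_len(nv)]^2
  keep <- sq > RANK_GUARD * sum(s$d^2)
  sq <- sq[keep]
  V <- s$v[, keep, drop = FALSE]
  V <- apply(V, 2L, fix_sign)
  if (!is.matrix(V)) V <- matrix(V, ncol = length(sq))
  list(values = sq / (n - 1L), sqnorm = sq, vectors = V)
}

#' Box-Cox-ordered ranking of geneset principal components
#'
#' For every geneset a full restricted PCA is computed on the current data;
#' all (geneset, component) explained variances are size-normalized with
#' [normalize_variance()], pooled, and sorted descending. The top `a1`
#' entries are returned; a geneset can appear once per retained component.
#' Ties are broken by lower geneset index, then lower component index.
#'
#' @param Xz Standardized data matrix (or current residual).
#' @param G A `membership_matrix` aligned with `Xz`'s columns.
#' @param a1 Number of entries to return.
#' @param lam Box-Cox parameter; `NULL` disables size normalization (raw
#'   explained-variance ranking), which makes the greedy selection biased
#'   towards large genesets.
#' @return Data frame with columns `geneset` (row index into `G`),
#'   `component` (component rank within its geneset), and `expected`
#'   (normalized variance, squared-norm units), sorted descending.
#' @export
order_of_genesets <- function(Xz, G, a1, lam) {
  stopifnot(inherits(G, "membership_matrix"), a1 >= 1)
  m <- nrow(G$matrix)
  gi <- integer(0); comp <- integer(0); vtil <- numeric(0)
  for (i in seq_len(m)) {
    g <- which(G$matrix[i, ] != 0)
    if (length(g) == 0L) next
    spec <- geneset_pca_spectrum(Xz, g, mode = "full")
    k <- length(spec$sqnorm)
    if (k == 0L) next
    gi <- c(gi, rep.int(i, k))
    comp <- c(comp, seq_len(k))
    vtil <- c(vtil,
              if (is.null(lam)) spec$sqnorm
              else normalize_variance(spec$sqnorm, length(g), lam))
  }
  ord <- order(-vtil, gi, comp)
  if (length(ord) < a1) {
    warning("only ", length(ord), " components available for an ordering of ",
            a1, " entries")
  } else {
    ord <- ord[seq_len(a1)]
  }
  data.frame(geneset = gi[ord], component = comp[ord], expected = vtil[ord])
}

#' Construct a geneset-constrained atom
#'
#' The leading principal component of the data restricted to the geneset's
#' features, padded with zeros on all other features. The atom's
#' `variance_removed` is the squared norm of the data's projection on it,
#' i.e. the Frobenius mass the subsequent deflation removes.
#'
#' @param Xz Standardized data matrix (or current residual).
#' @param g Integer vector of feature column indices (non-empty).
#' @return A `pasl_atom` (list with `coeffs`, `geneset_index`, `phase`,
#'   `variance_removed`), or `NULL` when the restricted data is numerically
#'   all-zero (fully deflated geneset).
#' @export
construct_atom <- function(Xz, g) {
  if (length(g) == 0L) stop("empty geneset support")
  sub <- Xz[, g, drop = FALSE]
  tot <- sum(sub^2)
  if (tot <= RANK_GUARD * max(sum(Xz^2), 1)) return(NULL)
  s <- svd(sub, nu = 0L, nv = 1L)
  u <- fix_sign(s$v[, 1L])
  d <- numeric(ncol(Xz))
  d[g] <- u
  structure(
    list(coeffs = d, geneset_index = NA_integer_, phase = "inference",
         variance_removed = s$d[1L]^2),
    class = "pasl_atom"
  )
}

#' Remove an atom's contribution from the data
#'
#' Projects every row onto the orthogonal complement of the unit-norm atom:
#' `Xz - (Xz d) d'`, computed without materializing the p x p projector.
#'
#' @param Xz Data matrix.
#' @param d A `pasl_atom` or a unit-norm numeric vector of length p.
#' @return The deflated matrix; `result %*% d` is zero and the Frobenius mass
#'   drops by exactly `||Xz d||^2`.
#' @export
deflate <- function(Xz, d) {
  if (inherits(d, "pasl_atom")) d <- d$coeffs
  nrm <- sqrt(sum(d^2))
  if (abs(nrm - 1) > 1e-8) stop("deflation requires a unit-norm atom")
  proj <- Xz %*% d
  Xz - tcrossprod(proj, d)
}

#' Greedy inference phase
#'
#' Builds geneset-constrained atoms one at a time, following the Box-Cox
#' ordered ranking from [order_of_genesets()]. For each candidate, the actual
#' normalized variance on the current residual is compared with the
#' ranking's expectation: if the ratio is at or below the threshold `t`, the
#' atom is dropped, the ordering recomputed on the residual, and the fresh
#' ordering's first atom accepted unconditionally (its expectation equals
#' its actual value by construction). `t = 0` gives the static strategy (one
#' ordering call); `t = 1` the fully dynamic one (reordering at every atom).
#'
#' @param Xz Standardized data matrix.
#' @param G A `membership_matrix` aligned with `Xz`.
#' @param a1 Number of atoms to construct.
#' @param t Reevaluation threshold in `[0, 1]`.
#' @param lam Box-Cox parameter; `NULL` disables size normalization.
#' @return List with `atoms` (list of `pasl_atom`, with `geneset_index`
#'   filled in), `ledger` (a `pasl_ledger` data frame: one row per accepted
#'   atom with geneset index, component rank, expected and actual normalized
#'   variance, raw `variance_removed`, and whether the atom came from a
#'   reevaluation), and `residual` (the deflated matrix).
#' @export
inference_phase <- function(Xz, G, a1, t = 0.9, lam = 1/3) {
  stopifnot(a1 >= 1, t >= 0, t <= 1)
  res <- Xz
  supports <- lapply(seq_len(nrow(G$matrix)),
                     function(i) which(G$matrix[i, ] != 0))
  ord <- order_of_genesets(res, G, a1, lam)
  n_order_calls <- 1L
  n_reeval <- 0L
  pos <- 1L
  fresh <- TRUE   # entry at pos comes from an ordering computed on `res`
  atoms <- vector("list", a1)
  led <- data.frame(geneset = integer(a1), component = integer(a1),
                    expected = numeric(a1), actual = numeric(a1),
                    variance_removed = numeric(a1), reevaluated = logical(a1))
  n_acc <- 0L

  while (n_acc < a1) {
    if (pos > nrow(ord)) {
      if (t == 0) {
        warning("ordering exhausted before ", a1,
                " atoms under the static strategy; returning ", n_acc)
        break
      }
      ord <- order_of_genesets(res, G, a1 - n_acc, lam)
      n_order_calls <- n_order_calls + 1L
      pos <- 1L
      fresh <- TRUE
      if (nrow(ord) == 0L) {
        warning("no geneset retains positive residual variance; returning ",
                n_acc, " atoms")
        break
      }
      next
    }
    entry <- ord[pos, ]
    g <- supports[[entry$geneset]]
    atom <- construct_atom(res, g)
    if (is.null(atom)) {
      # fully deflated geneset: cannot be accepted, skip its entry
      pos <- pos + 1L
      next
    }
    vhat <- if (is.null(lam)) atom$variance_removed
            else normalize_variance(atom$variance_removed, length(g), lam)
    from_fresh <- fresh && pos == 1L
    if (!from_fresh && vhat / entry$expected <= t) {
      ord <- order_of_genesets(res, G, a1 - n_acc, lam)
      n_order_calls <- n_order_calls + 1L
      n_reeval <- n_reeval + 1L
      pos <- 1L
      fresh <- TRUE
      if (nrow(ord) == 0L) {
        warning("no geneset retains positive residual variance; returning ",
                n_acc, " atoms")
        break
      }
      next
    }
    atom$geneset_index <- entry$geneset
    n_acc <- n_acc + 1L
    atoms[[n_acc]] <- atom
    led[n_acc, ] <- list(entry$geneset, entry$component, entry$expected,
                         vhat, atom$variance_removed, from_fresh && n_acc > 1L)
    res <- deflate(res, atom)
    pos <- pos + 1L
    fresh <- FALSE
  }

  if (n_acc < a1 && n_acc == 0L) {
    warning("no atoms could be constructed")
  }
  atoms <- atoms[seq_len(n_acc)]
  led <- led[seq_len(n_acc), , drop = FALSE]
  rownames(led) <- NULL
  attr(led, "t") <- t
  attr(led, "lam") <- lam %||% NA_real_
  attr(led, "n_reevaluations") <- n_reeval
  attr(led, "n_order_calls") <- n_order_calls
  class(led) <- c("pasl_ledger", "data.frame")
  list(atoms = atoms, ledger = led, residual = res)
}

#' Export a variance ledger as a plain table
#'
#' @param ledger A `pasl_ledger`.
#' @param geneset_names Optional character vector mapping geneset indices to
#'   names.
#' @return Data frame with atom index, geneset, component rank, expected and
#'   actual normalized variance, raw variance removed, and reevaluation flag.
#' @export
ledger_table <- function(ledger, geneset_names = NULL) {
  df <- as.data.frame(ledger)
  df <- cbind(atom = seq_len(nrow(df)), df)
  if (!is.null(geneset_names)) {
    df$geneset <- geneset_names[df$geneset]
  }
  df
}
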