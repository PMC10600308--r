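new_pasl_model <- function(D1, D2, std, atom_meta, hyper, ledger, feature_ids,
                           covered) {
  structure(
    list(D1 = D1, D2 = D2, std = std, atom_meta = atom_meta, hyper = hyper,
         ledger = ledger, feature_ids = feature_ids, covered = covered,
         cache = new.env(parent = emptyenv())),
    class = "pasl_model"
  )
}

#' Fit a pathway-activity dictionary
#'
#' Runs the full learning pipeline: column-wise standardization, the greedy
#' geneset-constrained inference phase ([inference_phase()]), and the sparse
#' discovery phase on the residual ([discovery_phase()]). The default
#' hyper-parameters are `t = 0.9`, `lam = 1/3`, `nz = 2000`.
#'
#' @param X Numeric expression matrix, samples x features, with feature ids
#'   as column names matching `G$feature_ids` (any order; columns of `G` are
#'   realigned).
#' @param G A `membership_matrix` from [build_membership()].
#' @param a1 Number of geneset-constrained (inference) atoms.
#' @param a2 Number of unconstrained sparse (discovery) atoms.
#' @param t Reevaluation threshold of the inference phase, in `[0, 1]`.
#' @param lam Box-Cox size-normalization parameter; `NULL` disables size
#'   normalization entirely (raw variance ranking).
#' @param nz Non-zeros per discovery atom (checked against p only when
#'   `a2 > 0`).
#' @param seed Seed controlling the optional discovery-phase row subsample;
#'   the rest of the pipeline is deterministic.
#' @param discovery_subsample Optional number of rows the discovery phase
#'   sees; `NULL` (default) uses the full residual.
#' @return A `pasl_model` with components `D1`, `D2` (sparse dictionaries;
#'   see [pasl_dictionary()] for the stacked form),
#'   `std` (`mu`, `sigma`), `atom_meta` (per-atom provenance),
#'   `hyper`, `ledger`, `feature_ids`, `covered` (features in any geneset).
#' @export
#' @examples
#' sim <- pasl_simulate(pasl_sim_spec(n = 60, p = 80, n_genesets = 6,
#'                                    n_active = 4, sizes = c(10, 20),
#'                                    seed = 1))
#' fit <- pasl_fit(sim$X, sim$truth$G, a1 = 4, a2 = 0)
#' fit$atom_meta
pasl_fit <- function(X, G, a1, a2 = 0, t = 0.9, lam = 1/3, nz = 2000,
                     seed = NULL, discovery_subsample = NULL) {
  stopifnot(inherits(G, "membership_matrix"))
  X <- as.matrix(X)
  if (a1 + a2 < 1) stop("a1 + a2 must be at least 1")
  feats <- colnames(X)
  if (is.null(feats)) stop("X must carry feature ids as column names")
  if (!setequal(feats, G$feature_ids)) {
    stop("features of X and G do not match")
  }
  Gm <- G
  Gm$matrix <- G$matrix[, match(feats, G$feature_ids), drop = FALSE]
  Gm$feature_ids <- feats
  if (a2 > 0 && nz > ncol(X)) {
    stop("nz (", nz, ") exceeds the number of features (", ncol(X), ")")
  }

  std <- standardize(X)
  Xz <- std$Xz

  if (a1 >= 1) {
    inf <- inference_phase(Xz, Gm, a1, t = t, lam = lam)
  } else {
    led <- data.frame(geneset = integer(0), component = integer(0),
                      expected = numeric(0), actual = numeric(0),
                      variance_removed = numeric(0), reevaluated = logical(0))
    attr(led, "t") <- t; attr(led, "lam") <- lam %||% NA_real_
    attr(led, "n_reevaluations") <- 0L; attr(led, "n_order_calls") <- 0L
    class(led) <- c("pasl_ledger", "data.frame")
    inf <- list(atoms = list(), ledger = led, residual = Xz)
  }

  disc <- discovery_phase(inf$residual,
                          discovery_config(a2 = a2, nz = min(nz, ncol(X)),
                                           subsample_rows = discovery_subsample,
                                           seed = seed))

  gs_names <- Gm$geneset_names
  inf_gs <- vapply(inf$atoms, function(a) gs_names[a$geneset_index], character(1))
  occ <- stats::ave(seq_along(inf_gs), inf_gs, FUN = seq_along)
  inf_names <- if (length(inf_gs)) paste0("GS:", inf_gs, "#", occ) else character(0)
  disc_names <- if (length(disc)) paste0("DISC#", seq_along(disc)) else character(0)

  p <- ncol(X)
  to_sparse <- function(atoms, rn) {
    if (length(atoms) == 0L) {
      return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                  dims = c(0L, p), dimnames = list(NULL, feats)))
    }
    M <- do.call(rbind, lapply(atoms, `[[`, "coeffs"))
    dimnames(M) <- list(rn, feats)
    methods::as(Matrix::Matrix(M, sparse = TRUE), "CsparseMatrix")
  }
  D1 <- to_sparse(inf$atoms, inf_names)
  D2 <- to_sparse(disc, disc_names)

  atom_meta <- data.frame(
    atom = c(inf_names, disc_names),
    phase = c(rep("inference", length(inf$atoms)),
              rep("discovery", length(disc))),
    geneset = c(inf_gs, rep(NA_character_, length(disc))),
    geneset_index = c(vapply(inf$atoms, `[[`, integer(1), "geneset_index"),
                      rep(NA_integer_, length(disc))),
    variance_removed = c(vapply(inf$atoms, `[[`, numeric(1), "variance_removed"),
                         vapply(disc, `[[`, numeric(1), "variance_removed")),
    stringsAsFactors = FALSE
  )

  hyper <- list(a1 = as.integer(a1), a2 = as.integer(a2), t = t, lam = lam,
                nz = as.integer(nz))
  new_pasl_model(
    D1 = D1, D2 = D2, std = std$params, atom_meta = atom_meta, hyper = hyper,
    ledger = inf$ledger, feature_ids = feats,
    covered = as.logical(Matrix::colSums(Gm$matrix) > 0)
  )
}

#' @export
print.pasl_model <- function(x, ...) {
  cat("<pasl_model>\n")
  cat("  atoms: ", nrow(x$D1), " inference + ", nrow(x$D2), " discovery, p = ",
      length(x$feature_ids), " features\n", sep = "")
  cat("  hyper: t = ", x$hyper$t, ", lambda = ", format(x$hyper$lam),
      ", nz = ", x$hyper$nz, "\n", sep = "")
  cat("  reevaluations during inference: ",
      attr(x$ledger, "n_reevaluations"), "\n", sep = "")
  invisible(x)
}

#' Extract the dictionary from a fitted model
#'
#' @param model A fitted `pasl_model`.
#' @param scope `"all"` for the stacked dictionary `[D1; D2]`,
#'   `"inference_only"` for `D1`.
#' @return Sparse matrix (atoms x features) with atom names as rownames.
#' @export
pasl_dictionary <- function(model, scope = c("all", "inference_only")) {
  scope <- match.arg(scope)
  if (scope == "inference_only") model$D1 else rbind(model$D1, model$D2)
}

# Moore-Penrose pseudo-inverse of the dictionary (p x a), cached per model
# and scope. Singular values below 1e-10 of the largest are treated as zero
# (atoms from overlapping genesets can be nearly dependent).
pasl_pinv <- function(model, scope = c("all", "inference_only")) {
  scope <- match.arg(scope)
  key <- paste0("pinv_", scope)
  if (!is.null(model$cache[[key]])) return(model$cache[[key]])
  D <- as.matrix(pasl_dictionary(model, scope))
  if (nrow(D) == 0L) stop("dictionary has no atoms in scope '", scope, "'")
  s <- svd(D)
  pos <- s$d > 1e-10 * max(s$d)
  pinv <- s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
  model$cache[[key]] <- pinv
  pinv
}

# Align the columns of a new matrix to the model's feature ids. Missing
# features are an error unless allow_subset, in which case they are
# zero-filled after standardization (their standardized value is 0).
align_features <- function(Xnew, model, allow_subset = FALSE) {
  feats <- colnames(Xnew)
  if (is.null(feats)) {
    if (ncol(Xnew) == length(model$feature_ids)) return(list(X = Xnew, missing = integer(0)))
    stop("new data has no feature ids and its width does not match the model")
  }
  idx <- match(model$feature_ids, feats)
  miss <- which(is.na(idx))
  if (length(miss) > 0L && !allow_subset) {
    stop(length(miss), " model feature(s) absent from the new data ",
         "(set allow_subset = TRUE to zero-fill)")
  }
  out <- matrix(0, nrow(Xnew), length(model$feature_ids),
                dimnames = list(rownames(Xnew), model$feature_ids))
  ok <- which(!is.na(idx))
  out[, ok] <- Xnew[, idx[ok], drop = FALSE]
  list(X = out, missing = miss)
}

#' Project new samples into pathway activity scores
#'
#' Standardizes `Xnew` with the training means and standard deviations stored
#' in the model (never refit) and computes `L = Xz %*% pinv(D)`, the least
#' squares coordinates of each sample on the dictionary rows. Works for a
#' single sample. The first `a1` columns are pathway activity scores; the
#' rest are discovery scores.
#'
#' @param Xnew Numeric matrix (samples x features) with feature ids as
#'   column names; a single named vector is accepted as one sample.
#' @param model A fitted `pasl_model`.
#' @param allow_subset If `TRUE`, model features absent from `Xnew` are
#'   zero-filled (logged via message) instead of raising an error.
#' @return Score matrix, samples x (a1 + a2), with atom names as column
#'   names and the model's `atom_meta` attached as attribute `"atom_meta"`.
#' @export
pasl_transform <- function(Xnew, model, allow_subset = FALSE) {
  stopifnot(inherits(model, "pasl_model"))
  if (is.null(dim(Xnew))) {
    Xnew <- matrix(Xnew, nrow = 1L, dimnames = list("sample_1", names(Xnew)))
  }
  al <- align_features(as.matrix(Xnew), model, allow_subset)
  if (length(al$missing) > 0L) {
    message(length(al$missing), " missing feature(s) zero-filled")
  }
  Xz <- apply_standardization(al$X, model$std)
  if (length(al$missing) > 0L) Xz[, al$missing] <- 0
  L <- Xz %*% pasl_pinv(model, "all")
  colnames(L) <- model$atom_meta$atom
  rownames(L) <- rownames(Xnew)
  attr(L, "atom_meta") <- model$atom_meta
  L
}

#' Fraction of variance explained by the dictionary
#'
#' `1 - ||Xz - L D||_F^2 / ||Xz||_F^2`, where `Xz` is the data standardized
#' with the model's training parameters and `L` the least squares projection
#' coordinates. With `restrict_to_covered_features = TRUE`, features that do
#' not appear in any geneset are removed from both numerator and denominator
#' (the inference dictionary cannot explain them by construction).
#'
#' @param X Numeric matrix (samples x features, named columns).
#' @param model A fitted `pasl_model`.
#' @param scope `"all"` (full dictionary) or `"inference_only"` (`D1`).
#' @param restrict_to_covered_features Drop geneset-uncovered features from
#'   the calculation.
#' @param allow_subset Passed to feature alignment, as in [pasl_transform()].
#' @return A fraction in `[0, 1]` (up to numerical error).
#' @export
explained_variance <- function(X, model,
                               scope = c("all", "inference_only"),
                               restrict_to_covered_features = FALSE,
                               allow_subset = FALSE) {
  scope <- match.arg(scope)
  stopifnot(inherits(model, "pasl_model"))
  if (is.null(dim(X))) {
    X <- matrix(X, nrow = 1L, dimnames = list(NULL, names(X)))
  }
  al <- align_features(as.matrix(X), model, allow_subset)
  Xz <- apply_standardization(al$X, model$std)
  if (length(al$missing) > 0L) Xz[, al$missing] <- 0
  D <- pasl_dictionary(model, scope)
  L <- Xz %*% pasl_pinv(model, scope)
  R <- Xz - as.matrix(L %*% D)
  cols <- if (restrict_to_covered_features) model$covered else rep(TRUE, ncol(Xz))
  denom <- sum(Xz[, cols]^2)
  if (denom <= 0) stop("explained variance undefined: data is all zero")
  1 - sum(R[, cols]^2) / denom
}

#' Column-permuted random-projection baseline
#'
#' Applies a uniform random permutation to the feature columns of a
#' validation matrix (values are shuffled across feature labels) and then
#' computes [explained_variance()]. This measures how much variance a random
#' sub-space projection of the same sparsity captures, the control against
#' which the dictionary's generalization is judged.
#'
#' @param X Validation matrix (samples x features, named columns).
#' @param model A fitted `pasl_model`.
#' @param seed Seed for the permutation.
#' @param perm Optional explicit permutation of `1:p` (overrides `seed`);
#'   the identity permutation reproduces [explained_variance()] exactly.
#' @param ... Passed to [explained_variance()] (`scope`,
#'   `restrict_to_covered_features`).
#' @return A fraction in `[0, 1]`.
#' @export
permuted_baseline <- function(X, model, seed = NULL, perm = NULL, ...) {
  stopifnot(inherits(model, "pasl_model"))
  if (is.null(dim(X))) {
    X <- matrix(X, nrow = 1L, dimnames = list(NULL, names(X)))
  }
  al <- align_features(as.matrix(X), model, allow_subset = FALSE)
  Xa <- al$X
  p <- ncol(Xa)
  if (is.null(perm)) perm <- with_seed(seed, sample.int(p))
  stopifnot(length(perm) == p)
  Xp <- Xa[, perm, drop = FALSE]
  colnames(Xp) <- colnames(Xa)
  explained_variance(Xp, model, ...)
}
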