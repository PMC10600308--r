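#' Specification of a planted-model simulation
#'
#' Describes the generative model used for validation: random genesets with
#' sizes drawn uniformly from `sizes`, a true dictionary supported on a
#' random subset of them, signed-uniform loadings and scores, and isotropic
#' Gaussian noise. Defaults reproduce the size-bias calibration design:
#' n = 400 samples, p = 500 features, geneset sizes uniform over
#' {30, 50, 100, 200}, loadings and scores uniform on
#' `[-1.5, -0.5] U [0.5, 1.5]`.
#'
#' @param n Number of samples.
#' @param p Number of features.
#' @param n_genesets Number of genesets in the collection.
#' @param n_active Number of genesets carrying a planted factor.
#' @param sizes Candidate geneset sizes (each drawn uniformly).
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param coeff_range Magnitude range of non-zero dictionary entries (sign
#'   is a fair coin).
#' @param score_range Magnitude range of true score entries.
#' @param disjoint If `TRUE`, geneset members are drawn without replacement
#'   globally so genesets are mutually disjoint (requires the drawn sizes to
#'   sum to at most p); otherwise members are sampled independently per
#'   geneset and overlaps occur by chance.
#' @param seed Seed; identical spec + seed gives a bitwise-identical dataset.
#' @return A `pasl_sim_spec` list.
#' @export
pasl_sim_spec <- function(n = 400, p = 500, n_genesets = 40, n_active = 20,
                          sizes = c(30, 50, 100, 200), noise_sd = 0.1,
                          coeff_range = c(0.5, 1.5),
                          score_range = c(0.5, 1.5),
                          disjoint = FALSE, seed = NULL) {
  if (max(sizes) > p) stop("largest geneset size exceeds p")
  if (n_active > n_genesets) stop("n_active cannot exceed n_genesets")
  structure(
    list(n = as.integer(n), p = as.integer(p),
         n_genesets = as.integer(n_genesets), n_active = as.integer(n_active),
         sizes = sizes, noise_sd = noise_sd, coeff_range = coeff_range,
         score_range = score_range, disjoint = isTRUE(disjoint), seed = seed),
    class = "pasl_sim_spec"
  )
}

# Signed uniform draw on [-hi, -lo] U [lo, hi].
runif_signed <- function(m, lo, hi) {
  runif(m, lo, hi) * sample(c(-1, 1), m, replace = TRUE)
}

pad_id <- function(prefix, k, n) sprintf("%s%0*d", prefix, nchar(n), k)

sim_genesets <- function(spec) {
  sz <- sample(spec$sizes, spec$n_genesets, replace = TRUE)
  if (spec$disjoint) {
    if (sum(sz) > spec$p) {
      stop("disjoint genesets need total size <= p (got ", sum(sz), " > ",
           spec$p, ")")
    }
    pool <- sample.int(spec$p)
    ends <- cumsum(sz)
    members <- lapply(seq_along(sz), function(i) {
      sort(pool[(ends[i] - sz[i] + 1L):ends[i]])
    })
  } else {
    members <- lapply(sz, function(s) sort(sample.int(spec$p, s)))
  }
  list(sizes = sz, members = members)
}

#' Simulate a planted-dictionary expression dataset
#'
#' Generates a random geneset collection, plants a true dictionary on a
#' random subset of `n_active` genesets (non-zeros drawn signed-uniform on
#' the coefficient range), draws true scores the same way, and emits
#' `X = L_true %*% D_true + noise`.
#'
#' @param spec A [pasl_sim_spec()].
#' @return List with `X` (n x p named matrix), `truth` (list: `genesets`
#'   collection, `G` membership matrix, `D_true`, `L_true`, `active`
#'   geneset indices, `size_class` of active genesets, `geneset_sizes` of
#'   all genesets), and `spec`.
#' @export
pasl_simulate <- function(spec) {
  stopifnot(inherits(spec, "pasl_sim_spec"))
  with_seed(spec$seed, {
    gs <- sim_genesets(spec)
    feature_ids <- vapply(seq_len(spec$p), pad_id, character(1),
                          prefix = "f", n = spec$p)
    gs_names <- vapply(seq_len(spec$n_genesets), pad_id, character(1),
                       prefix = "GS", n = spec$n_genesets)
    coll <- new_geneset_collection(
      gs_names,
      rep("simulated", spec$n_genesets),
      lapply(gs$members, function(m) feature_ids[m])
    )
    G <- build_membership(coll, feature_ids)
    active <- sort(sample.int(spec$n_genesets, spec$n_active))
    D_true <- matrix(0, spec$n_active, spec$p,
                     dimnames = list(gs_names[active], feature_ids))
    for (k in seq_along(active)) {
      mem <- gs$members[[active[k]]]
      D_true[k, mem] <- runif_signed(length(mem), spec$coeff_range[1L],
                                     spec$coeff_range[2L])
    }
    L_true <- matrix(runif_signed(spec$n * spec$n_active,
                                  spec$score_range[1L], spec$score_range[2L]),
                     spec$n, spec$n_active)
    X <- L_true %*% D_true
    if (spec$noise_sd > 0) {
      X <- X + matrix(rnorm(spec$n * spec$p, sd = spec$noise_sd),
                      spec$n, spec$p)
    }
    dimnames(X) <- list(vapply(seq_len(spec$n), pad_id, character(1),
                               prefix = "s", n = spec$n),
                        feature_ids)
    list(X = X,
         truth = list(genesets = coll, G = G, D_true = D_true,
                      L_true = L_true, active = active,
                      size_class = gs$sizes[active],
                      geneset_sizes = gs$sizes),
         spec = spec)
  })
}

#' Simulate a two-class dataset with planted activation shifts
#'
#' Same generative model as [pasl_simulate()], but the true scores of the
#' second class are shifted by `effect` (one entry per active geneset)
#' before mixing, creating genesets that are differentially activated
#' between the classes. `effect = 0` gives an exchangeable null.
#'
#' @param spec A [pasl_sim_spec()].
#' @param effect Numeric vector of per-factor mean shifts, length
#'   `n_active` (a scalar is recycled).
#' @param class_sizes Two integers summing to `spec$n`.
#' @return As [pasl_simulate()], plus `labels` (character vector `"A"`/`"B"`
#'   named by sample id).
#' @export
pasl_simulate_two_class <- function(spec, effect, class_sizes) {
  stopifnot(inherits(spec, "pasl_sim_spec"))
  if (length(effect) == 1L) effect <- rep(effect, spec$n_active)
  if (length(effect) != spec$n_active) {
    stop("effect must have one entry per active geneset")
  }
  if (length(class_sizes) != 2L || sum(class_sizes) != spec$n) {
    stop("class_sizes must be two integers summing to n")
  }
  sim <- pasl_simulate(spec)
  labels <- rep(c("A", "B"), class_sizes)
  names(labels) <- rownames(sim$X)
  if (any(effect != 0)) {
    shift <- outer(labels == "B", effect) * 1
    # reuse the same noise realization as the unshifted dataset
    X <- (sim$truth$L_true + shift) %*% sim$truth$D_true +
      (sim$X - sim$truth$L_true %*% sim$truth$D_true)
    dimnames(X) <- dimnames(sim$X)
    sim$X <- X
    sim$truth$L_true <- sim$truth$L_true + shift
  }
  sim$labels <- labels
  sim
}

#' Size-class histogram of selected inference atoms
#'
#' Counts the accepted inference atoms by the ground-truth size class of the
#' geneset each atom was built on — the statistic behind the size-bias
#' calibration: without size normalization the largest class dominates,
#' with Box-Cox normalization the histogram tracks the planted mixture.
#'
#' @param model A `pasl_model` fitted on a simulated dataset.
#' @param truth The `truth` component of [pasl_simulate()] output.
#' @param classes Size classes to tabulate over (default: the distinct
#'   geneset sizes present in the simulation).
#' @return Named integer vector of counts, one per size class.
#' @export
size_class_histogram <- function(model, truth, classes = NULL) {
  stopifnot(inherits(model, "pasl_model"))
  meta <- model$atom_meta
  gs <- meta$geneset[meta$phase == "inference"]
  sizes <- truth$geneset_sizes[match(gs, truth$genesets$names)]
  if (is.null(classes)) classes <- sort(unique(truth$geneset_sizes))
  tab <- table(factor(sizes, levels = classes))
  out <- as.integer(tab)
  names(out) <- as.character(classes)
  out
}
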