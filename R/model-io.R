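PASL_SCHEMA <- "pasl-model"
PASL_SCHEMA_VERSION <- 1L

# Doubles are stored as %.17g strings: 17 significant digits round-trip IEEE
# doubles exactly, which plain JSON number emission does not guarantee.
fmt_dbl <- function(x) sprintf("%.17g", x)
parse_dbl <- function(s) as.numeric(unlist(s))

sparse_to_triplets <- function(D) {
  T <- methods::as(methods::as(D, "CsparseMatrix"), "TsparseMatrix")
  list(i = T@i + 1L, j = T@j + 1L, x = T@x, nrow = nrow(D))
}

triplets_to_sparse <- function(tr, p, rownames = NULL, colnames = NULL) {
  # jsonlite reads empty arrays back as list(); coerce to typed vectors
  Matrix::sparseMatrix(i = as.integer(unlist(tr$i)),
                       j = as.integer(unlist(tr$j)),
                       x = as.numeric(unlist(tr$x)),
                       dims = c(as.integer(tr$nrow), p),
                       dimnames = list(rownames, colnames))
}

#' Save a fitted model to a portable archive
#'
#' The archive is a single JSON file holding a metadata block
#' (hyper-parameters, feature ids, standardization vectors, per-atom
#' provenance, the variance ledger) plus sparse-triplet arrays for the two
#' dictionaries. Numbers are written at full double precision, so a
#' save/load round trip reproduces transforms bit-exactly.
#'
#' @param model A fitted `pasl_model`.
#' @param path Output path (conventionally `.pasl`, plain JSON inside).
#' @return `path`, invisibly.
#' @seealso [load_pasl()]
#' @export
save_pasl <- function(model, path) {
  stopifnot(inherits(model, "pasl_model"))
  tr1 <- sparse_to_triplets(model$D1)
  tr2 <- sparse_to_triplets(model$D2)
  tr1$x <- fmt_dbl(tr1$x); tr2$x <- fmt_dbl(tr2$x)
  meta <- model$atom_meta
  meta$variance_removed <- fmt_dbl(meta$variance_removed)
  led <- as.data.frame(model$ledger)
  for (cl in c("expected", "actual", "variance_removed")) {
    led[[cl]] <- fmt_dbl(led[[cl]])
  }
  hyper <- model$hyper
  hyper$t <- fmt_dbl(hyper$t)
  if (!is.null(hyper$lam)) hyper$lam <- fmt_dbl(hyper$lam)
  obj <- list(
    schema = PASL_SCHEMA,
    version = PASL_SCHEMA_VERSION,
    hyper = hyper,
    feature_ids = model$feature_ids,
    covered = which(model$covered),
    mu = fmt_dbl(model$std$mu),
    sigma = fmt_dbl(model$std$sigma),
    atom_meta = meta,
    ledger = led,
    ledger_attrs = attributes(model$ledger)[c("t", "lam", "n_reevaluations",
                                              "n_order_calls")],
    D1 = tr1,
    D2 = tr2
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a model archive written by [save_pasl()]
#'
#' @param path Path to the archive.
#' @return A `pasl_model`.
#' @export
load_pasl <- function(path) {
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) stop("cannot parse model archive '", path,
                             "' (truncated or not a model file): ",
                             conditionMessage(e))
  )
  if (!identical(obj$schema, PASL_SCHEMA)) {
    stop("file is not a pasl model archive: ", path)
  }
  if (!identical(as.integer(obj$version), PASL_SCHEMA_VERSION)) {
    stop("unsupported model schema version ", obj$version,
         " (this build reads version ", PASL_SCHEMA_VERSION, ")")
  }
  p <- length(obj$feature_ids)
  obj$D1$x <- parse_dbl(obj$D1$x)
  obj$D2$x <- parse_dbl(obj$D2$x)
  atom_meta <- as.data.frame(obj$atom_meta)
  if (nrow(atom_meta) > 0L) {
    atom_meta$variance_removed <- parse_dbl(atom_meta$variance_removed)
    if (is.null(atom_meta$geneset)) atom_meta$geneset <- NA_character_
    atom_meta$geneset_index <- suppressWarnings(as.integer(atom_meta$geneset_index))
  }
  infer_names <- atom_meta$atom[atom_meta$phase == "inference"]
  disc_names <- atom_meta$atom[atom_meta$phase == "discovery"]
  D1 <- triplets_to_sparse(obj$D1, p, infer_names, obj$feature_ids)
  D2 <- triplets_to_sparse(obj$D2, p, disc_names, obj$feature_ids)
  covered <- logical(p)
  covered[unlist(obj$covered)] <- TRUE
  ledger <- as.data.frame(obj$ledger)
  for (cl in c("expected", "actual", "variance_removed")) {
    if (!is.null(ledger[[cl]])) ledger[[cl]] <- parse_dbl(ledger[[cl]])
  }
  for (nm in names(obj$ledger_attrs)) attr(ledger, nm) <- obj$ledger_attrs[[nm]]
  class(ledger) <- c("pasl_ledger", "data.frame")
  hyper <- obj$hyper
  hyper$t <- parse_dbl(hyper$t)
  if (!is.null(hyper$lam)) hyper$lam <- parse_dbl(hyper$lam)
  mu <- stats::setNames(parse_dbl(obj$mu), obj$feature_ids)
  sigma <- stats::setNames(parse_dbl(obj$sigma), obj$feature_ids)
  new_pasl_model(
    D1 = D1, D2 = D2,
    std = list(mu = mu, sigma = sigma),
    atom_meta = atom_meta,
    hyper = hyper,
    ledger = ledger,
    feature_ids = obj$feature_ids,
    covered = covered
  )
}
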