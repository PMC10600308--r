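#' Read a geneset collection from a GMT file
#'
#' GMT is the tab-separated geneset distribution format used by MSigDB: one
#' geneset per line, with fields `name`, `description`, then one field per
#' member identifier. Duplicate members within a line are removed (first
#' occurrence kept); duplicate geneset names across lines are an error.
#'
#' @param path Path to a GMT file.
#' @return A `geneset_collection`: list with components `names`,
#'   `descriptions`, and `members` (a list of character vectors), preserving
#'   file order.
#' @export
#' @examples
#' gmt <- tempfile(fileext = ".gmt")
#' writeLines(c("GS1\tfirst\tA\tB\tA", "GS2\tsecond\tB\tC"), gmt)
#' gs <- read_gmt(gmt)
#' gs$members$GS1
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(new_geneset_collection(character(), character(), list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- lineno[which(nf < 3L)[1L]]
    stop("malformed GMT line ", bad, ": expected at least 3 tab-separated fields")
  }
  nms <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nms)) {
    stop("duplicate geneset name in GMT: ", nms[duplicated(nms)][1L])
  }
  descs <- vapply(fields, `[[`, character(1), 2L)
  members <- lapply(seq_along(fields), function(i) {
    mem <- unique(fields[[i]][-(1:2)])
    mem <- mem[nzchar(mem)]
    if (length(mem) == 0L) {
      stop("GMT line ", lineno[i], " (", nms[i], ") has no non-empty members")
    }
    mem
  })
  new_geneset_collection(nms, descs, members)
}

new_geneset_collection <- function(names, descriptions, members) {
  names(members) <- names
  structure(
    list(names = names, descriptions = descriptions, members = members),
    class = "geneset_collection"
  )
}

#' @export
length.geneset_collection <- function(x) length(x$names)

#' @export
print.geneset_collection <- function(x, ...) {
  cat("<geneset_collection> ", length(x), " genesets\n", sep = "")
  if (length(x) > 0) {
    sz <- lengths(x$members)
    cat("  sizes: min ", min(sz), ", median ", stats::median(sz),
        ", max ", max(sz), "\n", sep = "")
  }
  invisible(x)
}

#' Write a geneset collection to a GMT file
#'
#' @param genesets A `geneset_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(genesets, path) {
  stopifnot(inherits(genesets, "geneset_collection"))
  lines <- vapply(seq_along(genesets$names), function(i) {
    paste(c(genesets$names[i], genesets$descriptions[i], genesets$members[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build the binary geneset membership matrix
#'
#' Produces the m x p matrix G with `G[i, j] = 1` when feature j measures at
#' least one gene belonging to geneset i. With microarray data, a probe-set
#' can map to several genes; the optional annotation multimap handles this:
#' a probe obtains a 1 in every geneset containing any of its genes. Without
#' an annotation, the feature identifiers are matched to geneset members
#' directly.
#'
#' Genesets whose support is empty on the given platform are dropped with a
#' warning; their names are recorded in the `dropped` component.
#'
#' @param genesets A `geneset_collection`.
#' @param feature_ids Character vector of feature (probe-set/gene)
#'   identifiers, aligned to the expression matrix columns. Must be unique.
#' @param annotation Optional probe-to-gene multimap: a data frame whose
#'   first two columns are probe id and gene symbol, one row per pair.
#' @return A `membership_matrix`: list with `matrix` (sparse binary, m x p),
#'   `geneset_names`, `feature_ids`, and `dropped` (names of genesets with
#'   empty support).
#' @export
build_membership <- function(genesets, feature_ids, annotation = NULL) {
  stopifnot(inherits(genesets, "geneset_collection"))
  if (length(feature_ids) == 0L) stop("feature_ids must be non-empty")
  if (anyDuplicated(feature_ids)) stop("feature_ids must be unique")
  p <- length(feature_ids)

  # gene symbol -> feature column indices
  if (is.null(annotation)) {
    gene2col <- split(seq_len(p), feature_ids)
  } else {
    ann <- as.data.frame(annotation)
    probe <- as.character(ann[[1L]])
    gene <- as.character(ann[[2L]])
    col <- match(probe, feature_ids)
    ok <- !is.na(col)
    gene2col <- split(col[ok], gene[ok])
  }

  ii <- integer(0); jj <- integer(0)
  for (i in seq_along(genesets$names)) {
    cols <- unique(unlist(gene2col[genesets$members[[i]]], use.names = FALSE))
    if (length(cols) > 0L) {
      ii <- c(ii, rep.int(i, length(cols)))
      jj <- c(jj, cols)
    }
  }
  m <- length(genesets$names)
  G <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(m, p),
                            dimnames = list(genesets$names, feature_ids))
  support <- Matrix::rowSums(G) > 0
  dropped <- genesets$names[!support]
  if (all(!support)) {
    stop("no geneset has non-empty support on the given features")
  }
  if (length(dropped) > 0L) {
    warning(length(dropped), " geneset(s) with empty support dropped: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
    G <- G[support, , drop = FALSE]
  }
  structure(
    list(matrix = G,
         geneset_names = rownames(G),
         feature_ids = feature_ids,
         dropped = dropped),
    class = "membership_matrix"
  )
}

#' @export
print.membership_matrix <- function(x, ...) {
  cat("<membership_matrix> ", nrow(x$matrix), " genesets x ",
      ncol(x$matrix), " features (",
      sum(Matrix::colSums(x$matrix) > 0), " covered)\n", sep = "")
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expected layout: header row of feature identifiers, first column of sample
#' identifiers, numeric body (samples x features). Missing values are
#' rejected by default; `na_action = "impute_mean"` replaces them with the
#' feature (column) mean.
#'
#' @param path Path to a TSV file.
#' @param na_action `"error"` (default) or `"impute_mean"`.
#' @return Numeric matrix with sample ids as rownames and feature ids as
#'   colnames.
#' @export
read_expression <- function(path, na_action = c("error", "impute_mean")) {
  na_action <- match.arg(na_action)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs a sample-id column plus features")
  ids <- as.character(df[[1L]])
  X <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- ids
  if (anyDuplicated(colnames(X))) stop("feature ids must be unique")
  if (anyNA(X)) {
    if (na_action == "error") {
      stop("expression matrix contains missing values (use na_action = \"impute_mean\")")
    }
    for (j in which(colSums(is.na(X)) > 0L)) {
      mj <- mean(X[, j], na.rm = TRUE)
      if (is.nan(mj)) mj <- 0
      X[is.na(X[, j]), j] <- mj
    }
  }
  X
}

#' Write an expression or score matrix to TSV
#'
#' Inverse of [read_expression()]: header row of column names, first column
#' `sample_id`.
#'
#' @param X Numeric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(X, path) {
  df <- data.frame(sample_id = rownames(X) %||% as.character(seq_len(nrow(X))),
                   X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column sample label table
#'
#' @param path TSV with columns sample id and class label (header optional
#'   but recommended: `sample_id`, `class`).
#' @return Named character vector of class labels, names = sample ids.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("label TSV needs two columns: sample_id, class")
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}
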