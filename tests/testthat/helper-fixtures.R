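# Small deterministic fixtures shared across test files.

# Random centered-ish matrix with feature ids.
rand_expr <- function(n, p, seed = 1, prefix = "f") {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0(prefix, seq_len(p))))
  X
}

# Membership matrix from an explicit list of member-index vectors.
membership_from_indices <- function(members, p, feature_ids = paste0("f", seq_len(p))) {
  coll <- pasl:::new_geneset_collection(
    paste0("g", seq_along(members)),
    rep("", length(members)),
    lapply(members, function(m) feature_ids[m])
  )
  build_membership(coll, feature_ids)
}

# One geneset covering all p features: reduces inference to plain PCA.
full_cover_membership <- function(p) {
  membership_from_indices(list(seq_len(p)), p)
}

# The three-geneset worked structure: g1={f1..f3}, g2={f3..f5}, g3={f5..f7}.
toy_gmt_lines <- c(
  "g1\tdesc1\tf1\tf2\tf3",
  "g2\tdesc2\tf3\tf4\tf5",
  "g3\tdesc3\tf5\tf6\tf7"
)

write_toy_gmt <- function(path = tempfile(fileext = ".gmt")) {
  writeLines(toy_gmt_lines, path)
  path
}
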