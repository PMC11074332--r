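#' Pluggable drug-pair featurizers
#'
#' A featurizer turns a drug (its component SMILES) into a fixed-length
#' numeric vector and a drug pair into the concatenation of the two vectors,
#' ARV half first. Three backends share this contract:
#'
#' * `"similarity"` — Tanimoto similarity profile against a fixed reference
#'   panel (vector length = panel size `R`; pair feature length `2R`);
#' * `"embedding-stub"` — a deterministic 768-dimensional pseudo-embedding:
#'   a fixed seeded random projection of the merged Morgan fingerprint. It
#'   stands in for an external pretrained sequence model during offline
#'   testing; identical molecules always map to identical vectors;
#' * `"embedding-external"` — an adapter slot for a real pretrained embedding
#'   model supplied by the user as `embed_fun(components) -> numeric(768)`;
#'   the adapter must document its token pooling choice.
#'
#' @param backend backend name.
#' @param panel reference panel (required for `"similarity"`), see
#'   [build_reference_panel()].
#' @param radius,n_bits fingerprint parameters used by the similarity and
#'   stub backends.
#' @param embed_fun external embedding function for `"embedding-external"`.
#' @return a `ddi_featurizer` object.
#' @export
featurizer <- function(backend = c("similarity", "embedding-stub",
                                   "embedding-external"),
                       panel = NULL, radius = 2, n_bits = 1024,
                       embed_fun = NULL) {
  backend <- match.arg(backend)
  if (backend == "similarity") {
    if (!inherits(panel, "ddi_panel")) {
      abort("the similarity backend requires a reference panel")
    }
    radius <- panel$radius
    n_bits <- panel$n_bits
  }
  if (backend == "embedding-external" && !is.function(embed_fun)) {
    abort("the embedding-external backend requires `embed_fun`")
  }
  structure(
    list(backend = backend, panel = panel, radius = radius, n_bits = n_bits,
         embed_fun = embed_fun),
    class = "ddi_featurizer"
  )
}

#' @export
print.ddi_featurizer <- function(x, ...) {
  cat(sprintf("<ddi_featurizer> backend '%s', drug vector length %d\n",
              x$backend, drug_vector_length(x)))
  invisible(x)
}

# length of one drug's feature vector under this featurizer
drug_vector_length <- function(ftz) {
  switch(ftz$backend,
         "similarity" = length(ftz$panel),
         768L)
}

#' @rdname featurizer
#' @param x a `ddi_featurizer`.
#' @return `feature_length()`: length of one *pair* feature vector
#'   (`2R` for the similarity backend, 1536 for embedding backends).
#' @export
feature_length <- function(x) {
  stopifnot(inherits(x, "ddi_featurizer"))
  2L * drug_vector_length(x)
}

#' Concatenated pair features
#'
#' Featurizes each `(arv_id, comed_id)` pair of `pairs` by concatenating the
#' two drug vectors, ARV half first (the database is asymmetric by
#' construction: pairs are oriented ARV vs comedication). Drug vectors are
#' computed once per distinct drug and reused.
#'
#' @param pairs data frame with `arv_id` and `comed_id` columns.
#' @param drugs drug table resolving every id.
#' @param ftz a [featurizer()].
#' @return numeric matrix, one row per pair, `feature_length(ftz)` columns.
#' @export
pair_features <- function(pairs, drugs, ftz) {
  stopifnot(inherits(ftz, "ddi_featurizer"))
  drugs <- check_drug_table(drugs)
  ids <- unique(c(pairs$arv_id, pairs$comed_id))
  dangling <- setdiff(ids, drugs$drug_id)
  if (length(dangling) > 0) {
    abort(sprintf("pair table references unknown drug id(s): %s",
                  paste(dangling, collapse = ", ")))
  }
  sub <- drugs[match(ids, drugs$drug_id), ]
  vecs <- drug_vectors(sub, ftz)           # ids x len
  a <- vecs[match(pairs$arv_id, ids), , drop = FALSE]
  b <- vecs[match(pairs$comed_id, ids), , drop = FALSE]
  out <- cbind(a, b)
  rownames(out) <- NULL
  out
}

# one feature vector per drug row, as a matrix
drug_vectors <- function(drugs, ftz) {
  fps <- fingerprint_matrix(drugs$components, radius = ftz$radius,
                            n_bits = ftz$n_bits)
  switch(
    ftz$backend,
    "similarity" = profile_matrix(fps, ftz$panel),
    "embedding-stub" = stub_project(fps),
    "embedding-external" = {
      out <- t(vapply(drugs$components,
                      function(cc) as.numeric(ftz$embed_fun(cc)),
                      numeric(768)))
      out
    }
  )
}

#' Deterministic pseudo-embedding of a molecule
#'
#' Projects the merged Morgan fingerprint through a fixed, internally seeded
#' Gaussian random matrix to 768 dimensions. The projection matrix depends
#' only on the fingerprint length, never on the run seed, so the same
#' molecule (any SMILES spelling) always yields the same embedding, across
#' sessions and machines.
#'
#' @param components character vector of component SMILES.
#' @param radius,n_bits fingerprint parameters.
#' @return numeric vector of length 768.
#' @export
embed_smiles_stub <- function(components, radius = 2, n_bits = 1024) {
  fp <- morgan_fingerprint(components, radius = radius, n_bits = n_bits)
  drop(stub_project(matrix(fp, nrow = 1)))
}

# fixed random projection (rows of fps are 0/1 fingerprints)
stub_project <- function(fps) {
  W <- stub_projection_matrix(ncol(fps))
  out <- fps %*% W / sqrt(ncol(fps))
  tanh(out)
}

stub_projection_matrix <- function(n_bits) {
  key <- as.character(n_bits)
  if (is.null(.stub_cache[[key]])) {
    W <- withr::with_seed(
      760413L,  # fixed: the stub must be identical across runs and seeds
      matrix(rnorm(n_bits * 768L), nrow = n_bits, ncol = 768L)
    )
    .stub_cache[[key]] <- W
  }
  .stub_cache[[key]]
}

.stub_cache <- new.env(parent = emptyenv())
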