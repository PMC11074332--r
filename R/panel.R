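#' Build the fixed reference panel for similarity profiles
#'
#' A drug's learned representation is its vector of Tanimoto similarities
#' against a fixed, ordered reference panel of drugs ("similar structure
#' implies similar interactions"). The panel is frozen at training time:
#' model weights depend on its order, so it is sorted lexicographically by
#' `drug_id` (locale-independent radix sort) and persisted with the model.
#' Training drugs stay in the panel (self-similarity 1 is informative);
#' held-out drugs are simply absent.
#'
#' @param drugs drug table: a data frame with columns `drug_id` and
#'   `components` (list of SMILES vectors), as returned by
#'   [read_drug_table()] or [generate_drug_universe()].
#' @param radius,n_bits fingerprint parameters, see [morgan_fingerprint()].
#' @return a `ddi_panel` object: ordered drug ids plus their fingerprint
#'   matrix.
#' @export
build_reference_panel <- function(drugs, radius = 2, n_bits = 1024) {
  drugs <- check_drug_table(drugs)
  if (nrow(drugs) == 0) abort("cannot build a reference panel from 0 drugs")
  ord <- order(drugs$drug_id, method = "radix")
  drugs <- drugs[ord, ]
  fps <- fingerprint_matrix(drugs$components, radius = radius, n_bits = n_bits)
  rownames(fps) <- drugs$drug_id
  structure(
    list(drug_id = drugs$drug_id, fingerprints = fps,
         radius = radius, n_bits = n_bits),
    class = "ddi_panel"
  )
}

#' @export
print.ddi_panel <- function(x, ...) {
  cat(sprintf("<ddi_panel> %d reference drugs, %d-bit fingerprints (radius %d)\n",
              length(x$drug_id), x$n_bits, x$radius))
  invisible(x)
}

#' @export
length.ddi_panel <- function(x) length(x$drug_id)

#' Similarity profile of one fingerprint against a panel
#'
#' @param fp 0/1 fingerprint vector of the panel's bit length.
#' @param panel a [build_reference_panel()] object.
#' @return numeric vector of Tanimoto scores, one per panel drug, in panel
#'   order.
#' @export
similarity_profile <- function(fp, panel) {
  stopifnot(inherits(panel, "ddi_panel"))
  if (length(fp) != panel$n_bits) {
    abort(sprintf("fingerprint length %d does not match panel bit length %d",
                  length(fp), panel$n_bits))
  }
  drop(tanimoto_cross(matrix(as.integer(fp), nrow = 1), panel$fingerprints))
}

# profiles for many drugs at once: rows = drugs, cols = panel members
profile_matrix <- function(fps, panel) {
  stopifnot(inherits(panel, "ddi_panel"), ncol(fps) == panel$n_bits)
  tanimoto_cross(fps, panel$fingerprints)
}

# panel persistence: plain CSV with drug_id + hex-encoded bit string
panel_to_tibble <- function(panel) {
  tibble(
    drug_id = panel$drug_id,
    fingerprint_hex = apply(panel$fingerprints, 1, bits_to_hex)
  )
}

write_panel <- function(panel, path) {
  readr::write_csv(panel_to_tibble(panel), path)
  invisible(path)
}

read_panel <- function(path, radius = 2) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  fps <- do.call(rbind, lapply(tb$fingerprint_hex, hex_to_bits))
  rownames(fps) <- tb$drug_id
  structure(
    list(drug_id = tb$drug_id, fingerprints = fps,
         radius = radius, n_bits = ncol(fps)),
    class = "ddi_panel"
  )
}

bits_to_hex <- function(bits) {
  n <- length(bits)
  pad <- (4 - n %% 4) %% 4
  bits <- c(as.integer(bits), rep(0L, pad))
  nib <- matrix(bits, nrow = 4)
  paste(sprintf("%x", colSums(nib * c(8L, 4L, 2L, 1L))), collapse = "")
}

hex_to_bits <- function(hex) {
  vals <- strtoi(strsplit(hex, "")[[1]], base = 16L)
  as.integer(unlist(lapply(vals, function(v) as.integer(intToBits(v))[4:1])))
}
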