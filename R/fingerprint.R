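#' Morgan (ECFP) circular fingerprints
#'
#' Hashes the circular atom environments of a molecule up to a bond radius
#' (default 2, i.e. ECFP4) into a fixed-length binary vector. The chemistry
#' engine is OpenBabel's extended-connectivity fingerprint, which hashes into
#' 4096 bits; the vector is then folded to `n_bits` by modular OR, the
#' standard way of resizing ECFPs. For a fixed-dose combination product all
#' component fingerprints are merged by bitwise union while maintaining the
#' fingerprint size, so one product has one fingerprint.
#'
#' @param components character vector of component SMILES (length 1 for a
#'   single-agent drug, >= 2 for a combination).
#' @param radius bond radius of the circular environments (default 2).
#' @param n_bits fingerprint length in bits (default 1024).
#' @return integer vector of 0/1 of length `n_bits`.
#' @examples
#' fp <- morgan_fingerprint("CCO")
#' length(fp)
#' sum(fp)
#' @export
morgan_fingerprint <- function(components, radius = 2, n_bits = 1024) {
  m <- fingerprint_matrix(list(components), radius = radius, n_bits = n_bits)
  m[1L, ]
}

#' Fingerprint many drugs in one batch
#'
#' @param component_list list of character vectors of SMILES, one element per
#'   drug (components of a combination product are merged by bitwise union).
#' @inheritParams morgan_fingerprint
#' @return integer 0/1 matrix, one row per drug, `n_bits` columns.
#' @export
fingerprint_matrix <- function(component_list, radius = 2, n_bits = 1024) {
  stopifnot(is.list(component_list), length(component_list) >= 1,
            radius >= 0, n_bits >= 1)
  all_smi <- unlist(component_list, use.names = FALSE)
  if (length(all_smi) == 0) abort("no SMILES to fingerprint")
  uniq <- unique(all_smi)
  bad <- uniq[!smiles_is_valid(uniq)]
  if (length(bad) > 0) {
    abort(sprintf("cannot featurize invalid SMILES: %s",
                  paste(bad, collapse = ", ")))
  }
  raw <- ob_ecfp(uniq, radius)
  folded <- fold_bits(raw, n_bits)
  nz <- rowSums(folded) == 0 & nzchar(uniq)
  # a valid non-empty molecule always sets at least one bit
  if (any(nz)) {
    abort(sprintf("fingerprint has no set bits for: %s",
                  paste(uniq[nz], collapse = ", ")))
  }
  rows <- lapply(component_list, function(cc) {
    idx <- match(cc, uniq)
    merge_combination(lapply(idx, function(i) folded[i, ]))
  })
  do.call(rbind, rows)
}

# raw OpenBabel ECFP{2*radius}; one row per SMILES, 4096 columns.
# One toolkit process per batch: hex fingerprint blocks are parsed from the
# text output, ">"-headed per molecule.
ob_ecfp <- function(smiles, radius) {
  fpname <- paste0("ECFP", 2L * as.integer(radius))
  supported <- c("ECFP0", "ECFP2", "ECFP4", "ECFP6", "ECFP8", "ECFP10")
  if (!fpname %in% supported) {
    abort(sprintf("unsupported fingerprint radius %s", radius))
  }
  inp <- tempfile(fileext = ".smi")
  on.exit(unlink(inp), add = TRUE)
  writeLines(smiles, inp)
  lines <- run_obabel(c(inp, "-ofpt", paste0("-xf", fpname), "-xh"))
  starts <- grep("^>", lines)
  if (length(starts) != length(smiles)) {
    abort("fingerprint engine returned a different number of molecules")
  }
  m <- matrix(0L, length(smiles), 4096L)
  ends <- c(starts[-1] - 1L, length(lines))
  for (i in seq_along(starts)) {
    if (ends[i] <= starts[i]) next
    block <- lines[(starts[i] + 1L):ends[i]]
    block <- block[grepl("^[0-9a-fA-F ]+$", block)]   # hex rows only
    hex <- gsub(" ", "", paste(block, collapse = ""))
    bits <- hex_to_bits(hex)
    if (length(bits) > 4096L) {
      abort("unexpected fingerprint block length from the engine")
    }
    m[i, seq_along(bits)] <- bits
  }
  m
}

# fold columns by index modulo n_bits, OR-combining overlapping positions
fold_bits <- function(m, n_bits) {
  if (ncol(m) <= n_bits) {
    out <- matrix(0L, nrow(m), n_bits)
    out[, seq_len(ncol(m))] <- m
    return(out)
  }
  grp <- (seq_len(ncol(m)) - 1L) %% n_bits
  out <- matrix(0L, nrow(m), n_bits)
  for (g in 0:(n_bits - 1L)) {
    cols <- which(grp == g)
    out[, g + 1L] <- as.integer(rowSums(m[, cols, drop = FALSE]) > 0)
  }
  out
}

#' Merge component fingerprints of a combination product
#'
#' The fingerprint of a fixed-dose combination is the bitwise union of its
#' component fingerprints: a bit is set iff it is set in any component, and
#' the fingerprint size is maintained. Union is commutative, associative and
#' idempotent.
#'
#' @param fps list of equal-length 0/1 vectors.
#' @return single 0/1 integer vector of the same length.
#' @examples
#' merge_combination(list(c(1, 0, 0), c(0, 1, 0)))
#' @export
merge_combination <- function(fps) {
  if (!is.list(fps) || length(fps) == 0) abort("need at least one fingerprint")
  len <- unique(lengths(fps))
  if (length(len) != 1) {
    abort(sprintf("fingerprint lengths differ: %s", paste(len, collapse = ", ")))
  }
  as.integer(Reduce(`|`, fps))
}

#' Tanimoto similarity of two fingerprints
#'
#' The number of bits set in both fingerprints divided by the number set in
#' either (intersection over union), ranging 0 (no common substructure) to 1
#' (identical bit sets). Two all-zero fingerprints — which cannot arise from
#' valid molecules — are defined to have similarity 0 with a warning, avoiding
#' 0/0.
#'
#' @param a,b equal-length 0/1 vectors.
#' @return similarity in `[0, 1]`.
#' @examples
#' tanimoto(c(1, 1, 1, 0), c(0, 1, 1, 1))
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    abort(sprintf("fingerprint length mismatch: %d vs %d", length(a), length(b)))
  }
  a <- as.logical(a); b <- as.logical(b)
  un <- sum(a | b)
  if (un == 0) {
    warn("tanimoto of two all-zero fingerprints defined as 0")
    return(0)
  }
  sum(a & b) / un
}

# all-pairs Tanimoto between rows of two 0/1 matrices (shared bit length);
# vectorized via popcounts: |A&B| / (|A| + |B| - |A&B|)
tanimoto_cross <- function(A, B) {
  stopifnot(ncol(A) == ncol(B))
  inter <- A %*% t(B)
  pa <- rowSums(A)
  pb <- rowSums(B)
  un <- outer(pa, pb, `+`) - inter
  out <- inter / un
  out[un == 0] <- 0
  out
}
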