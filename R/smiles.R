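#' Validate and canonicalize SMILES strings
#'
#' Checks each string with a syntactic pre-screen (non-empty, no embedded
#' whitespace, balanced parentheses) followed by OpenBabel parsing; a string
#' is valid only if the toolkit can canonicalize it. The pre-screen matters
#' because OpenBabel silently truncates some malformed inputs (e.g. dangling
#' open parentheses) instead of rejecting them. The whole vector is
#' canonicalized in one toolkit invocation.
#'
#' @param smiles character vector of SMILES strings.
#' @return `canonical_smiles()`: character vector of canonical SMILES, `NA`
#'   where invalid. `smiles_is_valid()`: logical vector.
#' @examples
#' smiles_is_valid(c("CCO", "C((("))
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(trimws(smiles)) &
    !grepl("[[:space:]]", trimws(smiles)) & smiles_balanced(smiles)
  idx <- which(ok)
  if (length(idx) == 0) return(out)
  inp <- tempfile(fileext = ".smi")
  on.exit(unlink(inp), add = TRUE)
  writeLines(paste(trimws(smiles[idx]), paste0("m", idx)), inp)
  lines <- run_obabel(c(inp, "-ocan", "-e"))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (p in parts) {
    if (length(p) < 2 || !nzchar(p[[1]])) next
    i <- as.integer(sub("^m", "", trimws(p[[2]])))
    if (!is.na(i)) out[[i]] <- p[[1]]
  }
  out
}

# invoke the OpenBabel command-line tool; its stderr chatter is dropped
run_obabel <- function(args) {
  exe <- Sys.which("obabel")
  if (!nzchar(exe)) {
    abort("the OpenBabel command-line tool `obabel` is required on PATH")
  }
  suppressWarnings(system2(exe, args, stdout = TRUE, stderr = FALSE))
}

#' @rdname canonical_smiles
#' @export
smiles_is_valid <- function(smiles) !is.na(canonical_smiles(smiles))

# balanced "(" / ")" with no premature close
smiles_balanced <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s)) return(FALSE)
    depth <- 0L
    for (ch in strsplit(s, "", fixed = TRUE)[[1]]) {
      if (ch == "(") depth <- depth + 1L
      if (ch == ")") {
        depth <- depth - 1L
        if (depth < 0L) return(FALSE)
      }
    }
    depth == 0L
  }, logical(1), USE.NAMES = FALSE)
}

#' Split a components cell into individual SMILES
#'
#' Fixed-dose combination products keep one row per marketed product; the
#' `components` cell holds the SMILES of each active component separated by
#' `";"`.
#'
#' @param x character vector of components cells.
#' @return list of character vectors, one per cell.
#' @export
split_components <- function(x) {
  out <- strsplit(as.character(x), ";", fixed = TRUE)
  lapply(out, function(cc) trimws(cc[nzchar(trimws(cc))]))
}
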