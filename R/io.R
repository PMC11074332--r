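#' Read a drug table
#'
#' A drug table is delimited text (CSV, or TSV for `.tsv`/`.tab` files) with
#' header columns `drug_id,name,role,components` and optionally `arv_class`.
#' The `components` cell holds one or more SMILES separated by `";"`, one row
#' per marketed product, so fixed-dose combinations stay single records.
#'
#' Rows with invalid SMILES, duplicated ids, or an unknown role are dropped
#' and collected in the `problems` attribute (a tibble with `row`, `drug_id`,
#' `problem`) so a partly defective table still loads.
#'
#' @param path file path.
#' @return tibble with columns `drug_id`, `name`, `role` (`"ARV"` or
#'   `"comedication"`), `components` (list of character vectors) and
#'   `arv_class`; failed rows in `attr(, "problems")`.
#' @export
read_drug_table <- function(path) {
  raw <- read_delim_auto(path)
  need <- c("drug_id", "name", "role", "components")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("drug table %s lacks column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  if (!"arv_class" %in% names(raw)) raw$arv_class <- NA_character_
  comp <- split_components(raw$components)
  problems <- list()
  keep <- rep(TRUE, nrow(raw))
  role <- normalize_role(raw$role)
  for (i in seq_len(nrow(raw))) {
    bad_smi <- comp[[i]][!smiles_is_valid(comp[[i]])]
    if (length(comp[[i]]) == 0) {
      problems[[length(problems) + 1]] <-
        tibble(row = i, drug_id = raw$drug_id[i], problem = "empty components")
      keep[i] <- FALSE
    } else if (length(bad_smi) > 0) {
      problems[[length(problems) + 1]] <-
        tibble(row = i, drug_id = raw$drug_id[i],
               problem = sprintf("invalid SMILES: %s",
                                 paste(bad_smi, collapse = ", ")))
      keep[i] <- FALSE
    } else if (is.na(role[i])) {
      problems[[length(problems) + 1]] <-
        tibble(row = i, drug_id = raw$drug_id[i],
               problem = sprintf("unknown role: %s", raw$role[i]))
      keep[i] <- FALSE
    }
  }
  dup <- duplicated(raw$drug_id) & keep
  for (i in which(dup)) {
    problems[[length(problems) + 1]] <-
      tibble(row = i, drug_id = raw$drug_id[i], problem = "duplicate drug_id")
    keep[i] <- FALSE
  }
  out <- tibble(
    drug_id = as.character(raw$drug_id)[keep],
    name = as.character(raw$name)[keep],
    role = role[keep],
    components = comp[keep],
    arv_class = as.character(raw$arv_class)[keep]
  )
  attr(out, "problems") <- if (length(problems)) bind_rows(problems) else
    tibble(row = integer(), drug_id = character(), problem = character())
  if (nrow(attr(out, "problems")) > 0) {
    warn(sprintf("%d row(s) of %s dropped; see attr(x, 'problems')",
                 nrow(attr(out, "problems")), path))
  }
  out
}

#' Write a drug table
#'
#' Inverse of [read_drug_table()]: `read(write(x))` is field-identical for
#' valid tables.
#'
#' @param drugs drug table tibble.
#' @param path output path (`.tsv`/`.tab` writes TSV, otherwise CSV).
#' @export
write_drug_table <- function(drugs, path) {
  drugs <- check_drug_table(drugs)
  flat <- tibble(
    drug_id = drugs$drug_id, name = drugs$name, role = drugs$role,
    components = map_chr(drugs$components, paste, collapse = ";"),
    arv_class = drugs$arv_class
  )
  write_delim_auto(flat, path)
}

#' Read a labeled pair table
#'
#' Delimited text with header `arv_id,comed_id,grade`. Grades accept
#' case-insensitive names or codes 0-3. Rows whose ids do not resolve in the
#' drug table (dangling ids), with an unknown grade token, or duplicating an
#' earlier `(arv_id, comed_id)` pair are dropped and reported in the
#' `problems` attribute with their row numbers.
#'
#' @param path file path.
#' @param drugs drug table used to resolve ids.
#' @return tibble `arv_id`, `comed_id`, `grade` (ordered factor);
#'   failed rows in `attr(, "problems")`.
#' @export
read_pair_table <- function(path, drugs) {
  drugs <- check_drug_table(drugs)
  raw <- read_delim_auto(path)
  need <- c("arv_id", "comed_id", "grade")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("pair table %s lacks column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  problems <- list()
  keep <- rep(TRUE, nrow(raw))
  grade <- rep(NA_character_, nrow(raw))
  for (i in seq_len(nrow(raw))) {
    g <- tryCatch(as.character(as_grade(raw$grade[i])), error = function(e) NA)
    dangling <- setdiff(c(raw$arv_id[i], raw$comed_id[i]), drugs$drug_id)
    if (length(dangling) > 0) {
      problems[[length(problems) + 1]] <-
        tibble(row = i, arv_id = raw$arv_id[i], comed_id = raw$comed_id[i],
               problem = sprintf("unknown drug id(s): %s",
                                 paste(dangling, collapse = ", ")))
      keep[i] <- FALSE
    } else if (is.na(g)) {
      problems[[length(problems) + 1]] <-
        tibble(row = i, arv_id = raw$arv_id[i], comed_id = raw$comed_id[i],
               problem = sprintf("unknown grade token: %s", raw$grade[i]))
      keep[i] <- FALSE
    } else {
      grade[i] <- g
    }
  }
  key <- paste(raw$arv_id, raw$comed_id, sep = "\r")
  for (i in which(duplicated(key) & keep)) {
    first <- which(key == key[i])[1]
    problems[[length(problems) + 1]] <-
      tibble(row = i, arv_id = raw$arv_id[i], comed_id = raw$comed_id[i],
             problem = sprintf("duplicate of row %d", first))
    keep[i] <- FALSE
  }
  out <- tibble(
    arv_id = as.character(raw$arv_id)[keep],
    comed_id = as.character(raw$comed_id)[keep],
    grade = as_grade(grade[keep])
  )
  attr(out, "problems") <- if (length(problems)) bind_rows(problems) else
    tibble(row = integer(), arv_id = character(), comed_id = character(),
           problem = character())
  if (nrow(attr(out, "problems")) > 0) {
    warn(sprintf("%d row(s) of %s dropped; see attr(x, 'problems')",
                 nrow(attr(out, "problems")), path))
  }
  out
}

#' @rdname read_pair_table
#' @param pairs pair table tibble.
#' @export
write_pair_table <- function(pairs, path) {
  pairs <- check_pair_table(pairs)
  flat <- tibble(arv_id = pairs$arv_id, comed_id = pairs$comed_id,
                 grade = as.character(pairs$grade))
  write_delim_auto(flat, path)
}

#' Write / read a prediction table
#'
#' Columns `arv_id,comed_id,p_green,p_yellow,p_amber,p_red,predicted`.
#' Probabilities are written with full precision so two runs with the same
#' seed produce byte-identical files.
#'
#' @param predictions prediction tibble from [predict.ddi_ensemble()].
#' @param path file path.
#' @export
write_predictions <- function(predictions, path) {
  stopifnot(all(c("arv_id", "comed_id", "p_green", "p_yellow", "p_amber",
                  "p_red", "predicted") %in% names(predictions)))
  flat <- predictions
  flat$predicted <- as.character(flat$predicted)
  for (cl in c("p_green", "p_yellow", "p_amber", "p_red")) {
    flat[[cl]] <- sprintf("%.17g", flat[[cl]])
  }
  write_delim_auto(flat, path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  tb <- read_delim_auto(path)
  for (cl in c("p_green", "p_yellow", "p_amber", "p_red")) {
    tb[[cl]] <- as.numeric(tb[[cl]])
  }
  tb$predicted <- as_grade(tb$predicted)
  tb
}

#' Run configuration
#'
#' Bundles every tunable of the pipeline; the defaults reproduce the
#' published settings (fingerprint radius 2, 1024 bits, ensemble of 5,
#' similarity backend, Adam at learning rate 0.001).
#'
#' @param fingerprint_radius,fingerprint_bits Morgan fingerprint parameters.
#' @param ensemble_size number of undersampling ensemble members `k`.
#' @param network network preset name, see [network_spec()].
#' @param backend featurizer backend, see [featurizer()].
#' @param seed master seed; all stage seeds derive from it.
#' @param cv_folds folds for stratified cross-validation.
#' @param holdout_arvs number of ARVs held out for the independent test.
#' @param both_orientations also train on (comedication, ARV)-flipped
#'   features; pair orientation is otherwise fixed as (ARV, comedication).
#' @param class_weighting apply inverse-frequency class weights.
#' @return a `ddi_config` list.
#' @export
run_config <- function(fingerprint_radius = 2, fingerprint_bits = 1024,
                       ensemble_size = 5, network = "sim",
                       backend = "similarity", seed = 1L, cv_folds = 5,
                       holdout_arvs = 8, both_orientations = FALSE,
                       class_weighting = TRUE) {
  cfg <- list(
    fingerprint_radius = fingerprint_radius,
    fingerprint_bits = fingerprint_bits,
    ensemble_size = ensemble_size,
    network = network,
    backend = match.arg(backend,
                        c("similarity", "embedding-stub", "embedding-external")),
    seed = as.integer(seed),
    cv_folds = cv_folds,
    holdout_arvs = holdout_arvs,
    both_orientations = isTRUE(both_orientations),
    class_weighting = isTRUE(class_weighting)
  )
  structure(cfg, class = "ddi_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}

#' @rdname run_config
#' @param config a `ddi_config` object.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# ---- internal table plumbing -------------------------------------------------

read_delim_auto <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read file: %s", path))
  if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = "c"))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = "c"))
  }
}

write_delim_auto <- function(x, path) {
  if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) {
    readr::write_tsv(x, path, progress = FALSE)
  } else {
    readr::write_csv(x, path, progress = FALSE)
  }
  invisible(path)
}

normalize_role <- function(role) {
  rl <- tolower(trimws(as.character(role)))
  out <- rep(NA_character_, length(rl))
  out[rl %in% c("arv", "antiretroviral")] <- "ARV"
  out[rl %in% c("comedication", "comed", "com")] <- "comedication"
  out
}

check_drug_table <- function(drugs) {
  if (!is.data.frame(drugs)) abort("`drugs` must be a data frame")
  need <- c("drug_id", "components")
  missing_cols <- setdiff(need, names(drugs))
  if (length(missing_cols) > 0) {
    abort(sprintf("drug table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(drugs$drug_id)) {
    abort(sprintf("duplicate drug_id: %s",
                  paste(unique(drugs$drug_id[duplicated(drugs$drug_id)]),
                        collapse = ", ")))
  }
  if (is.character(drugs$components)) {
    drugs$components <- split_components(drugs$components)
  }
  if (!"name" %in% names(drugs)) drugs$name <- drugs$drug_id
  if (!"role" %in% names(drugs)) drugs$role <- NA_character_
  if (!"arv_class" %in% names(drugs)) drugs$arv_class <- NA_character_
  as_tibble(drugs)
}

check_pair_table <- function(pairs) {
  if (!is.data.frame(pairs)) abort("`pairs` must be a data frame")
  need <- c("arv_id", "comed_id", "grade")
  missing_cols <- setdiff(need, names(pairs))
  if (length(missing_cols) > 0) {
    abort(sprintf("pair table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  pairs <- as_tibble(pairs)
  pairs$grade <- as_grade(pairs$grade)
  pairs
}
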