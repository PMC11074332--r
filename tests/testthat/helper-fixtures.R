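# shared fixtures; expensive ones are built lazily and cached for the session
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# a dozen hand-picked valid molecules: small, diverse, fast to fingerprint
toy_smiles <- function() {
  c("CCO", "CCN", "c1ccccc1", "CC(=O)O", "CCOC(=O)C", "c1ccncc1",
    "CC(C)O", "CCCCO", "C1CCCCC1", "CC(N)C", "COc1ccccc1", "CCCN")
}

# small drug table: 4 ARVs (one a 2-component combination) + 8 comedications
toy_drugs <- function() {
  smi <- toy_smiles()
  tibble::tibble(
    drug_id = c(sprintf("A%02d", 1:4), sprintf("C%02d", 1:8)),
    name = c(sprintf("arv%d", 1:4), sprintf("com%d", 1:8)),
    role = rep(c("ARV", "comedication"), c(4, 8)),
    components = c(list(c(smi[1], smi[2])), as.list(smi[3:5]),
                   as.list(smi[c(6:12, 1)])),
    arv_class = c("PIs", "NNRTIs", "NRTIs", "INSTIs", rep(NA, 8))
  )
}

# every ARV x comedication pair with a deterministic skewed grading
toy_pairs <- function(seed = 42) {
  drugs <- toy_drugs()
  arvs <- drugs$drug_id[drugs$role == "ARV"]
  comeds <- drugs$drug_id[drugs$role == "comedication"]
  pairs <- tidyr::crossing(arv_id = arvs, comed_id = comeds)
  n <- nrow(pairs)
  withr::with_seed(seed, {
    grade <- sample(rep(0:3, times = c(n - 10, 4, 4, 2)))
  })
  pairs$grade <- as_grade(grade)
  pairs
}

# random 0/1 fingerprints for property tests
random_bits <- function(n, len, p = 0.2, seed = 1) {
  withr::with_seed(seed, {
    matrix(as.integer(stats::runif(n * len) < p), n, len)
  })
}

# brute-force set-arithmetic Tanimoto oracle over explicit bit-position sets
oracle_tanimoto <- function(a, b) {
  sa <- which(a == 1); sb <- which(b == 1)
  un <- union(sa, sb)
  if (length(un) == 0) return(0)
  length(intersect(sa, sb)) / length(un)
}

# small synthetic universe shared across test files (built once)
universe_10x100 <- function() {
  fixture("universe_10x100", function() {
    generate_drug_universe(dataset_config(n_arvs = 10, n_comedications = 100,
                                          seed = 3))
  })
}

# mid-sized synthetic study shared by the pipeline tests (built once);
# features depend only on the drug grid, so they are shared across sigma
pipeline_study <- function() {
  fixture("pipeline_study", function() {
    cfg <- dataset_config(n_arvs = 25, n_comedications = 200, sigma = 1,
                          seed = 11)
    drugs <- generate_drug_universe(cfg)
    panel <- build_reference_panel(drugs, radius = cfg$fingerprint_radius,
                                   n_bits = cfg$fingerprint_bits)
    ftz <- featurizer("similarity", panel = panel)
    grid <- grade_pairs(drugs, cfg)[, c("arv_id", "comed_id")]
    x <- pair_features(grid, drugs, ftz)
    list(cfg = cfg, drugs = drugs, ftz = ftz, grid = grid, x = x)
  })
}

# train a k-member ensemble on pre-featurized rows and score the held fold
fit_and_score <- function(x, pairs, train_rows, test_rows, k, spec, seed,
                          class_weighting = TRUE) {
  part <- partition_majority(pairs[train_rows, ], k = k, seed = seed)
  key <- paste(pairs$arv_id, pairs$comed_id)[train_rows]
  xtr <- x[train_rows, , drop = FALSE]
  probs <- 0
  for (i in seq_len(k)) {
    s <- part$subsets[[i]]
    idx <- match(paste(s$arv_id, s$comed_id), key)
    w <- if (class_weighting) class_weights(s) else NULL
    m <- train_member(spec, xtr[idx, , drop = FALSE], s$grade, weights = w,
                      seed = seed + i)
    probs <- probs + predict(m, x[test_rows, , drop = FALSE])
  }
  probs <- probs / k
  pred <- as_grade(max.col(probs, ties.method = "last") - 1L)
  metrics_report(pairs$grade[test_rows], pred, probs)
}
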