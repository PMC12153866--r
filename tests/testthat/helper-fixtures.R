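# Shared fixtures, built once per test run. Sizes are desk-scale: a 300 kb
# two-chromosome genome holds ~9k sites per collapsed trinucleotide, ample
# for cohorts of a few thousand mutations per sample.

fix_ref <- make_toy_reference(c(200000, 100000), exon_fraction = 0.1,
                              gene_count = 6, seed = 11)
fix_sigs <- make_signature_set(6, n_dominant = 3, noise = 0.1, seed = 12)

fix_class_defs <- stats::setNames(
  lapply(sprintf("sig%02d", 1:6), function(s) stats::setNames(1, s)),
  LETTERS[1:6])

fix_cohort <- simulate_cohort(
  fix_ref, fix_sigs,
  cohort_config(fix_class_defs,
                stats::setNames(rep(12L, 6), LETTERS[1:6]),
                burden_median = 200, burden_sigma = 0.4, seed = 13))

fix_features <- context_features(fix_cohort$mutations, fix_ref,
                                 samples = fix_cohort$labels$sample_id)

# A tiny hand-made reference where windows are known exactly.
#   chrT: A A C G T T C A  (pos 3 = C with window ACG, pos 6 = T in TTC)
make_micro_reference <- function(seq = "AACGTTCA") {
  structure(list(
    chrom_names = "chrT",
    lengths = c(chrT = nchar(seq)),
    sequences = c(chrT = seq),
    regions = tibble::tibble(chrom = "chrT", start = 0L,
                             end = nchar(seq), label = "intergenic"),
    genes = tibble::tibble(gene = character(), chrom = character(),
                           start = integer(), end = integer())),
    class = "toy_reference")
}

# Hand-made trained networks for LRP oracles: weights given explicitly,
# identity standardization, optional zero biases.
make_manual_network <- function(W, b = NULL, classes = NULL,
                                feature_names = NULL) {
  p <- nrow(W[[1]])
  out_dim <- ncol(W[[length(W)]])
  if (is.null(b)) b <- lapply(W, function(w) rep(0, ncol(w)))
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(p))
  if (is.null(classes)) classes <- paste0("c", seq_len(out_dim))
  structure(list(
    W = W, b = b, activation = "relu", n_hidden = length(W) - 1L,
    feature_names = feature_names, classes = classes,
    center = stats::setNames(rep(0, p), feature_names),
    scale = stats::setNames(rep(1, p), feature_names),
    spec = network_spec(hidden_layers = max(length(W) - 1L, 1L),
                        neurons_per_layer = max(vapply(W, ncol, 1L))),
    log = tibble::tibble(epoch = integer(), train_loss = numeric(),
                         val_accuracy = numeric()),
    best_epoch = 0L, stop_epoch = 0L, stopped_early = FALSE),
    class = "trained_network")
}

random_bias_free_network <- function(p, hidden_dims, out_dim, seed) {
  withr::local_seed(seed)
  dims <- c(p, hidden_dims, out_dim)
  W <- lapply(seq_len(length(dims) - 1L), function(l) {
    matrix(stats::rnorm(dims[l] * dims[l + 1L]), nrow = dims[l])
  })
  make_manual_network(W)
}

feature_tibble <- function(X, feature_names = NULL, ids = NULL) {
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(X)))
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(X)))
  colnames(X) <- feature_names
  dplyr::bind_cols(tibble::tibble(sample_id = ids), tibble::as_tibble(X))
}

# Desk-scale network spec used for synthetic experiments: the 150-feature
# toy problems need far less capacity than the default architecture.
desk_spec <- function(seed = 1L) {
  network_spec(hidden_layers = 2L, neurons_per_layer = 64L,
               learning_rate = 1e-3, seed = seed)
}
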