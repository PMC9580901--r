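# synthetic labeled datasets for classifier tests, bypassing the network
# pipeline: positives shifted by `shift` pooled SDs on every feature
make_shifted_dataset <- function(n_per = 30L, shift = 2, rng_seed = 1L) {
  set.seed(rng_seed)
  X <- matrix(rnorm(2 * n_per * 8), ncol = 8,
              dimnames = list(NULL, feature_names()))
  X[seq_len(n_per), ] <- X[seq_len(n_per), ] + shift
  data <- cbind(
    data.frame(accession = sprintf("S%03d", seq_len(2 * n_per))),
    as.data.frame(X),
    label = rep(c(1L, -1L), each = n_per))
  structure(list(data = data,
                 config = training_config(0.9, 1.0, rng_seed),
                 adr_label = "synthetic"),
            class = "labeled_dataset")
}

permute_labels <- function(ds, rng_seed = 1L) {
  set.seed(rng_seed)
  ds$data$label <- sample(ds$data$label)
  ds
}

small_grids <- list(
  SVM = list(C = c(1, 10), gamma = c(0.01, 0.1)),
  RF  = list(max_features = c(2, 3), depth = c(5, Inf)),
  NN  = list(learning_rate = c(0.01, 0.1), epochs = 100,
             hidden_layers = 1, neurons = 8)
)

# train/test split of a labeled_dataset, stratified
split_dataset <- function(ds, test_frac = 0.3, rng_seed = 1L) {
  set.seed(rng_seed)
  test_idx <- unlist(lapply(c(-1L, 1L), function(cl) {
    idx <- which(ds$data$label == cl)
    sample(idx, max(1L, round(test_frac * length(idx))))
  }))
  train <- ds; train$data <- ds$data[-test_idx, ]
  test <- ds; test$data <- ds$data[test_idx, ]
  list(train = train, test = test)
}
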