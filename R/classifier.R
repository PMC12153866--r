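#' Feed-forward network specification
#'
#' The default values are the selected architecture of the cancer-type
#' classifier: 4 hidden layers of 1024 rectified-linear units, learning rate
#' 0.000195, dropout 1e-6, L2 penalty 0.001, at most 50 epochs with early
#' stopping after 10 stagnant epochs. Optimization uses Adam with seeded
#' mini-batch shuffling (batch size 32); inputs are standardized per feature
#' using training-fold statistics only.
#'
#' @param hidden_layers Number of hidden layers.
#' @param neurons_per_layer Units per hidden layer.
#' @param activation Hidden activation; only `"relu"` is supported.
#' @param learning_rate Adam step size.
#' @param dropout_rate Hidden-layer dropout probability during training.
#' @param l2_penalty L2 weight penalty added to the gradient.
#' @param max_epochs Epoch cap.
#' @param patience Stagnant epochs (no strict improvement of validation
#'   accuracy) tolerated before stopping; must be <= `max_epochs`.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return A `network_spec` list.
#' @export
network_spec <- function(hidden_layers = 4L, neurons_per_layer = 1024L,
                         activation = "relu", learning_rate = 0.000195,
                         dropout_rate = 1e-6, l2_penalty = 0.001,
                         max_epochs = 50L, patience = 10L, batch_size = 32L,
                         seed = 1L) {
  stopifnot(hidden_layers >= 1, neurons_per_layer >= 1,
            learning_rate > 0, dropout_rate > 0, dropout_rate < 1,
            l2_penalty > 0, max_epochs >= 1, patience >= 1,
            patience <= max_epochs, batch_size >= 1)
  if (!identical(activation, "relu")) {
    stop("network_spec(): only the relu activation is supported")
  }
  structure(list(hidden_layers = as.integer(hidden_layers),
                 neurons_per_layer = as.integer(neurons_per_layer),
                 activation = activation, learning_rate = learning_rate,
                 dropout_rate = dropout_rate, l2_penalty = l2_penalty,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "network_spec")
}

#' Stratified k-fold assignments
#'
#' Each class is divided separately into k pieces of (as near as possible)
#' equal size: within a class, fold sizes differ by at most one, and which
#' folds receive the remainder is randomized. Classes with fewer than k
#' samples trigger a warning and leave some folds without that class.
#'
#' @param labels Tibble with `sample_id` and the class column.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param class Name of the class column (default `"cancer_type"`).
#' @return Tibble `sample_id`, `fold` (integer in 1..k).
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L,
                             class = "cancer_type") {
  if (nrow(labels) == 0L) stop("stratified_folds(): empty label set")
  k <- as.integer(k)
  withr::local_seed(seed)
  out <- lapply(split(labels$sample_id, labels[[class]]), function(ids) {
    n <- length(ids)
    if (n < k) {
      warning("stratified_folds(): a class has fewer samples (", n,
              ") than folds (", k, ")")
    }
    sizes <- rep(n %/% k, k)
    extra <- n %% k
    if (extra > 0L) sizes[sample.int(k, extra)] <- n %/% k + 1L
    tibble::tibble(sample_id = sample(ids),
                   fold = rep(seq_len(k), times = sizes))
  })
  dplyr::arrange(dplyr::bind_rows(out),
                 match(.data$sample_id, labels$sample_id))
}

#' Inverse-frequency class weights
#'
#' The weight of a class is the total number of samples divided by the
#' number of samples in the class, so smaller classes weigh more.
#'
#' @param labels Label tibble.
#' @param class Class column name.
#' @return Tibble `class`, `n`, `weight`.
#' @export
class_weights <- function(labels, class = "cancer_type") {
  tab <- dplyr::count(labels, class = .data[[class]])
  if (any(tab$n == 0L)) stop("class_weights(): empty class")
  dplyr::mutate(tab, weight = nrow(labels) / .data$n)
}

# --- internal numerics ------------------------------------------------------

.softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Epoch at which training stops and the epoch whose parameters are kept,
# given the per-epoch validation accuracies so far. "Stagnation" is the lack
# of strict improvement over the running best; after `patience` consecutive
# stagnant epochs training ends and the last improving epoch's parameters
# are restored.
.early_stop <- function(val_acc, patience) {
  best <- -Inf; best_epoch <- 0L; stagnant <- 0L
  for (e in seq_along(val_acc)) {
    if (val_acc[e] > best) {
      best <- val_acc[e]; best_epoch <- e; stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
      if (stagnant >= patience) {
        return(list(stop_epoch = e, best_epoch = best_epoch, stopped = TRUE))
      }
    }
  }
  list(stop_epoch = length(val_acc), best_epoch = best_epoch, stopped = FALSE)
}

.init_params <- function(dims) {
  W <- list(); b <- list()
  for (l in seq_len(length(dims) - 1L)) {
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L],
                                  sd = sqrt(2 / dims[l])),
                     nrow = dims[l])
    b[[l]] <- rep(0, dims[l + 1L])
  }
  list(W = W, b = b)
}

# Forward pass. X: n x p standardized inputs. Returns logits and, if traced,
# the input activations of every affine layer (post-relu for hidden layers).
.forward <- function(params, X, trace = FALSE, dropout = 0, n_hidden) {
  A <- X
  acts <- if (trace) vector("list", length(params$W)) else NULL
  for (l in seq_along(params$W)) {
    if (trace) acts[[l]] <- A
    Z <- A %*% params$W[[l]] + rep(params$b[[l]], each = nrow(A))
    if (l <= n_hidden) {
      A <- pmax(Z, 0)
      if (dropout > 0) {
        mask <- matrix(stats::rbinom(length(A), 1L, 1 - dropout) /
                         (1 - dropout), nrow = nrow(A))
        A <- A * mask
      }
    } else {
      A <- Z
    }
  }
  list(logits = A, acts = acts)
}

#' Train the feed-forward classifier
#'
#' Minimizes class-weighted cross-entropy with an L2 penalty by Adam over
#' seeded mini-batches. If a validation split is given, training stops at
#' `max_epochs` or as soon as the validation accuracy has not strictly
#' improved for `patience` consecutive epochs, restoring the parameters of
#' the last improving epoch. Deterministic for a fixed spec seed.
#'
#' @param features Feature tibble (`sample_id` + numeric columns).
#' @param labels Label tibble (`sample_id` + class column).
#' @param spec A [network_spec()].
#' @param weights Optional tibble from [class_weights()]; `NULL` trains
#'   unweighted.
#' @param validation Optional character vector of validation sample ids
#'   (never used for gradients or standardization).
#' @param class Class column name in `labels`.
#' @return A `trained_network`: per-layer weights/biases, activation spec,
#'   feature names, class labels, standardization parameters, and a
#'   per-epoch training log.
#' @export
fit_network <- function(features, labels, spec = network_spec(),
                        weights = NULL, validation = NULL,
                        class = "cancer_type") {
  stopifnot(inherits(spec, "network_spec"))
  labels <- labels[match(features$sample_id, labels$sample_id), ]
  if (anyNA(labels$sample_id)) {
    stop("fit_network(): features and labels do not align")
  }
  feat_names <- setdiff(names(features), "sample_id")
  classes <- sort(unique(labels[[class]]))
  y_all <- match(labels[[class]], classes)

  is_val <- features$sample_id %in% (validation %||% character(0))
  if (!is.null(validation) && !any(is_val)) {
    stop("fit_network(): no validation ids found among samples")
  }
  Xr <- as.matrix(features[feat_names])
  storage.mode(Xr) <- "double"
  center <- colMeans(Xr[!is_val, , drop = FALSE])
  scale_ <- apply(Xr[!is_val, , drop = FALSE], 2L, stats::sd)
  scale_[scale_ == 0 | is.na(scale_)] <- 1
  X <- sweep(sweep(Xr, 2L, center), 2L, scale_, "/")
  Xtr <- X[!is_val, , drop = FALSE]; ytr <- y_all[!is_val]
  Xva <- X[is_val, , drop = FALSE]; yva <- y_all[is_val]

  wt <- rep(1, length(classes))
  if (!is.null(weights)) {
    wt[match(weights$class, classes)] <- weights$weight
  }
  samp_w <- wt[ytr]
  n_hidden <- spec$hidden_layers
  dims <- c(ncol(X), rep(spec$neurons_per_layer, n_hidden), length(classes))

  withr::local_seed(spec$seed)
  params <- .init_params(dims)
  mom <- lapply(params, function(g) lapply(g, function(x) x * 0))
  vel <- lapply(params, function(g) lapply(g, function(x) x * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0
  n <- nrow(Xtr)
  log_rows <- list(); best_params <- params; val_hist <- numeric(0)

  for (epoch in seq_len(spec$max_epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / spec$batch_size))
    ep_loss <- 0
    for (bi in batches) {
      A <- Xtr[bi, , drop = FALSE]
      acts <- vector("list", length(params$W))
      for (l in seq_along(params$W)) {
        acts[[l]] <- A
        Z <- A %*% params$W[[l]] + rep(params$b[[l]], each = nrow(A))
        if (l <= n_hidden) {
          A <- pmax(Z, 0)
          if (spec$dropout_rate > 0) {
            mask <- matrix(stats::rbinom(length(A), 1L,
                                         1 - spec$dropout_rate) /
                             (1 - spec$dropout_rate), nrow = nrow(A))
            A <- A * mask
          }
        } else A <- Z
      }
      P <- .softmax(A)
      w <- samp_w[bi]
      idx <- cbind(seq_along(bi), ytr[bi])
      loss <- -sum(w * log(pmax(P[idx], 1e-12))) / sum(w)
      if (!is.finite(loss)) stop("fit_network(): non-finite loss at epoch ",
                                 epoch)
      ep_loss <- ep_loss + loss * length(bi)
      # Backward: d(weighted CE)/d logits.
      G <- P
      G[idx] <- G[idx] - 1
      G <- G * (w / sum(w))
      t_step <- t_step + 1
      for (l in rev(seq_along(params$W))) {
        gW <- crossprod(acts[[l]], G) + spec$l2_penalty * params$W[[l]]
        gb <- colSums(G)
        if (l > 1L) {
          G <- (G %*% t(params$W[[l]])) * (acts[[l]] > 0)
        }
        for (nm in c("W", "b")) {
          g <- if (nm == "W") gW else gb
          mom[[nm]][[l]] <- beta1 * mom[[nm]][[l]] + (1 - beta1) * g
          vel[[nm]][[l]] <- beta2 * vel[[nm]][[l]] + (1 - beta2) * g^2
          mhat <- mom[[nm]][[l]] / (1 - beta1^t_step)
          vhat <- vel[[nm]][[l]] / (1 - beta2^t_step)
          params[[nm]][[l]] <- params[[nm]][[l]] -
            spec$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
    }
    val_acc <- NA_real_
    if (nrow(Xva) > 0L) {
      pv <- .forward(params, Xva, n_hidden = n_hidden)$logits
      val_acc <- mean(max.col(pv, ties.method = "first") == yva)
      val_hist <- c(val_hist, val_acc)
      es <- .early_stop(val_hist, spec$patience)
      if (es$best_epoch == epoch) best_params <- params
      log_rows[[epoch]] <- tibble::tibble(epoch = epoch,
                                          train_loss = ep_loss / n,
                                          val_accuracy = val_acc)
      if (es$stopped) break
    } else {
      best_params <- params
      log_rows[[epoch]] <- tibble::tibble(epoch = epoch,
                                          train_loss = ep_loss / n,
                                          val_accuracy = NA_real_)
    }
  }
  log <- dplyr::bind_rows(log_rows)
  es <- if (length(val_hist)) .early_stop(val_hist, spec$patience) else
    list(stop_epoch = nrow(log), best_epoch = nrow(log), stopped = FALSE)
  structure(list(W = best_params$W, b = best_params$b,
                 activation = spec$activation, n_hidden = n_hidden,
                 feature_names = feat_names, classes = classes,
                 center = center, scale = scale_, spec = spec,
                 log = log, best_epoch = es$best_epoch,
                 stop_epoch = es$stop_epoch, stopped_early = es$stopped),
            class = "trained_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @exportS3Method base::print
print.trained_network <- function(x, ...) {
  cat("<trained_network> ", length(x$feature_names), " features -> ",
      x$n_hidden, " x ", ncol(x$W[[1]]), " relu -> ",
      length(x$classes), " classes\n", sep = "")
  if (any(!is.na(x$log$val_accuracy))) {
    cat("  kept epoch ", x$best_epoch, " (val accuracy ",
        signif(x$log$val_accuracy[x$best_epoch], 3), "), stopped after ",
        x$stop_epoch, "\n", sep = "")
  }
  invisible(x)
}

#' Predict classes and probabilities
#'
#' Columns of `newdata` are aligned to the training features by name and
#' standardized with the stored training statistics. Softmax probabilities
#' and the pre-softmax outputs are both returned (the latter are the initial
#' relevance of the LRP backward pass). Ties in the maximal probability are
#' broken toward the lowest class index.
#'
#' @param object A `trained_network`.
#' @param newdata Feature tibble with `sample_id`.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `.pred` (predicted label), `.confidence`
#'   (max probability), one `.p_<class>` probability column and one
#'   `.logit_<class>` pre-softmax column per class.
#' @export
predict.trained_network <- function(object, newdata, ...) {
  miss <- setdiff(object$feature_names, names(newdata))
  if (length(miss)) {
    stop("predict(): missing feature column(s): ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  X <- as.matrix(newdata[object$feature_names])
  storage.mode(X) <- "double"
  X <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  logits <- .forward(object, X, n_hidden = object$n_hidden)$logits
  P <- .softmax(logits)
  pred_i <- max.col(P, ties.method = "first")
  out <- tibble::tibble(sample_id = newdata$sample_id,
                        .pred = object$classes[pred_i],
                        .confidence = P[cbind(seq_len(nrow(P)), pred_i)])
  colnames(P) <- paste0(".p_", object$classes)
  colnames(logits) <- paste0(".logit_", object$classes)
  dplyr::bind_cols(out, tibble::as_tibble(P), tibble::as_tibble(logits))
}

#' Samples predicted with high confidence
#'
#' Returns the ids whose maximal softmax probability is strictly greater
#' than the threshold; these survive into the second, high-confidence
#' training round.
#'
#' @param predictions A prediction tibble from [predict.trained_network()].
#' @param threshold Confidence cutoff (strict).
#' @return Character vector of sample ids.
#' @export
high_confidence_subset <- function(predictions, threshold = 0.9) {
  predictions$sample_id[predictions$.confidence > threshold]
}

#' Stratified cross-validated training
#'
#' Runs the full protocol: stratified folds, per-fold class weights (from the
#' training portion), training with early stopping on the fold's validation
#' samples, and pooled out-of-fold predictions.
#'
#' @inheritParams fit_network
#' @param k Number of folds.
#' @param seed Seed for the fold split; fold f trains with spec seed
#'   `spec$seed + f`.
#' @param weighted Use inverse-frequency class weights (default `TRUE`).
#' @return A `cv_result` list: `predictions` (out-of-fold tibble with a
#'   `fold` column), `models` (list of `trained_network`), `folds`.
#' @export
crossvalidate <- function(features, labels, spec = network_spec(), k = 10L,
                          seed = 1L, weighted = TRUE, class = "cancer_type") {
  folds <- stratified_folds(labels, k = k, seed = seed, class = class)
  models <- vector("list", k)
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    val_ids <- folds$sample_id[folds$fold == f]
    tr_labels <- labels[!labels$sample_id %in% val_ids, ]
    w <- if (weighted) class_weights(tr_labels, class = class) else NULL
    spec_f <- spec
    spec_f$seed <- spec$seed + f
    fit <- fit_network(features, labels, spec = spec_f, weights = w,
                       validation = val_ids, class = class)
    models[[f]] <- fit
    p <- predict(fit, features[features$sample_id %in% val_ids, ])
    p$fold <- f
    preds[[f]] <- p
  }
  structure(list(predictions = dplyr::bind_rows(preds), models = models,
                 folds = folds),
            class = "cv_result")
}

#' @exportS3Method base::print
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", length(x$models), " folds, ",
      nrow(x$predictions), " out-of-fold predictions\n", sep = "")
  invisible(x)
}

#' @rdname fit_network
#' @param x A `trained_network`.
#' @export
tidy.trained_network <- function(x, ...) x$log

#' @rdname fit_network
#' @export
glance.trained_network <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$feature_names),
    n_classes = length(x$classes),
    best_epoch = x$best_epoch,
    stop_epoch = x$stop_epoch,
    stopped_early = x$stopped_early,
    val_accuracy = if (nrow(x$log) && any(!is.na(x$log$val_accuracy)))
      x$log$val_accuracy[x$best_epoch] else NA_real_)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
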