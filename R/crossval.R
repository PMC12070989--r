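# Stratified K-fold cross-validation, grid search, two-phase training.

#' Stratified K-fold split
#'
#' Seeded stratified partition: folds are pairwise disjoint, cover every
#' item, differ in size by at most 1, and each class's items are spread
#' across folds with per-class counts differing by at most 1 (items are
#' shuffled within class and dealt cyclically with a running pointer).
#'
#' @param labels vector of class labels (any type with equality).
#' @param K number of folds (>= 2).
#' @param rng_seed seed.
#' @return An object of class `fold_split`: list with `K` and `fold`, the
#'   0-based fold id of each item.
#' @export
kfold_split <- function(labels, K, rng_seed = 1L) {
  stopifnot(K >= 2)
  n <- length(labels)
  counts <- table(labels)
  if (any(counts < K)) {
    cg_stop("cg_stratification_error",
            "every class needs >= K items; smallest has %d", min(counts))
  }
  fold <- integer(n)
  ptr <- 0L
  for (cls in names(counts)) {
    idx <- which(labels == cls)
    idx <- with_seed(derive_seed(rng_seed, "fold", cls), sample(idx))
    for (i in idx) {
      fold[i] <- ptr %% K
      ptr <- ptr + 1L
    }
  }
  structure(list(K = as.integer(K), fold = fold), class = "fold_split")
}

#' Hyperparameter grid
#'
#' Default grid: hidden dimension in \{32, 64\}, learning rate in
#' \{0.001, 0.01\}, grid-trial epochs in \{10, 20\} (8 combinations).
#'
#' @param hidden_dims,learning_rates,epoch_options non-empty vectors.
#' @return An object of class `hyper_grid`.
#' @export
hyper_grid <- function(hidden_dims = c(32L, 64L),
                       learning_rates = c(0.001, 0.01),
                       epoch_options = c(10L, 20L)) {
  stopifnot(length(hidden_dims) >= 1, length(learning_rates) >= 1,
            length(epoch_options) >= 1)
  structure(list(hidden_dims = as.integer(hidden_dims),
                 learning_rates = learning_rates,
                 epoch_options = as.integer(epoch_options)),
            class = "hyper_grid")
}

grid_combos <- function(grid) {
  expand.grid(epochs = grid$epoch_options,
              learning_rate = grid$learning_rates,
              hidden_dim = grid$hidden_dims)[, c("hidden_dim", "learning_rate", "epochs")]
}

# stratified holdout: returns list(train_idx, val_idx)
stratified_holdout <- function(labels, fraction, rng_seed) {
  val_idx <- integer(0)
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    if (length(idx) < 2) {
      cg_stop("cg_stratification_error",
              "class %s has %d item(s); inner split infeasible", cls, length(idx))
    }
    n_val <- max(1L, round(fraction * length(idx)))
    n_val <- min(n_val, length(idx) - 1L)
    take <- with_seed(derive_seed(rng_seed, "holdout", cls),
                      sample(idx, n_val))
    val_idx <- c(val_idx, take)
  }
  list(train_idx = setdiff(seq_along(labels), val_idx), val_idx = sort(val_idx))
}

item_labels <- function(items) {
  vapply(items, function(it) as.integer(it$label), integer(1))
}

#' Exhaustive grid search on an inner validation split
#'
#' Evaluates every combination in the grid (lexicographic order: hidden
#' dimension, then learning rate, then epochs) by training on a stratified
#' inner split of `train_items` and scoring macro F1 on the inner
#' validation part. The first combination attaining the maximum wins ties.
#'
#' @param train_items list of `list(graph, label)` items covering all classes.
#' @param grid a [hyper_grid()].
#' @param inner_val_fraction stratified inner validation fraction
#'   (default 0.2).
#' @param base_cfg a [train_config()] supplying everything the grid does
#'   not vary (batch size, patience, optimizer, ...).
#' @param rng_seed seed for the split and every trial.
#' @param n_classes number of classes (default inferred).
#' @return List with `best` (named list hidden_dim / learning_rate /
#'   epochs), `scores` (data.frame with one row per combination and its
#'   inner macro F1).
#' @export
grid_search <- function(train_items, grid, inner_val_fraction = 0.2,
                        base_cfg = train_config(), rng_seed = 1L,
                        n_classes = NULL) {
  stopifnot(inherits(grid, "hyper_grid"))
  labels <- item_labels(train_items)
  C <- n_classes %||% (max(labels) + 1L)
  sp <- stratified_holdout(labels, inner_val_fraction, rng_seed)
  inner_tr <- train_items[sp$train_idx]
  inner_va <- train_items[sp$val_idx]
  combos <- grid_combos(grid)
  scores <- numeric(nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    cfg <- base_cfg
    cfg$hidden_dim <- as.integer(combos$hidden_dim[ci])
    cfg$learning_rate <- combos$learning_rate[ci]
    cfg$epochs <- as.integer(combos$epochs[ci])
    cfg$rng_seed <- derive_seed(rng_seed, "trial", ci)
    fit <- gcn_train(inner_tr, inner_va, cfg, n_classes = C)
    pred <- vapply(inner_va, function(it) gcn_predict(fit$params, it$graph),
                   integer(1))
    scores[ci] <- macro_f1(item_labels(inner_va), pred, C)
  }
  best_i <- which.max(scores) # first max wins
  list(best = list(hidden_dim = as.integer(combos$hidden_dim[best_i]),
                   learning_rate = combos$learning_rate[best_i],
                   epochs = as.integer(combos$epochs[best_i])),
       scores = cbind(combos, macro_f1 = scores))
}

#' K-fold cross-validation with per-fold grid search
#'
#' For each fold: grid search on the training portion, final training with
#' the selected hidden dimension and learning rate for `final_epochs`
#' epochs (early stopping on a stratified inner validation split), then
#' evaluation on the held-out fold. Aggregated metrics are means over
#' folds.
#'
#' @param items list of `list(graph, label)` items.
#' @param K folds.
#' @param grid a [hyper_grid()].
#' @param base_cfg a [train_config()].
#' @param rng_seed seed.
#' @param final_epochs training budget for the per-fold final model
#'   (default 100; grid epochs apply to grid-search trials only).
#' @return An object of class `cv_report`: per-fold [classification_report()]s
#'   and chosen hyperparameters, plus aggregate means (`macro_f1`,
#'   `accuracy`, `macro_accuracy`).
#' @export
run_cv <- function(items, K = 5L, grid = hyper_grid(),
                   base_cfg = train_config(), rng_seed = 1L,
                   final_epochs = 100L) {
  labels <- item_labels(items)
  C <- max(labels) + 1L
  split <- kfold_split(labels, K, derive_seed(rng_seed, "kfold"))
  folds <- vector("list", K)
  for (f in 0:(K - 1)) {
    te_idx <- which(split$fold == f)
    tr_idx <- which(split$fold != f)
    tr_items <- items[tr_idx]
    gs <- grid_search(tr_items, grid, 0.2, base_cfg,
                      derive_seed(rng_seed, "grid", f), n_classes = C)
    cfg <- base_cfg
    cfg$hidden_dim <- gs$best$hidden_dim
    cfg$learning_rate <- gs$best$learning_rate
    cfg$epochs <- as.integer(final_epochs)
    cfg$rng_seed <- derive_seed(rng_seed, "final", f)
    sp <- stratified_holdout(item_labels(tr_items), 0.2,
                             derive_seed(rng_seed, "finalval", f))
    fit <- gcn_train(tr_items[sp$train_idx], tr_items[sp$val_idx], cfg,
                     n_classes = C)
    te_items <- items[te_idx]
    pred <- vapply(te_items, function(it) gcn_predict(fit$params, it$graph),
                   integer(1))
    probs <- do.call(rbind, lapply(te_items, function(it) {
      gcn_forward(fit$params, it$graph)$probs
    }))
    rep_f <- classification_report(item_labels(te_items), pred, probs, C)
    folds[[f + 1]] <- list(fold = f, hyperparams = gs$best,
                           grid_scores = gs$scores, report = rep_f,
                           test_idx = te_idx)
  }
  agg <- list(
    macro_f1 = mean(vapply(folds, function(x) x$report$macro$f1, numeric(1))),
    accuracy = mean(vapply(folds, function(x) x$report$accuracy, numeric(1))),
    macro_accuracy = mean(vapply(folds, function(x) x$report$macro$accuracy,
                                 numeric(1))))
  structure(list(K = as.integer(K), folds = folds, aggregate = agg,
                 split = split), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report K=%d: mean macro F1 %.4f, mean accuracy %.4f>\n",
              x$K, x$aggregate$macro_f1, x$aggregate$accuracy))
  invisible(x)
}

#' Serialize a CV report as JSON
#'
#' @param report a `cv_report`.
#' @param path output path.
#' @export
write_cv_report <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  payload <- list(
    K = report$K,
    aggregate = report$aggregate,
    folds = lapply(report$folds, function(f) {
      list(fold = f$fold, hyperparams = f$hyperparams,
           macro_f1 = f$report$macro$f1, accuracy = f$report$accuracy,
           per_class = f$report$per_class,
           confusion = f$report$confusion)
    }))
  jsonlite::write_json(payload, path, digits = 10, auto_unbox = TRUE)
  invisible(path)
}

#' Fine-tuning phase
#'
#' Continues training warm-started parameters at a (typically lower)
#' learning rate with patience-based early stopping; parameters only change
#' if an epoch improves on the warm start's validation loss, so the
#' fine-tuned validation loss never worsens.
#'
#' @param params trained [gcn_params()].
#' @param train_set,val_set item lists.
#' @param cfg a [train_config()] holding the fine-tuning rate, budget and
#'   patience.
#' @return List with `params` and `history` as in [gcn_train()].
#' @export
fine_tune <- function(params, train_set, val_set, cfg) {
  stopifnot(inherits(params, "gcn_params"))
  pre <- evaluate_items(params, prepare_items(val_set, params$scaler))
  gcn_train(train_set, val_set, cfg, params = params,
            n_classes = params$n_classes, baseline_val_loss = pre$loss)
}
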