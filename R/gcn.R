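# Two-layer graph convolutional classifier, written from scratch.
#
# Propagation operator: Ahat = D^{-1/2} (A + I) D^{-1/2} with edge weights
# in A and unit self-loops. Forward pass:
#   H1 = ReLU(Ahat X W1), H2 = ReLU(Ahat H1 W2),
#   hg = mean over nodes of H2, logits = hg Wc + bc, p = softmax(logits).
# Per-layer biases are omitted (W-only layers); the classifier head has a
# bias. Training is mini-batch Adam (or plain SGD) on the mean multi-class
# cross-entropy, with patience-based early stopping on validation loss and
# best-epoch parameter restoration.

#' Training configuration for the GCN
#'
#' @param hidden_dim width of both hidden layers.
#' @param learning_rate optimizer step size.
#' @param epochs maximum epochs.
#' @param batch_size graphs per gradient step (default 8).
#' @param patience early-stopping patience in epochs (default 3).
#' @param rng_seed seed controlling initialization and batch shuffling.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param standardize z-score node features using statistics pooled over
#'   the training set (stored with the parameters and re-applied at
#'   prediction time). Raw region features span several orders of magnitude,
#'   which saturates ReLU/softmax otherwise.
#' @return An object of class `train_config`.
#' @export
train_config <- function(hidden_dim = 32L, learning_rate = 0.001,
                         epochs = 100L, batch_size = 8L, patience = 3L,
                         rng_seed = 1L, optimizer = c("adam", "sgd"),
                         standardize = TRUE) {
  optimizer <- match.arg(optimizer)
  stopifnot(hidden_dim >= 1, learning_rate >= 0, epochs >= 1,
            batch_size >= 1, patience >= 1)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 rng_seed = as.integer(rng_seed), optimizer = optimizer,
                 standardize = standardize),
            class = "train_config")
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Initialize GCN parameters
#'
#' Glorot-uniform weight matrices `W1 (F x F')`, `W2 (F' x F'')`,
#' `Wc (F'' x C)` and zero classifier bias, seeded.
#'
#' @param feature_dim input feature dimension `F` (14 for lesion graphs).
#' @param hidden_dim hidden width (`F' = F''`).
#' @param n_classes number of classes `C`.
#' @param rng_seed seed.
#' @return An object of class `gcn_params`.
#' @export
gcn_init <- function(feature_dim, hidden_dim, n_classes, rng_seed = 1L) {
  with_seed(rng_seed, {
    structure(list(W1 = glorot(feature_dim, hidden_dim),
                   W2 = glorot(hidden_dim, hidden_dim),
                   Wc = glorot(hidden_dim, n_classes),
                   bc = numeric(n_classes),
                   feature_dim = as.integer(feature_dim),
                   hidden_dim = as.integer(hidden_dim),
                   n_classes = as.integer(n_classes),
                   scaler = NULL),
              class = "gcn_params")
  })
}

#' Symmetrically normalized adjacency with self-loops
#'
#' `Ahat = D^{-1/2} (A + I) D^{-1/2}` where `A` holds the edge weights
#' (0 where no edge) and each node gets a unit self-loop.
#'
#' @param graph a [lesion_graph()].
#' @return Dense symmetric `n x n` matrix.
#' @export
normalized_adjacency <- function(graph) {
  stopifnot(inherits(graph, "lesion_graph"))
  n <- nrow(graph$nodes)
  A <- matrix(0, n, n)
  if (nrow(graph$edges) > 0) {
    A[cbind(graph$edges$i, graph$edges$j)] <- graph$edges$weight
    A[cbind(graph$edges$j, graph$edges$i)] <- graph$edges$weight
  }
  At <- A + diag(n)
  dinv <- 1 / sqrt(rowSums(At))
  At * outer(dinv, dinv)
}

apply_scaler <- function(X, scaler) {
  if (is.null(scaler)) return(X)
  sweep(sweep(X, 2, scaler$mean), 2, scaler$sd, "/")
}

# Forward pass on precomputed (Ahat, X); returns intermediates for backprop.
gcn_forward_core <- function(params, Ahat, X) {
  AX <- Ahat %*% X
  Z1 <- AX %*% params$W1
  H1 <- pmax(Z1, 0)
  M <- Ahat %*% H1
  Z2 <- M %*% params$W2
  H2 <- pmax(Z2, 0)
  hg <- colMeans(H2)
  logits <- drop(crossprod(params$Wc, hg)) + params$bc
  s <- logits - max(logits)
  e <- exp(s)
  probs <- e / sum(e)
  list(AX = AX, Z1 = Z1, M = M, Z2 = Z2, hg = hg,
       logits = logits, probs = probs)
}

#' GCN forward pass
#'
#' @param params a [gcn_params()] object.
#' @param graph a [lesion_graph()] whose feature dimension matches `W1`.
#' @return List with `logits` and `probs` (each length `C`; probabilities
#'   sum to 1).
#' @export
gcn_forward <- function(params, graph) {
  stopifnot(inherits(params, "gcn_params"))
  X <- unname(as.matrix(graph$nodes[, cg_feature_names]))
  if (ncol(X) != params$feature_dim) {
    cg_stop("cg_shape_error", "feature dimension %d does not match W1 (%d)",
            ncol(X), params$feature_dim)
  }
  fw <- gcn_forward_core(params, normalized_adjacency(graph),
                         apply_scaler(X, params$scaler))
  list(logits = fw$logits, probs = fw$probs)
}

#' Predicted class of a graph
#'
#' Argmax of the class probabilities; ties break toward the lowest class
#' index. Classes are 0-based.
#'
#' @inheritParams gcn_forward
#' @return Integer class index in `[0, C)`.
#' @export
gcn_predict <- function(params, graph) {
  p <- gcn_forward(params, graph)$probs
  which.max(p) - 1L
}

#' Mean multi-class cross-entropy
#'
#' `L = -(1/N) sum_i log p_i[y_i]`, with predicted probabilities floored at
#' `1e-12` for numeric stability.
#'
#' @param probs numeric matrix (`N x C`) of predicted class probabilities,
#'   or a single probability vector.
#' @param labels integer vector of 0-based true classes.
#' @return Non-negative scalar loss.
#' @export
cross_entropy <- function(probs, labels) {
  if (is.vector(probs)) probs <- matrix(probs, nrow = 1)
  stopifnot(nrow(probs) == length(labels),
            all(labels >= 0), all(labels < ncol(probs)))
  p_true <- probs[cbind(seq_len(nrow(probs)), labels + 1L)]
  mean(-log(pmax(p_true, 1e-12)))
}

# gradient of the per-graph cross-entropy w.r.t. all parameter tensors
gcn_backward_core <- function(params, Ahat, X, fw, label) {
  n <- nrow(X)
  dl <- fw$probs
  dl[label + 1L] <- dl[label + 1L] - 1 # d loss / d logits
  dWc <- outer(fw$hg, dl)
  dbc <- dl
  dhg <- drop(params$Wc %*% dl)
  dH2 <- matrix(rep(dhg / n, each = n), n)
  dZ2 <- dH2 * (fw$Z2 > 0)
  dW2 <- crossprod(fw$M, dZ2)
  dH1 <- Ahat %*% dZ2 %*% t(params$W2)
  dZ1 <- dH1 * (fw$Z1 > 0)
  dW1 <- crossprod(fw$AX, dZ1)
  list(W1 = dW1, W2 = dW2, Wc = dWc, bc = dbc)
}

prepare_items <- function(items, scaler) {
  lapply(items, function(it) {
    X <- unname(as.matrix(it$graph$nodes[, cg_feature_names]))
    list(Ahat = normalized_adjacency(it$graph),
         X = apply_scaler(X, scaler), label = as.integer(it$label))
  })
}

fit_scaler <- function(items) {
  X <- do.call(rbind, lapply(items, function(it) {
    as.matrix(it$graph$nodes[, cg_feature_names])
  }))
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mean = unname(colMeans(X)), sd = unname(sdv))
}

adam_state <- function(params) {
  lapply(params[c("W1", "W2", "Wc", "bc")], function(p) {
    list(m = p * 0, v = p * 0)
  })
}

#' Train the GCN
#'
#' Mini-batch gradient descent on the cross-entropy loss with the
#' configured optimizer. Validation loss is monitored every epoch; training
#' halts when it fails to improve for `cfg$patience` consecutive epochs and
#' the parameters from the best validation epoch are restored. Fully
#' deterministic for a fixed `cfg$rng_seed`.
#'
#' @param train_set,val_set lists of items `list(graph = <lesion_graph>,
#'   label = <0-based integer>)`; `train_set` must cover at least 2 classes.
#' @param cfg a [train_config()].
#' @param params optional warm-start [gcn_params()] (used by fine-tuning);
#'   when supplied, its scaler is kept.
#' @param n_classes number of classes; default is inferred from the labels.
#' @param baseline_val_loss validation loss the warm-start parameters must
#'   beat before a checkpoint replaces them (used by [fine_tune()] to
#'   guarantee non-worsening; default `Inf`).
#' @return List with `params` (best-epoch [gcn_params()]) and `history`
#'   (data.frame with columns epoch, ATL, ATA, AVL, AVA: training/validation
#'   loss and accuracy-in-percent per epoch) plus `best_epoch` and
#'   `epochs_run` attributes on the history.
#' @export
gcn_train <- function(train_set, val_set, cfg, params = NULL, n_classes = NULL,
                      baseline_val_loss = Inf) {
  stopifnot(inherits(cfg, "train_config"),
            length(train_set) >= 1, length(val_set) >= 1)
  tr_labels <- vapply(train_set, function(it) as.integer(it$label), integer(1))
  if (length(unique(tr_labels)) < 2) {
    cg_stop("cg_training_error", "training set must cover at least 2 classes")
  }
  C <- n_classes %||% (max(c(tr_labels,
                             vapply(val_set, function(it) as.integer(it$label),
                                    integer(1)))) + 1L)
  Fdim <- length(cg_feature_names)
  if (is.null(params)) {
    params <- gcn_init(Fdim, cfg$hidden_dim, C, derive_seed(cfg$rng_seed, "init"))
    if (cfg$standardize) params$scaler <- fit_scaler(train_set)
  }
  tr <- prepare_items(train_set, params$scaler)
  va <- prepare_items(val_set, params$scaler)
  n_tr <- length(tr)
  opt <- adam_state(params)
  t_step <- 0
  b1 <- 0.9; b2 <- 0.999; eps_adam <- 1e-8
  hist_rows <- vector("list", cfg$epochs)
  best <- list(loss = baseline_val_loss, params = params, epoch = 0L)
  stall <- 0
  epochs_run <- 0
  for (epoch in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$rng_seed, "shuffle", epoch), sample.int(n_tr))
    tr_loss <- 0; tr_correct <- 0
    for (bstart in seq(1, n_tr, by = cfg$batch_size)) {
      batch <- ord[bstart:min(bstart + cfg$batch_size - 1, n_tr)]
      grads <- NULL
      for (k in batch) {
        it <- tr[[k]]
        fw <- gcn_forward_core(params, it$Ahat, it$X)
        g <- gcn_backward_core(params, it$Ahat, it$X, fw, it$label)
        tr_loss <- tr_loss + (-log(max(fw$probs[it$label + 1L], 1e-12)))
        tr_correct <- tr_correct + (which.max(fw$probs) - 1L == it$label)
        if (is.null(grads)) grads <- g else {
          for (nm in names(g)) grads[[nm]] <- grads[[nm]] + g[[nm]]
        }
      }
      nb <- length(batch)
      t_step <- t_step + 1
      for (nm in names(grads)) {
        g <- grads[[nm]] / nb
        if (cfg$optimizer == "adam") {
          opt[[nm]]$m <- b1 * opt[[nm]]$m + (1 - b1) * g
          opt[[nm]]$v <- b2 * opt[[nm]]$v + (1 - b2) * g^2
          mhat <- opt[[nm]]$m / (1 - b1^t_step)
          vhat <- opt[[nm]]$v / (1 - b2^t_step)
          params[[nm]] <- params[[nm]] - cfg$learning_rate * mhat / (sqrt(vhat) + eps_adam)
        } else {
          params[[nm]] <- params[[nm]] - cfg$learning_rate * g
        }
      }
    }
    tr_loss <- tr_loss / n_tr
    val <- evaluate_items(params, va)
    epochs_run <- epoch
    hist_rows[[epoch]] <- data.frame(
      epoch = epoch, ATL = tr_loss, ATA = 100 * tr_correct / n_tr,
      AVL = val$loss, AVA = 100 * val$acc)
    if (!is.finite(tr_loss) || !is.finite(val$loss)) {
      history <- do.call(rbind, hist_rows[seq_len(epochs_run)])
      cond <- structure(
        class = c("cg_training_error", "cervigraph_error", "error", "condition"),
        list(message = "training diverged (non-finite loss)", history = history))
      stop(cond)
    }
    if (val$loss < best$loss - 1e-12) {
      best <- list(loss = val$loss, params = params, epoch = epoch)
      stall <- 0
    } else {
      stall <- stall + 1
      if (stall >= cfg$patience) break
    }
  }
  history <- do.call(rbind, hist_rows[seq_len(epochs_run)])
  attr(history, "best_epoch") <- best$epoch
  attr(history, "epochs_run") <- epochs_run
  list(params = best$params, history = history)
}

# mean loss and accuracy over prepared items
evaluate_items <- function(params, items) {
  loss <- 0; correct <- 0
  for (it in items) {
    fw <- gcn_forward_core(params, it$Ahat, it$X)
    loss <- loss + (-log(max(fw$probs[it$label + 1L], 1e-12)))
    correct <- correct + (which.max(fw$probs) - 1L == it$label)
  }
  list(loss = loss / length(items), acc = correct / length(items))
}

#' Save / load GCN parameters as JSON
#'
#' Versioned plain-JSON checkpoint with shapes and the feature scaler.
#'
#' @param params a [gcn_params()].
#' @param path file path.
#' @return `load_gcn_params` returns a [gcn_params()].
#' @export
save_gcn_params <- function(params, path) {
  stopifnot(inherits(params, "gcn_params"))
  payload <- list(version = 1L,
                  feature_dim = params$feature_dim,
                  hidden_dim = params$hidden_dim,
                  n_classes = params$n_classes,
                  W1 = params$W1, W2 = params$W2, Wc = params$Wc, bc = params$bc,
                  scaler = params$scaler)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_gcn_params
#' @export
load_gcn_params <- function(path) {
  p <- jsonlite::fromJSON(path)
  out <- structure(list(
    W1 = matrix(p$W1, nrow = p$feature_dim),
    W2 = matrix(p$W2, nrow = p$hidden_dim),
    Wc = matrix(p$Wc, nrow = p$hidden_dim),
    bc = as.numeric(p$bc),
    feature_dim = as.integer(p$feature_dim),
    hidden_dim = as.integer(p$hidden_dim),
    n_classes = as.integer(p$n_classes),
    scaler = if (is.null(p$scaler)) NULL else {
      list(mean = as.numeric(p$scaler$mean), sd = as.numeric(p$scaler$sd))
    }), class = "gcn_params")
  out
}
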