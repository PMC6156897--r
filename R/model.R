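#' Network architecture configuration
#'
#' The classifier is a fully connected feed-forward network with ReLU hidden
#' units and a 2-way softmax output. The reference architecture for the full
#' 978-feature landmark panel is `c(1956, 200, 10, 2)`: a 1956-neuron input
#' layer (two fused 978-feature profiles), hidden layers of 200 and 10
#' neurons, and the softmax layer. Dropout (inverted scaling) is applied to
#' the hidden activations during training only.
#'
#' @param layer_sizes Integer vector of layer widths; the first entry must
#'   equal the fused input width (2n) and the last must be 2.
#' @param dropout_rate Probability in `[0, 1)` of dropping a hidden unit
#'   during training (default 0.5).
#' @return A `network_config` list.
#' @export
network_config <- function(layer_sizes = c(1956L, 200L, 10L, 2L),
                           dropout_rate = 0.5) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2) abort("need at least input and output layers")
  if (layer_sizes[length(layer_sizes)] != 2L) {
    abort("output layer must have 2 units (binary softmax)")
  }
  if (any(layer_sizes < 1)) abort("layer sizes must be positive")
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort("`dropout_rate` must be in [0, 1)")
  }
  structure(list(layer_sizes = layer_sizes, dropout_rate = dropout_rate),
            class = "network_config")
}

#' Training configuration
#'
#' @param eta Nonnegative weight of the negative-class penalty in the
#'   objective (default 10). See [penalized_loss()].
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param epochs Maximum training epochs (default 200).
#' @param batch_size Minibatch size (default 128).
#' @param seed Integer seed controlling initialization, shuffling and dropout.
#' @param prob_floor Probability clip for logs and logits (default 1e-7).
#' @param patience Early-stopping patience in epochs on validation loss when
#'   validation data is supplied (default 20); `Inf` disables early stopping.
#' @return A `train_config` list.
#' @export
train_config <- function(eta = 10, learning_rate = 1e-4, epochs = 200L,
                         batch_size = 128L, seed = 1L, prob_floor = 1e-7,
                         patience = 20L) {
  if (eta < 0) abort("`eta` must be nonnegative")
  if (learning_rate <= 0) abort("`learning_rate` must be positive")
  if (epochs < 1 || batch_size < 1) abort("`epochs` and `batch_size` must be positive")
  if (prob_floor <= 0 || prob_floor >= 0.5) abort("`prob_floor` must be in (0, 0.5)")
  structure(
    list(eta = eta, learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), seed = as.integer(seed),
         prob_floor = prob_floor, patience = patience),
    class = "train_config"
  )
}

# He-scaled random init for ReLU layers; weights W[[l]] are out x in
nn_init <- function(net) {
  sizes <- net$layer_sizes
  n_layers <- length(sizes) - 1L
  weights <- vector("list", n_layers)
  biases <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    weights[[l]] <- matrix(rnorm(sizes[l + 1] * sizes[l], sd = sqrt(2 / sizes[l])),
                           nrow = sizes[l + 1])
    biases[[l]] <- numeric(sizes[l + 1])
  }
  list(weights = weights, biases = biases)
}

# numerically stable row-wise softmax (max subtraction)
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass of the classifier
#'
#' Propagates a batch of fused sample vectors through the network: affine map
#' then ReLU at each hidden layer, softmax (computed with max subtraction) at
#' the output. With `train_mode = TRUE` inverted dropout masks are sampled
#' for the hidden activations; with `train_mode = FALSE` the pass is
#' deterministic and unscaled.
#'
#' @param params List with `weights` and `biases` per layer (as stored in a
#'   fitted `dti_dnn`).
#' @param x Numeric matrix, one row per sample, width = input layer size.
#' @param net A [network_config()].
#' @param train_mode Logical; sample dropout masks?
#' @return List with `prob` (m x 2 class-probability matrix whose rows sum to
#'   1) and, for backpropagation, the per-layer activations and masks.
#' @export
nn_forward <- function(params, x, net, train_mode = FALSE) {
  x <- as.matrix(x)
  if (ncol(x) != net$layer_sizes[1]) {
    abort(paste0("input width ", ncol(x), " does not match input layer ",
                 net$layer_sizes[1]))
  }
  n_layers <- length(params$weights)
  activations <- vector("list", n_layers + 1L)
  masks <- vector("list", n_layers)
  activations[[1]] <- x
  a <- x
  for (l in seq_len(n_layers - 1L)) {
    z <- a %*% t(params$weights[[l]])
    z <- sweep(z, 2, params$biases[[l]], "+")
    a <- pmax(z, 0)
    if (train_mode && net$dropout_rate > 0) {
      keep <- matrix(runif(length(a)) >= net$dropout_rate, nrow = nrow(a))
      a <- a * keep / (1 - net$dropout_rate)
      masks[[l]] <- keep
    }
    activations[[l + 1L]] <- a
  }
  logits <- sweep(a %*% t(params$weights[[n_layers]]), 2,
                  params$biases[[n_layers]], "+")
  prob <- softmax_rows(logits)
  activations[[n_layers + 1L]] <- prob
  list(prob = prob, activations = activations, masks = masks)
}

#' Penalized cross-entropy objective
#'
#' The training objective is binary cross-entropy on the positive-class
#' probability, minus an L1 reward on the negative-class probability of the
#' true negative samples:
#' \deqn{J = \frac{1}{m}\Big[\sum_i -y_i \ln p_{i,1} - (1-y_i)\ln(1-p_{i,1})
#'   \;-\; \eta \sum_{i \in \mathrm{neg}} p_{i,0}\Big]}
#' The subtracted term rewards confident negative-class probability on true
#' negatives, pushing the decision boundary toward the positive cluster; with
#' `eta = 0` the objective reduces to plain cross-entropy. Because the
#' penalty is subtracted the objective can be negative. Probabilities are
#' clipped to `[prob_floor, 1 - prob_floor]` inside the logarithms.
#'
#' @param prob m x 2 class-probability matrix (columns: negative, positive).
#' @param labels Integer vector in `{0, 1}` (1 = positive).
#' @param eta Nonnegative penalty weight.
#' @param prob_floor Clip for the logs (default 1e-7).
#' @return The scalar objective value.
#' @export
penalized_loss <- function(prob, labels, eta, prob_floor = 1e-7) {
  prob <- as.matrix(prob)
  if (!all(labels %in% c(0, 1))) abort("labels must be 0 or 1")
  if (nrow(prob) != length(labels)) abort("labels not aligned with probabilities")
  p1 <- pmin(pmax(prob[, 2], prob_floor), 1 - prob_floor)
  ce <- -labels * log(p1) - (1 - labels) * log(1 - p1)
  penalty <- eta * sum(prob[labels == 0, 1])
  (sum(ce) - penalty) / length(labels)
}

# gradient of the per-sample objective w.r.t. output logits (before 1/m):
#   positive: p - (0, 1)
#   negative: d/dz [-ln p0 - eta * p0] = (p0 - 1 - eta*p0*p1, p1 + eta*p0*p1)
loss_logit_grad <- function(prob, labels, eta) {
  g <- prob
  pos <- labels == 1
  g[pos, 2] <- g[pos, 2] - 1
  p0 <- prob[!pos, 1]
  p1 <- prob[!pos, 2]
  g[!pos, 1] <- p0 - 1 - eta * p0 * p1
  g[!pos, 2] <- p1 + eta * p0 * p1
  g
}

# full backprop through the cached forward pass; returns mean gradients
nn_gradient <- function(params, fwd, labels, eta) {
  m <- nrow(fwd$prob)
  n_layers <- length(params$weights)
  dW <- vector("list", n_layers)
  db <- vector("list", n_layers)
  delta <- loss_logit_grad(fwd$prob, labels, eta) / m
  for (l in rev(seq_len(n_layers))) {
    a_prev <- fwd$activations[[l]]
    dW[[l]] <- t(delta) %*% a_prev
    db[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- delta %*% params$weights[[l]]
      if (!is.null(fwd$masks[[l - 1L]])) {
        delta <- delta * fwd$masks[[l - 1L]] / (1 - attr(fwd, "dropout_rate"))
      }
      delta <- delta * (fwd$activations[[l]] > 0)
    }
  }
  list(weights = dW, biases = db)
}

#' Train the drug-target interaction classifier
#'
#' Fits the feed-forward network on fused samples by minibatch Adam on the
#' penalized cross-entropy objective of [penalized_loss()]. Layers are
#' randomly initialized (He scaling for ReLU) from the seed; the same seed
#' and data reproduce identical final weights on one thread. When validation
#' data is supplied, per-epoch validation loss/accuracy are recorded and
#' early stopping (patience from the [train_config()]) restores the best
#' validation-loss weights.
#'
#' @param x Numeric matrix of fused training samples (rows = samples).
#' @param labels Integer labels in `{0, 1}` (1 = positive interaction).
#' @param net A [network_config()]; input size must match `ncol(x)`.
#' @param tc A [train_config()].
#' @param x_val,labels_val Optional validation set.
#' @return A fitted `dti_dnn` object: `params` (weights/biases), `net`, `tc`
#'   and a per-epoch `history` tibble (`epoch`, `loss`, `train_accuracy`,
#'   `val_loss`, `val_accuracy`).
#' @export
train_dnn <- function(x, labels, net, tc = train_config(),
                      x_val = NULL, labels_val = NULL) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  if (!all(labels %in% 0:1)) abort("labels must be 0 or 1")
  if (length(unique(labels)) < 2) abort("training fold has a single class")
  has_val <- !is.null(x_val)
  if (has_val) x_val <- as.matrix(x_val)

  withr::with_seed(tc$seed, {
    params <- nn_init(net)
    adam <- adam_state(params)
    step <- 0L
    best <- list(loss = Inf, params = params, epoch = 0L)
    wait <- 0L
    hist <- vector("list", tc$epochs)

    for (epoch in seq_len(tc$epochs)) {
      idx <- sample.int(nrow(x))
      for (start in seq(1L, length(idx), by = tc$batch_size)) {
        b <- idx[start:min(start + tc$batch_size - 1L, length(idx))]
        fwd <- nn_forward(params, x[b, , drop = FALSE], net, train_mode = TRUE)
        attr(fwd, "dropout_rate") <- net$dropout_rate
        g <- nn_gradient(params, fwd, labels[b], tc$eta)
        step <- step + 1L
        upd <- adam_update(adam, params, g, tc$learning_rate, step)
        params <- upd$params
        adam <- upd$state
      }
      train_prob <- nn_forward(params, x, net)$prob
      row <- tibble(
        epoch = epoch,
        loss = penalized_loss(train_prob, labels, tc$eta, tc$prob_floor),
        train_accuracy = mean((train_prob[, 2] > 0.5) == (labels == 1)),
        val_loss = NA_real_, val_accuracy = NA_real_
      )
      if (has_val) {
        val_prob <- nn_forward(params, x_val, net)$prob
        row$val_loss <- penalized_loss(val_prob, labels_val, tc$eta, tc$prob_floor)
        row$val_accuracy <- mean((val_prob[, 2] > 0.5) == (labels_val == 1))
        if (row$val_loss < best$loss) {
          best <- list(loss = row$val_loss, params = params, epoch = epoch)
          wait <- 0L
        } else {
          wait <- wait + 1L
        }
      }
      hist[[epoch]] <- row
      if (has_val && is.finite(tc$patience) && wait >= tc$patience) break
    }

    if (has_val && is.finite(best$loss)) params <- best$params
    structure(
      list(params = params, net = net, tc = tc,
           history = dplyr::bind_rows(hist)),
      class = "dti_dnn"
    )
  })
}

adam_state <- function(params) {
  zero <- function(p) lapply(p, function(w) w * 0)
  list(mw = zero(params$weights), vw = zero(params$weights),
       mb = zero(params$biases), vb = zero(params$biases))
}

adam_update <- function(state, params, grad, lr, step,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^step
  c2 <- 1 - beta2^step
  for (l in seq_along(params$weights)) {
    state$mw[[l]] <- beta1 * state$mw[[l]] + (1 - beta1) * grad$weights[[l]]
    state$vw[[l]] <- beta2 * state$vw[[l]] + (1 - beta2) * grad$weights[[l]]^2
    params$weights[[l]] <- params$weights[[l]] -
      lr * (state$mw[[l]] / c1) / (sqrt(state$vw[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grad$biases[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grad$biases[[l]]^2
    params$biases[[l]] <- params$biases[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(params = params, state = state)
}

#' Predict class probabilities for fused samples
#'
#' Deterministic inference pass (dropout off). Rows of the returned
#' classification matrix sum to 1.
#'
#' @param object A fitted `dti_dnn`.
#' @param newdata Numeric matrix of fused samples.
#' @param ... Unused.
#' @return Tibble with columns `p_negative`, `p_positive`.
#' @export
predict.dti_dnn <- function(object, newdata, ...) {
  prob <- nn_forward(object$params, as.matrix(newdata), object$net)$prob
  tibble(p_negative = prob[, 1], p_positive = prob[, 2])
}

#' Predict class probabilities for drug-gene pairs
#'
#' Fuses every credible-row combination of each requested pair, runs
#' inference, and averages the class probabilities over the combinations so
#' that each (drug, gene) pair receives one classification-matrix row.
#'
#' @param model A fitted `dti_dnn`.
#' @param pool The [build_sample_pool()] the model was trained from.
#' @param pairs Tibble with `drug_id`, `gene_id` (defaults to the pool's
#'   unlabeled pairs -- the prediction universe).
#' @return Tibble `drug_id`, `gene_id`, `p_negative`, `p_positive`.
#' @export
predict_pairs <- function(model, pool, pairs = pool$unlabeled) {
  keys <- expand_pairs(pool, pairs)
  cm <- predict(model, pool_features(pool, keys))
  out <- dplyr::summarise(
    dplyr::group_by(dplyr::bind_cols(keys, cm), .data$drug_id, .data$gene_id),
    p_negative = mean(.data$p_negative),
    p_positive = mean(.data$p_positive),
    .groups = "drop"
  )
  # restore the request order
  out[match(paste(pairs$drug_id, pairs$gene_id),
            paste(out$drug_id, out$gene_id)), ]
}

#' @describeIn train_dnn Per-layer weight summary of a fitted network.
#' @param x,object A fitted `dti_dnn`.
#' @param ... Unused.
#' @export
#' @method tidy dti_dnn
tidy.dti_dnn <- function(x, ...) {
  sizes <- x$net$layer_sizes
  tibble(
    layer = seq_along(x$params$weights),
    input_dim = sizes[-length(sizes)],
    output_dim = sizes[-1],
    n_parameters = vapply(seq_along(x$params$weights), function(l) {
      length(x$params$weights[[l]]) + length(x$params$biases[[l]])
    }, integer(1)),
    weight_mean = vapply(x$params$weights, mean, numeric(1)),
    weight_sd = vapply(x$params$weights, stats::sd, numeric(1))
  )
}

#' @describeIn train_dnn One-row fit summary (final epoch of the history).
#' @export
#' @method glance dti_dnn
glance.dti_dnn <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble(
    epochs_trained = nrow(x$history),
    loss = last$loss,
    train_accuracy = last$train_accuracy,
    val_loss = last$val_loss,
    val_accuracy = last$val_accuracy
  )
}

#' @describeIn train_dnn Training-history curves (loss and accuracies).
#' @export
#' @method autoplot dti_dnn
autoplot.dti_dnn <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "metric", values_to = "value")
  h <- h[!is.na(h$value), ]
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}
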