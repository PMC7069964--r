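# Feed-forward neural classifiers, written directly in base R matrix
# algebra: a unimodal network per data modality (expression, clinical) and
# a bimodal network that concatenates the final hidden layers of the two
# branches and stacks further hidden layers before a logistic output.
# Training minimizes binary cross-entropy plus an L2 weight penalty with
# the Nadam optimizer, mini-batches, and early stopping on validation
# loss with best-epoch weight restoration. Everything is deterministic
# given the seeds, which makes training reproducible bit for bit.

#' Specification of one network branch
#'
#' @param input_dim number of input features.
#' @param hidden_widths hidden-layer widths (default four layers of 40).
#' @param activation hidden activation; only `"relu"` is supported.
#' @param l2_penalty L2 coefficient on weight matrices (default 1e-4).
#' @param seed seed for weight initialization.
#' @return object of class `branch_spec`.
#' @export
branch_spec <- function(input_dim, hidden_widths = c(40, 40, 40, 40),
                        activation = "relu", l2_penalty = 1e-4, seed = 1L) {
  if (input_dim < 1L) stopf("input_dim must be positive")
  if (length(hidden_widths) == 0L || any(hidden_widths < 1L)) {
    stopf("hidden_widths must be a non-empty vector of positive widths")
  }
  if (!identical(activation, "relu")) stopf("only 'relu' activation is supported")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_widths = as.integer(hidden_widths),
                 activation = activation, l2_penalty = l2_penalty,
                 seed = as.integer(seed)),
            class = "branch_spec")
}

#' Specification of the bimodal (integrative) network
#'
#' The two branch networks are merged by concatenating their final hidden
#' layers (default widths 40 and 18, merged width 58) and stacked with
#' further hidden layers (default two of 32) before a single logistic
#' output unit.
#'
#' @param microarray_branch `branch_spec` for the expression branch
#'   (default widths 40,40,40,40).
#' @param clinical_branch `branch_spec` for the clinical branch (default
#'   widths 18,18,18,18).
#' @param post_merge_widths hidden widths after the merge (default 32,32).
#' @param l2_penalty L2 coefficient for post-merge weights (defaults to the
#'   microarray branch's).
#' @param seed seed for post-merge weight initialization.
#' @return object of class `bimodal_spec`.
#' @export
bimodal_spec <- function(microarray_branch = branch_spec(15),
                         clinical_branch = branch_spec(
                           7, hidden_widths = c(18, 18, 18, 18)),
                         post_merge_widths = c(32, 32),
                         l2_penalty = microarray_branch$l2_penalty,
                         seed = 1L) {
  if (length(post_merge_widths) == 0L || any(post_merge_widths < 1L)) {
    stopf("post_merge_widths must be a non-empty vector of positive widths")
  }
  merged <- utils::tail(microarray_branch$hidden_widths, 1) +
    utils::tail(clinical_branch$hidden_widths, 1)
  structure(list(microarray_branch = microarray_branch,
                 clinical_branch = clinical_branch,
                 post_merge_widths = as.integer(post_merge_widths),
                 merged_width = as.integer(merged),
                 l2_penalty = l2_penalty, seed = as.integer(seed)),
            class = "bimodal_spec")
}

#' Training specification
#'
#' Defaults follow the published tuning: Nadam with learning rate 0.006,
#' at most 100 epochs of mini-batches of 20, early stopping when the
#' validation loss has not improved for 30 epochs.
#'
#' @param learning_rate Nadam learning rate.
#' @param max_epochs maximum training epochs.
#' @param batch_size mini-batch size.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping.
#' @param seed seed for batch shuffling.
#' @return object of class `train_spec`.
#' @export
train_spec <- function(learning_rate = 0.006, max_epochs = 100L,
                       batch_size = 20L, early_stop_patience = 30L,
                       seed = 1L) {
  if (early_stop_patience > max_epochs && max_epochs > 0L) {
    stopf("early_stop_patience must not exceed max_epochs")
  }
  structure(list(optimizer = "nadam", learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 early_stop_patience = as.integer(early_stop_patience),
                 loss = "binary_crossentropy", seed = as.integer(seed)),
            class = "train_spec")
}

# He-normal initialization for a chain of dense layers with dims
# c(in, h1, ..., out). RNG state is the caller's responsibility.
init_layers <- function(dims) {
  lapply(seq_len(length(dims) - 1L), function(i) {
    fan_in <- dims[i]
    list(W = matrix(stats::rnorm(fan_in * dims[i + 1L],
                                 sd = sqrt(2 / fan_in)),
                    nrow = fan_in, ncol = dims[i + 1L]),
         b = rep(0, dims[i + 1L]))
  })
}

#' Build an untrained network from a specification
#'
#' A `branch_spec` yields a unimodal classifier (branch plus logistic
#' head); a `bimodal_spec` yields the merged two-branch network. Weights
#' are He-normal, deterministic in the spec seeds.
#'
#' @param spec a `branch_spec` or `bimodal_spec`.
#' @return object of class `prognet_nn`.
#' @export
build_network <- function(spec) {
  if (inherits(spec, "branch_spec")) {
    local_seed(spec$seed, {
      layers <- init_layers(c(spec$input_dim, spec$hidden_widths, 1L))
    })
    structure(list(type = "unimodal", spec = spec, layers = layers,
                   history = NULL, best_epoch = NA_integer_),
              class = "prognet_nn")
  } else if (inherits(spec, "bimodal_spec")) {
    mb <- spec$microarray_branch
    cb <- spec$clinical_branch
    local_seed(mb$seed, {
      micro <- init_layers(c(mb$input_dim, mb$hidden_widths))
    })
    local_seed(cb$seed, {
      clin <- init_layers(c(cb$input_dim, cb$hidden_widths))
    })
    local_seed(spec$seed, {
      post <- init_layers(c(spec$merged_width, spec$post_merge_widths, 1L))
    })
    structure(list(type = "bimodal", spec = spec, micro = micro,
                   clin = clin, post = post, history = NULL,
                   best_epoch = NA_integer_),
              class = "prognet_nn")
  } else {
    stopf("spec must be a branch_spec or bimodal_spec")
  }
}

#' Number of trainable parameters
#' @param model a `prognet_nn`.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  count <- function(layers) {
    sum(vapply(layers, function(l) length(l$W) + length(l$b), numeric(1)))
  }
  if (model$type == "unimodal") {
    as.integer(count(model$layers))
  } else {
    as.integer(count(model$micro) + count(model$clin) + count(model$post))
  }
}

relu <- function(z) (z > 0) * z
sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass through a dense chain; `head` applies a sigmoid to the last
# layer, otherwise every layer is ReLU. Returns activations (including the
# input) and pre-activations for backprop.
chain_forward <- function(layers, X, head) {
  A <- list(X)
  Z <- list()
  L <- length(layers)
  for (i in seq_len(L)) {
    z <- sweep(A[[i]] %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
    Z[[i]] <- z
    A[[i + 1L]] <- if (head && i == L) sigmoid(z) else relu(z)
  }
  list(A = A, Z = Z)
}

# Backward pass through a dense chain given the gradient w.r.t. its output
# activation-input (delta already includes the output-layer derivative for
# the head case). Returns per-layer gradients and the gradient w.r.t. the
# chain input.
chain_backward <- function(layers, fwd, delta, l2) {
  L <- length(layers)
  grads <- vector("list", L)
  for (i in rev(seq_len(L))) {
    grads[[i]] <- list(W = crossprod(fwd$A[[i]], delta) + 2 * l2 * layers[[i]]$W,
                       b = colSums(delta))
    if (i > 1L) {
      delta <- (delta %*% t(layers[[i]]$W)) * (fwd$Z[[i - 1L]] > 0)
    } else {
      delta <- delta %*% t(layers[[i]]$W)
    }
  }
  list(grads = grads, delta_input = delta)
}

nn_forward <- function(model, X) {
  if (model$type == "unimodal") {
    fwd <- chain_forward(model$layers, X, head = TRUE)
    list(prob = as.vector(fwd$A[[length(fwd$A)]]), fwd = fwd)
  } else {
    fm <- chain_forward(model$micro, X$micro, head = FALSE)
    fc <- chain_forward(model$clin, X$clinical, head = FALSE)
    H <- cbind(fm$A[[length(fm$A)]], fc$A[[length(fc$A)]])
    fp <- chain_forward(model$post, H, head = TRUE)
    list(prob = as.vector(fp$A[[length(fp$A)]]), fwd_m = fm, fwd_c = fc,
         fwd_p = fp)
  }
}

# Mean binary cross-entropy (no penalty), clipped for numerical safety.
bce_loss <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Gradients of mean BCE + L2 penalty for a mini-batch.
nn_grad <- function(model, X, y) {
  out <- nn_forward(model, X)
  n <- length(y)
  delta_out <- matrix((out$prob - y) / n, ncol = 1L)
  if (model$type == "unimodal") {
    l2 <- model$spec$l2_penalty
    bk <- chain_backward(model$layers, out$fwd, delta_out, l2)
    list(layers = bk$grads)
  } else {
    l2m <- model$spec$microarray_branch$l2_penalty
    l2c <- model$spec$clinical_branch$l2_penalty
    l2p <- model$spec$l2_penalty
    bp <- chain_backward(model$post, out$fwd_p, delta_out, l2p)
    wm <- utils::tail(model$spec$microarray_branch$hidden_widths, 1)
    delta_m <- bp$delta_input[, seq_len(wm), drop = FALSE] *
      (out$fwd_m$Z[[length(out$fwd_m$Z)]] > 0)
    delta_c <- bp$delta_input[, -seq_len(wm), drop = FALSE] *
      (out$fwd_c$Z[[length(out$fwd_c$Z)]] > 0)
    # delta at a branch's output must pass through that branch's final ReLU
    bm <- chain_backward_from_top(model$micro, out$fwd_m, delta_m, l2m)
    bc <- chain_backward_from_top(model$clin, out$fwd_c, delta_c, l2c)
    list(micro = bm, clin = bc, post = bp$grads)
  }
}

# Like chain_backward, but `delta` is already the gradient w.r.t. the last
# layer's pre-activation (the ReLU derivative has been applied).
chain_backward_from_top <- function(layers, fwd, delta, l2) {
  L <- length(layers)
  grads <- vector("list", L)
  for (i in rev(seq_len(L))) {
    grads[[i]] <- list(W = crossprod(fwd$A[[i]], delta) + 2 * l2 * layers[[i]]$W,
                       b = colSums(delta))
    if (i > 1L) {
      delta <- (delta %*% t(layers[[i]]$W)) * (fwd$Z[[i - 1L]] > 0)
    }
  }
  grads
}

# ---------------------------------------------------------------------------
# Nadam optimizer over an arbitrary nested list of parameter tensors.

nadam_state <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

nadam_update <- function(params, grads, state_m, state_v, t,
                         lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, m, v) {
    m_new <- beta1 * m + (1 - beta1) * g
    v_new <- beta2 * v + (1 - beta2) * g^2
    m_hat <- m_new / (1 - beta1^t)
    v_hat <- v_new / (1 - beta2^t)
    # Nesterov momentum term of Nadam
    step <- lr * (beta1 * m_hat + (1 - beta1) * g / (1 - beta1^t)) /
      (sqrt(v_hat) + eps)
    list(p = p - step, m = m_new, v = v_new)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      upd(p, g, m, v)
    }
  }
  walk(params, grads, state_m, state_v)
}

get_params <- function(model) {
  if (model$type == "unimodal") list(layers = model$layers)
  else list(micro = model$micro, clin = model$clin, post = model$post)
}

set_params <- function(model, params) {
  if (model$type == "unimodal") model$layers <- params$layers
  else {
    model$micro <- params$micro
    model$clin <- params$clin
    model$post <- params$post
  }
  model
}

# Shared training loop: mini-batch Nadam with early stopping on the
# validation cross-entropy and restoration of the best-epoch weights.
train_nn <- function(model, X, y, Xv, yv, tspec) {
  n <- length(y)
  subset_X <- function(X, idx) {
    if (model$type == "unimodal") X[idx, , drop = FALSE]
    else list(micro = X$micro[idx, , drop = FALSE],
              clinical = X$clinical[idx, , drop = FALSE])
  }
  params <- get_params(model)
  m_state <- nadam_state(params)
  v_state <- nadam_state(params)
  best_params <- params
  best_val <- bce_loss(nn_forward(model, Xv)$prob, yv)
  best_epoch <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  t_step <- 0L
  if (tspec$max_epochs > 0L) {
    local_seed(tspec$seed, {
      for (epoch in seq_len(tspec$max_epochs)) {
        idx <- sample.int(n)
        starts <- seq(1L, n, by = tspec$batch_size)
        for (s in starts) {
          batch <- idx[s:min(s + tspec$batch_size - 1L, n)]
          grads <- nn_grad(model, subset_X(X, batch), y[batch])
          t_step <- t_step + 1L
          out <- nadam_update(params, grads, m_state, v_state, t_step,
                              tspec$learning_rate)
          params <- out$p
          m_state <- out$m
          v_state <- out$v
          model <- set_params(model, params)
        }
        train_loss <- bce_loss(nn_forward(model, X)$prob, y)
        val_loss <- bce_loss(nn_forward(model, Xv)$prob, yv)
        history <- rbind(history, data.frame(epoch = epoch,
                                             train_loss = train_loss,
                                             val_loss = val_loss))
        if (val_loss < best_val - 1e-12) {
          best_val <- val_loss
          best_params <- params
          best_epoch <- epoch
        } else if (epoch - best_epoch > tspec$early_stop_patience) {
          break
        }
      }
    })
  }
  model <- set_params(model, best_params)
  model$history <- history
  model$best_epoch <- best_epoch
  model$best_val_loss <- best_val
  model$tspec <- tspec
  model
}

as_feature_matrix <- function(features) {
  if (inherits(features, "feature_block")) features$values
  else as.matrix(features)
}

#' Train a unimodal network
#'
#' @param model untrained `prognet_nn` from [build_network()] on a
#'   `branch_spec`.
#' @param features training features (`feature_block` or matrix,
#'   samples x features).
#' @param labels binary outcome (1 = death) for the training samples.
#' @param val_features,val_labels validation data for early stopping.
#' @param tspec a [train_spec()].
#' @return the trained `prognet_nn` with `history` and `best_epoch` set.
#' @export
train_unimodal <- function(model, features, labels, val_features, val_labels,
                           tspec = train_spec()) {
  if (model$type != "unimodal") stopf("model is not a unimodal network")
  X <- as_feature_matrix(features)
  Xv <- as_feature_matrix(val_features)
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L) {
    stopf("training labels contain a single class")
  }
  if (ncol(X) != model$spec$input_dim) {
    stopf("feature dimension %d does not match the network input %d",
          ncol(X), model$spec$input_dim)
  }
  train_nn(model, X, labels, Xv, as.numeric(val_labels), tspec)
}

#' Train the bimodal network with branch pre-training
#'
#' Initializes the expression and clinical branches from the weights of
#' two trained unimodal networks (their logistic heads are discarded),
#' freshly initializes the post-merge layers, and jointly fine-tunes all
#' weights with both inputs fed simultaneously. With `max_epochs = 0` the
#' returned model is exactly the initialized one (branch weights equal the
#' unimodal weights).
#'
#' @param micro_model trained unimodal network for expression features.
#' @param clin_model trained unimodal network for clinical features.
#' @param micro_features,clinical_features training features per modality.
#' @param labels binary outcome for the training samples.
#' @param micro_val,clinical_val,val_labels validation data.
#' @param tspec a [train_spec()].
#' @param post_merge_widths hidden widths after the merge (default 32,32).
#' @param seed seed for the post-merge initialization.
#' @return the trained bimodal `prognet_nn`.
#' @export
train_bimodal <- function(micro_model, clin_model,
                          micro_features, clinical_features, labels,
                          micro_val, clinical_val, val_labels,
                          tspec = train_spec(),
                          post_merge_widths = c(32, 32), seed = 1L) {
  if (micro_model$type != "unimodal" || clin_model$type != "unimodal") {
    stopf("both pre-trained models must be unimodal networks")
  }
  Xm <- as_feature_matrix(micro_features)
  Xc <- as_feature_matrix(clinical_features)
  if (ncol(Xm) != micro_model$spec$input_dim ||
      ncol(Xc) != clin_model$spec$input_dim) {
    stopf("feature dimensions do not match the pre-trained branch inputs")
  }
  spec <- bimodal_spec(micro_model$spec, clin_model$spec,
                       post_merge_widths = post_merge_widths, seed = seed)
  model <- build_network(spec)
  # branch pre-training: copy hidden-layer weights, drop the heads
  nh_m <- length(micro_model$spec$hidden_widths)
  nh_c <- length(clin_model$spec$hidden_widths)
  model$micro <- micro_model$layers[seq_len(nh_m)]
  model$clin <- clin_model$layers[seq_len(nh_c)]
  X <- list(micro = Xm, clinical = Xc)
  Xv <- list(micro = as_feature_matrix(micro_val),
             clinical = as_feature_matrix(clinical_val))
  train_nn(model, X, as.numeric(labels), Xv, as.numeric(val_labels), tspec)
}

#' Predict death probabilities
#'
#' @param model a trained model (neural network or benchmark).
#' @param features features matching the model: a `feature_block`/matrix
#'   for unimodal and benchmark models, or a list with elements `micro`
#'   and `clinical` for the bimodal network.
#' @param ... unused.
#' @return numeric vector of death probabilities in `[0, 1]`.
#' @export
predict_risk <- function(model, features, ...) UseMethod("predict_risk")

#' @export
predict_risk.prognet_nn <- function(model, features, ...) {
  if (model$type == "unimodal") {
    X <- as_feature_matrix(features)
    if (ncol(X) != model$spec$input_dim) {
      stopf("feature dimension %d does not match the network input %d",
            ncol(X), model$spec$input_dim)
    }
    p <- nn_forward(model, X)$prob
    names(p) <- rownames(X)
  } else {
    if (!is.list(features) || !all(c("micro", "clinical") %in% names(features))) {
      stopf("bimodal prediction needs list(micro = ..., clinical = ...)")
    }
    X <- list(micro = as_feature_matrix(features$micro),
              clinical = as_feature_matrix(features$clinical))
    if (ncol(X$micro) != model$spec$microarray_branch$input_dim ||
        ncol(X$clinical) != model$spec$clinical_branch$input_dim) {
      stopf("feature dimensions do not match the bimodal branch inputs")
    }
    p <- nn_forward(model, X)$prob
    names(p) <- rownames(X$micro)
  }
  p
}

#' @export
print.prognet_nn <- function(x, ...) {
  cat(sprintf("%s neural network, %d parameters%s\n",
              if (x$type == "unimodal") "Unimodal" else "Bimodal",
              n_params(x),
              if (!is.null(x$history) && nrow(x$history)) {
                sprintf("; trained %d epochs (best %d, val loss %.4f)",
                        max(x$history$epoch), x$best_epoch, x$best_val_loss)
              } else " (untrained)"))
  invisible(x)
}
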