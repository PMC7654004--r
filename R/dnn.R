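## Step two, neural half: multilayer perceptron on standardized dosages with
## ReLU hidden layers, linear output, L2-penalized squared-error loss,
## inverted dropout, Adam optimization, tuning-set early stopping, and
## random architecture search over the hyperparameter grids.

#' MLP architecture
#'
#' @param n_hidden_layers Hidden layer count (1-4 in the search space).
#' @param units_per_layer Integer vector, one entry per hidden layer.
#' @param l2_lambda Ridge penalty on weights (biases excluded).
#' @param dropout_keep Keep probability applied to the input and every
#'   hidden layer during training; 1 = no dropout.
#' @return List of class `architecture`.
#' @export
architecture <- function(n_hidden_layers, units_per_layer, l2_lambda = 0,
                         dropout_keep = 1) {
  if (length(units_per_layer) != n_hidden_layers)
    stop("architecture: units_per_layer length must equal n_hidden_layers",
         call. = FALSE)
  if (any(units_per_layer < 1))
    stop("architecture: units must be >= 1", call. = FALSE)
  if (l2_lambda < 0) stop("architecture: l2_lambda must be >= 0",
                          call. = FALSE)
  if (dropout_keep <= 0 || dropout_keep > 1)
    stop("architecture: dropout_keep must be in (0, 1]", call. = FALSE)
  structure(list(n_hidden_layers = as.integer(n_hidden_layers),
                 units_per_layer = as.integer(units_per_layer),
                 l2_lambda = l2_lambda, dropout_keep = dropout_keep),
            class = "architecture")
}

#' Hyperparameter search space
#'
#' The grids searched over: units per layer 1, 100, ..., 1000, 2000, ...,
#' 5000; 1-4 hidden layers; dropout keep rate 0.5-0.9 or 1; L2 from 0 to
#' 0.1 in steps of 0.0025. Pass smaller grids for desk-scale searches.
#'
#' @return List with `units`, `layers`, `dropout`, `l2`.
#' @export
table_grids <- function() {
  list(units = c(1, seq(100, 1000, by = 100), seq(2000, 5000, by = 1000)),
       layers = 1:4,
       dropout = c(0.5, 0.6, 0.7, 0.8, 0.9, 1),
       l2 = seq(0, 0.1, by = 0.0025))
}

#' Training protocol settings
#'
#' Defaults follow the study protocol: Adam with learning rate 1e-4,
#' mini-batches of 256, at most 1000 epochs, tuning MSE evaluated every 5
#' epochs, stopping after 5 consecutive evaluations without improvement,
#' weights initialized N(0, 1e-4) (SD 1e-2) with zero biases.
#'
#' @param learning_rate,batch_size,max_epochs,eval_every,patience,init_sd
#'   See description.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return List of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 256L,
                         max_epochs = 1000L, eval_every = 5L,
                         patience = 5L, init_sd = 1e-2, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            eval_every >= 1, patience >= 1, init_sd > 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 eval_every = as.integer(eval_every),
                 patience = as.integer(patience),
                 init_sd = init_sd, seed = as.integer(seed)),
            class = "train_config")
}

#' Initialize MLP weights
#'
#' Weights ~ N(0, init_sd^2), biases 0, for `n_hidden_layers` ReLU layers
#' plus a single linear output unit. Uses the current RNG state.
#'
#' @param arch An [architecture()].
#' @param n_inputs Input dimension (markers).
#' @param init_sd Weight SD (default 1e-2, i.e. variance 1e-4).
#' @return List of layers, each `list(W, b)`.
#' @export
init_mlp <- function(arch, n_inputs, init_sd = 1e-2) {
  sizes <- c(n_inputs, arch$units_per_layer, 1L)
  lapply(seq_len(length(sizes) - 1L), function(l) {
    list(W = matrix(rnorm(sizes[l] * sizes[l + 1L], sd = init_sd),
                    sizes[l], sizes[l + 1L]),
         b = numeric(sizes[l + 1L]))
  })
}

#' Inverted dropout
#'
#' Keeps each unit independently with probability `keep_rate` and rescales
#' kept activations by 1/keep_rate so expected activations match predict
#' mode; keep_rate = 1 is the identity. Uses the current RNG state.
#'
#' @param activations Numeric matrix (rows = records) or vector.
#' @param keep_rate Keep probability in (0, 1].
#' @return Masked activations of the same shape.
#' @export
apply_dropout <- function(activations, keep_rate) {
  if (keep_rate <= 0 || keep_rate > 1)
    stop("apply_dropout: keep_rate must be in (0, 1]", call. = FALSE)
  if (keep_rate == 1) return(activations)
  mask <- (runif(length(activations)) < keep_rate) / keep_rate
  activations * mask
}

## forward pass with cached pre-activations/masked activations for backprop;
## dropout masks (already scaled by 1/keep) are applied to the input layer
## and every hidden layer, never the output
mlp_forward_cache <- function(weights, X, keep = 1, training = FALSE) {
  L <- length(weights)           # hidden layers + output layer
  A <- vector("list", L)         # layer inputs (post-dropout)
  S <- vector("list", L - 1L)    # hidden pre-activations
  cur <- X
  if (training && keep < 1) {
    mask <- matrix((runif(length(cur)) < keep) / keep, nrow(cur), ncol(cur))
    cur <- cur * mask
  }
  for (l in seq_len(L - 1L)) {
    A[[l]] <- cur
    s <- sweep(cur %*% weights[[l]]$W, 2, weights[[l]]$b, "+")
    S[[l]] <- s
    h <- pmax(s, 0)
    if (training && keep < 1) {
      mask <- matrix((runif(length(h)) < keep) / keep, nrow(h), ncol(h))
      h <- h * mask
    }
    cur <- h
  }
  A[[L]] <- cur
  pred <- drop(cur %*% weights[[L]]$W + weights[[L]]$b)
  list(pred = pred, A = A, S = S)
}

#' MLP forward pass
#'
#' Hidden units apply `max(., 0)`; the output layer is the plain linear
#' combination. In train mode inverted-dropout masks are drawn from the
#' current RNG state; predict mode is deterministic.
#'
#' @param weights Layer list from [init_mlp()] or [train_mlp()].
#' @param x Input matrix (rows = records) or a single input vector.
#' @param mode "predict" (deterministic) or "train" (dropout applied).
#' @param keep_rate Dropout keep probability used in train mode.
#' @return Numeric vector of predictions.
#' @export
mlp_forward <- function(weights, x, mode = c("predict", "train"),
                        keep_rate = 1) {
  mode <- match.arg(mode)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != nrow(weights[[1L]]$W))
    stop("mlp_forward: input dimension mismatch", call. = FALSE)
  mlp_forward_cache(weights, x, keep = keep_rate,
                    training = mode == "train")$pred
}

#' Penalized squared-error loss
#'
#' `L = (y - y_hat)'(y - y_hat) + lambda * w'w`, with the penalty summing
#' squared connection weights only (biases excluded).
#'
#' @param y,y_hat Observed and predicted vectors.
#' @param weights Layer list.
#' @param l2_lambda Ridge penalty.
#' @return Scalar loss.
#' @export
penalized_loss <- function(y, y_hat, weights, l2_lambda) {
  stopifnot(length(y) == length(y_hat))
  wss <- sum(vapply(weights, function(l) sum(l$W^2), numeric(1)))
  sum((y - y_hat)^2) + l2_lambda * wss
}

## analytic gradient of penalized_loss on one batch; masks must be the ones
## used in the forward pass, so the caller passes training = FALSE here and
## applies dropout by pre-masking when needed (train_mlp draws masks inside
## a single combined forward+backward).
mlp_backward <- function(weights, cache, y, l2_lambda) {
  L <- length(weights)
  grads <- vector("list", L)
  delta <- matrix(2 * (cache$pred - y), ncol = 1L)
  grads[[L]] <- list(W = crossprod(cache$A[[L]], delta) +
                       2 * l2_lambda * weights[[L]]$W,
                     b = colSums(delta))
  dA <- delta %*% t(weights[[L]]$W)
  for (l in rev(seq_len(L - 1L))) {
    ## A[[l+1]] = relu(S[[l]]) * mask; recover mask effect via ratio where
    ## the unit was active, else 0
    act <- pmax(cache$S[[l]], 0)
    mask_scale <- ifelse(act > 0, cache$A[[l + 1L]] / act, 0)
    dH <- dA * mask_scale
    dS <- dH * (cache$S[[l]] > 0)
    grads[[l]] <- list(W = crossprod(cache$A[[l]], dS) +
                         2 * l2_lambda * weights[[l]]$W,
                       b = colSums(dS))
    dA <- dS %*% t(weights[[l]]$W)
  }
  grads
}

#' Gradient of the penalized loss (analytic backpropagation)
#'
#' Exposed for verification against finite differences. No dropout is
#' applied (deterministic forward pass).
#'
#' @param weights Layer list.
#' @param x Input matrix.
#' @param y Targets.
#' @param l2_lambda Ridge penalty.
#' @return List of `list(W, b)` gradients matching `weights`.
#' @export
mlp_gradient <- function(weights, x, y, l2_lambda = 0) {
  cache <- mlp_forward_cache(weights, as.matrix(x), keep = 1,
                             training = FALSE)
  mlp_backward(weights, cache, y, l2_lambda)
}

#' Trace the early-stopping rule over a tuning-MSE sequence
#'
#' "No improvement" means not strictly lower than the best MSE so far.
#' Stopping occurs at the first evaluation completing `patience` consecutive
#' non-improving assessments.
#'
#' @param mse_sequence Tuning MSE per evaluation, in order.
#' @param patience Consecutive non-improving evaluations tolerated.
#' @return List with `stop_index` (evaluation triggering the stop, NA if
#'   never) and `best_index` (evaluation with the lowest MSE seen by then).
#' @export
early_stop_trace <- function(mse_sequence, patience = 5L) {
  best <- Inf; best_i <- NA_integer_; bad <- 0L
  for (i in seq_along(mse_sequence)) {
    if (mse_sequence[i] < best) {
      best <- mse_sequence[i]; best_i <- i; bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience)
        return(list(stop_index = i, best_index = best_i))
    }
  }
  list(stop_index = NA_integer_, best_index = best_i)
}

#' Train an MLP with Adam, dropout and early stopping
#'
#' Mini-batch Adam minimizing [penalized_loss()]; the tuning MSE (plain,
#' unpenalized) is computed every `eval_every` epochs and training stops
#' after `patience` consecutive evaluations without strict improvement, or
#' at `max_epochs`. The returned weights are the snapshot from the best
#' tuning evaluation.
#'
#' @param arch An [architecture()].
#' @param x_train,y_train Training inputs/targets.
#' @param x_tune,y_tune Held-out tuning inputs/targets (must be non-empty).
#' @param config A [train_config()].
#' @return List of class `train_result`: `weights`, `history` (tuning MSE
#'   per evaluation), `stopped_epoch`, `stop_reason`, `best_tune_mse`.
#' @export
train_mlp <- function(arch, x_train, y_train, x_tune, y_tune,
                      config = train_config()) {
  x_train <- as.matrix(x_train); x_tune <- as.matrix(x_tune)
  if (!nrow(x_tune))
    stop("train_mlp: empty tuning set; early stopping undefined",
         call. = FALSE)
  set.seed(config$seed)
  weights <- init_mlp(arch, ncol(x_train), config$init_sd)
  adam_m <- lapply(weights, function(l) list(W = 0 * l$W, b = 0 * l$b))
  adam_v <- lapply(weights, function(l) list(W = 0 * l$W, b = 0 * l$b))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  n <- nrow(x_train)
  history <- numeric(0)
  best <- Inf; best_w <- weights; bad <- 0L
  stop_reason <- "max-epochs"; stopped <- config$max_epochs

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      cache <- mlp_forward_cache(weights, x_train[idx, , drop = FALSE],
                                 keep = arch$dropout_keep, training = TRUE)
      grads <- mlp_backward(weights, cache, y_train[idx], arch$l2_lambda)
      t_step <- t_step + 1L
      for (l in seq_along(weights)) {
        for (nm in c("W", "b")) {
          g <- grads[[l]][[nm]]
          adam_m[[l]][[nm]] <- b1 * adam_m[[l]][[nm]] + (1 - b1) * g
          adam_v[[l]][[nm]] <- b2 * adam_v[[l]][[nm]] + (1 - b2) * g^2
          mhat <- adam_m[[l]][[nm]] / (1 - b1^t_step)
          vhat <- adam_v[[l]][[nm]] / (1 - b2^t_step)
          weights[[l]][[nm]] <- weights[[l]][[nm]] -
            config$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
    }
    if (epoch %% config$eval_every == 0L) {
      pred <- mlp_forward_cache(weights, x_tune, keep = 1,
                                training = FALSE)$pred
      mse <- mean((y_tune - pred)^2)
      history <- c(history, mse)
      if (mse < best) {
        best <- mse; best_w <- weights; bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= config$patience) {
          stop_reason <- "early-stop"; stopped <- epoch
          break
        }
      }
      stopped <- epoch
    }
  }
  if (!length(history)) {  # max_epochs < eval_every: evaluate once at end
    pred <- mlp_forward_cache(weights, x_tune, keep = 1,
                              training = FALSE)$pred
    history <- mean((y_tune - pred)^2)
    best <- history; best_w <- weights
  }
  structure(list(weights = best_w, history = history,
                 stopped_epoch = stopped, stop_reason = stop_reason,
                 best_tune_mse = best, arch = arch),
            class = "train_result")
}

#' Random architecture search
#'
#' Each candidate is drawn by independent uniform choices from the
#' hyperparameter grids (layer count, units per layer, L2, dropout keep),
#' trained with [train_mlp()], and scored by prediction correlation on the
#' tuning set. Ties are broken by lower tuning MSE, then draw order.
#' Candidates whose tuning correlation is undefined (constant predictions)
#' rank last.
#'
#' @param x_train,y_train,x_tune,y_tune Data partitions.
#' @param config A [train_config()] applied to every candidate.
#' @param n_candidates Architectures to draw (protocol default 200).
#' @param grids Hyperparameter grids as from [table_grids()].
#' @param seed Seed for the candidate draw; candidate k trains with seed
#'   `seed + k` so the list and results are reproducible.
#' @return List with `best` (a `train_result`), `best_arch` and
#'   `leaderboard` (data frame: candidate, layers, units, l2, dropout_keep,
#'   tune_cor, tune_mse, stopped_epoch).
#' @export
random_search <- function(x_train, y_train, x_tune, y_tune,
                          config = train_config(), n_candidates = 200L,
                          grids = table_grids(), seed = 1L) {
  if (n_candidates < 1) stop("random_search: n_candidates must be >= 1",
                             call. = FALSE)
  set.seed(seed)
  cands <- lapply(seq_len(n_candidates), function(k) {
    L <- sample(grids$layers, 1L)
    architecture(L, sample(grids$units, L, replace = TRUE),
                 l2_lambda = sample(grids$l2, 1L),
                 dropout_keep = sample(grids$dropout, 1L))
  })
  fits <- vector("list", n_candidates)
  tune_cor <- tune_mse <- numeric(n_candidates)
  for (k in seq_len(n_candidates)) {
    cfg <- config
    cfg$seed <- as.integer(config$seed + k)
    fit <- train_mlp(cands[[k]], x_train, y_train, x_tune, y_tune, cfg)
    pred <- mlp_forward(fit$weights, x_tune)
    tune_cor[k] <- if (stats::sd(pred) > 0) stats::cor(y_tune, pred)
                   else NA_real_
    tune_mse[k] <- mean((y_tune - pred)^2)
    fits[[k]] <- fit
  }
  score <- ifelse(is.na(tune_cor), -Inf, tune_cor)
  ord <- order(-score, tune_mse, seq_len(n_candidates))
  best_k <- ord[1L]
  leaderboard <- data.frame(
    candidate = seq_len(n_candidates),
    layers = vapply(cands, function(a) a$n_hidden_layers, integer(1)),
    units = vapply(cands, function(a)
      paste(a$units_per_layer, collapse = "-"), character(1)),
    l2 = vapply(cands, function(a) a$l2_lambda, numeric(1)),
    dropout_keep = vapply(cands, function(a) a$dropout_keep, numeric(1)),
    tune_cor = tune_cor, tune_mse = tune_mse,
    stopped_epoch = vapply(fits, function(f) f$stopped_epoch, numeric(1)),
    stringsAsFactors = FALSE)
  list(best = fits[[best_k]], best_arch = cands[[best_k]],
       best_index = best_k, leaderboard = leaderboard)
}
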