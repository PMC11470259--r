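#' Configuration for an attention-MIL classifier
#'
#' Defaults mirror the standard recipe for attention-based multiple instance
#' learning over patch embeddings: a D -> 256 ReLU embedding, a 128-unit
#' tanh attention module, batch normalization and dropout 0.5 on the pooled
#' bag vector, softmax classification, weighted cross-entropy, one-cycle
#' cosine learning-rate schedule peaking at 1e-4, mini-batches of 64 bags, at
#' most 64 epochs with early stopping after 16 epochs without validation
#' improvement, and at most K = 512 patches sampled per bag per epoch.
#'
#' @param input_dim embedding dimension D of the patch features.
#' @param n_classes number of classes C (>= 2).
#' @param embed_dim width of the patch embedding layer.
#' @param attn_dim width of the attention hidden layer.
#' @param dropout dropout probability on the pooled bag vector, in `[0, 1)`.
#' @param K maximum number of patches sampled per bag per training epoch.
#' @param batch_size bags per mini-batch.
#' @param max_epochs training epoch cap.
#' @param patience early-stopping patience (epochs without a lower validation
#'   loss), `<= max_epochs`.
#' @param max_lr peak learning rate of the one-cycle schedule.
#' @param seed RNG seed controlling initialization, shuffling, subsampling
#'   and dropout.
#' @return an `amil_config`.
#' @export
amil_config <- function(input_dim, n_classes, embed_dim = 256L,
                        attn_dim = 128L, dropout = 0.5, K = 512L,
                        batch_size = 64L, max_epochs = 64L, patience = 16L,
                        max_lr = 1e-4, seed = 1L) {
  stopifnot(input_dim >= 1, n_classes >= 2, embed_dim >= 1, attn_dim >= 1,
            dropout >= 0, dropout < 1, K >= 1, batch_size >= 1,
            max_epochs >= 1, patience <= max_epochs, max_lr > 0)
  structure(list(input_dim = as.integer(input_dim),
                 n_classes = as.integer(n_classes),
                 embed_dim = as.integer(embed_dim),
                 attn_dim = as.integer(attn_dim),
                 dropout = dropout, K = as.integer(K),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 max_lr = max_lr, seed = as.integer(seed)),
            class = "amil_config")
}

# fan-based (He for ReLU layer, Xavier elsewhere) seeded initialization
amil_init <- function(config) {
  D <- config$input_dim; E <- config$embed_dim
  A <- config$attn_dim; C <- config$n_classes
  list(W1 = matrix(stats::rnorm(D * E, 0, sqrt(2 / D)), D, E),
       b1 = numeric(E),
       V = matrix(stats::rnorm(A * E, 0, sqrt(1 / E)), A, E),
       w = stats::rnorm(A, 0, sqrt(1 / A)),
       bn_gamma = rep(1, E), bn_beta = numeric(E),
       W2 = matrix(stats::rnorm(E * C, 0, sqrt(1 / E)), E, C),
       b2 = numeric(C))
}

softmax_vec <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

softmax_rows <- function(L) {
  e <- exp(L - apply(L, 1L, max))
  e / rowSums(e)
}

#' Attention scores for a bag of embedded patches
#'
#' Computes \eqn{a_k = \mathrm{softmax}_k(w^\top \tanh(V h_k))} over the K
#' embedded patches of one bag, stably (max-shifted exponentials).
#'
#' @param H K x E matrix of embedded patch vectors.
#' @param V attention weight matrix (A x E).
#' @param w attention projection vector (length A).
#' @return length-K vector of positive scores summing to 1.
#' @export
attention_scores <- function(H, V, w) {
  H <- as.matrix(H)
  if (!all(is.finite(H))) stop("attention_scores: non-finite input")
  s <- as.numeric(tanh(H %*% t(V)) %*% w)
  softmax_vec(s)
}

#' Attention-weighted pooling of a bag
#'
#' \eqn{h_{sum} = \sum_k a_k h_k}; jointly permutation invariant in
#' (rows of `H`, entries of `a`).
#'
#' @param H K x E matrix of embedded patches.
#' @param a length-K attention weights summing to 1.
#' @return length-E pooled vector.
#' @export
amil_pool <- function(H, a) {
  H <- as.matrix(H)
  if (length(a) != nrow(H)) stop("amil_pool: length mismatch")
  as.numeric(crossprod(H, a))
}

# forward through embedding + attention for one raw bag matrix; keeps the
# intermediates needed by backprop
amil_bag_forward <- function(X, par) {
  Z <- sweep(X %*% par$W1, 2L, par$b1, `+`)
  H <- pmax(Z, 0)
  T_ <- tanh(H %*% t(par$V))
  a <- softmax_vec(as.numeric(T_ %*% par$w))
  list(X = X, H = H, T = T_, a = a, hsum = as.numeric(crossprod(H, a)))
}

# gradient of the loss w.r.t. one bag's parameters given g = dL/dhsum
amil_bag_backward <- function(fw, par, g, grads) {
  a <- fw$a; H <- fw$H; T_ <- fw$T; X <- fw$X
  G_H <- a %o% g                                  # through the weighted sum
  da <- as.numeric(H %*% g)
  ds <- a * (da - sum(a * da))                    # softmax backward
  dT <- ds %o% par$w
  dPre <- dT * (1 - T_^2)
  grads$V <- grads$V + crossprod(dPre, H)
  grads$w <- grads$w + as.numeric(crossprod(T_, ds))
  G_H <- G_H + dPre %*% par$V
  dZ <- G_H * (H > 0)
  grads$W1 <- grads$W1 + crossprod(X, dZ)
  grads$b1 <- grads$b1 + colSums(dZ)
  grads
}

#' Forward pass of an A-MIL model on one bag
#'
#' In `"eval"` mode all patches are used, normalization uses the running
#' statistics accumulated during training, and dropout is disabled, so the
#' output is deterministic and invariant to patch order. In `"train"` mode at
#' most `K` patches are sampled uniformly without replacement (all patches
#' when `P <= K`); normalization still uses running statistics because batch
#' statistics only exist inside a mini-batch.
#'
#' @param bag a [patch_bag()] (or plain P x D matrix).
#' @param model a trained `amil_model` (or an initialized one).
#' @param mode `"eval"` or `"train"`.
#' @return named length-C vector of class probabilities summing to 1.
#' @export
amil_forward <- function(bag, model, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  X <- if (inherits(bag, "patch_bag")) bag$features else as.matrix(bag)
  if (nrow(X) < 1L) stop("amil_forward: empty bag")
  if (ncol(X) != model$config$input_dim)
    stop("amil_forward: feature dimension mismatch")
  if (mode == "train" && nrow(X) > model$config$K)
    X <- X[sample.int(nrow(X), model$config$K), , drop = FALSE]
  par <- model$par
  fw <- amil_bag_forward(X, par)
  xhat <- (fw$hsum - model$bn_mean) / sqrt(model$bn_var + 1e-5)
  y <- par$bn_gamma * xhat + par$bn_beta
  p <- softmax_vec(as.numeric(y %*% par$W2) + par$b2)
  stats::setNames(p, model$classes)
}

# evaluation-mode probabilities for a list of bag matrices
amil_eval_probs <- function(Xs, par, bn_mean, bn_var) {
  P <- matrix(NA_real_, length(Xs), ncol(par$W2))
  inv_sd <- 1 / sqrt(bn_var + 1e-5)
  for (i in seq_along(Xs)) {
    fw <- amil_bag_forward(Xs[[i]], par)
    y <- par$bn_gamma * ((fw$hsum - bn_mean) * inv_sd) + par$bn_beta
    P[i, ] <- softmax_vec(as.numeric(y %*% par$W2) + par$b2)
  }
  P
}

# one-cycle learning-rate schedule (30% cosine warmup from max_lr/25, then
# cosine annealing to max_lr/1e4)
one_cycle_lr <- function(step, total_steps, max_lr, pct_start = 0.3,
                         div = 25, final_div = 1e4) {
  warm <- max(1, round(pct_start * total_steps))
  if (step <= warm) {
    lo <- max_lr / div
    lo + (max_lr - lo) * (1 - cos(pi * step / warm)) / 2
  } else {
    lo <- max_lr / final_div
    frac <- (step - warm) / max(1, total_steps - warm)
    lo + (max_lr - lo) * (1 + cos(pi * min(1, frac))) / 2
  }
}

adam_step <- function(par, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grads[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grads[[nm]]^2
    par[[nm]] <- par[[nm]] - lr * (state$m[[nm]] / corr1) /
      (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(par = par, state = state)
}

zero_like <- function(par) lapply(par, function(p) p * 0)

# weighted cross-entropy of eval probabilities; weights indexed by class
weighted_ce <- function(P, y_idx, w_class) {
  wv <- w_class[y_idx]
  ce <- -log(pmax(P[cbind(seq_along(y_idx), y_idx)], 1e-12))
  sum(wv * ce) / sum(wv)
}

#' Train an attention-MIL classifier on a cohort
#'
#' Optimizes the weighted cross-entropy (class weights proportional to the
#' inverse class frequency in the training split) with Adam under a one-cycle
#' cosine learning-rate schedule. Validation loss is monitored each epoch in
#' evaluation mode; training stops early after `config$patience` epochs
#' without improvement and the parameters from the best-validation epoch are
#' returned. Deterministic under `config$seed`.
#'
#' @param cohort a [cohort()].
#' @param target name of the attribute column to predict; slides with missing
#'   labels must be excluded beforehand.
#' @param train_ids slide ids of the training split.
#' @param val_ids slide ids used for early stopping (may overlap a CV test
#'   fold by design; pass `NULL` to train for `max_epochs` without early
#'   stopping).
#' @param config an [amil_config()].
#' @return an `amil_model`: parameters, running normalization statistics,
#'   class levels, config, and per-epoch loss history.
#' @export
amil_train <- function(cohort, target, train_ids, val_ids = NULL, config) {
  stopifnot(inherits(config, "amil_config"))
  ids <- slide_ids(cohort)
  lab <- cohort$attributes[[target]]
  if (is.null(lab)) stop("amil_train: unknown target ", target)
  names(lab) <- ids
  if (anyNA(lab[train_ids]) || any(lab[train_ids] == MISSING_CODE))
    stop("amil_train: missing labels in training split")
  classes <- sort(unique(lab[c(train_ids, val_ids)]))
  if (length(unique(lab[train_ids])) < 2L)
    stop("amil_train: < 2 classes present in training split")
  if (length(classes) != config$n_classes)
    stop("amil_train: n_classes does not match labels present")
  bag_by_id <- stats::setNames(lapply(cohort$bags, function(b) b$features),
                               ids)
  Xtr <- bag_by_id[train_ids]
  ytr <- match(lab[train_ids], classes)
  n_c <- tabulate(ytr, nbins = length(classes))
  w_class <- 1 / n_c           # inverse occurrence
  w_class <- w_class / mean(w_class)
  has_val <- !is.null(val_ids) && length(val_ids) > 0L
  if (has_val) {
    Xva <- bag_by_id[val_ids]
    yva <- match(lab[val_ids], classes)
  }

  set.seed(config$seed)
  par <- amil_init(config)
  state <- list(m = zero_like(par), v = zero_like(par), t = 0L)
  E <- config$embed_dim
  bn_mean <- numeric(E)
  bn_var <- rep(1, E)
  momentum <- 0.1
  n_tr <- length(Xtr)
  steps_per_epoch <- ceiling(n_tr / config$batch_size)
  total_steps <- config$max_epochs * steps_per_epoch
  step <- 0L
  best <- list(val = Inf, par = par, bn_mean = bn_mean, bn_var = bn_var,
               epoch = 0L)
  since_best <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n_tr)
    ep_loss <- 0; ep_w <- 0
    for (mb in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
      step <- step + 1L
      B <- length(mb)
      fws <- vector("list", B)
      S <- matrix(NA_real_, B, E)
      for (k in seq_len(B)) {
        X <- Xtr[[mb[k]]]
        if (nrow(X) > config$K)
          X <- X[sample.int(nrow(X), config$K), , drop = FALSE]
        fws[[k]] <- amil_bag_forward(X, par)
        S[k, ] <- fws[[k]]$hsum
      }
      # batch normalization over the mini-batch of pooled vectors
      mu_B <- colMeans(S)
      var_B <- colvar_pop(S)
      inv_sd <- 1 / sqrt(var_B + 1e-5)
      xhat <- sweep(sweep(S, 2L, mu_B), 2L, inv_sd, `*`)
      Y <- sweep(sweep(xhat, 2L, par$bn_gamma, `*`), 2L, par$bn_beta, `+`)
      bn_mean <- (1 - momentum) * bn_mean + momentum * mu_B
      bn_var <- (1 - momentum) * bn_var +
        momentum * var_B * B / max(1, B - 1)
      # dropout (inverted scaling)
      if (config$dropout > 0) {
        mask <- matrix(stats::rbinom(B * E, 1L, 1 - config$dropout), B, E) /
          (1 - config$dropout)
        Yd <- Y * mask
      } else Yd <- Y
      logits <- sweep(Yd %*% par$W2, 2L, par$b2, `+`)
      Pr <- softmax_rows(logits)
      yb <- ytr[mb]
      wv <- w_class[yb]
      ce <- -log(pmax(Pr[cbind(seq_len(B), yb)], 1e-12))
      loss <- sum(wv * ce) / sum(wv)
      ep_loss <- ep_loss + loss * sum(wv); ep_w <- ep_w + sum(wv)
      if (!is.finite(loss)) stop("amil_train: non-finite loss at epoch ",
                                 epoch)

      # backward
      dlog <- Pr
      dlog[cbind(seq_len(B), yb)] <- dlog[cbind(seq_len(B), yb)] - 1
      dlog <- dlog * (wv / sum(wv))
      grads <- zero_like(par)
      grads$W2 <- crossprod(Yd, dlog)
      grads$b2 <- colSums(dlog)
      dYd <- dlog %*% t(par$W2)
      dY <- if (config$dropout > 0) dYd * mask else dYd
      grads$bn_gamma <- colSums(dY * xhat)
      grads$bn_beta <- colSums(dY)
      dxhat <- sweep(dY, 2L, par$bn_gamma, `*`)
      # standard batch-norm backward (per feature, over the batch dim)
      dS <- sweep(dxhat, 2L, colMeans(dxhat)) -
        xhat * matrix(colMeans(dxhat * xhat), B, E, byrow = TRUE)
      dS <- sweep(dS, 2L, inv_sd, `*`)
      for (k in seq_len(B))
        grads <- amil_bag_backward(fws[[k]], par, dS[k, ], grads)

      lr <- one_cycle_lr(step, total_steps, config$max_lr)
      up <- adam_step(par, grads, state, lr)
      par <- up$par; state <- up$state
    }
    train_loss <- ep_loss / ep_w

    if (has_val) {
      Pv <- amil_eval_probs(Xva, par, bn_mean, bn_var)
      val_loss <- weighted_ce(Pv, yva, w_class)
    } else val_loss <- NA_real_
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = train_loss,
                                         val_loss = val_loss))
    if (has_val) {
      if (val_loss < best$val) {
        best <- list(val = val_loss, par = par, bn_mean = bn_mean,
                     bn_var = bn_var, epoch = epoch)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= config$patience) break
      }
    }
  }

  if (!has_val) best <- list(val = NA_real_, par = par, bn_mean = bn_mean,
                             bn_var = bn_var, epoch = nrow(history))
  structure(list(par = best$par, bn_mean = best$bn_mean,
                 bn_var = best$bn_var, classes = classes,
                 class_weights = stats::setNames(w_class, classes),
                 config = config, best_epoch = best$epoch,
                 best_val_loss = best$val, history = history),
            class = "amil_model")
}

#' @export
print.amil_model <- function(x, ...) {
  cat(sprintf(
    "<amil_model> D=%d -> %d (attn %d) -> %d classes; best epoch %d%s\n",
    x$config$input_dim, x$config$embed_dim, x$config$attn_dim,
    length(x$classes), x$best_epoch,
    if (is.na(x$best_val_loss)) "" else
      sprintf(" (val loss %.4f)", x$best_val_loss)))
  invisible(x)
}

#' Evaluation-mode class probabilities for every bag of a cohort
#'
#' @param model an `amil_model`.
#' @param cohort a [cohort()] with the same feature dimension as the model.
#' @return slides x C matrix of probabilities (rows sum to 1), rownames =
#'   slide ids, colnames = class levels.
#' @export
amil_predict_proba <- function(model, cohort) {
  Xs <- lapply(cohort$bags, function(b) b$features)
  if (ncol(Xs[[1]]) != model$config$input_dim)
    stop("amil_predict_proba: feature dimension mismatch")
  P <- amil_eval_probs(Xs, model$par, model$bn_mean, model$bn_var)
  dimnames(P) <- list(slide_ids(cohort), model$classes)
  P
}
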