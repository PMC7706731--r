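#' Model configuration
#'
#' Hyperparameters of the hybrid convolutional-recurrent topic classifier:
#' a 1D convolution (ReLU) over the one-hot sequence, non-overlapping max
#' pooling, a position-wise (time-distributed) dense layer feeding a
#' bidirectional LSTM, a fully connected ReLU layer, and a sigmoid output
#' unit per topic (multilabel). Defaults follow the published
#' architecture: 128 filters of width 20, pool 10/10, 128 recurrent units
#' (dropout 0.1 on inputs and recurrent state), 256 dense units, dropout
#' 0.2/0.2/0.4 after pooling, recurrent and dense layers, Adam at 0.001,
#' two epochs at batch size 128 on 500-bp input, 24 output classes.
#'
#' @param n_filters,kernel_size Convolution filters and width.
#' @param pool_size,pool_stride Max-pooling window and stride (must be
#'   equal; non-overlapping floor pooling).
#' @param position_dense_units Width of the position-wise dense layer.
#' @param recurrent_units LSTM units per direction.
#' @param recurrent_dropout,recurrent_input_dropout LSTM dropout rates.
#' @param dense_units Fully connected layer width.
#' @param dropout_after_pool,dropout_after_recurrent,dropout_after_dense
#'   Dropout rates.
#' @param n_classes Number of output classes (topics).
#' @param learning_rate,epochs,batch_size Training parameters.
#' @param input_length Input sequence length (bp).
#' @param seed Integer seed for initialization and training.
#' @return A `model_config` list.
#' @export
model_config <- function(n_filters = 128L, kernel_size = 20L, pool_size = 10L,
                         pool_stride = 10L, position_dense_units = 128L,
                         recurrent_units = 128L, recurrent_dropout = 0.1,
                         recurrent_input_dropout = 0.1, dense_units = 256L,
                         dropout_after_pool = 0.2, dropout_after_recurrent = 0.2,
                         dropout_after_dense = 0.4, n_classes = 24L,
                         learning_rate = 0.001, epochs = 2L, batch_size = 128L,
                         input_length = 500L, seed = 1L) {
  assert_that(pool_size == pool_stride,
              "only non-overlapping pooling is supported (pool_size == pool_stride)")
  cfg <- list(
    n_filters = as.integer(n_filters), kernel_size = as.integer(kernel_size),
    pool_size = as.integer(pool_size), pool_stride = as.integer(pool_stride),
    position_dense_units = as.integer(position_dense_units),
    recurrent_units = as.integer(recurrent_units),
    recurrent_dropout = recurrent_dropout,
    recurrent_input_dropout = recurrent_input_dropout,
    dense_units = as.integer(dense_units),
    dropout_after_pool = dropout_after_pool,
    dropout_after_recurrent = dropout_after_recurrent,
    dropout_after_dense = dropout_after_dense,
    n_classes = as.integer(n_classes), learning_rate = learning_rate,
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    input_length = as.integer(input_length), seed = as.integer(seed)
  )
  counts <- c(cfg$n_filters, cfg$kernel_size, cfg$pool_size,
              cfg$position_dense_units, cfg$recurrent_units, cfg$dense_units,
              cfg$n_classes, cfg$batch_size, cfg$input_length)
  assert_that(all(counts >= 1), "all size parameters must be >= 1")
  drops <- c(cfg$recurrent_dropout, cfg$recurrent_input_dropout,
             cfg$dropout_after_pool, cfg$dropout_after_recurrent,
             cfg$dropout_after_dense)
  assert_that(all(drops >= 0 & drops < 1), "dropout rates must be in [0,1)")
  structure(cfg, class = "model_config")
}

#' Reduced desk-scale configuration
#'
#' A smaller configuration (32 filters, 32-unit position-wise dense, 32
#' recurrent units, 64 dense units) used throughout examples and tests so
#' that training stays within minutes on one CPU; the full published
#' configuration remains available through [model_config()].
#'
#' @param n_classes Number of classes.
#' @param ... Overrides passed to [model_config()].
#' @export
desk_config <- function(n_classes = 4L, ...) {
  args <- list(...)
  defaults <- list(n_filters = 32L, position_dense_units = 32L,
                   recurrent_units = 32L, dense_units = 64L,
                   n_classes = as.integer(n_classes))
  do.call(model_config, utils::modifyList(defaults, args))
}

conv_positions <- function(cfg) cfg$input_length - cfg$kernel_size + 1L

pooled_positions <- function(cfg) {
  T_ <- conv_positions(cfg)
  as.integer(floor((T_ - cfg$pool_size) / cfg$pool_stride) + 1L)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an untrained model
#'
#' Initializes all parameters (Glorot-uniform weights, zero biases, LSTM
#' forget-gate bias 1) deterministically from `config$seed`.
#'
#' @param config A [model_config()].
#' @param class_names Optional class names (default `class_1..n`).
#' @return An `enhancer_model`.
#' @export
build_model <- function(config, class_names = NULL) {
  cfg <- config
  assert_that(cfg$input_length >= cfg$kernel_size,
              "input_length must be >= kernel_size")
  assert_that(pooled_positions(cfg) >= 1,
              "input too short for the pooling configuration")
  set.seed(cfg$seed)
  K4 <- 4L * cfg$kernel_size
  F_ <- cfg$n_filters
  D <- cfg$position_dense_units
  H <- cfg$recurrent_units
  U <- cfg$dense_units
  C_ <- cfg$n_classes
  P <- pooled_positions(cfg)
  lstm_bias <- function() {
    b <- numeric(4L * H)
    b[(H + 1L):(2L * H)] <- 1   # forget gate bias
    b
  }
  params <- list(
    Wc = glorot(K4, F_), bc = numeric(F_),
    Wp = glorot(F_, D), bp = numeric(D),
    Wx_f = glorot(D, 4L * H), Wh_f = glorot(H, 4L * H), b_f = lstm_bias(),
    Wx_b = glorot(D, 4L * H), Wh_b = glorot(H, 4L * H), b_b = lstm_bias(),
    Wd = glorot(P * 2L * H, U), bd = numeric(U),
    Wo = glorot(U, C_), bo = numeric(C_)
  )
  class_names <- class_names %||% paste0("class_", seq_len(C_))
  assert_that(length(class_names) == C_, "class_names length must equal n_classes")
  structure(
    list(config = cfg, params = params, class_names = class_names,
         log = tibble(epoch = integer(), loss = numeric()), trained = FALSE),
    class = "enhancer_model"
  )
}

#' @export
print.enhancer_model <- function(x, ...) {
  cfg <- x$config
  cat("<enhancer_model> ", cfg$n_filters, " filters x ", cfg$kernel_size,
      " bp -> pool ", cfg$pool_size, " -> BiLSTM(", cfg$recurrent_units,
      ") -> dense(", cfg$dense_units, ") -> ", cfg$n_classes,
      " sigmoid classes; ", if (x$trained) "trained" else "untrained",
      " (", format(n_parameters(x), big.mark = ","), " parameters)\n", sep = "")
  invisible(x)
}

#' Number of trainable parameters
#' @param model An `enhancer_model`.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# bias add without sweep()'s overhead
add_bias <- function(M, b) M + rep(b, each = nrow(M))

.idx_cache <- new.env(parent = emptyenv())

cached_idx <- function(kind, B, P, W, builder) {
  key <- paste(kind, B, P, W, sep = "_")
  if (is.null(.idx_cache[[key]])) .idx_cache[[key]] <- builder(B, P, W)
  .idx_cache[[key]]
}

# Flatten P*B x W (t-major rows) into B x (P*W) with position-major columns,
# via a precomputed single-subscript gather (faster than aperm).
flatten_idx <- function(B, P, W) {
  # target element (b, (p-1)*W + j) <- source element ((p-1)*B + b, j)
  b <- rep(seq_len(B), times = P * W)
  pj <- rep(seq_len(P * W), each = B)
  p <- (pj - 1L) %/% W + 1L
  j <- (pj - 1L) %% W + 1L
  (j - 1L) * (P * B) + (p - 1L) * B + b
}

unflatten_idx <- function(B, P, W) {
  # target element ((p-1)*B + b, j) <- source element (b, (p-1)*W + j)
  row <- rep(seq_len(P * B), times = W)
  j <- rep(seq_len(W), each = P * B)
  p <- (row - 1L) %/% B + 1L
  b <- (row - 1L) %% B + 1L
  (((p - 1L) * W + j) - 1L) * B + b
}

# ---- forward pass -----------------------------------------------------------

# Conv layer on a batch: Xb is B x 4L (position-major one-hot).
# Returns Z (B*T x 4K, rows t-major) and post-ReLU activations A1 (B*T x F).
conv_forward <- function(params, cfg, Xb) {
  res <- cpp_conv_forward(Xb, params$Wc, params$bc)
  list(Z = res$Z, A1 = res$A1, B = nrow(Xb))
}

make_dropout_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix(stats::rbinom(nr * nc, 1L, 1 - rate) / (1 - rate), nr, nc)
}

apply_mask <- function(x, m) if (is.null(m)) x else x * m

# Everything after the conv layer. A1: B*T x F (t-major rows).
# train = TRUE applies (inverted) dropout with freshly drawn masks.
head_forward <- function(params, cfg, A1, B, train = FALSE,
                         want_cache = TRUE) {
  T_ <- conv_positions(cfg)
  P <- pooled_positions(cfg)
  F_ <- cfg$n_filters
  H <- cfg$recurrent_units
  pool <- cfg$pool_size
  # max pooling
  pm <- cpp_pool_max(A1, B, P, pool)
  M <- pm$M
  amax <- pm$amax
  masks_in <- if (train) draw_masks(cfg, B) else NULL
  m_pool <- masks_in$pool
  Md <- apply_mask(M, m_pool)
  # position-wise dense (linear)
  S <- add_bias(Md %*% params$Wp, params$bp)
  # variational dropout masks for the recurrent layer
  mx_f <- masks_in$mx_f
  mh_f <- masks_in$mh_f
  mx_b <- masks_in$mx_b
  mh_b <- masks_in$mh_b
  fwd <- cpp_lstm_forward(S, params$Wx_f, params$Wh_f, params$b_f, B, P,
                          TRUE, mx_f, mh_f, want_cache)
  bwd <- cpp_lstm_forward(S, params$Wx_b, params$Wh_b, params$b_b, B, P,
                          FALSE, mx_b, mh_b, want_cache)
  Hcat <- cbind(fwd$Hseq, bwd$Hseq)
  m_rec <- masks_in$rec
  Hd <- apply_mask(Hcat, m_rec)
  # flatten (B x P*2H, position-major columns)
  Fl <- matrix(Hd[cached_idx("fl", B, P, 2L * H, flatten_idx)], B, 2L * H * P)
  Dh_pre <- add_bias(Fl %*% params$Wd, params$bd)
  Dh <- Dh_pre
  Dh[Dh < 0] <- 0
  m_dense <- masks_in$dense
  Dhd <- apply_mask(Dh, m_dense)
  logits <- add_bias(Dhd %*% params$Wo, params$bo)
  out <- sigmoid(logits)
  list(out = out, logits = logits, embedding = Dh,
       cache = list(A1 = A1, amax = amax, M = M, Md = Md, S = S,
                    fwd = fwd, bwd = bwd, Hd = Hd, Fl = Fl,
                    Dh_pre = Dh_pre, Dh = Dh, Dhd = Dhd, B = B,
                    masks = list(pool = m_pool, rec = m_rec, dense = m_dense,
                                 mx_f = mx_f, mh_f = mh_f,
                                 mx_b = mx_b, mh_b = mh_b)))
}

# ---- backward pass ----------------------------------------------------------

# dlogits: B x C gradient w.r.t. the output logits.
head_backward <- function(params, cfg, cache, dlogits) {
  B <- cache$B
  P <- pooled_positions(cfg)
  T_ <- conv_positions(cfg)
  F_ <- cfg$n_filters
  H <- cfg$recurrent_units
  pool <- cfg$pool_size
  masks <- cache$masks
  grads <- list()
  grads$Wo <- crossprod(cache$Dhd, dlogits)
  grads$bo <- colSums(dlogits)
  dDhd <- dlogits %*% t(params$Wo)
  dDh <- apply_mask(dDhd, masks$dense)
  dDh_pre <- dDh * (cache$Dh_pre > 0)
  grads$Wd <- crossprod(cache$Fl, dDh_pre)
  grads$bd <- colSums(dDh_pre)
  dFl <- dDh_pre %*% t(params$Wd)
  dHd <- matrix(dFl[cached_idx("ufl", B, P, 2L * H, unflatten_idx)],
                P * B, 2L * H)
  dHcat <- apply_mask(dHd, masks$rec)
  dS <- matrix(0, P * B, cfg$position_dense_units)
  bf <- cpp_lstm_backward(cache$fwd, dHcat[, 1:H, drop = FALSE],
                          params$Wx_f, params$Wh_f, dS, B, P, TRUE,
                          masks$mx_f, masks$mh_f)
  grads$Wx_f <- bf$dWx; grads$Wh_f <- bf$dWh; grads$b_f <- as.vector(bf$db)
  bb <- cpp_lstm_backward(cache$bwd, dHcat[, (H + 1L):(2L * H), drop = FALSE],
                          params$Wx_b, params$Wh_b, bf$dS, B, P, FALSE,
                          masks$mx_b, masks$mh_b)
  grads$Wx_b <- bb$dWx; grads$Wh_b <- bb$dWh; grads$b_b <- as.vector(bb$db)
  dS <- bb$dS
  grads$Wp <- crossprod(cache$Md, dS)
  grads$bp <- colSums(dS)
  dMd <- dS %*% t(params$Wp)
  dM <- apply_mask(dMd, masks$pool)
  dA1 <- cpp_unpool(dM, cache$amax, cache$A1, B, P, pool, T_)
  list(grads = grads, dA1 = dA1)
}

conv_backward <- function(params, cfg, conv_cache, dA1, want_input_grad = FALSE) {
  grads <- list(Wc = crossprod(conv_cache$Z, dA1), bc = colSums(dA1))
  dXb <- NULL
  if (want_input_grad) {
    dZ <- dA1 %*% t(params$Wc)
    dXb <- cpp_col2im(dZ, conv_cache$B, cfg$input_length, cfg$kernel_size)
  }
  list(grads = grads, dXb = dXb)
}

# Dropout masks for one batch, drawn in a fixed order so results are
# reproducible for a given seed state.
draw_masks <- function(cfg, B) {
  P <- pooled_positions(cfg)
  list(
    pool = make_dropout_mask(P * B, cfg$n_filters, cfg$dropout_after_pool),
    mx_f = make_dropout_mask(B, cfg$position_dense_units,
                             cfg$recurrent_input_dropout),
    mh_f = make_dropout_mask(B, cfg$recurrent_units, cfg$recurrent_dropout),
    mx_b = make_dropout_mask(B, cfg$position_dense_units,
                             cfg$recurrent_input_dropout),
    mh_b = make_dropout_mask(B, cfg$recurrent_units, cfg$recurrent_dropout),
    rec = make_dropout_mask(P * B, 2L * cfg$recurrent_units,
                            cfg$dropout_after_recurrent),
    dense = make_dropout_mask(B, cfg$dense_units, cfg$dropout_after_dense)
  )
}

# Full forward + backward on one minibatch; returns loss, grads.
# Runs through the fused C++ kernel; the R-level conv_forward/head_forward
# path below computes the same function and anchors the gradient tests.
batch_grads <- function(params, cfg, Xb, Y, train = TRUE) {
  masks <- if (train) draw_masks(cfg, nrow(Xb)) else list()
  res <- cpp_batch(Xb, Y, params, masks, cfg$pool_size,
                   pooled_positions(cfg), TRUE, FALSE, 0L)
  list(loss = res$loss, grads = res$grads)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

as_code_matrix <- function(x, input_length) {
  if (is.matrix(x) && is.numeric(x)) {
    storage.mode(x) <- "integer"
    assert_that(ncol(x) == input_length,
                paste0("sequences must have length ", input_length))
    return(x)
  }
  L <- unique(nchar(x))
  assert_that(length(L) == 1 && L == input_length,
              paste0("sequences must have length ", input_length))
  encode_matrix(x)
}

#' Train the model
#'
#' Minimizes mean binary cross-entropy with Adam. Each training sequence
#' contributes both its forward and reverse-complement strand, matching
#' the strand-symmetric design of the predictor. Per-epoch mean loss is
#' appended to the training log. Training aborts with a diagnostic if the
#' loss becomes non-finite.
#'
#' @param model An `enhancer_model`.
#' @param x Character vector of sequences of `input_length` (or an integer
#'   code matrix from the internal encoder).
#' @param y Binary label matrix (N x n_classes).
#' @param epochs,batch_size,learning_rate Optional overrides of the
#'   configured values.
#' @param verbose Print per-epoch loss.
#' @return The trained `enhancer_model` (with `log` filled in).
#' @export
train_model <- function(model, x, y, epochs = NULL, batch_size = NULL,
                        learning_rate = NULL, verbose = FALSE) {
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  batch_size <- batch_size %||% cfg$batch_size
  lr <- learning_rate %||% cfg$learning_rate
  codes <- as_code_matrix(x, cfg$input_length)
  y <- as.matrix(y)
  assert_that(nrow(y) == nrow(codes), "x and y must have matching rows")
  assert_that(ncol(y) == cfg$n_classes, "y must have n_classes columns")
  assert_that(all(y %in% c(0, 1)), "labels must be binary")
  if (epochs == 0L) return(model)
  # both strands as training examples
  codes_all <- rbind(codes, rc_codes(codes))
  y_all <- rbind(y, y)
  n <- nrow(codes_all)
  params <- model$params
  state <- adam_init(params)
  for (ep in seq_len(epochs)) {
    set.seed(derive_seed(cfg$seed, paste0("epoch", ep)))
    ord <- sample.int(n)
    losses <- numeric(0)
    for (b0 in seq(1L, n, by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1L, n)]
      Xb <- codes_to_batch(codes_all[idx, , drop = FALSE])
      Yb <- y_all[idx, , drop = FALSE]
      res <- batch_grads(params, cfg, Xb, Yb, train = TRUE)
      if (!is.finite(res$loss)) {
        abort(paste0("training aborted: non-finite loss at epoch ", ep,
                     ", batch starting at ", b0))
      }
      upd <- adam_step(params, res$grads, state, lr)
      params <- upd$params
      state <- upd$state
      losses <- c(losses, res$loss)
    }
    model$log <- dplyr::bind_rows(model$log,
                                  tibble(epoch = ep, loss = mean(losses)))
    if (verbose) {
      message(sprintf("epoch %d: mean loss %.5f", ep, mean(losses)))
    }
  }
  model$params <- params
  model$trained <- TRUE
  model
}

# Forward in inference mode over an arbitrary number of sequences, chunked.
# Returns list(out, embedding), forward strand only.
forward_inference <- function(model, codes, chunk = 128L) {
  cfg <- model$config
  n <- nrow(codes)
  out <- matrix(0, n, cfg$n_classes)
  emb <- matrix(0, n, cfg$dense_units)
  dummy <- matrix(0, 1, cfg$n_classes)
  for (b0 in seq(1L, n, by = chunk)) {
    idx <- b0:min(b0 + chunk - 1L, n)
    Xb <- codes_to_batch(codes[idx, , drop = FALSE])
    res <- cpp_batch(Xb, dummy[rep(1L, length(idx)), , drop = FALSE],
                     model$params, list(), cfg$pool_size,
                     pooled_positions(cfg), FALSE, FALSE, 0L)
    out[idx, ] <- res$out
    emb[idx, ] <- res$embedding
  }
  list(out = out, embedding = emb)
}

#' Strand-averaged prediction
#'
#' Scores each sequence on the forward and reverse-complement strand and
#' averages the per-class sigmoid outputs, making predictions exactly
#' invariant to reverse complementation.
#'
#' @param model A trained (or untrained) `enhancer_model`.
#' @param x Character vector of sequences of the configured input length.
#' @return An N x n_classes matrix of scores in `[0, 1]` (column names =
#'   class names; rownames from `names(x)`).
#' @export
rc_averaged_predict <- function(model, x) {
  codes <- as_code_matrix(x, model$config$input_length)
  fwd <- forward_inference(model, codes)$out
  rev_ <- forward_inference(model, rc_codes(codes))$out
  out <- (fwd + rev_) / 2
  dimnames(out) <- list(if (is.character(x)) names(x) else rownames(x),
                        model$class_names)
  out
}

#' @export
predict.enhancer_model <- function(object, x, type = c("response", "embedding"),
                                   ...) {
  type <- match.arg(type)
  if (type == "response") rc_averaged_predict(object, x)
  else extract_embedding(object, x)
}

#' Dense-layer embedding
#'
#' The post-ReLU activations of the fully connected layer, averaged over
#' the forward and reverse-complement strand (mirroring the strand
#' handling of prediction), giving a reduced-dimensional representation of
#' each region for similarity analyses.
#'
#' @inheritParams rc_averaged_predict
#' @return An N x dense_units matrix.
#' @export
extract_embedding <- function(model, x) {
  codes <- as_code_matrix(x, model$config$input_length)
  fwd <- forward_inference(model, codes)$embedding
  rev_ <- forward_inference(model, rc_codes(codes))$embedding
  out <- (fwd + rev_) / 2
  rownames(out) <- if (is.character(x)) names(x) else rownames(x)
  out
}

#' Evaluate a model with a chromosome-held-out split
#'
#' Computes per-class auROC and auPR on the training chromosomes, the
#' held-out chromosome(s), and a label-shuffled control of the held-out
#' split (labels permuted with a fixed seed). Classes without positives
#' (or negatives) in a split report `NA` metrics rather than NaN.
#'
#' @param model A trained `enhancer_model`.
#' @param x Sequences (character vector).
#' @param y Binary label matrix.
#' @param chroms Chromosome of each sequence (character vector), used for
#'   the split.
#' @param heldout_chrom Chromosome(s) held out for testing.
#' @param shuffle_seed Seed for the label-shuffled control.
#' @return An `enhancer_eval` tibble: `split`, `class`, `auroc`, `aupr`,
#'   `n_pos`, `n`.
#' @export
evaluate_model <- function(model, x, y, chroms, heldout_chrom,
                           shuffle_seed = 1L) {
  assert_that(all(heldout_chrom %in% chroms),
              "heldout chromosome not present in `chroms`")
  scores <- rc_averaged_predict(model, x)
  y <- as.matrix(y)
  test <- chroms %in% heldout_chrom
  set.seed(shuffle_seed)
  y_shuf <- y[sample.int(nrow(y)), , drop = FALSE]
  splits <- list(train = !test, test = test, shuffled = test)
  labels <- list(train = y, test = y, shuffled = y_shuf)
  out <- lapply(names(splits), function(s) {
    keep <- splits[[s]]
    lab <- labels[[s]]
    tibble(
      split = s,
      class = model$class_names,
      auroc = vapply(seq_len(ncol(y)), function(j) {
        as.numeric(auroc(scores[keep, j], lab[keep, j]))
      }, numeric(1)),
      aupr = vapply(seq_len(ncol(y)), function(j) {
        as.numeric(aupr(scores[keep, j], lab[keep, j]))
      }, numeric(1)),
      n_pos = vapply(seq_len(ncol(y)), function(j) sum(lab[keep, j]), numeric(1)),
      n = sum(keep)
    )
  })
  structure(dplyr::bind_rows(out), class = c("enhancer_eval", "tbl_df", "tbl",
                                             "data.frame"))
}

#' Call regions for a class at a score threshold
#'
#' Keeps regions whose score for `class` is strictly above `threshold`
#' (matching the "scores above threshold" convention).
#'
#' @param regions A region tibble (rows aligned with `scores`).
#' @param scores Prediction matrix from [rc_averaged_predict()].
#' @param class Class name or index.
#' @param threshold Score threshold in (0, 1).
#' @return The called subset of `regions`, with `score` replaced by the
#'   class score.
#' @export
call_class <- function(regions, scores, class, threshold) {
  regions <- as_tibble(regions)
  if (is.character(class)) class <- match(class, colnames(scores))
  s <- scores[, class]
  out <- regions[s > threshold, , drop = FALSE]
  out$score <- s[s > threshold]
  out
}

#' Sweep class-call thresholds against known labels
#'
#' Utility for choosing a class-call threshold: reports recall, FDR and
#' Youden's J over a threshold grid.
#'
#' @param scores Score vector for one class.
#' @param labels Binary truth for that class.
#' @param thresholds Threshold grid (default 99 quantile steps).
#' @return A tibble: `threshold`, `recall`, `fdr`, `youden`.
#' @export
threshold_sweep <- function(scores, labels, thresholds = seq(0.01, 0.99, 0.01)) {
  labels <- as.logical(labels)
  out <- lapply(thresholds, function(th) {
    called <- scores > th
    tp <- sum(called & labels)
    fp <- sum(called & !labels)
    fn <- sum(!called & labels)
    tn <- sum(!called & !labels)
    tibble(threshold = th,
           recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
           fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
           youden = (if (tp + fn > 0) tp / (tp + fn) else 0) +
             (if (tn + fp > 0) tn / (tn + fp) else 0) - 1)
  })
  dplyr::bind_rows(out)
}

#' Save / load a model checkpoint
#'
#' A single self-describing JSON file holding the configuration, class
#' names, training log and raw parameter tensors (with dimensions); no
#' opaque binary blob. Round-trips exactly at double precision.
#'
#' @param model An `enhancer_model`.
#' @param path Output path (conventionally `.json`).
#' @export
write_model <- function(model, path) {
  obj <- list(
    format = "enhancerkit-model-v1",
    config = unclass(model$config),
    class_names = model$class_names,
    trained = model$trained,
    log = model$log,
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
      else list(dim = length(p), data = as.vector(p))
    })
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  assert_that(identical(obj$format, "enhancerkit-model-v1"),
              "not an enhancerkit model checkpoint")
  cfg <- do.call(model_config, obj$config[setdiff(names(obj$config), character(0))])
  params <- lapply(obj$params, function(p) {
    if (length(p$dim) == 2) matrix(p$data, p$dim[1], p$dim[2]) else p$data
  })
  structure(
    list(config = cfg, params = params, class_names = obj$class_names,
         log = as_tibble(obj$log), trained = isTRUE(obj$trained)),
    class = "enhancer_model"
  )
}

#' @export
tidy.enhancer_model <- function(x, ...) x$log

#' @export
glance.enhancer_model <- function(x, ...) {
  tibble(
    n_parameters = n_parameters(x),
    n_classes = x$config$n_classes,
    n_filters = x$config$n_filters,
    recurrent_units = x$config$recurrent_units,
    dense_units = x$config$dense_units,
    input_length = x$config$input_length,
    trained = x$trained,
    final_loss = if (nrow(x$log) > 0) x$log$loss[nrow(x$log)] else NA_real_
  )
}
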