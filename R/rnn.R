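# Masked LSTM / GRU sequence classifiers, implemented directly on matrix
# algebra. The cells follow the dual-bias convention (separate input-to-hidden
# and hidden-to-hidden bias vectors), which is the convention the published
# parameter counts are consistent with. Padded time steps are carried through
# the recurrence unchanged and excluded from the loss, so appending padding
# to a sequence provably leaves the logits unchanged.

#' Describe a recurrent classifier architecture
#'
#' A stack of `num_layers` LSTM or GRU layers (`hidden_size` units each)
#' followed by a two-layer head: linear `H -> H`, rectified-linear
#' activation, linear `H -> n_classes`.
#'
#' @param cell `"lstm"` or `"gru"`.
#' @param input_size number of input features (41 for the full schema).
#' @param hidden_size hidden units per layer (256 in the reference
#'   configuration; reduce for desk-scale training).
#' @param num_layers stacked recurrent layers (default 3).
#' @param n_classes output classes (default 4).
#' @return object of class `recurrent_architecture`.
#' @export
recurrent_architecture <- function(cell = c("lstm", "gru"), input_size = 41L,
                                   hidden_size = 256L, num_layers = 3L,
                                   n_classes = 4L) {
  cell <- match.arg(cell)
  structure(list(cell = cell, input_size = as.integer(input_size),
                 hidden_size = as.integer(hidden_size),
                 num_layers = as.integer(num_layers),
                 n_classes = as.integer(n_classes)),
            class = "recurrent_architecture")
}

#' Closed-form trainable-parameter count of a recurrent architecture
#'
#' Layer `l` with input width `I_l` (the feature count for the first layer,
#' `H` thereafter) contributes `4 H (I_l + H) + 8 H` parameters for an LSTM
#' and `3 H (I_l + H) + 6 H` for a GRU (dual bias vectors). The head adds
#' `(H * H + H) + (H * n_classes + n_classes)`. The reference 3-layer
#' configurations on 41 features give 1,425,668 (LSTM) and 1,085,956 (GRU).
#'
#' @param arch a [recurrent_architecture()].
#' @param head include the fully connected head (default TRUE).
#' @return integer parameter count.
#' @examples
#' count_parameters(recurrent_architecture("lstm"))  # 1425668
#' @export
count_parameters <- function(arch, head = TRUE) {
  stopifnot(inherits(arch, "recurrent_architecture"))
  H <- arch$hidden_size
  gates <- if (arch$cell == "lstm") 4L else 3L
  total <- 0
  for (l in seq_len(arch$num_layers)) {
    I <- if (l == 1L) arch$input_size else H
    total <- total + gates * H * (I + H) + 2L * gates * H
  }
  if (head)
    total <- total + (H * H + H) + (H * arch$n_classes + arch$n_classes)
  as.integer(total)
}

# ---- parameter containers ---------------------------------------------------

runif_mat <- function(nr, nc, k) matrix(runif(nr * nc, -k, k), nr, nc)

rnn_init <- function(arch, seed = 42L) {
  set.seed(seed)
  H <- arch$hidden_size
  k <- 1 / sqrt(H)
  gates <- if (arch$cell == "lstm") c("i", "f", "g", "o") else c("r", "z", "n")
  layers <- vector("list", arch$num_layers)
  for (l in seq_len(arch$num_layers)) {
    I <- if (l == 1L) arch$input_size else H
    pl <- list()
    for (gt in gates) {
      pl[[paste0("Wi", gt)]] <- runif_mat(H, I, k)
      pl[[paste0("Wh", gt)]] <- runif_mat(H, H, k)
      pl[[paste0("bi", gt)]] <- runif(H, -k, k)
      pl[[paste0("bh", gt)]] <- runif(H, -k, k)
    }
    layers[[l]] <- pl
  }
  head <- list(W1 = runif_mat(H, H, k), b1 = runif(H, -k, k),
               W2 = runif_mat(arch$n_classes, H, k),
               b2 = runif(arch$n_classes, -k, k))
  list(arch = arch, layers = layers, head = head)
}

sigm <- function(x) 1 / (1 + exp(-x))

# forward one layer over time; X list over t of B x I, mask B x T (1 valid)
layer_forward <- function(pl, cell, X, mask) {
  Tn <- length(X); B <- nrow(X[[1]]); H <- nrow(pl[[1]])
  h <- matrix(0, B, H); c <- matrix(0, B, H)
  Hs <- vector("list", Tn); cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    m <- mask[, t]
    x <- X[[t]] * m   # zero padded inputs
    if (cell == "lstm") {
      ai <- x %*% t(pl$Wii) + h %*% t(pl$Whi) + rep(pl$bii + pl$bhi, each = B)
      af <- x %*% t(pl$Wif) + h %*% t(pl$Whf) + rep(pl$bif + pl$bhf, each = B)
      ag <- x %*% t(pl$Wig) + h %*% t(pl$Whg) + rep(pl$big + pl$bhg, each = B)
      ao <- x %*% t(pl$Wio) + h %*% t(pl$Who) + rep(pl$bio + pl$bho, each = B)
      gi <- sigm(ai); gf <- sigm(af); gg <- tanh(ag); go <- sigm(ao)
      c_new <- gf * c + gi * gg
      tc <- tanh(c_new)
      h_new <- go * tc
      cache[[t]] <- list(x = x, h_prev = h, c_prev = c, gi = gi, gf = gf,
                         gg = gg, go = go, c_new = c_new, tc = tc, m = m)
      c <- m * c_new + (1 - m) * c
      h <- m * h_new + (1 - m) * h
    } else {
      ar <- x %*% t(pl$Wir) + h %*% t(pl$Whr) + rep(pl$bir + pl$bhr, each = B)
      az <- x %*% t(pl$Wiz) + h %*% t(pl$Whz) + rep(pl$biz + pl$bhz, each = B)
      q <- h %*% t(pl$Whn) + rep(pl$bhn, each = B)
      gr <- sigm(ar); gz <- sigm(az)
      an <- x %*% t(pl$Win) + rep(pl$bin, each = B) + gr * q
      gn <- tanh(an)
      h_new <- (1 - gz) * gn + gz * h
      cache[[t]] <- list(x = x, h_prev = h, gr = gr, gz = gz, gn = gn,
                         q = q, m = m)
      h <- m * h_new + (1 - m) * h
    }
    Hs[[t]] <- h
  }
  list(H = Hs, cache = cache)
}

# backward one layer; dH list over t of B x H gradients flowing into h_t
layer_backward <- function(pl, cell, dH, cache) {
  Tn <- length(dH); B <- nrow(dH[[1]])
  grads <- lapply(pl, function(w) if (is.matrix(w)) w * 0 else w * 0)
  H <- if (is.matrix(pl[[1]])) nrow(pl[[1]])
  dh_carry <- matrix(0, B, H); dc_carry <- matrix(0, B, H)
  dX <- vector("list", Tn)
  for (t in rev(seq_len(Tn))) {
    ca <- cache[[t]]
    m <- ca$m
    dh <- dH[[t]] + dh_carry
    dh_new <- dh * m
    dh_carry <- dh * (1 - m)
    if (cell == "lstm") {
      dc <- dc_carry
      dc_new <- dc * m
      dc_carry <- dc * (1 - m)
      dgo <- dh_new * ca$tc
      dct <- dh_new * ca$go * (1 - ca$tc^2) + dc_new
      dgf <- dct * ca$c_prev
      dgi <- dct * ca$gg
      dgg <- dct * ca$gi
      dc_carry <- dc_carry + dct * ca$gf
      dai <- dgi * ca$gi * (1 - ca$gi)
      daf <- dgf * ca$gf * (1 - ca$gf)
      dag <- dgg * (1 - ca$gg^2)
      dao <- dgo * ca$go * (1 - ca$go)
      for (gt in list(list("i", dai), list("f", daf), list("g", dag),
                      list("o", dao))) {
        nm <- gt[[1]]; da <- gt[[2]]
        grads[[paste0("Wi", nm)]] <- grads[[paste0("Wi", nm)]] + t(da) %*% ca$x
        grads[[paste0("Wh", nm)]] <- grads[[paste0("Wh", nm)]] + t(da) %*% ca$h_prev
        grads[[paste0("bi", nm)]] <- grads[[paste0("bi", nm)]] + colSums(da)
        grads[[paste0("bh", nm)]] <- grads[[paste0("bh", nm)]] + colSums(da)
      }
      dX[[t]] <- (dai %*% pl$Wii + daf %*% pl$Wif + dag %*% pl$Wig +
                  dao %*% pl$Wio) * m
      dh_carry <- dh_carry +
        dai %*% pl$Whi + daf %*% pl$Whf + dag %*% pl$Whg + dao %*% pl$Who
    } else {
      dgz <- dh_new * (ca$h_prev - ca$gn)
      dgn <- dh_new * (1 - ca$gz)
      dh_prev_direct <- dh_new * ca$gz
      dan <- dgn * (1 - ca$gn^2)
      dgr <- dan * ca$q
      dq <- dan * ca$gr
      dar <- dgr * ca$gr * (1 - ca$gr)
      daz <- dgz * ca$gz * (1 - ca$gz)
      grads$Win <- grads$Win + t(dan) %*% ca$x
      grads$bin <- grads$bin + colSums(dan)
      grads$Whn <- grads$Whn + t(dq) %*% ca$h_prev
      grads$bhn <- grads$bhn + colSums(dq)
      grads$Wir <- grads$Wir + t(dar) %*% ca$x
      grads$Whr <- grads$Whr + t(dar) %*% ca$h_prev
      grads$bir <- grads$bir + colSums(dar)
      grads$bhr <- grads$bhr + colSums(dar)
      grads$Wiz <- grads$Wiz + t(daz) %*% ca$x
      grads$Whz <- grads$Whz + t(daz) %*% ca$h_prev
      grads$biz <- grads$biz + colSums(daz)
      grads$bhz <- grads$bhz + colSums(daz)
      dX[[t]] <- (dar %*% pl$Wir + daz %*% pl$Wiz + dan %*% pl$Win) * m
      dh_carry <- dh_carry + dh_prev_direct +
        dar %*% pl$Whr + daz %*% pl$Whz + dq %*% pl$Whn
    }
  }
  list(grads = grads, dX = dX)
}

# full forward: x array B x T x F, mask B x T -> logits B x K (+ caches)
rnn_forward <- function(params, x, mask, want_cache = FALSE) {
  arch <- params$arch
  B <- dim(x)[1]; Tn <- dim(x)[2]
  X <- lapply(seq_len(Tn), function(t) x[, t, , drop = FALSE][, 1, ])
  X <- lapply(X, function(m) if (is.matrix(m)) m else matrix(m, B))
  caches <- vector("list", arch$num_layers)
  inp <- X
  for (l in seq_len(arch$num_layers)) {
    fw <- layer_forward(params$layers[[l]], arch$cell, inp, mask)
    caches[[l]] <- fw
    inp <- fw$H
  }
  # last valid step per sample (carry-through makes any later step identical,
  # but selecting it explicitly also covers all-padding rows)
  t_last <- apply(mask, 1, function(r) { w <- which(r == 1); if (length(w)) max(w) else 1L })
  h_last <- t(vapply(seq_len(B), function(b) inp[[t_last[b]]][b, ],
                     numeric(arch$hidden_size)))
  if (arch$hidden_size == 1L) h_last <- matrix(h_last, B)
  a1 <- h_last %*% t(params$head$W1) + rep(params$head$b1, each = B)
  r1 <- pmax(a1, 0)
  logits <- r1 %*% t(params$head$W2) + rep(params$head$b2, each = B)
  out <- list(logits = logits, t_last = t_last)
  if (want_cache) {
    out$caches <- caches
    out$h_last <- h_last
    out$a1 <- a1
    out$r1 <- r1
    out$top_H <- inp
  }
  out
}

rnn_backward <- function(params, x, mask, fw, dlogits) {
  arch <- params$arch
  B <- dim(x)[1]; Tn <- dim(x)[2]
  gh <- list(W2 = t(dlogits) %*% fw$r1, b2 = colSums(dlogits))
  dr1 <- dlogits %*% params$head$W2
  da1 <- dr1 * (fw$a1 > 0)
  gh$W1 <- t(da1) %*% fw$h_last
  gh$b1 <- colSums(da1)
  dh_last <- da1 %*% params$head$W1
  # inject head gradient at each sample's last valid step of the top layer
  dH_top <- lapply(seq_len(Tn), function(t) matrix(0, B, arch$hidden_size))
  for (b in seq_len(B)) dH_top[[fw$t_last[b]]][b, ] <-
    dH_top[[fw$t_last[b]]][b, ] + dh_last[b, ]
  glayers <- vector("list", arch$num_layers)
  dH <- dH_top
  for (l in rev(seq_len(arch$num_layers))) {
    bw <- layer_backward(params$layers[[l]], arch$cell, dH,
                         fw$caches[[l]]$cache)
    glayers[[l]] <- bw$grads
    dH <- bw$dX
  }
  list(layers = glayers, head = gh)
}

weighted_ce <- function(logits, y, class_w) {
  B <- nrow(logits)
  p <- softmax_rows(logits)
  w <- class_w[y + 1L]
  loss <- sum(-w * log(pmax(p[cbind(seq_len(B), y + 1L)], 1e-15))) / sum(w)
  dlogits <- p
  dlogits[cbind(seq_len(B), y + 1L)] <-
    dlogits[cbind(seq_len(B), y + 1L)] - 1
  dlogits <- dlogits * (w / sum(w))
  list(loss = loss, dlogits = dlogits)
}

# ---- training ---------------------------------------------------------------

#' Training configuration for recurrent classifiers
#'
#' Defaults follow the reference configuration: batch 64, learning rate
#' 0.001, 15 epochs, weight decay 1e-4, class-weighted cross-entropy.
#'
#' @param batch_size,learning_rate,epochs,weight_decay,seed usual meanings.
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 64L, learning_rate = 0.001,
                         epochs = 15L, weight_decay = 1e-4, seed = 42L) {
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "train_config")
}

flatten_params <- function(p) c(lapply(p$layers, unlist), list(unlist(p$head)))

#' Train a masked LSTM/GRU classifier on window samples
#'
#' Adam optimization of class-weighted cross-entropy. Padded rows are
#' carried through the recurrence unchanged and excluded from the loss;
#' batches consisting solely of padding are skipped with a warning.
#' Parameters are checkpointed each epoch and the model is reloaded from the
#' epoch with the best validation loss.
#'
#' @param arch a [recurrent_architecture()].
#' @param config a [train_config()].
#' @param x `n x T x F` array of window features.
#' @param y integer labels (0-based).
#' @param pad optional `n x T` validity mask (1 = real row); default all
#'   valid.
#' @param val_x,val_y optional validation windows.
#' @param class_w per-class loss weights (default: inverse frequency on `y`).
#' @return object of class `news2_rnn_model` with fitted parameters,
#'   per-epoch metric table, and `best_epoch`.
#' @export
train_recurrent <- function(arch, config, x, y, pad = NULL,
                            val_x = NULL, val_y = NULL, class_w = NULL) {
  stopifnot(inherits(arch, "recurrent_architecture"),
            inherits(config, "train_config"))
  n <- dim(x)[1]; Tn <- dim(x)[2]
  y <- as.integer(y)
  if (is.null(pad)) pad <- matrix(1, n, Tn)
  if (is.null(class_w)) {
    tab <- tabulate(y + 1L, nbins = arch$n_classes)
    class_w <- if (all(tab > 0)) as.numeric(class_weights(tab))
               else rep(1, arch$n_classes)
  }
  params <- rnn_init(arch, seed = config$seed)
  mstate <- rapply(params[c("layers", "head")], function(w) w * 0, how = "replace")
  vstate <- mstate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L
  set.seed(config$seed)
  history <- data.table(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_macro_f1 = numeric())
  checkpoints <- vector("list", config$epochs)
  best_val <- Inf; best_epoch <- 1L

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_n <- 0
    for (s in seq(1L, n, by = config$batch_size)) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      xb <- x[idx, , , drop = FALSE]
      mb <- pad[idx, , drop = FALSE]
      if (all(mb == 0)) { warning("skipping all-padding batch"); next }
      fw <- rnn_forward(params, xb, mb, want_cache = TRUE)
      lg <- weighted_ce(fw$logits, y[idx], class_w)
      gr <- rnn_backward(params, xb, mb, fw, lg$dlogits)
      step <- step + 1L
      for (part in c("layers", "head")) {
        # walk parallel nested lists: params/grads/adam moments
        upd <- function(p, g, m, v) {
          g <- g + config$weight_decay * p
          m <- b1 * m + (1 - b1) * g
          v <- b2 * v + (1 - b2) * g^2
          mh <- m / (1 - b1^step); vh <- v / (1 - b2^step)
          list(p = p - config$learning_rate * mh / (sqrt(vh) + eps),
               m = m, v = v)
        }
        if (part == "head") {
          for (nm in names(params$head)) {
            u <- upd(params$head[[nm]], gr$head[[nm]],
                     mstate$head[[nm]], vstate$head[[nm]])
            params$head[[nm]] <- u$p
            mstate$head[[nm]] <- u$m; vstate$head[[nm]] <- u$v
          }
        } else {
          for (l in seq_along(params$layers))
            for (nm in names(params$layers[[l]])) {
              u <- upd(params$layers[[l]][[nm]], gr$layers[[l]][[nm]],
                       mstate$layers[[l]][[nm]], vstate$layers[[l]][[nm]])
              params$layers[[l]][[nm]] <- u$p
              mstate$layers[[l]][[nm]] <- u$m; vstate$layers[[l]][[nm]] <- u$v
            }
        }
      }
      ep_loss <- ep_loss + lg$loss * length(idx); ep_n <- ep_n + length(idx)
    }
    vl <- NA_real_; vf1 <- NA_real_
    if (!is.null(val_x)) {
      fwv <- rnn_forward(params, val_x, matrix(1, dim(val_x)[1], Tn))
      vl <- weighted_ce(fwv$logits, as.integer(val_y), class_w)$loss
      pred <- max.col(fwv$logits, ties.method = "first") - 1L
      vf1 <- macro_f1(as.integer(val_y), pred, arch$n_classes)
      if (vl < best_val) { best_val <- vl; best_epoch <- ep }
    } else best_epoch <- ep
    checkpoints[[ep]] <- params
    history <- rbind(history, data.table(epoch = ep, train_loss = ep_loss / ep_n,
                                         val_loss = vl, val_macro_f1 = vf1))
  }
  structure(list(arch = arch, config = config,
                 params = checkpoints[[best_epoch]],
                 best_epoch = best_epoch, history = history,
                 class_w = class_w),
            class = "news2_rnn_model")
}

macro_f1 <- function(y, pred, k) {
  f1 <- vapply(seq_len(k) - 1L, function(c) {
    tp <- sum(y == c & pred == c)
    fp <- sum(y != c & pred == c)
    fn <- sum(y == c & pred != c)
    if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1, na.rm = TRUE)
}

#' Predict from a fitted recurrent model
#'
#' @param object fitted `news2_rnn_model`.
#' @param newdata `n x T x F` array.
#' @param pad optional `n x T` validity mask.
#' @param type `"prob"` or `"class"`.
#' @param ... unused.
#' @export
predict.news2_rnn_model <- function(object, newdata, pad = NULL,
                                    type = c("prob", "class"), ...) {
  type <- match.arg(type)
  n <- dim(newdata)[1]; Tn <- dim(newdata)[2]
  if (is.null(pad)) pad <- matrix(1, n, Tn)
  fw <- rnn_forward(object$params, newdata, pad)
  pr <- softmax_rows(fw$logits)
  if (type == "prob") pr else max.col(pr, ties.method = "first") - 1L
}

#' @export
print.news2_rnn_model <- function(x, ...) {
  cat(sprintf("<masked %s: %d layer(s) x %d units, best epoch %d/%d>\n",
              toupper(x$arch$cell), x$arch$num_layers, x$arch$hidden_size,
              x$best_epoch, nrow(x$history)))
  invisible(x)
}
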