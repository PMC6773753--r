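# A compact LSTM sequence classifier written with base R matrix operations:
# embedding (fine-tuned) -> LSTM (tanh, last hidden state only) -> dropout ->
# dense softmax, trained with Adam on categorical cross-entropy. Designed for
# desk-scale corpora; everything is deterministic under the seed.

#' Random word-embedding table
#'
#' Builds a small Gaussian-initialized embedding table for a vocabulary,
#' useful for fully offline tests and experiments in place of large
#' pretrained tweet vectors.
#'
#' @param words Character vector of vocabulary words.
#' @param dim Embedding dimension (the pipeline default is 100, matching
#'   public pretrained tweet vectors).
#' @param seed Integer seed.
#' @param sd Standard deviation of the initial values.
#' @return A numeric matrix with one named row per word.
#' @export
random_embeddings <- function(words, dim = 100, seed = 1, sd = 0.1) {
  words <- unique(words)
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(length(words) * dim, sd = sd),
                nrow = length(words), ncol = dim)
  })
  rownames(m) <- words
  m
}

#' LSTM sequence classifier
#'
#' Trains the sequence model: an input layer of word-embedding vectors
#' (out-of-vocabulary words start as zero vectors and are updated during
#' training, as is the whole embedding table), an LSTM layer (default 128
#' units, tanh activation) of which only the last hidden state is used, a
#' dropout layer (default probability 0.5), and a fully connected softmax
#' layer over the classes. Sequences are right-padded with zeros to
#' `max_len` (default 800 tokens); longer sequences are truncated and the
#' count is reported. Training runs `epochs` iterations (default 15) of
#' minibatch Adam on categorical cross-entropy. Fixed `seed` gives identical
#' weights across runs.
#'
#' @param tokens List of token vectors from [embed_tokenize()].
#' @param labels Class labels, one per sequence.
#' @param embeddings Embedding matrix with words as row names (e.g.
#'   pretrained 100-dimensional tweet vectors, or [random_embeddings()]).
#' @param units LSTM hidden dimension.
#' @param epochs Training iterations over the data.
#' @param max_len Sequence length after right-padding/truncation.
#' @param batch_size Minibatch size.
#' @param dropout Dropout probability on the last hidden state.
#' @param learning_rate Adam step size.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @return A fitted model of class `bd_lstm`.
#' @export
train_lstm <- function(tokens, labels, embeddings, units = 128, epochs = 15,
                       max_len = 800, batch_size = 32, dropout = 0.5,
                       learning_rate = 0.01, seed = 1) {
  labels <- factor(as.character(labels), levels = class_levels(labels))
  k <- nlevels(labels)
  vocab <- unique(c(rownames(embeddings),
                    setdiff(unique(unlist(tokens)), rownames(embeddings))))
  d <- ncol(embeddings)
  # row 1 is the frozen zero padding vector; OOV words start at zero but train
  emb <- matrix(0, nrow = length(vocab) + 1, ncol = d)
  known <- intersect(vocab, rownames(embeddings))
  emb[match(known, vocab) + 1, ] <- embeddings[known, , drop = FALSE]
  ids <- encode_sequences(tokens, vocab, max_len)

  withr::with_seed(seed, {
    rg <- function(nr, nc) matrix(runif(nr * nc, -0.08, 0.08), nr, nc)
    par <- list(Wx = rg(d, 4 * units), Wh = rg(units, 4 * units),
                b = numeric(4 * units), Wy = rg(units, k), by = numeric(k),
                Emb = emb)
    opt <- adam_state(par)
    n <- nrow(ids)
    y <- diag(k)[as.integer(labels), , drop = FALSE]
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        bidx <- ord[start:min(start + batch_size - 1, n)]
        mask <- (matrix(runif(length(bidx) * units), length(bidx), units) >=
                   dropout) / (1 - dropout)
        grads <- lstm_grad(par, ids[bidx, , drop = FALSE],
                           y[bidx, , drop = FALSE], units, mask)
        opt <- adam_step(par, grads, opt, learning_rate)
        par <- opt$par
        par$Emb[1, ] <- 0
      }
    }
  })
  structure(list(kind = "lstm", classes = levels(labels), par = par,
                 vocab = vocab, units = units, max_len = max_len,
                 dropout = dropout, epochs = epochs, seed = seed,
                 n_train = length(tokens)),
            class = c("bd_lstm", "bd_model"))
}

encode_sequences <- function(tokens, vocab, max_len) {
  idx <- setNames(seq_along(vocab), vocab)
  truncated <- sum(lengths(tokens) > max_len)
  if (truncated > 0) {
    message(truncated, " sequence(s) longer than ", max_len, " truncated")
  }
  ids <- matrix(0L, nrow = length(tokens), ncol = max_len)
  for (i in seq_along(tokens)) {
    t <- head(tokens[[i]], max_len)
    v <- unname(idx[t])
    v[is.na(v)] <- 0L  # unseen at predict time: the zero vector
    if (length(v) > 0) ids[i, seq_along(v)] <- v
  }
  ids
}

sigm <- function(x) 1 / (1 + exp(-x))

lstm_forward <- function(par, ids, units, cache = FALSE) {
  nb <- nrow(ids); tmax <- ncol(ids)
  h <- matrix(0, nb, units); cc <- matrix(0, nb, units)
  steps <- if (cache) vector("list", tmax) else NULL
  iu <- seq_len(units)
  for (t in seq_len(tmax)) {
    x <- par$Emb[ids[, t] + 1L, , drop = FALSE]
    z <- x %*% par$Wx + h %*% par$Wh +
      matrix(par$b, nb, 4 * units, byrow = TRUE)
    gi <- sigm(z[, iu, drop = FALSE])
    gf <- sigm(z[, iu + units, drop = FALSE])
    go <- sigm(z[, iu + 2 * units, drop = FALSE])
    gg <- tanh(z[, iu + 3 * units, drop = FALSE])
    c_prev <- cc
    h_prev <- h
    cc <- gf * cc + gi * gg
    h <- go * tanh(cc)
    if (cache) {
      steps[[t]] <- list(gi = gi, gf = gf, go = go, gg = gg, c = cc,
                         c_prev = c_prev, h_prev = h_prev)
    }
  }
  list(h = h, steps = steps)
}

lstm_grad <- function(par, ids, y, units, mask) {
  nb <- nrow(ids); tmax <- ncol(ids)
  fw <- lstm_forward(par, ids, units, cache = TRUE)
  hd <- fw$h * mask
  logits <- hd %*% par$Wy + matrix(par$by, nb, ncol(par$Wy), byrow = TRUE)
  p <- softmax_rows(logits)
  dlog <- (p - y) / nb
  g <- list(Wx = 0 * par$Wx, Wh = 0 * par$Wh, b = 0 * par$b,
            Wy = crossprod(hd, dlog), by = colSums(dlog),
            Emb = 0 * par$Emb)
  dh <- (dlog %*% t(par$Wy)) * mask
  dc <- matrix(0, nb, units)
  for (t in rev(seq_len(tmax))) {
    s <- fw$steps[[t]]
    tc <- tanh(s$c)
    dgo <- dh * tc * s$go * (1 - s$go)
    dc <- dc + dh * s$go * (1 - tc^2)
    dgf <- dc * s$c_prev * s$gf * (1 - s$gf)
    dgi <- dc * s$gg * s$gi * (1 - s$gi)
    dgg <- dc * s$gi * (1 - s$gg^2)
    dz <- cbind(dgi, dgf, dgo, dgg)
    x <- par$Emb[ids[, t] + 1L, , drop = FALSE]
    g$Wx <- g$Wx + crossprod(x, dz)
    g$Wh <- g$Wh + crossprod(s$h_prev, dz)
    g$b <- g$b + colSums(dz)
    dx <- dz %*% t(par$Wx)
    rows <- ids[, t] + 1L
    for (r in unique(rows[rows > 1L])) {
      g$Emb[r, ] <- g$Emb[r, ] + colSums(dx[rows == r, , drop = FALSE])
    }
    dh <- dz %*% t(par$Wh)
    dc <- dc * s$gf
  }
  g
}

adam_state <- function(par) {
  list(par = par, m = lapply(par, function(p) 0 * p),
       v = lapply(par, function(p) 0 * p), t = 0)
}

adam_step <- function(par, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1
  for (nm in names(par)) {
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * grads[[nm]]
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  opt$par <- par
  opt
}

#' @export
predict.bd_lstm <- function(object, tokens, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  ids <- encode_sequences(tokens, object$vocab, object$max_len)
  fw <- lstm_forward(object$par, ids, object$units)
  logits <- fw$h %*% object$par$Wy +
    matrix(object$par$by, nrow(ids), length(object$classes), byrow = TRUE)
  p <- softmax_rows(logits)
  colnames(p) <- object$classes
  if (type == "class") {
    factor(object$classes[max.col(p, ties.method = "first")],
           levels = object$classes)
  } else {
    p
  }
}

#' @exportS3Method generics::glance
glance.bd_lstm <- function(x, ...) {
  tibble::tibble(kind = "lstm", n_train = x$n_train, units = x$units,
                 max_len = x$max_len, epochs = x$epochs,
                 vocab_size = length(x$vocab),
                 n_classes = length(x$classes))
}
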