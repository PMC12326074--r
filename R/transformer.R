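# SMILES transformer autoencoder.
#
# Encoder: token embedding + sinusoidal positional encoding followed by
# n_blocks post-norm transformer blocks (multi-head self-attention, residual,
# layer norm, position-wise feed-forward, residual, layer norm). The
# reconstruction head is a stack of n_linear_layers position-wise linear
# layers (ReLU between) mapping final states to vocabulary logits; training
# minimises token cross-entropy against the input sequence, i.e. a
# non-autoregressive sequence-to-sequence autoencoder.
#
# The molecular fingerprint is the concatenation over blocks of the max-pool
# (over sequence positions) of each block's output: n_blocks * embed_dim
# dimensions, 4 * 256 = 1024 under the default architecture.
#
# Implemented in plain R with manual backpropagation: no deep-learning
# runtime is assumed, desk-scale corpora are the design point, and
# single-threaded R matrix ops keep training bit-reproducible per seed.

#' Encoder architecture configuration
#'
#' Defaults reproduce the reference architecture: 4 transformer blocks,
#' 4 attention heads, 256 embedding dimensions, a 2-linear-layer
#' reconstruction head, giving 4 x 256 = 1024 fingerprint dimensions.
#'
#' @param n_blocks number of transformer blocks.
#' @param n_heads attention heads per block; must divide `embed_dim`.
#' @param embed_dim model width.
#' @param n_linear_layers linear layers in the reconstruction head (1 or 2).
#' @param max_sequence_length longest token sequence accepted.
#' @param vocab optional ordered token vocabulary; built from the corpus at
#'   pretraining time when `NULL`.
#' @param seed integer seed for weight initialisation.
#' @return an `encoder_config` list.
#' @export
encoder_config <- function(n_blocks = 4L, n_heads = 4L, embed_dim = 256L,
                           n_linear_layers = 2L, max_sequence_length = 128L,
                           vocab = NULL, seed = 0L) {
  stopifnot(n_blocks >= 1L, n_heads >= 1L, embed_dim >= n_heads,
            n_linear_layers >= 1L, max_sequence_length >= 1L)
  if (embed_dim %% n_heads != 0L) {
    stop("embed_dim must be divisible by n_heads")
  }
  structure(list(n_blocks = as.integer(n_blocks),
                 n_heads = as.integer(n_heads),
                 embed_dim = as.integer(embed_dim),
                 n_linear_layers = as.integer(n_linear_layers),
                 max_sequence_length = as.integer(max_sequence_length),
                 vocab = vocab, seed = as.integer(seed)),
            class = "encoder_config")
}

#' Pretraining configuration
#'
#' @param corpus_path optional path to a one-SMILES-per-line corpus file.
#' @param n_samples number of corpus entries used (the full-scale default in
#'   the reference workflow is 861000 unlabeled SMILES; desk-scale runs use
#'   far fewer).
#' @param epochs training epochs.
#' @param batch_size sequences per optimiser step.
#' @param learning_rate Adam learning rate.
#' @param seed integer seed for shuffling/noise during training.
#' @return a `pretrain_config` list.
#' @export
pretrain_config <- function(corpus_path = NULL, n_samples = 861000L,
                            epochs = 10L, batch_size = 16L,
                            learning_rate = 1e-3, seed = 0L) {
  stopifnot(n_samples >= 1L, epochs >= 1L, batch_size >= 1L,
            learning_rate > 0)
  structure(list(corpus_path = corpus_path, n_samples = as.integer(n_samples),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "pretrain_config")
}

# ---- parameter initialisation -------------------------------------------

.glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

st_init_params <- function(cfg, vocab_size) {
  d <- cfg$embed_dim
  dff <- 4L * d
  set.seed(cfg$seed)
  p <- list(embed = matrix(stats::rnorm(vocab_size * d, sd = 0.05), vocab_size, d))
  for (b in seq_len(cfg$n_blocks)) {
    pre <- sprintf("b%d.", b)
    p[[paste0(pre, "Wq")]] <- .glorot(d, d)
    p[[paste0(pre, "Wk")]] <- .glorot(d, d)
    p[[paste0(pre, "Wv")]] <- .glorot(d, d)
    p[[paste0(pre, "Wo")]] <- .glorot(d, d)
    p[[paste0(pre, "bq")]] <- numeric(d)
    p[[paste0(pre, "bk")]] <- numeric(d)
    p[[paste0(pre, "bv")]] <- numeric(d)
    p[[paste0(pre, "bo")]] <- numeric(d)
    p[[paste0(pre, "ln1.g")]] <- rep(1, d)
    p[[paste0(pre, "ln1.b")]] <- numeric(d)
    p[[paste0(pre, "W1")]] <- .glorot(d, dff)
    p[[paste0(pre, "b1")]] <- numeric(dff)
    p[[paste0(pre, "W2")]] <- .glorot(dff, d)
    p[[paste0(pre, "b2")]] <- numeric(d)
    p[[paste0(pre, "ln2.g")]] <- rep(1, d)
    p[[paste0(pre, "ln2.b")]] <- numeric(d)
  }
  # reconstruction head: n_linear_layers position-wise linear maps to vocab
  if (cfg$n_linear_layers == 1L) {
    p[["head.W1"]] <- .glorot(d, vocab_size)
    p[["head.c1"]] <- numeric(vocab_size)
  } else {
    p[["head.W1"]] <- .glorot(d, d)
    p[["head.c1"]] <- numeric(d)
    p[["head.W2"]] <- .glorot(d, vocab_size)
    p[["head.c2"]] <- numeric(vocab_size)
  }
  p
}

# sinusoidal positional encoding, L x d
.pos_encoding <- function(L, d) {
  pos <- matrix(0, L, d)
  position <- seq_len(L) - 1
  i <- seq(0, d - 1, by = 2)
  div <- exp(-log(10000) * i / d)
  ang <- outer(position, div)
  pos[, i + 1] <- sin(ang)
  if (d > 1) {
    j <- pmin(i + 2, d)
    pos[, j] <- cos(ang[, seq_along(i), drop = FALSE])
  }
  pos
}

# ---- layer forward/backward ---------------------------------------------

.LN_EPS <- 1e-5

ln_forward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  istd <- 1 / sqrt(v + .LN_EPS)
  xhat <- xc * istd
  list(out = sweep(xhat, 2, g, "*") + rep(b, each = nrow(x)),
       cache = list(xhat = xhat, istd = istd, xc = xc, g = g))
}

ln_backward <- function(dout, cache) {
  d <- ncol(dout)
  dxhat <- sweep(dout, 2, cache$g, "*")
  # per-row reductions
  s1 <- rowSums(dxhat)
  s2 <- rowSums(dxhat * cache$xhat)
  dx <- (dxhat - s1 / d - cache$xhat * s2 / d) * cache$istd
  list(dx = dx,
       dg = colSums(dout * cache$xhat),
       db = colSums(dout))
}

mha_forward <- function(x, p, pre, n_heads) {
  d <- ncol(x); dk <- d %/% n_heads; s <- 1 / sqrt(dk)
  Q <- x %*% p[[paste0(pre, "Wq")]] + rep(p[[paste0(pre, "bq")]], each = nrow(x))
  K <- x %*% p[[paste0(pre, "Wk")]] + rep(p[[paste0(pre, "bk")]], each = nrow(x))
  V <- x %*% p[[paste0(pre, "Wv")]] + rep(p[[paste0(pre, "bv")]], each = nrow(x))
  O <- matrix(0, nrow(x), d)
  A_list <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    S <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) * s
    S <- S - apply(S, 1, max)            # row-wise stabilisation
    E <- exp(S)
    A <- E / rowSums(E)
    A_list[[h]] <- A
    O[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  out <- O %*% p[[paste0(pre, "Wo")]] + rep(p[[paste0(pre, "bo")]], each = nrow(x))
  list(out = out, cache = list(x = x, Q = Q, K = K, V = V, O = O,
                               A = A_list, n_heads = n_heads, s = s))
}

mha_backward <- function(dout, cache, p, pre) {
  x <- cache$x; n_heads <- cache$n_heads; s <- cache$s
  d <- ncol(x); dk <- d %/% n_heads
  g <- list()
  g[[paste0(pre, "Wo")]] <- t(cache$O) %*% dout
  g[[paste0(pre, "bo")]] <- colSums(dout)
  dO <- dout %*% t(p[[paste0(pre, "Wo")]])
  dQ <- matrix(0, nrow(x), d); dK <- dQ; dV <- dQ
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    A <- cache$A[[h]]
    dOh <- dO[, cols, drop = FALSE]
    dA <- dOh %*% t(cache$V[, cols, drop = FALSE])
    dV[, cols] <- t(A) %*% dOh
    dS <- A * (dA - rowSums(dA * A))
    dQ[, cols] <- (dS %*% cache$K[, cols, drop = FALSE]) * s
    dK[, cols] <- (t(dS) %*% cache$Q[, cols, drop = FALSE]) * s
  }
  g[[paste0(pre, "Wq")]] <- t(x) %*% dQ
  g[[paste0(pre, "bq")]] <- colSums(dQ)
  g[[paste0(pre, "Wk")]] <- t(x) %*% dK
  g[[paste0(pre, "bk")]] <- colSums(dK)
  g[[paste0(pre, "Wv")]] <- t(x) %*% dV
  g[[paste0(pre, "bv")]] <- colSums(dV)
  dx <- dQ %*% t(p[[paste0(pre, "Wq")]]) +
        dK %*% t(p[[paste0(pre, "Wk")]]) +
        dV %*% t(p[[paste0(pre, "Wv")]])
  list(dx = dx, grads = g)
}

ffn_forward <- function(x, p, pre) {
  H <- x %*% p[[paste0(pre, "W1")]] + rep(p[[paste0(pre, "b1")]], each = nrow(x))
  Hr <- pmax(H, 0)
  out <- Hr %*% p[[paste0(pre, "W2")]] + rep(p[[paste0(pre, "b2")]], each = nrow(x))
  list(out = out, cache = list(x = x, H = H, Hr = Hr))
}

ffn_backward <- function(dout, cache, p, pre) {
  g <- list()
  g[[paste0(pre, "W2")]] <- t(cache$Hr) %*% dout
  g[[paste0(pre, "b2")]] <- colSums(dout)
  dHr <- dout %*% t(p[[paste0(pre, "W2")]])
  dH <- dHr * (cache$H > 0)
  g[[paste0(pre, "W1")]] <- t(cache$x) %*% dH
  g[[paste0(pre, "b1")]] <- colSums(dH)
  list(dx = dH %*% t(p[[paste0(pre, "W1")]]), grads = g)
}

# full encoder forward on one id sequence; returns block outputs and caches
st_forward <- function(p, cfg, ids, need_cache = FALSE) {
  d <- cfg$embed_dim
  L <- length(ids)
  x <- p$embed[ids, , drop = FALSE] * sqrt(d) + .pos_encoding(L, d)
  block_out <- vector("list", cfg$n_blocks)
  caches <- if (need_cache) vector("list", cfg$n_blocks) else NULL
  for (b in seq_len(cfg$n_blocks)) {
    pre <- sprintf("b%d.", b)
    att <- mha_forward(x, p, pre, cfg$n_heads)
    r1 <- x + att$out
    n1 <- ln_forward(r1, p[[paste0(pre, "ln1.g")]], p[[paste0(pre, "ln1.b")]])
    ff <- ffn_forward(n1$out, p, pre)
    r2 <- n1$out + ff$out
    n2 <- ln_forward(r2, p[[paste0(pre, "ln2.g")]], p[[paste0(pre, "ln2.b")]])
    if (need_cache) {
      caches[[b]] <- list(x_in = x, att = att$cache, ln1 = n1$cache,
                          ffn = ff$cache, ln2 = n2$cache)
    }
    x <- n2$out
    block_out[[b]] <- x
  }
  list(block_out = block_out, top = x, caches = caches, ids = ids)
}

head_forward <- function(p, cfg, top) {
  if (cfg$n_linear_layers == 1L) {
    logits <- top %*% p$head.W1 + rep(p$head.c1, each = nrow(top))
    list(logits = logits, cache = list(top = top))
  } else {
    H <- top %*% p$head.W1 + rep(p$head.c1, each = nrow(top))
    Hr <- pmax(H, 0)
    logits <- Hr %*% p$head.W2 + rep(p$head.c2, each = nrow(top))
    list(logits = logits, cache = list(top = top, H = H, Hr = Hr))
  }
}

# softmax cross-entropy over positions; returns loss and dlogits
ce_loss <- function(logits, targets) {
  m <- apply(logits, 1, max)
  E <- exp(logits - m)
  P <- E / rowSums(E)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), targets)
  loss <- -mean(log(pmax(P[idx], 1e-300)))
  dlog <- P
  dlog[idx] <- dlog[idx] - 1
  list(loss = loss, dlogits = dlog / n)
}

# backward through head + all blocks + embedding for one sequence
st_backward <- function(p, cfg, fwd, hcache, dlogits) {
  g <- list()
  if (cfg$n_linear_layers == 1L) {
    g$head.W1 <- t(hcache$top) %*% dlogits
    g$head.c1 <- colSums(dlogits)
    dx <- dlogits %*% t(p$head.W1)
  } else {
    g$head.W2 <- t(hcache$Hr) %*% dlogits
    g$head.c2 <- colSums(dlogits)
    dHr <- dlogits %*% t(p$head.W2)
    dH <- dHr * (hcache$H > 0)
    g$head.W1 <- t(hcache$top) %*% dH
    g$head.c1 <- colSums(dH)
    dx <- dH %*% t(p$head.W1)
  }
  for (b in rev(seq_len(cfg$n_blocks))) {
    pre <- sprintf("b%d.", b)
    cc <- fwd$caches[[b]]
    l2 <- ln_backward(dx, cc$ln2)
    g[[paste0(pre, "ln2.g")]] <- l2$dg
    g[[paste0(pre, "ln2.b")]] <- l2$db
    fb <- ffn_backward(l2$dx, cc$ffn, p, pre)
    g <- c(g, fb$grads)
    dn1 <- l2$dx + fb$dx
    l1 <- ln_backward(dn1, cc$ln1)
    g[[paste0(pre, "ln1.g")]] <- l1$dg
    g[[paste0(pre, "ln1.b")]] <- l1$db
    ab <- mha_backward(l1$dx, cc$att, p, pre)
    g <- c(g, ab$grads)
    dx <- l1$dx + ab$dx
  }
  dE <- matrix(0, nrow(p$embed), ncol(p$embed))
  sc <- sqrt(cfg$embed_dim)
  for (i in seq_along(fwd$ids)) {
    dE[fwd$ids[i], ] <- dE[fwd$ids[i], ] + dx[i, ] * sc
  }
  g$embed <- dE
  g
}

# loss + grads for one sequence (ids reconstruct themselves)
st_seq_loss_grad <- function(p, cfg, ids, want_grad = TRUE) {
  fwd <- st_forward(p, cfg, ids, need_cache = want_grad)
  hd <- head_forward(p, cfg, fwd$top)
  cl <- ce_loss(hd$logits, ids)
  if (!want_grad) return(list(loss = cl$loss))
  list(loss = cl$loss, grads = st_backward(p, cfg, fwd, hd$cache, cl$dlogits))
}

# ---- training ------------------------------------------------------------

adam_init <- function(p) {
  list(m = lapply(p, function(w) w * 0), v = lapply(p, function(w) w * 0),
       t = 0L)
}

adam_step <- function(p, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  corr1 <- 1 - beta1^st$t
  corr2 <- 1 - beta2^st$t
  for (nm in names(g)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    p[[nm]] <- p[[nm]] - lr * (st$m[[nm]] / corr1) /
      (sqrt(st$v[[nm]] / corr2) + eps)
  }
  list(p = p, st = st)
}

#' Instantiate an untrained (randomly initialised) SMILES transformer
#'
#' @param enc_cfg an [encoder_config()]; its `vocab` must be set (e.g. via
#'   [build_vocab()]).
#' @return an `st_model` handle with random weights.
#' @export
st_model <- function(enc_cfg) {
  stopifnot(inherits(enc_cfg, "encoder_config"))
  if (is.null(enc_cfg$vocab)) stop("enc_cfg$vocab must be set (see build_vocab)")
  params <- st_init_params(enc_cfg, length(enc_cfg$vocab))
  structure(list(cfg = enc_cfg, vocab = enc_cfg$vocab, params = params,
                 trained = FALSE, loss_trace = numeric(0)),
            class = "st_model")
}

#' @export
print.st_model <- function(x, ...) {
  cat(sprintf("SMILES transformer: %d blocks, %d heads, width %d, vocab %d, %s\n",
              x$cfg$n_blocks, x$cfg$n_heads, x$cfg$embed_dim, length(x$vocab),
              if (x$trained) sprintf("trained (%d epochs)", length(x$loss_trace))
              else "untrained"))
  invisible(x)
}

#' Pretrain the sequence-to-sequence SMILES autoencoder
#'
#' Trains the encoder + reconstruction head to reproduce each input token
#' sequence (cross-entropy over positions) with Adam. Deterministic for a
#' fixed pair of seeds under single-threaded BLAS.
#'
#' @param corpus character vector of SMILES strings (or the file named in
#'   `pre_cfg$corpus_path` when `corpus` is `NULL`).
#' @param enc_cfg an [encoder_config()].
#' @param pre_cfg a [pretrain_config()].
#' @return a trained `st_model`; `$loss_trace` holds the mean per-epoch loss.
#' @export
pretrain_autoencoder <- function(corpus = NULL, enc_cfg = encoder_config(),
                                 pre_cfg = pretrain_config()) {
  if (is.null(corpus)) {
    if (is.null(pre_cfg$corpus_path)) stop("no corpus given")
    corpus <- read_smiles_corpus(pre_cfg$corpus_path)
  }
  if (length(corpus) == 0) stop("empty SMILES corpus")
  bad <- corpus[!vapply(corpus, function(s)
    tryCatch({ tokenize(s); TRUE }, error = function(e) FALSE), logical(1))]
  if (length(bad) > 0) {
    stop("untokenizable SMILES in corpus: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (length(corpus) > pre_cfg$n_samples) {
    set.seed(pre_cfg$seed)
    corpus <- corpus[sample.int(length(corpus), pre_cfg$n_samples)]
  }
  if (is.null(enc_cfg$vocab)) enc_cfg$vocab <- build_vocab(corpus)
  ids_list <- lapply(corpus, token_ids, vocab = enc_cfg$vocab)
  lens <- lengths(ids_list)
  if (any(lens > enc_cfg$max_sequence_length)) {
    stop(sprintf("%d corpus sequences exceed max_sequence_length=%d",
                 sum(lens > enc_cfg$max_sequence_length),
                 enc_cfg$max_sequence_length))
  }
  p <- st_init_params(enc_cfg, length(enc_cfg$vocab))
  st <- adam_init(p)
  set.seed(pre_cfg$seed)
  trace <- numeric(pre_cfg$epochs)
  n <- length(ids_list)
  for (ep in seq_len(pre_cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    i <- 1L
    while (i <= n) {
      batch <- ord[i:min(i + pre_cfg$batch_size - 1L, n)]
      acc <- NULL
      bl <- 0
      for (k in batch) {
        lg <- st_seq_loss_grad(p, enc_cfg, ids_list[[k]])
        bl <- bl + lg$loss
        if (is.null(acc)) {
          acc <- lg$grads
        } else {
          for (nm in names(lg$grads)) acc[[nm]] <- acc[[nm]] + lg$grads[[nm]]
        }
      }
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / length(batch)
      upd <- adam_step(p, acc, st, pre_cfg$learning_rate)
      p <- upd$p; st <- upd$st
      ep_loss <- ep_loss + bl
      i <- i + pre_cfg$batch_size
    }
    trace[ep] <- ep_loss / n
  }
  structure(list(cfg = enc_cfg, vocab = enc_cfg$vocab, params = p,
                 trained = TRUE, loss_trace = trace),
            class = "st_model")
}

#' Token-level reconstruction accuracy of the autoencoder
#'
#' @param model an `st_model`.
#' @param smiles character vector of SMILES.
#' @return fraction of token positions whose argmax logit equals the input
#'   token, pooled over the whole set.
#' @export
reconstruction_accuracy <- function(model, smiles) {
  stopifnot(inherits(model, "st_model"))
  hits <- 0L; total <- 0L
  for (s in smiles) {
    ids <- token_ids(s, model$vocab)
    fwd <- st_forward(model$params, model$cfg, ids)
    logits <- head_forward(model$params, model$cfg, fwd$top)$logits
    pred <- max.col(logits, ties.method = "first")
    hits <- hits + sum(pred == ids)
    total <- total + length(ids)
  }
  hits / total
}

#' Extract a pooled transformer fingerprint for one molecule
#'
#' The fingerprint concatenates, block by block, the maximum over sequence
#' positions of each coordinate of that block's output: length
#' `n_blocks * embed_dim`, 1024 under the default architecture.
#'
#' @param model an `st_model` (trained or randomly initialised).
#' @param smiles a single SMILES string.
#' @return a `fingerprint` object: list with `values`, `dim`, `smiles`.
#' @export
extract_fingerprint <- function(model, smiles) {
  stopifnot(inherits(model, "st_model"))
  ids <- token_ids(smiles, model$vocab)
  fwd <- st_forward(model$params, model$cfg, ids)
  vals <- unlist(lapply(fwd$block_out, function(m) apply(m, 2, max)),
                 use.names = FALSE)
  structure(list(values = vals, dim = length(vals), smiles = smiles),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("fingerprint: %d dims for '%s'\n", x$dim, x$smiles))
  invisible(x)
}

#' Embed every compound of a target dataset
#'
#' @param model an `st_model`.
#' @param dataset a `target_dataset` (see [aggregate_replicates()]) or a
#'   data.frame with `compound_id` and `smiles` columns.
#' @return numeric matrix, one fingerprint row per record in dataset order;
#'   rownames are compound ids.
#' @export
embed_dataset <- function(model, dataset) {
  recs <- if (inherits(dataset, "target_dataset")) dataset$records else dataset
  fdim <- model$cfg$n_blocks * model$cfg$embed_dim
  out <- matrix(0, nrow(recs), fdim)
  if (nrow(recs) > 0) {
    for (i in seq_len(nrow(recs))) {
      fp <- tryCatch(extract_fingerprint(model, recs$smiles[i]),
                     error = function(e)
                       stop(sprintf("compound '%s': %s", recs$compound_id[i],
                                    conditionMessage(e)), call. = FALSE))
      out[i, ] <- fp$values
    }
    rownames(out) <- recs$compound_id
  }
  out
}

#' Read a one-SMILES-per-line corpus file
#'
#' @param path corpus file path.
#' @return character vector of SMILES (blank lines dropped).
#' @export
read_smiles_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  x <- readLines(path, warn = FALSE)
  x[nzchar(trimws(x))]
}
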