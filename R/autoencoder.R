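#' Autoencoder configuration
#'
#' Defaults are sized for desk-scale CPU training on binarized 30-min daily
#' signature matrices (48 time steps): a single-layer GRU encoder whose
#' final hidden state is the latent code, or a two-block 1-D convolutional
#' encoder (16 and 8 filters, kernel 5, max-pool 2) followed by a dense
#' map to the latent space. Both decode through a dense sigmoid layer back
#' to the full day, trained under binary log loss; the encoder is what
#' defines the embedding, and the dense decoder keeps the reconstruction
#' objective identical while training fast and stably on a CPU.
#'
#' @param arch `"gru"` or `"conv1d"`.
#' @param n_bins Time steps per day (default 48).
#' @param n_sensors Number of sensor channels.
#' @param latent_dim Embedding size (default 32 for GRU — the hidden state
#'   size — and 16 for conv1d). Must be smaller than `n_bins * n_sensors`.
#' @param conv_filters Filters of the two convolutional blocks.
#' @param kernel_size Convolution kernel length (time steps).
#' @param pool Max-pool width.
#' @param optimizer `"adam"` (default), `"rmsprop"` or `"sgd"`.
#' @param lr Learning rate.
#' @param epochs Training epochs (default 200).
#' @param batch_size Mini-batch size (default 16).
#' @param seed RNG seed for initialization and batch order.
#' @return An `ae_config` list.
#' @export
ae_config <- function(arch = c("gru", "conv1d"), n_bins = 48, n_sensors,
                      latent_dim = NULL, conv_filters = c(16, 8),
                      kernel_size = 5, pool = 2,
                      optimizer = c("adam", "rmsprop", "sgd"),
                      lr = 0.01, epochs = 200, batch_size = 16, seed = 1) {
  arch <- match.arg(arch)
  optimizer <- match.arg(optimizer)
  if (is.null(latent_dim)) latent_dim <- if (arch == "gru") 32L else 16L
  if (latent_dim >= n_bins * n_sensors) {
    stop("latent_dim must be smaller than n_bins * n_sensors (compression)")
  }
  structure(list(arch = arch, n_bins = as.integer(n_bins),
                 n_sensors = as.integer(n_sensors),
                 latent_dim = as.integer(latent_dim),
                 conv_filters = as.integer(conv_filters),
                 kernel_size = as.integer(kernel_size), pool = as.integer(pool),
                 optimizer = optimizer, lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "ae_config")
}

glorot <- function(nr, nc) {
  l <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -l, l), nr, nc)
}

init_ae_params <- function(cfg) {
  T_ <- cfg$n_bins; S <- cfg$n_sensors; H <- cfg$latent_dim
  if (cfg$arch == "gru") {
    p <- list(
      W_z = glorot(S, H), W_r = glorot(S, H), W_h = glorot(S, H),
      U_z = glorot(H, H), U_r = glorot(H, H), U_h = glorot(H, H),
      b_z = numeric(H), b_r = numeric(H), b_h = numeric(H),
      Wd = glorot(H, T_ * S), bd = numeric(T_ * S)
    )
  } else {
    k <- cfg$kernel_size; f1 <- cfg$conv_filters[1]; f2 <- cfg$conv_filters[2]
    p <- cfg$pool
    T1 <- (T_ - k + 1L) %/% p
    T2 <- (T1 - k + 1L) %/% p
    if (T2 < 1) stop("input too short for the convolutional stack")
    p <- list(
      K1 = glorot(k * S, f1), b1 = numeric(f1),
      K2 = glorot(k * f1, f2), b2 = numeric(f2),
      Wl = glorot(T2 * f2, cfg$latent_dim), bl = numeric(cfg$latent_dim),
      Wd = glorot(cfg$latent_dim, T_ * S), bd = numeric(T_ * S)
    )
    attr(p, "geom") <- list(T1 = T1, T2 = T2)
  }
  p
}

make_optimizer <- function(cfg, params) {
  m <- lapply(params, function(x) x * 0)
  v <- lapply(params, function(x) x * 0)
  t_step <- 0
  function(params, grads) {
    t_step <<- t_step + 1
    for (nm in names(params)) {
      g <- grads[[nm]]
      if (cfg$optimizer == "sgd") {
        params[[nm]] <- params[[nm]] - cfg$lr * g
      } else if (cfg$optimizer == "rmsprop") {
        v[[nm]] <<- 0.9 * v[[nm]] + 0.1 * g^2
        params[[nm]] <- params[[nm]] - cfg$lr * g / (sqrt(v[[nm]]) + 1e-8)
      } else {
        m[[nm]] <<- 0.9 * m[[nm]] + 0.1 * g
        v[[nm]] <<- 0.999 * v[[nm]] + 0.001 * g^2
        mh <- m[[nm]] / (1 - 0.9^t_step)
        vh <- v[[nm]] / (1 - 0.999^t_step)
        params[[nm]] <- params[[nm]] - cfg$lr * mh / (sqrt(vh) + 1e-8)
      }
    }
    params
  }
}

maxpool_rows <- function(R, p) {
  n_groups <- nrow(R) %/% p
  out <- matrix(0, n_groups, ncol(R))
  arg <- matrix(0L, n_groups, ncol(R))
  for (g in seq_len(n_groups)) {
    rows <- ((g - 1L) * p + 1L):(g * p)
    block <- R[rows, , drop = FALSE]
    j <- max.col(t(block), ties.method = "first")
    arg[g, ] <- rows[j]
    out[g, ] <- block[cbind(j, seq_len(ncol(R)))]
  }
  list(out = out, arg = arg)
}

# --- GRU encoder, batched over days: X is B x T x S --------------------------

gru_encode_batch <- function(params, X, cache = FALSE) {
  B <- dim(X)[1]; T_ <- dim(X)[2]; H <- ncol(params$W_z)
  h <- matrix(0, B, H)
  steps <- if (cache) vector("list", T_) else NULL
  for (t in seq_len(T_)) {
    x <- X[, t, , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, B)
    z <- sigmoid(sweep(x %*% params$W_z + h %*% params$U_z, 2, params$b_z, "+"))
    r <- sigmoid(sweep(x %*% params$W_r + h %*% params$U_r, 2, params$b_r, "+"))
    rh <- r * h
    cand <- tanh(sweep(x %*% params$W_h + rh %*% params$U_h, 2, params$b_h, "+"))
    h_new <- (1 - z) * h + z * cand
    if (cache) steps[[t]] <- list(x = x, hprev = h, z = z, r = r, cand = cand)
    h <- h_new
  }
  list(latent = h, steps = steps)
}

gru_backward_batch <- function(params, steps, dh) {
  g <- lapply(params, function(x) x * 0)
  for (t in rev(seq_along(steps))) {
    s <- steps[[t]]
    dcand <- dh * s$z
    dz <- dh * (s$cand - s$hprev)
    da_c <- dcand * (1 - s$cand^2)
    da_z <- dz * s$z * (1 - s$z)
    q <- da_c %*% t(params$U_h)
    dr <- q * s$hprev
    da_r <- dr * s$r * (1 - s$r)
    g$W_h <- g$W_h + t(s$x) %*% da_c
    g$U_h <- g$U_h + t(s$r * s$hprev) %*% da_c
    g$b_h <- g$b_h + colSums(da_c)
    g$W_z <- g$W_z + t(s$x) %*% da_z
    g$U_z <- g$U_z + t(s$hprev) %*% da_z
    g$b_z <- g$b_z + colSums(da_z)
    g$W_r <- g$W_r + t(s$x) %*% da_r
    g$U_r <- g$U_r + t(s$hprev) %*% da_r
    g$b_r <- g$b_r + colSums(da_r)
    dh <- dh * (1 - s$z) + q * s$r + da_z %*% t(params$U_z) + da_r %*% t(params$U_r)
  }
  g
}

# --- Conv1D encoder, per-sample --------------------------------------------

conv_encode_sample <- function(params, cfg, X, cache = FALSE) {
  k <- cfg$kernel_size; p <- cfg$pool
  E1 <- time_embed(X, k)
  A1 <- sweep(E1 %*% params$K1, 2, params$b1, "+")
  P1 <- maxpool_rows(relu(A1), p)
  E2 <- time_embed(P1$out, k)
  A2 <- sweep(E2 %*% params$K2, 2, params$b2, "+")
  P2 <- maxpool_rows(relu(A2), p)
  f <- as.numeric(P2$out)
  latent <- as.numeric(f %*% params$Wl) + params$bl
  out <- list(latent = latent)
  if (cache) out$cache <- list(E1 = E1, A1 = A1, P1 = P1, E2 = E2, A2 = A2,
                               P2 = P2, f = f)
  out
}

conv_backward_sample <- function(params, cfg, X, cache, dlatent, g) {
  k <- cfg$kernel_size; p <- cfg$pool
  g$Wl <- g$Wl + outer(cache$f, dlatent)
  g$bl <- g$bl + dlatent
  df <- as.numeric(params$Wl %*% dlatent)
  dP2 <- matrix(df, nrow(cache$P2$out), ncol(cache$P2$out))
  dR2 <- matrix(0, nrow(cache$A2), ncol(cache$A2))
  dR2[cbind(as.vector(cache$P2$arg), rep(seq_len(ncol(dP2)), each = nrow(dP2)))] <-
    as.vector(dP2)
  dA2 <- dR2 * (cache$A2 > 0)
  g$K2 <- g$K2 + t(cache$E2) %*% dA2
  g$b2 <- g$b2 + colSums(dA2)
  dE2 <- dA2 %*% t(params$K2)
  dP1 <- time_unembed(dE2, nrow(cache$P1$out), ncol(cache$P1$out), k)
  dR1 <- matrix(0, nrow(cache$A1), ncol(cache$A1))
  dR1[cbind(as.vector(cache$P1$arg), rep(seq_len(ncol(dP1)), each = nrow(dP1)))] <-
    as.vector(dP1)
  dA1 <- dR1 * (cache$A1 > 0)
  g$K1 <- g$K1 + t(cache$E1) %*% dA1
  g$b1 <- g$b1 + colSums(dA1)
  g
}

days_to_array <- function(days, cfg) {
  stopifnot(is.list(days), length(days) >= 1)
  X <- array(0, c(length(days), cfg$n_bins, cfg$n_sensors))
  for (i in seq_along(days)) {
    d <- as.matrix(days[[i]])
    if (!all(dim(d) == c(cfg$n_bins, cfg$n_sensors))) {
      stop("day ", i, " has geometry ", nrow(d), "x", ncol(d),
           ", expected ", cfg$n_bins, "x", cfg$n_sensors)
    }
    X[i, , ] <- d
  }
  X
}

#' Train a daily-habits autoencoder
#'
#' Trains the configured encoder-decoder on binarized daily signature
#' matrices by minimizing the binary log loss between each day and its
#' reconstruction, using mini-batch gradient descent with the configured
#' optimizer. Deterministic given the configuration seed.
#'
#' @param days List of daily matrices (`n_bins` x `n_sensors`, values in
#'   0/1), at least 30 days.
#' @param cfg An [ae_config()].
#' @return A `habit_autoencoder`: list with `params`, `cfg`, `loss_curve`
#'   (mean training loss per epoch) and `final_loss`.
#' @export
train_autoencoder <- function(days, cfg) {
  stopifnot(inherits(cfg, "ae_config"))
  if (length(days) < 30) stop("need at least 30 days to train")
  X <- days_to_array(days, cfg)
  if (!all(X %in% c(0, 1))) {
    stop("inputs must be binary (0/1) for the log-loss objective; ",
         "binarize real-valued sensors upstream")
  }
  B_all <- dim(X)[1]; T_ <- cfg$n_bins; S <- cfg$n_sensors
  Yflat <- matrix(X, B_all, T_ * S)  # sample-major flattening

  set.seed(cfg$seed)
  params <- init_ae_params(cfg)
  geom <- attr(params, "geom")
  step <- make_optimizer(cfg, params)
  loss_curve <- numeric(cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(B_all)
    batch_losses <- c()
    for (start in seq(1, B_all, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, B_all)]
      B <- length(idx)
      Y <- Yflat[idx, , drop = FALSE]
      if (cfg$arch == "gru") {
        enc <- gru_encode_batch(params, X[idx, , , drop = FALSE], cache = TRUE)
        latent <- enc$latent
      } else {
        caches <- vector("list", B)
        latent <- matrix(0, B, cfg$latent_dim)
        for (i in seq_len(B)) {
          e <- conv_encode_sample(params, cfg, X[idx[i], , ], cache = TRUE)
          latent[i, ] <- e$latent
          caches[[i]] <- e$cache
        }
      }
      logits <- sweep(latent %*% params$Wd, 2, params$bd, "+")
      Yhat <- sigmoid(logits)
      loss <- log_loss(Y, Yhat)
      if (!is.finite(loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch,
             "; reduce the learning rate")
      }
      batch_losses <- c(batch_losses, loss)

      dlogit <- (Yhat - Y) / (B * T_ * S)
      grads <- lapply(params, function(x) x * 0)
      grads$Wd <- t(latent) %*% dlogit
      grads$bd <- colSums(dlogit)
      dlat <- dlogit %*% t(params$Wd)
      if (cfg$arch == "gru") {
        genc <- gru_backward_batch(params, enc$steps, dlat)
        for (nm in names(genc)) grads[[nm]] <- grads[[nm]] + genc[[nm]]
      } else {
        for (i in seq_len(B)) {
          grads <- conv_backward_sample(params, cfg, X[idx[i], , ],
                                        caches[[i]], dlat[i, ], grads)
        }
      }
      params <- step(params, grads)
    }
    loss_curve[epoch] <- mean(batch_losses)
  }
  attr(params, "geom") <- geom
  structure(list(params = params, cfg = cfg, loss_curve = loss_curve,
                 final_loss = loss_curve[cfg$epochs]),
            class = "habit_autoencoder")
}

#' @export
print.habit_autoencoder <- function(x, ...) {
  cat(sprintf("<habit_autoencoder> %s, latent %d, %d epochs, final loss %.4f\n",
              x$cfg$arch, x$cfg$latent_dim, x$cfg$epochs, x$final_loss))
  invisible(x)
}

#' Encode days into the learned embedding
#'
#' Runs the encoder of a trained autoencoder over daily matrices,
#' returning one latent vector per day.
#'
#' @param ae A trained `habit_autoencoder`.
#' @param days List of daily matrices with the training geometry; may be
#'   empty.
#' @param dates Optional day identifiers (default: list names or indices).
#' @return An `embedding_set`: list with `dates`, `vectors`
#'   (days x latent_dim) and `final_loss` of the training run.
#' @export
encode_days <- function(ae, days, dates = NULL) {
  stopifnot(inherits(ae, "habit_autoencoder"))
  cfg <- ae$cfg
  if (length(days) == 0) {
    return(structure(list(dates = character(0),
                          vectors = matrix(0, 0, cfg$latent_dim),
                          final_loss = ae$final_loss),
                     class = "embedding_set"))
  }
  X <- days_to_array(days, cfg)
  if (cfg$arch == "gru") {
    vectors <- gru_encode_batch(ae$params, X)$latent
  } else {
    vectors <- t(vapply(seq_len(dim(X)[1]), function(i) {
      conv_encode_sample(ae$params, cfg, X[i, , ])$latent
    }, numeric(cfg$latent_dim)))
  }
  if (is.null(dates)) {
    dates <- if (!is.null(names(days))) names(days) else as.character(seq_along(days))
  }
  structure(list(dates = dates, vectors = vectors, final_loss = ae$final_loss),
            class = "embedding_set")
}
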