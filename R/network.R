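#' Feed-forward network specification
#'
#' Architecture and training hyperparameters of one ensemble member. Two
#' presets reproduce the published optimized architectures:
#'
#' * `"sim"` — four hidden layers \{1024, 512, 256, 128\}, ReLU
#'   (`f(x) = max(x, 0)`), for similarity-profile features;
#' * `"embedding"` — two hidden layers \{256, 128\}, tanh
#'   (`(e^{2x}-1)/(e^{2x}+1)`), for 768-dimensional embeddings;
#' * `"small"` — two hidden layers \{64, 32\}, ReLU: a light preset for
#'   modest synthetic studies and continuous testing.
#'
#' All presets end in a 4-unit softmax output. Training uses class-weighted
#' sparse categorical cross-entropy, Adam (`beta1 = 0.9`, `beta2 = 0.999`,
#' `epsilon = 1e-7`, learning rate 0.001), dropout 0.2 after each hidden
#' layer, and early stopping on a 10% stratified validation slice of the
#' training subset (patience 10, best weights restored, at most `epochs`
#' epochs). Epochs, batch size, patience and the validation-slice rule are
#' this package's defaults; they are exposed so they can be changed.
#'
#' @param preset preset name, or `NULL` when `hidden` is given explicitly.
#' @param hidden integer vector of hidden layer widths.
#' @param activation `"relu"` or `"tanh"`.
#' @param dropout dropout rate after each hidden layer.
#' @param learning_rate Adam learning rate.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param patience early-stopping patience in epochs.
#' @param val_fraction fraction of the training subset held back (stratified)
#'   to monitor early stopping; never drawn from an outer validation fold.
#' @return a `ddi_network_spec` list.
#' @export
network_spec <- function(preset = c("sim", "embedding", "small"),
                         hidden = NULL, activation = NULL, dropout = 0.2,
                         learning_rate = 0.001, epochs = 200,
                         batch_size = 128, patience = 10,
                         val_fraction = 0.1) {
  if (is.null(hidden)) {
    preset <- match.arg(preset)
    hidden <- switch(preset, sim = c(1024L, 512L, 256L, 128L),
                     embedding = c(256L, 128L), small = c(64L, 32L))
    if (is.null(activation)) {
      activation <- switch(preset, embedding = "tanh", "relu")
    }
  } else {
    preset <- if (is.character(preset) && length(preset) == 1) preset else "custom"
    if (is.null(activation)) activation <- "relu"
  }
  activation <- match.arg(activation, c("relu", "tanh"))
  structure(
    list(preset = preset, hidden = as.integer(hidden), activation = activation,
         n_classes = 4L, dropout = dropout, learning_rate = learning_rate,
         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), patience = as.integer(patience),
         val_fraction = val_fraction),
    class = "ddi_network_spec"
  )
}

#' @export
print.ddi_network_spec <- function(x, ...) {
  cat(sprintf("<ddi_network_spec> '%s': [input] -> %s -> 4 (softmax), %s, dropout %.1f\n",
              x$preset, paste(x$hidden, collapse = " -> "), x$activation,
              x$dropout))
  invisible(x)
}

#' Build an untrained network member
#'
#' Seeded weight initialization (He for ReLU, Glorot for tanh), zero biases.
#'
#' @param spec a [network_spec()].
#' @param input_len feature vector length.
#' @param seed initialization seed.
#' @return a `ddi_mlp` with untrained parameters.
#' @export
build_network <- function(spec, input_len, seed = 1L) {
  stopifnot(inherits(spec, "ddi_network_spec"), input_len > 0)
  dims <- c(as.integer(input_len), spec$hidden, spec$n_classes)
  params <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(length(dims) - 1L), function(l) {
      fan_in <- dims[l]; fan_out <- dims[l + 1L]
      sdv <- if (spec$activation == "relu") sqrt(2 / fan_in) else
        sqrt(2 / (fan_in + fan_out))
      list(W = matrix(rnorm(fan_in * fan_out, sd = sdv), fan_in, fan_out),
           b = rep(0, fan_out))
    })
  })
  structure(list(spec = spec, input_len = as.integer(input_len),
                 params = params, trained = FALSE, history = NULL),
            class = "ddi_mlp")
}

#' @export
print.ddi_mlp <- function(x, ...) {
  cat(sprintf("<ddi_mlp> %s, input %d, %strained\n", x$spec$preset,
              x$input_len, if (x$trained) "" else "un"))
  invisible(x)
}

#' Train one network member
#'
#' Minimizes class-weighted sparse categorical cross-entropy with Adam; see
#' [network_spec()] for the training protocol. Aborts with diagnostics if the
#' loss diverges to NaN.
#'
#' @param member an untrained [build_network()] member (built fresh if a spec
#'   is supplied instead).
#' @param x numeric feature matrix (rows = pairs).
#' @param y grade labels (anything [as_grade()] accepts).
#' @param weights per-class loss weights: a [class_weights()] tibble, a named
#'   or plain numeric vector of length 4 (Green..Red), or `NULL` for all 1.
#' @param seed seed for initialization, shuffling and dropout.
#' @return the trained `ddi_mlp`, with a `history` tibble (epoch, training
#'   loss, validation loss).
#' @export
train_member <- function(member, x, y, weights = NULL, seed = 1L) {
  if (inherits(member, "ddi_network_spec")) {
    member <- build_network(member, ncol(x), seed = seed)
  }
  stopifnot(inherits(member, "ddi_mlp"), nrow(x) >= 1,
            ncol(x) == member$input_len)
  spec <- member$spec
  ycode <- grade_code(y)
  stopifnot(length(ycode) == nrow(x))
  w4 <- normalize_weights(weights)
  present <- sort(unique(ycode))
  if (any(w4[present + 1L] <= 0)) {
    abort("every class present in training data needs a positive weight")
  }
  sw <- w4[ycode + 1L]

  withr::with_seed(as.integer(seed), {
    member$params <- build_network(spec, member$input_len, seed = seed)$params
    # stratified validation slice for early stopping
    val_idx <- integer(0)
    if (spec$val_fraction > 0) {
      for (cl in present) {
        cls <- which(ycode == cl)
        n_val <- floor(spec$val_fraction * length(cls))
        if (n_val >= 1) val_idx <- c(val_idx, sample(cls, n_val))
      }
    }
    tr_idx <- setdiff(seq_len(nrow(x)), val_idx)
    xv <- x[val_idx, , drop = FALSE]; yv <- ycode[val_idx]; swv <- sw[val_idx]
    xt <- x[tr_idx, , drop = FALSE]; yt <- ycode[tr_idx]; swt <- sw[tr_idx]

    adam <- init_adam(member$params)
    best <- list(loss = Inf, params = member$params, epoch = 0L)
    waited <- 0L
    hist <- vector("list", spec$epochs)
    step <- 0L
    for (epoch in seq_len(spec$epochs)) {
      ord <- sample.int(nrow(xt))
      starts <- seq(1L, nrow(xt), by = spec$batch_size)
      ep_loss <- 0
      for (s in starts) {
        bi <- ord[s:min(s + spec$batch_size - 1L, nrow(xt))]
        step <- step + 1L
        res <- mlp_step(member$params, xt[bi, , drop = FALSE], yt[bi],
                        swt[bi], spec, adam, step)
        member$params <- res$params; adam <- res$adam
        ep_loss <- ep_loss + res$loss * length(bi)
      }
      ep_loss <- ep_loss / nrow(xt)
      if (!is.finite(ep_loss)) {
        abort(sprintf(
          "training diverged (non-finite loss) at epoch %d; learning rate %.3g, batch %d",
          epoch, spec$learning_rate, spec$batch_size))
      }
      mon <- if (length(val_idx) > 0) {
        weighted_ce(mlp_probs(member$params, xv, spec), yv, swv)
      } else ep_loss
      hist[[epoch]] <- tibble(epoch = epoch, loss = ep_loss, val_loss = mon)
      if (mon < best$loss - 1e-12) {
        best <- list(loss = mon, params = member$params, epoch = epoch)
        waited <- 0L
      } else {
        waited <- waited + 1L
        if (waited >= spec$patience) break
      }
    }
    member$params <- best$params   # restore best weights
    member$history <- bind_rows(hist[!vapply(hist, is.null, logical(1))])
    member$best_epoch <- best$epoch
  })
  member$trained <- TRUE
  member$class_weights <- w4
  member
}

#' Class probabilities from one member
#'
#' @param object a `ddi_mlp`.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return matrix of softmax probabilities, columns Green..Red.
#' @export
predict.ddi_mlp <- function(object, newdata, ...) {
  p <- mlp_probs(object$params, as.matrix(newdata), object$spec)
  colnames(p) <- grade_levels()
  p
}

# ---- internals ---------------------------------------------------------------

normalize_weights <- function(weights) {
  if (is.null(weights)) return(rep(1, 4))
  if (is.data.frame(weights)) {
    stopifnot(all(c("grade", "weight") %in% names(weights)))
    w <- setNames(weights$weight, as.character(weights$grade))
    return(as.numeric(w[grade_levels()]))
  }
  if (!is.null(names(weights))) {
    return(as.numeric(weights[grade_levels()]))
  }
  stopifnot(length(weights) == 4)
  as.numeric(weights)
}

act_fun <- function(z, activation) {
  if (activation == "relu") pmax(z, 0) else tanh(z)
}

act_grad <- function(a, activation) {
  if (activation == "relu") (a > 0) * 1 else 1 - a * a
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward pass without dropout
mlp_probs <- function(params, x, spec) {
  a <- x
  n_l <- length(params)
  for (l in seq_len(n_l - 1L)) {
    a <- act_fun(sweep(a %*% params[[l]]$W, 2, params[[l]]$b, `+`),
                 spec$activation)
  }
  softmax_rows(sweep(a %*% params[[n_l]]$W, 2, params[[n_l]]$b, `+`))
}

# mean over samples of w_i * -log p_{y_i}
weighted_ce <- function(probs, ycode, sw) {
  p <- probs[cbind(seq_along(ycode), ycode + 1L)]
  mean(sw * -log(pmax(p, 1e-12)))
}

init_adam <- function(params) {
  lapply(params, function(p) list(
    mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0))
}

# one minibatch: forward with inverted dropout, backprop, Adam update
mlp_step <- function(params, xb, yb, swb, spec, adam, step) {
  n <- nrow(xb)
  n_l <- length(params)
  acts <- vector("list", n_l + 1L); acts[[1]] <- xb   # post-dropout inputs
  raw <- vector("list", n_l + 1L)                     # pre-dropout activations
  masks <- vector("list", n_l)
  for (l in seq_len(n_l - 1L)) {
    a <- act_fun(sweep(acts[[l]] %*% params[[l]]$W, 2, params[[l]]$b, `+`),
                 spec$activation)
    raw[[l + 1L]] <- a
    if (spec$dropout > 0) {
      m <- matrix(runif(length(a)) >= spec$dropout, nrow(a), ncol(a)) /
        (1 - spec$dropout)
      a <- a * m
      masks[[l]] <- m
    }
    acts[[l + 1L]] <- a
  }
  probs <- softmax_rows(sweep(acts[[n_l]] %*% params[[n_l]]$W, 2,
                              params[[n_l]]$b, `+`))
  loss <- weighted_ce(probs, yb, swb)

  delta <- probs
  delta[cbind(seq_len(n), yb + 1L)] <- delta[cbind(seq_len(n), yb + 1L)] - 1
  delta <- delta * swb / n
  for (l in n_l:1) {
    gW <- crossprod(acts[[l]], delta)
    gb <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(params[[l]]$W)
      if (!is.null(masks[[l - 1L]])) delta <- delta * masks[[l - 1L]]
      delta <- delta * act_grad(raw[[l]], spec$activation)
    }
    adam[[l]]$mW <- spec$beta1 * adam[[l]]$mW + (1 - spec$beta1) * gW
    adam[[l]]$vW <- spec$beta2 * adam[[l]]$vW + (1 - spec$beta2) * gW^2
    adam[[l]]$mb <- spec$beta1 * adam[[l]]$mb + (1 - spec$beta1) * gb
    adam[[l]]$vb <- spec$beta2 * adam[[l]]$vb + (1 - spec$beta2) * gb^2
    mW_hat <- adam[[l]]$mW / (1 - spec$beta1^step)
    vW_hat <- adam[[l]]$vW / (1 - spec$beta2^step)
    mb_hat <- adam[[l]]$mb / (1 - spec$beta1^step)
    vb_hat <- adam[[l]]$vb / (1 - spec$beta2^step)
    params[[l]]$W <- params[[l]]$W -
      spec$learning_rate * mW_hat / (sqrt(vW_hat) + spec$epsilon)
    params[[l]]$b <- params[[l]]$b -
      spec$learning_rate * mb_hat / (sqrt(vb_hat) + spec$epsilon)
  }
  list(params = params, adam = adam, loss = loss)
}
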