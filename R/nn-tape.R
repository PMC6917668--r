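# Minimal reverse-mode automatic differentiation over matrices.
#
# A tape records a DAG of matrix-valued nodes (inputs, dense layers,
# activations, batch-norm, dropout, concat/slice, reparameterization).
# backward() seeds gradients at chosen nodes and accumulates parameter
# gradients into layer environments, which an Adam step then consumes.
# All randomness (init, dropout masks, reparameterization noise) is drawn
# from the caller's RNG stream, so a single set.seed() makes training
# bitwise-reproducible on one thread.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp
}

tp_push <- function(tp, node) {
  id <- length(tp$nodes) + 1L
  node$id <- id
  tp$nodes[[id]] <- node
  id
}

tp_value <- function(tp, id) tp$nodes[[id]]$value

tp_input <- function(tp, X) {
  tp_push(tp, list(op = "input", inputs = integer(0), value = X))
}

# --- parameter containers -------------------------------------------------

new_dense <- function(n_in, n_out, name = "dense") {
  limit <- sqrt(6 / (n_in + n_out))  # Glorot uniform
  ly <- new.env(parent = emptyenv())
  ly$kind <- "dense"; ly$name <- name
  ly$W <- matrix(stats::runif(n_in * n_out, -limit, limit), n_in, n_out)
  ly$b <- numeric(n_out)
  ly$gW <- NULL; ly$gb <- NULL
  ly
}

new_batchnorm <- function(dim, name = "bn", momentum = 0.9, eps = 1e-3) {
  ly <- new.env(parent = emptyenv())
  ly$kind <- "batchnorm"; ly$name <- name
  ly$gamma <- rep(1, dim); ly$beta <- rep(0, dim)
  ly$running_mean <- rep(0, dim); ly$running_var <- rep(1, dim)
  ly$momentum <- momentum; ly$eps <- eps
  ly$ggamma <- NULL; ly$gbeta <- NULL
  ly
}

layer_params <- function(ly) {
  switch(ly$kind,
         dense = c("W", "b"),
         batchnorm = c("gamma", "beta"))
}

# --- ops ------------------------------------------------------------------

# Add a per-column vector to every row (fast replacement for sweep()).
addcols <- function(Y, v) Y + rep(v, each = nrow(Y))
mulcols <- function(Y, v) Y * rep(v, each = nrow(Y))

tp_dense <- function(tp, x_id, layer) {
  X <- tp_value(tp, x_id)
  Y <- addcols(X %*% layer$W, layer$b)
  tp_push(tp, list(op = "dense", inputs = x_id, value = Y, layer = layer))
}

tp_elu <- function(tp, x_id, alpha = 1) {
  X <- tp_value(tp, x_id)
  if (anyNA(X)) stop("non-finite loss (non-finite activations in forward pass)")
  neg <- X < 0
  Y <- X
  Y[neg] <- alpha * (exp(X[neg]) - 1)
  tp_push(tp, list(op = "elu", inputs = x_id, value = Y, alpha = alpha,
                   neg = neg))
}

tp_sigmoid <- function(tp, x_id) {
  X <- tp_value(tp, x_id)
  Y <- 1 / (1 + exp(-X))
  tp_push(tp, list(op = "sigmoid", inputs = x_id, value = Y))
}

tp_batchnorm <- function(tp, x_id, layer, training) {
  X <- tp_value(tp, x_id)
  if (training) {
    mu <- colMeans(X)
    xc <- addcols(X, -mu)
    v <- colMeans(xc^2)  # biased batch variance
    istd <- 1 / sqrt(v + layer$eps)
    xhat <- mulcols(xc, istd)
    m <- layer$momentum
    layer$running_mean <- m * layer$running_mean + (1 - m) * mu
    layer$running_var <- m * layer$running_var + (1 - m) * v
    Y <- addcols(mulcols(xhat, layer$gamma), layer$beta)
    tp_push(tp, list(op = "batchnorm", inputs = x_id, value = Y, layer = layer,
                     xhat = xhat, istd = istd, training = TRUE))
  } else {
    istd <- 1 / sqrt(layer$running_var + layer$eps)
    xhat <- mulcols(addcols(X, -layer$running_mean), istd)
    Y <- addcols(mulcols(xhat, layer$gamma), layer$beta)
    tp_push(tp, list(op = "batchnorm", inputs = x_id, value = Y, layer = layer,
                     xhat = xhat, istd = istd, training = FALSE))
  }
}

tp_dropout <- function(tp, x_id, rate, training) {
  X <- tp_value(tp, x_id)
  if (!training || rate <= 0) {
    return(tp_push(tp, list(op = "dropout", inputs = x_id, value = X,
                            mask = NULL)))
  }
  mask <- matrix((stats::runif(length(X)) >= rate) / (1 - rate),
                 nrow(X), ncol(X))
  tp_push(tp, list(op = "dropout", inputs = x_id, value = X * mask,
                   mask = mask))
}

tp_concat <- function(tp, x_ids) {
  x_ids <- as.integer(unlist(x_ids))
  vals <- lapply(x_ids, tp_value, tp = tp)
  widths <- vapply(vals, ncol, integer(1))
  tp_push(tp, list(op = "concat", inputs = x_ids, value = do.call(cbind, vals),
                   widths = widths))
}

tp_slice <- function(tp, x_id, cols) {
  X <- tp_value(tp, x_id)
  tp_push(tp, list(op = "slice", inputs = x_id,
                   value = X[, cols, drop = FALSE], cols = cols,
                   full_width = ncol(X)))
}

# z = mu + exp(logvar / 2) * eps
tp_reparam <- function(tp, mu_id, logvar_id, eps) {
  mu <- tp_value(tp, mu_id); lv <- tp_value(tp, logvar_id)
  if (!identical(dim(eps), dim(mu))) stop("eps shape mismatch in reparameterize")
  sd <- exp(lv / 2)
  tp_push(tp, list(op = "reparam", inputs = c(mu_id, logvar_id),
                   value = mu + sd * eps, sd = sd, eps = eps))
}

# --- backward pass --------------------------------------------------------

# seeds: list of list(id = node id, g = gradient matrix); the same node may
# be seeded several times (gradients accumulate). Parameter gradients
# accumulate into each layer's g* fields (zeroed beforehand via zero_grads()).
tape_backward <- function(tp, seeds) {
  n <- length(tp$nodes)
  grads <- vector("list", n)
  for (s in seeds) {
    grads[[s$id]] <- add_grad(grads[[s$id]], s$g)
  }
  for (id in rev(seq_len(n))) {
    g <- grads[[id]]
    if (is.null(g)) next
    node <- tp$nodes[[id]]
    switch(node$op,
      input = NULL,
      dense = {
        X <- tp_value(tp, node$inputs)
        ly <- node$layer
        ly$gW <- ly$gW + crossprod(X, g)
        ly$gb <- ly$gb + colSums(g)
        grads[[node$inputs]] <- add_grad(grads[[node$inputs]],
                                         tcrossprod(g, ly$W))
      },
      elu = {
        dx <- g
        neg <- node$neg
        dx[neg] <- g[neg] * (node$value[neg] + node$alpha)
        grads[[node$inputs]] <- add_grad(grads[[node$inputs]], dx)
      },
      sigmoid = {
        Y <- node$value
        grads[[node$inputs]] <- add_grad(grads[[node$inputs]], g * Y * (1 - Y))
      },
      batchnorm = {
        ly <- node$layer
        ly$ggamma <- ly$ggamma + colSums(g * node$xhat)
        ly$gbeta <- ly$gbeta + colSums(g)
        if (node$training) {
          nb <- nrow(node$xhat)
          dxhat <- mulcols(g, ly$gamma)
          t1 <- colSums(dxhat)
          t2 <- colSums(dxhat * node$xhat)
          dx <- mulcols(addcols(dxhat, -t1 / nb) -
                          mulcols(node$xhat, t2 / nb), node$istd)
        } else {
          dx <- mulcols(g, ly$gamma * node$istd)
        }
        grads[[node$inputs]] <- add_grad(grads[[node$inputs]], dx)
      },
      dropout = {
        dx <- if (is.null(node$mask)) g else g * node$mask
        grads[[node$inputs]] <- add_grad(grads[[node$inputs]], dx)
      },
      concat = {
        off <- 0L
        for (k in seq_along(node$inputs)) {
          w <- node$widths[k]
          gk <- g[, (off + 1L):(off + w), drop = FALSE]
          grads[[node$inputs[k]]] <- add_grad(grads[[node$inputs[k]]], gk)
          off <- off + w
        }
      },
      slice = {
        full <- matrix(0, nrow(g), node$full_width)
        full[, node$cols] <- g
        grads[[node$inputs]] <- add_grad(grads[[node$inputs]], full)
      },
      reparam = {
        mu_id <- node$inputs[1]; lv_id <- node$inputs[2]
        grads[[mu_id]] <- add_grad(grads[[mu_id]], g)
        grads[[lv_id]] <- add_grad(grads[[lv_id]], g * node$sd * node$eps * 0.5)
      },
      stop(sprintf("no backward rule for op '%s'", node$op))
    )
  }
  invisible(grads)
}

add_grad <- function(acc, g) if (is.null(acc)) g else acc + g

zero_grads <- function(layers) {
  for (ly in layers) {
    for (p in layer_params(ly)) {
      ly[[paste0("g", p)]] <- ly[[p]] * 0
    }
  }
  invisible(layers)
}

# --- Adam optimizer -------------------------------------------------------

adam_new <- function(layers, lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- list(); st$v <- list()
  for (i in seq_along(layers)) {
    for (p in layer_params(layers[[i]])) {
      key <- paste0(i, ".", p)
      st$m[[key]] <- layers[[i]][[p]] * 0
      st$v[[key]] <- layers[[i]][[p]] * 0
    }
  }
  st
}

adam_step <- function(st, layers) {
  st$t <- st$t + 1L
  # folded bias correction: theta -= lr_t * m / (sqrt(v) + eps_t)
  lr_t <- st$lr * sqrt(1 - st$beta2^st$t) / (1 - st$beta1^st$t)
  eps_t <- st$eps * sqrt(1 - st$beta2^st$t)
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    for (p in layer_params(ly)) {
      key <- paste0(i, ".", p)
      g <- ly[[paste0("g", p)]]
      m <- st$beta1 * st$m[[key]] + (1 - st$beta1) * g
      v <- st$beta2 * st$v[[key]] + (1 - st$beta2) * g^2
      st$m[[key]] <- m
      st$v[[key]] <- v
      ly[[p]] <- ly[[p]] - lr_t * m / (sqrt(v) + eps_t)
    }
  }
  invisible(st)
}

# Flatten all parameters of a layer list into one numeric vector
# (used for reproducibility and leakage tests).
flatten_params <- function(layers) {
  unlist(lapply(layers, function(ly) {
    c(lapply(layer_params(ly), function(p) as.vector(ly[[p]])),
      if (ly$kind == "batchnorm") list(ly$running_mean, ly$running_var))
  }), use.names = FALSE)
}

# Deep-copy layer environments (models hold mutable state).
clone_layers <- function(layers) {
  lapply(layers, function(ly) {
    new <- new.env(parent = emptyenv())
    for (nm in ls(ly)) assign(nm, get(nm, envir = ly), envir = new)
    new
  })
}
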