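#' Training configuration for the one-vs-all ensemble
#'
#' @param hidden_nodes Nodes per hidden layer (default 25).
#' @param hidden_layers Number of hidden layers (default 1).
#' @param max_iter Scaled-conjugate-gradient iteration cap per network
#'   (default 300).
#' @param grad_tol Gradient-norm stopping tolerance.
#' @param seed Integer seed for the weight initialization.
#' @param scg_sigma,scg_lambda0 Optimizer constants, see [scg_minimize()].
#' @return A `train_config` object.
#' @export
train_config <- function(hidden_nodes = 25L, hidden_layers = 1L,
                         max_iter = 300L, grad_tol = 1e-6, seed = 1L,
                         scg_sigma = 1e-4, scg_lambda0 = 1e-6) {
  if (hidden_nodes < 1 || hidden_layers < 1 || max_iter < 1) {
    abort("hidden_nodes, hidden_layers and max_iter must be >= 1",
          class = "handwashr_validation_error")
  }
  if (grad_tol <= 0 || scg_sigma <= 0 || scg_lambda0 <= 0) {
    abort("tolerances must be > 0", class = "handwashr_validation_error")
  }
  structure(list(hidden_nodes = as.integer(hidden_nodes),
                 hidden_layers = as.integer(hidden_layers),
                 max_iter = as.integer(max_iter), grad_tol = grad_tol,
                 seed = as.integer(seed), scg_sigma = scg_sigma,
                 scg_lambda0 = scg_lambda0),
            class = "train_config")
}

# ---- multilayer perceptron plumbing: tanh hidden layers, one logit output

mlp_shapes <- function(layer_sizes) {
  k <- length(layer_sizes) - 1
  lapply(seq_len(k), function(i) {
    c(layer_sizes[i], layer_sizes[i + 1])
  })
}

mlp_n_params <- function(layer_sizes) {
  sum(vapply(mlp_shapes(layer_sizes),
             function(s) s[1] * s[2] + s[2], numeric(1)))
}

mlp_unpack <- function(theta, layer_sizes) {
  shapes <- mlp_shapes(layer_sizes)
  out <- vector("list", length(shapes))
  off <- 0L
  for (i in seq_along(shapes)) {
    s <- shapes[[i]]
    nw <- s[1] * s[2]
    out[[i]] <- list(W = matrix(theta[off + seq_len(nw)], s[1], s[2]),
                     b = theta[off + nw + seq_len(s[2])])
    off <- off + nw + s[2]
  }
  out
}

mlp_init <- function(layer_sizes, seed) {
  # uniform in +/- 1/sqrt(fan_in), per layer
  withr::with_seed(seed, {
    unlist(lapply(mlp_shapes(layer_sizes), function(s) {
      lim <- 1 / sqrt(s[1])
      c(runif(s[1] * s[2], -lim, lim), rep(0, s[2]))
    }))
  })
}

# forward pass to the output logit; returns activations when wanted
mlp_logits <- function(layers, X, keep = FALSE) {
  acts <- if (keep) vector("list", length(layers)) else NULL
  A <- X
  k <- length(layers)
  for (i in seq_len(k)) {
    Z <- A %*% layers[[i]]$W
    Z <- sweep(Z, 2, layers[[i]]$b, `+`)
    if (i < k) {
      A <- tanh(Z)
      if (keep) acts[[i]] <- A
    } else {
      A <- Z                                 # output logit
    }
  }
  list(logit = A, acts = acts)
}

# mean binary cross-entropy with logits: mean(softplus(z) - y*z), stable
bce_loss <- function(z, y) {
  mean(ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z))) - y * z)
}

mlp_obj_grad <- function(layer_sizes, X, y) {
  n <- nrow(X)
  list(
    fn = function(theta) {
      layers <- mlp_unpack(theta, layer_sizes)
      bce_loss(drop(mlp_logits(layers, X)$logit), y)
    },
    gr = function(theta) {
      layers <- mlp_unpack(theta, layer_sizes)
      fw <- mlp_logits(layers, X, keep = TRUE)
      k <- length(layers)
      # d loss / d logit = (sigmoid(z) - y) / n
      delta <- (1 / (1 + exp(-fw$logit)) - y) / n
      grads <- vector("list", k)
      for (i in rev(seq_len(k))) {
        A_prev <- if (i == 1) X else fw$acts[[i - 1]]
        grads[[i]] <- list(W = crossprod(A_prev, delta),
                           b = colSums(delta))
        if (i > 1) {
          delta <- (delta %*% t(layers[[i]]$W)) * (1 - fw$acts[[i - 1]]^2)
        }
      }
      unlist(lapply(grads, function(g) c(as.numeric(g$W), g$b)))
    }
  )
}

standardizer_fit <- function(X) {
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  sdev[!is.finite(sdev) | sdev == 0] <- 1   # zero-variance features untouched
  list(mean = mu, sd = sdev)
}

standardizer_apply <- function(std, X) {
  sweep(sweep(X, 2, std$mean, `-`), 2, std$sd, `/`)
}

#' Train the one-vs-all gesture ensemble
#'
#' Standardizes the features (z-score on the training statistics, carried in
#' the returned object so prediction never re-fits them) and trains one
#' binary feed-forward network per gesture on targets "frame is this
#' gesture", with tanh hidden layers, a single sigmoid output, and mean
#' binary cross-entropy minimized by [scg_minimize()]. Weight initialization
#' is seeded per network, so training is deterministic for a fixed
#' configuration.
#'
#' @param features Feature tibble from [extract_features()] (rows from
#'   several sessions may be bound together); must contain a `label` column
#'   with at least 2 distinct gestures.
#' @param cfg A [train_config()].
#' @return An `ova_ensemble` object.
#' @export
train_ensemble <- function(features, cfg = train_config()) {
  y_all <- gesture_factor(features$label)
  if (length(unique(y_all[!is.na(y_all)])) < 2) {
    abort("training data must contain at least 2 gesture classes",
          class = "handwashr_validation_error")
  }
  X <- feature_matrix(features)
  std <- standardizer_fit(X)
  Xs <- standardizer_apply(std, X)
  D <- ncol(Xs)
  layer_sizes <- c(D, rep(cfg$hidden_nodes, cfg$hidden_layers), 1L)
  networks <- lapply(seq_along(gesture_codes()), function(gi) {
    y <- as.numeric(as.integer(y_all) == gi)
    og <- mlp_obj_grad(layer_sizes, Xs, y)
    theta0 <- mlp_init(layer_sizes, seed = cfg$seed + 1000L * gi)
    fit <- scg_minimize(og$fn, og$gr, theta0, max_iter = cfg$max_iter,
                        grad_tol = cfg$grad_tol, sigma = cfg$scg_sigma,
                        lambda0 = cfg$scg_lambda0)
    list(label = gesture_codes()[gi], layer_sizes = layer_sizes,
         theta = fit$par, loss = fit$value, iterations = fit$iterations,
         converged = fit$converged)
  })
  names(networks) <- gesture_codes()
  structure(list(networks = networks, standardizer = std,
                 train_config = cfg, n_train = nrow(Xs),
                 feature_names = colnames(X)),
            class = "ova_ensemble")
}

#' @export
print.ova_ensemble <- function(x, ...) {
  cat(sprintf("<ova_ensemble> 9 binary networks (%s), %d features, %d training frames\n",
              paste(x$networks[[1]]$layer_sizes, collapse = "-"),
              length(x$feature_names), x$n_train))
  invisible(x)
}

#' Predict gesture labels for feature frames
#'
#' Applies the ensemble's training standardizer, evaluates every binary
#' network, and assigns each frame to the gesture whose network responds
#' most strongly; ties go to the earliest gesture in routine order.
#'
#' @param ensemble An [train_ensemble()] fit.
#' @param features Feature tibble with the same feature columns the ensemble
#'   was trained on.
#' @return A tibble with `frame` (if present in `features`), the true
#'   `label` (if present), the predicted `.pred`, and one `score_<code>`
#'   column per gesture with the sigmoid response in `[0, 1]`.
#' @export
predict_frames <- function(ensemble, features) {
  stopifnot(inherits(ensemble, "ova_ensemble"))
  X <- feature_matrix(features)
  if (!identical(colnames(X), ensemble$feature_names)) {
    abort(sprintf("feature columns (%d) do not match the ensemble (%d)",
                  ncol(X), length(ensemble$feature_names)),
          class = "handwashr_validation_error")
  }
  Xs <- standardizer_apply(ensemble$standardizer, X)
  scores <- vapply(ensemble$networks, function(net) {
    layers <- mlp_unpack(net$theta, net$layer_sizes)
    z <- drop(mlp_logits(layers, Xs)$logit)
    1 / (1 + exp(-z))
  }, numeric(nrow(Xs)))
  if (nrow(Xs) == 1) scores <- matrix(scores, nrow = 1,
                                      dimnames = list(NULL, gesture_codes()))
  pred <- gesture_factor(gesture_codes()[max.col(scores, ties.method = "first")])
  out <- tibble(.pred = pred)
  if ("frame" %in% names(features)) out <- dplyr::bind_cols(
    tibble(frame = features$frame), out)
  if ("label" %in% names(features)) out <- dplyr::bind_cols(
    tibble(label = gesture_factor(features$label)), out)
  scores_tbl <- as_tibble(scores)
  names(scores_tbl) <- paste0("score_", gesture_codes())
  dplyr::bind_cols(out, scores_tbl)
}

#' @rdname train_ensemble
#' @param x An `ova_ensemble`.
#' @param ... Unused.
#' @return `tidy()` returns one row per binary network (label, parameter
#'   count, final cross-entropy, iterations); `glance()` one summary row.
#' @export
tidy.ova_ensemble <- function(x, ...) {
  purrr::map_dfr(x$networks, function(net) {
    tibble(label = net$label,
           n_params = length(net$theta),
           loss = net$loss,
           iterations = net$iterations,
           converged = net$converged)
  })
}

#' @rdname train_ensemble
#' @export
glance.ova_ensemble <- function(x, ...) {
  td <- tidy(x)
  tibble(n_networks = nrow(td),
         n_features = length(x$feature_names),
         n_train = x$n_train,
         hidden_nodes = x$train_config$hidden_nodes,
         hidden_layers = x$train_config$hidden_layers,
         mean_loss = mean(td$loss))
}
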