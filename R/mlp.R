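# Multilayer-perceptron release-curve fitter: a fully connected network
# mapping the 21-feature input (6 carrier + 14 drug + time) to release
# percent, trained with Adam on squared-percent loss. Implemented directly
# with matrix operations so training is seed-deterministic and the per-epoch
# loss trace is exact.

#' Configuration for the release MLP
#'
#' @param hidden integer vector of hidden-layer widths (default `c(64, 64)`).
#' @param activation hidden activation, `"relu"` or `"tanh"`.
#' @param learning_rate Adam step size (default 1e-3).
#' @param epochs training epochs (default 2000).
#' @param batch_size minibatch size (default 32).
#' @param seed integer seed for weight initialization and shuffling.
#' @param early_stop_patience optional integer: stop when the validation
#'   loss has not improved for this many epochs; `NULL` disables.
#' @return list of class `mlp_config`.
#' @export
mlp_config <- function(hidden = c(64L, 64L), activation = c("relu", "tanh"),
                       learning_rate = 1e-3, epochs = 2000L,
                       batch_size = 32L, seed = 1L,
                       early_stop_patience = NULL) {
  activation <- match.arg(activation)
  stopifnot(all(hidden >= 1L), epochs >= 1L, batch_size >= 1L,
            learning_rate > 0)
  structure(list(hidden = as.integer(hidden), activation = activation,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 early_stop_patience = early_stop_patience),
            class = "mlp_config")
}

#' Train the release MLP on pooled feature rows
#'
#' Fits a fully connected network (linear output, squared-error loss in
#' squared-percent units) to pooled time-point rows. A z-score scaler is
#' fitted on the training rows only and stored inside the model, so callers
#' always pass raw (unscaled) features; validation rows are scaled with the
#' training scaler and never influence it. Weights use He-uniform
#' initialization with the output bias seeded at the mean training target,
#' so optimization starts from the mean predictor rather than from zero on
#' the 0-100 percent output scale; optimization is minibatch Adam. With a
#' fixed seed the
#' whole procedure, including shuffling, is bit-reproducible on one
#' platform.
#'
#' @param train_rows feature rows from [to_feature_rows()] (imputed).
#' @param val_rows optional held-out rows; their loss is traced each epoch.
#' @param config an [mlp_config()].
#' @return list with `model` (class `release_mlp`) and `trace` (data.frame
#'   `epoch`, `train_loss`, `val_loss`; `val_loss` is `NA` without
#'   validation rows).
#' @export
train_release_mlp <- function(train_rows, val_rows = NULL,
                              config = mlp_config()) {
  stopifnot(inherits(config, "mlp_config"), is.data.frame(train_rows),
            nrow(train_rows) >= 1L)
  feats <- feature_names()
  scaler <- fit_scaler(train_rows)
  x <- as.matrix(scale_rows(scaler, train_rows)[, feats, drop = FALSE])
  y <- train_rows$release_pct
  has_val <- !is.null(val_rows) && nrow(val_rows) > 0L
  if (has_val) {
    xv <- as.matrix(scale_rows(scaler, val_rows)[, feats, drop = FALSE])
    yv <- val_rows$release_pct
  }

  layers <- c(length(feats), config$hidden, 1L)
  net <- with_seed(config$seed, init_layers(layers))
  # start from the mean predictor: targets live on the 0-100 percent scale
  # while He-initialized outputs sit near 0, so seeding the output bias at
  # the training mean removes a long bias-only warm-up phase
  net[[length(net)]]$b <- mean(y)
  act <- config$activation
  lr <- config$learning_rate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  mom <- lapply(net, function(l) list(W = l$W * 0, b = l$b * 0))
  vel <- lapply(net, function(l) list(W = l$W * 0, b = l$b * 0))
  step <- 0L

  n <- nrow(x)
  epochs_run <- config$epochs
  train_loss <- val_loss <- rep(NA_real_, config$epochs)
  best_val <- Inf; stale <- 0L

  shuffle_seed <- derive_seed(config$seed, "shuffle")
  perms <- with_seed(shuffle_seed, replicate(config$epochs, sample.int(n),
                                             simplify = FALSE))

  for (ep in seq_len(config$epochs)) {
    idx <- perms[[ep]]
    for (start in seq(1L, n, by = config$batch_size)) {
      bi <- idx[start:min(start + config$batch_size - 1L, n)]
      g <- mlp_gradients(net, x[bi, , drop = FALSE], y[bi], act)
      step <- step + 1L
      for (l in seq_along(net)) {
        for (w in c("W", "b")) {
          mom[[l]][[w]] <- b1 * mom[[l]][[w]] + (1 - b1) * g[[l]][[w]]
          vel[[l]][[w]] <- b2 * vel[[l]][[w]] + (1 - b2) * g[[l]][[w]]^2
          mhat <- mom[[l]][[w]] / (1 - b1^step)
          vhat <- vel[[l]][[w]] / (1 - b2^step)
          net[[l]][[w]] <- net[[l]][[w]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
    }
    train_loss[ep] <- mean((mlp_forward(net, x, act) - y)^2)
    if (!is.finite(train_loss[ep])) {
      stop("training diverged (non-finite loss) at epoch ", ep, call. = FALSE)
    }
    if (has_val) {
      val_loss[ep] <- mean((mlp_forward(net, xv, act) - yv)^2)
      if (!is.null(config$early_stop_patience)) {
        if (val_loss[ep] < best_val - 1e-12) {
          best_val <- val_loss[ep]; stale <- 0L
        } else {
          stale <- stale + 1L
          if (stale >= config$early_stop_patience) { epochs_run <- ep; break }
        }
      }
    }
  }

  keep <- seq_len(epochs_run)
  model <- structure(list(net = net, scaler = scaler, config = config,
                          input_order = feats),
                     class = "release_mlp")
  list(model = model,
       trace = data.frame(epoch = keep, train_loss = train_loss[keep],
                          val_loss = val_loss[keep]))
}

init_layers <- function(layers) {
  lapply(seq_len(length(layers) - 1L), function(i) {
    fan_in <- layers[i]
    lim <- sqrt(6 / fan_in)
    list(W = matrix(runif(fan_in * layers[i + 1L], -lim, lim),
                    fan_in, layers[i + 1L]),
         b = rep(0, layers[i + 1L]))
  })
}

act_fun <- function(z, act) if (act == "relu") pmax(z, 0) else tanh(z)
act_grad <- function(z, act) if (act == "relu") (z > 0) * 1 else 1 - tanh(z)^2

mlp_forward <- function(net, x, act) {
  a <- x
  nl <- length(net)
  for (l in seq_len(nl)) {
    z <- a %*% net[[l]]$W + rep(net[[l]]$b, each = nrow(a))
    a <- if (l < nl) act_fun(z, act) else z
  }
  as.numeric(a)
}

# Backprop of the mean-squared-error loss over one minibatch.
mlp_gradients <- function(net, x, y, act) {
  nl <- length(net)
  zs <- vector("list", nl)
  as <- vector("list", nl + 1L)
  as[[1L]] <- x
  for (l in seq_len(nl)) {
    zs[[l]] <- as[[l]] %*% net[[l]]$W + rep(net[[l]]$b, each = nrow(x))
    as[[l + 1L]] <- if (l < nl) act_fun(zs[[l]], act) else zs[[l]]
  }
  m <- nrow(x)
  delta <- 2 * (as[[nl + 1L]] - y) / m          # d(loss)/d(output)
  g <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    g[[l]] <- list(W = crossprod(as[[l]], delta),
                   b = colSums(delta))
    if (l > 1L) {
      delta <- (delta %*% t(net[[l]]$W)) * act_grad(zs[[l - 1L]], act)
    }
  }
  g
}

#' Predict release percent from raw feature vectors
#'
#' The model applies its own stored scaler, so `newdata` is always raw
#' (unscaled) features in the documented [feature_names()] order.
#'
#' @param object a `release_mlp`.
#' @param newdata data.frame or matrix containing the 21 feature columns,
#'   or a single unnamed 21-vector.
#' @param ... unused.
#' @return numeric vector of predicted release percent (unclamped).
#' @export
predict.release_mlp <- function(object, newdata, ...) {
  feats <- object$input_order
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    if (length(newdata) != length(feats)) {
      stop("feature vector must have length ", length(feats), call. = FALSE)
    }
    newdata <- as.data.frame(as.list(setNames(newdata, feats)))
  }
  newdata <- as.data.frame(newdata)
  miss <- setdiff(feats, names(newdata))
  if (length(miss)) {
    stop("missing feature column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(newdata[, feats]) || any(!is.finite(as.matrix(newdata[, feats])))) {
    stop("features must be finite and non-missing", call. = FALSE)
  }
  x <- as.matrix(scale_rows(object$scaler, newdata)[, feats, drop = FALSE])
  mlp_forward(object$net, x, object$config$activation)
}

#' Predict a full release curve for one sample
#'
#' Evaluates the trained network along a time grid while holding the
#' sample's 20 non-time features fixed, yielding the fitted release curve
#' used for curve overlays and per-sample scoring.
#'
#' @param model a `release_mlp`.
#' @param dataset a `release_dataset` containing the sample (descriptors
#'   imputed/computed).
#' @param sample_id sample to predict.
#' @param time_grid non-negative, nondecreasing times in hours.
#' @return data.frame with columns `time_h` and `release_pct`.
#' @export
predict_curve <- function(model, dataset, sample_id, time_grid) {
  stopifnot(inherits(model, "release_mlp"),
            inherits(dataset, "release_dataset"))
  if (length(time_grid) == 0L) {
    return(data.frame(time_h = numeric(0), release_pct = numeric(0)))
  }
  if (any(time_grid < 0) || is.unsorted(time_grid)) {
    stop("time grid must be non-negative and nondecreasing", call. = FALSE)
  }
  s <- dataset$samples
  i <- match(sample_id, s$sample_id)
  if (is.na(i)) stop("unknown sample_id: ", sample_id, call. = FALSE)
  feats20 <- c(carrier_features(), descriptor_features())
  if (anyNA(s[i, feats20])) {
    stop("sample ", sample_id, " has missing features", call. = FALSE)
  }
  newdata <- cbind(s[rep(i, length(time_grid)), feats20, drop = FALSE],
                   data.frame(time_h = time_grid))
  data.frame(time_h = time_grid,
             release_pct = predict(model, newdata))
}

#' @export
print.release_mlp <- function(x, ...) {
  widths <- c(length(x$input_order), x$config$hidden, 1L)
  cat(sprintf("release_mlp: %s network, %s activation, seed %d\n",
              paste(widths, collapse = "-"), x$config$activation,
              x$config$seed))
  invisible(x)
}

#' Serialize a trained release MLP to a portable JSON file
#'
#' Weights, scaler, configuration and feature order are stored in one
#' plain-text JSON document at full printed double precision; a reloaded
#' model reproduces predictions to better than 1e-10 percent. Writing the
#' same model twice yields byte-identical files.
#'
#' @param model a `release_mlp`.
#' @param path output file.
#' @return `write_release_mlp()` the path, invisibly; `read_release_mlp()`
#'   the restored `release_mlp`.
#' @export
write_release_mlp <- function(model, path) {
  stopifnot(inherits(model, "release_mlp"))
  doc <- list(
    format = "plgarelease-mlp-1",
    input_order = model$input_order,
    config = unclass(model$config),
    scaler = list(center = as.list(model$scaler$center),
                  scale = as.list(model$scaler$scale),
                  features = model$scaler$features,
                  target_scaled = model$scaler$target_scaled),
    layers = lapply(model$net, function(l) {
      list(dim = dim(l$W), W = as.numeric(l$W), b = l$b)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_release_mlp
#' @export
read_release_mlp <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(doc$format, "plgarelease-mlp-1")) {
    stop("not a plgarelease MLP file: ", path, call. = FALSE)
  }
  cfg <- doc$config
  config <- mlp_config(hidden = cfg$hidden, activation = cfg$activation,
                       learning_rate = cfg$learning_rate, epochs = cfg$epochs,
                       batch_size = cfg$batch_size, seed = cfg$seed,
                       early_stop_patience = cfg$early_stop_patience)
  scaler <- structure(list(
    center = unlist(doc$scaler$center), scale = unlist(doc$scaler$scale),
    features = doc$scaler$features,
    target_scaled = isTRUE(doc$scaler$target_scaled)),
    class = "release_scaler")
  net <- lapply(seq_len(nrow(doc$layers)), function(i) {
    l <- doc$layers[i, ]
    list(W = matrix(l$W[[1]], l$dim[[1]][1], l$dim[[1]][2]),
         b = as.numeric(l$b[[1]]))
  })
  structure(list(net = net, scaler = scaler, config = config,
                 input_order = doc$input_order),
            class = "release_mlp")
}
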