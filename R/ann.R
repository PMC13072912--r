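#' Network architecture specification
#'
#' A feed-forward multilayer perceptron with fully connected hidden layers,
#' rectified-linear activations and dropout, mapping the windowed spectral
#' features to the two output concentrations (As, Pb).
#'
#' @param hidden_sizes Integer vector of hidden-layer widths; default
#'   `c(256, 128)`.
#' @param dropout_p Dropout probability applied to each hidden layer during
#'   training; default 0.1.
#' @param n_outputs Number of outputs; fixed at 2 (As, Pb).
#' @return An object of class `net_spec`.
#' @export
net_spec <- function(hidden_sizes = c(256L, 128L), dropout_p = 0.1,
                     n_outputs = 2L) {
  if (any(hidden_sizes < 1)) xrf_abort("hidden widths must be >= 1", "validation_error")
  if (dropout_p < 0 || dropout_p >= 1) {
    xrf_abort("dropout_p must be in [0, 1)", "validation_error")
  }
  if (n_outputs != 2L) xrf_abort("n_outputs is fixed at 2 (As, Pb)", "validation_error")
  structure(
    list(hidden_sizes = as.integer(hidden_sizes), activation = "relu",
         dropout_p = dropout_p, n_outputs = 2L),
    class = "net_spec"
  )
}

#' Training configuration
#'
#' Full-batch Adam with the root-mean-squared error over both outputs jointly
#' (in ug/kg) as the loss, evaluated on the test table at a fixed epoch
#' cadence; the weights at the evaluation with the lowest test RMSE are kept
#' (best-model checkpointing as an early-stopping strategy).
#'
#' @param learning_rate Adam step size; default 1e-5.
#' @param n_epochs Number of full-batch epochs; default 10000.
#' @param eval_every Epochs between test evaluations; default 500.
#' @param seed Integer seed controlling weight initialization and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-5, n_epochs = 10000L,
                         eval_every = 500L, seed = 1L) {
  if (learning_rate <= 0) xrf_abort("learning_rate must be > 0", "validation_error")
  if (n_epochs < eval_every) {
    xrf_abort("n_epochs must be >= eval_every", "validation_error")
  }
  structure(
    list(learning_rate = learning_rate, n_epochs = as.integer(n_epochs),
         eval_every = as.integer(eval_every), optimizer = "adam",
         batch = "full", loss = "rmse", seed = as.integer(seed)),
    class = "train_config"
  )
}

# ---- internal MLP engine ----------------------------------------------------

# PyTorch-style fan-in uniform initialization: U(-1/sqrt(fan_in), 1/sqrt(fan_in))
init_params <- function(dims) {
  W <- list(); b <- list()
  for (l in seq_len(length(dims) - 1)) {
    fi <- dims[l]
    W[[l]] <- matrix(runif(fi * dims[l + 1], -1, 1) / sqrt(fi), fi, dims[l + 1])
    b[[l]] <- runif(dims[l + 1], -1, 1) / sqrt(fi)
  }
  list(W = W, b = b)
}

# forward pass without dropout; returns scaled-space outputs
mlp_forward <- function(X, par) {
  L <- length(par$W)
  H <- X
  for (l in seq_len(L - 1)) {
    H <- pmax(sweep(H %*% par$W[[l]], 2, par$b[[l]], "+"), 0)
  }
  sweep(H %*% par$W[[L]], 2, par$b[[L]], "+")
}

#' Train the calibration network
#'
#' Features are standardized per channel and targets per element using
#' training-set means and standard deviations (predictions are returned in
#' ug/kg). Training is full-batch gradient descent with Adam; the loss and
#' all logged errors are the joint RMSE over both elements in ug/kg. Every
#' `eval_every` epochs the model is evaluated on `test` with dropout
#' disabled, and the parameter state with the lowest test RMSE is returned.
#' Bit-reproducible given `train_config$seed`.
#'
#' @param train,test Feature tables from [assemble_dataset()] with matching
#'   feature dimensions.
#' @param spec A [net_spec()].
#' @param config A [train_config()].
#' @return An object of class `xrf_ann` holding the checkpointed weights, the
#'   feature/target scalers, the evaluation log, and `best_epoch`.
#' @export
ann_train <- function(train, test, spec = net_spec(), config = train_config()) {
  X <- feature_matrix(train); Y <- target_matrix(train)
  Xt <- feature_matrix(test); Yt <- target_matrix(test)
  if (ncol(X) != ncol(Xt)) {
    xrf_abort("train and test feature dimensions differ", "validation_error")
  }
  if (length(unique(Y[, 1])) < 2 && length(unique(Y[, 2])) < 2) {
    xrf_abort("training targets are degenerate", "validation_error")
  }

  x_center <- colMeans(X)
  x_scale <- apply(X, 2, sd); x_scale[x_scale == 0] <- 1
  y_center <- colMeans(Y)
  y_scale <- apply(Y, 2, sd); y_scale[y_scale == 0] <- 1
  Xs <- scale(X, x_center, x_scale)
  Xts <- scale(Xt, x_center, x_scale)

  dims <- c(ncol(X), spec$hidden_sizes, spec$n_outputs)
  p <- spec$dropout_p
  lr <- config$learning_rate
  n <- nrow(Xs)
  L <- length(dims) - 1

  unscale <- function(O) sweep(sweep(O, 2, y_scale, "*"), 2, y_center, "+")
  rmse_of <- function(par, Xin, Ytrue) {
    sqrt(mean((unscale(mlp_forward(Xin, par)) - Ytrue)^2))
  }

  with_preserved_seed(config$seed, {
    par <- init_params(dims)
    mW <- lapply(par$W, function(w) w * 0); vW <- mW
    mb <- lapply(par$b, function(b) b * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    log_rows <- vector("list", config$n_epochs %/% config$eval_every)
    best_rmse <- Inf; best_par <- par; best_epoch <- 0L; li <- 0L

    for (ep in seq_len(config$n_epochs)) {
      # forward with inverted dropout on hidden layers
      A <- vector("list", L); Hd <- vector("list", L + 1); M <- vector("list", L)
      Hd[[1]] <- Xs
      for (l in seq_len(L - 1)) {
        A[[l]] <- sweep(Hd[[l]] %*% par$W[[l]], 2, par$b[[l]], "+")
        H <- pmax(A[[l]], 0)
        if (p > 0) {
          M[[l]] <- (matrix(runif(n * dims[l + 1]), n, dims[l + 1]) > p) / (1 - p)
          H <- H * M[[l]]
        }
        Hd[[l + 1]] <- H
      }
      out <- sweep(Hd[[L]] %*% par$W[[L]], 2, par$b[[L]], "+")
      E <- unscale(out) - Y
      loss <- sqrt(mean(E^2))
      if (!is.finite(loss)) {
        xrf_abort(sprintf("training diverged at epoch %d (non-finite loss)", ep),
                  "training_divergence_error")
      }
      # backward: dRMSE/dpred = resid / (N * RMSE); chain through target scale
      delta <- sweep(E / (length(E) * loss), 2, y_scale, "*")
      gW <- vector("list", L); gb <- vector("list", L)
      for (l in rev(seq_len(L))) {
        gW[[l]] <- crossprod(Hd[[l]], delta)
        gb[[l]] <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(par$W[[l]])) * (A[[l - 1]] > 0)
          if (p > 0) delta <- delta * M[[l - 1]]
        }
      }
      bc1 <- 1 - beta1^ep; bc2 <- 1 - beta2^ep
      for (l in seq_len(L)) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
        par$W[[l]] <- par$W[[l]] - lr * (mW[[l]] / bc1) / (sqrt(vW[[l]] / bc2) + eps)
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb[[l]]
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb[[l]]^2
        par$b[[l]] <- par$b[[l]] - lr * (mb[[l]] / bc1) / (sqrt(vb[[l]] / bc2) + eps)
      }
      if (ep %% config$eval_every == 0) {
        train_rmse <- rmse_of(par, Xs, Y)
        test_rmse <- rmse_of(par, Xts, Yt)
        li <- li + 1L
        log_rows[[li]] <- tibble(epoch = ep, train_rmse = train_rmse,
                                 test_rmse = test_rmse)
        if (test_rmse < best_rmse) {
          best_rmse <- test_rmse; best_par <- par; best_epoch <- ep
        }
      }
    }

    structure(
      list(
        spec = spec, config = config, par = best_par,
        scaler = list(x_center = x_center, x_scale = x_scale,
                      y_center = y_center, y_scale = y_scale),
        region = attr(train, "region"),
        feature_names = colnames(X),
        best_epoch = best_epoch, best_test_rmse = best_rmse,
        log = bind_rows(log_rows)
      ),
      class = "xrf_ann"
    )
  })
}

#' Predict concentrations for new spectra
#'
#' Applies the stored feature scaler and the checkpointed weights with
#' dropout disabled. Outputs are in ug/kg and are not clipped: negative
#' predictions are reported as-is.
#'
#' @param object An `xrf_ann` model.
#' @param newdata A feature table (or bare feature matrix) whose feature
#'   length matches the model input.
#' @param ... Unused.
#' @return A tibble with any metadata columns of `newdata` plus `as_pred`,
#'   `pb_pred`.
#' @export
predict.xrf_ann <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  if (ncol(X) != length(object$scaler$x_center)) {
    xrf_abort("feature length does not match the model input", "validation_error")
  }
  Xs <- scale(X, object$scaler$x_center, object$scaler$x_scale)
  out <- mlp_forward(Xs, object$par)
  P <- sweep(sweep(out, 2, object$scaler$y_scale, "*"), 2,
             object$scaler$y_center, "+")
  meta <- if (is.matrix(newdata)) {
    tibble(.rows = nrow(X))
  } else {
    newdata[, intersect(c("standard_id", "pellet_id", "repeat_id",
                          "as_ug_kg", "pb_ug_kg"), names(newdata)),
            drop = FALSE]
  }
  mutate(meta, as_pred = P[, 1], pb_pred = P[, 2])
}

#' @export
print.xrf_ann <- function(x, ...) {
  cat(sprintf(
    "<xrf_ann> %d-%s-2 MLP, best epoch %d (test RMSE %.2f ug/kg), %d epochs trained\n",
    length(x$scaler$x_center),
    paste(x$spec$hidden_sizes, collapse = "-"),
    x$best_epoch, x$best_test_rmse, x$config$n_epochs))
  invisible(x)
}

#' @describeIn ann_train Evaluation log as a tibble (one row per test
#'   evaluation: `epoch`, `train_rmse`, `test_rmse`).
#' @param x An `xrf_ann` model.
#' @param ... Unused.
#' @export
tidy.xrf_ann <- function(x, ...) x$log

#' @describeIn ann_train One-row model summary.
#' @export
glance.xrf_ann <- function(x, ...) {
  tibble(
    input_dim = length(x$scaler$x_center),
    hidden = paste(x$spec$hidden_sizes, collapse = "x"),
    n_epochs = x$config$n_epochs,
    best_epoch = x$best_epoch,
    best_test_rmse = x$best_test_rmse,
    final_train_rmse = x$log$train_rmse[nrow(x$log)],
    final_test_rmse = x$log$test_rmse[nrow(x$log)]
  )
}

#' @describeIn ann_train Training-curve plot (train and test RMSE against
#'   epoch, with the checkpointed epoch marked).
#' @param object An `xrf_ann` model.
#' @export
autoplot.xrf_ann <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, c("train_rmse", "test_rmse"),
                            names_to = "set", values_to = "rmse")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$rmse, colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::labs(x = "Epoch", y = "RMSE (ug/kg)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Save / load a trained model
#'
#' The model artifact is an RDS file holding weights, scalers, region and log,
#' with a JSON sidecar of training metadata and a CSV export of the log.
#'
#' @param model An `xrf_ann` model.
#' @param path Path of the RDS artifact; the sidecars take `.json` / `_log.csv`
#'   suffixes.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  side <- sub("\\.rds$", "", path)
  jsonlite::write_json(
    list(
      input_dim = length(model$scaler$x_center),
      hidden_sizes = model$spec$hidden_sizes,
      dropout_p = model$spec$dropout_p,
      learning_rate = model$config$learning_rate,
      n_epochs = model$config$n_epochs,
      eval_every = model$config$eval_every,
      seed = model$config$seed,
      best_epoch = model$best_epoch,
      best_test_rmse = model$best_test_rmse
    ),
    paste0(side, ".json"), auto_unbox = TRUE, digits = NA
  )
  readr::write_csv(model$log, paste0(side, "_log.csv"), progress = FALSE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "xrf_ann")) xrf_abort("not an xrf_ann artifact", "format_error")
  m
}
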