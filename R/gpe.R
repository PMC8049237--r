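# Gaussian-process emulator ------------------------------------------------------

gp_kernel <- function(X1, X2, ls, sf2) {
  D <- ncol(X1)
  d2 <- matrix(0, nrow(X1), nrow(X2))
  for (d in seq_len(D)) {
    d2 <- d2 + outer(X1[, d], X2[, d], `-`)^2 / ls[d]^2
  }
  sf2 * exp(-0.5 * d2)
}

gp_nll <- function(par, X, y) {
  D <- ncol(X)
  ls <- exp(par[seq_len(D)])
  sf2 <- exp(2 * par[D + 1])
  sn2 <- exp(2 * par[D + 2])
  K <- gp_kernel(X, X, ls, sf2) + diag(sn2, nrow(X))
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  0.5 * sum(y * alpha) + sum(log(diag(L))) + 0.5 * length(y) * log(2 * pi)
}

#' Fit a Gaussian-process emulator
#'
#' Anisotropic squared-exponential kernel with a nugget; outputs are
#' standardised (zero mean, unit variance) before fitting and hyperparameters
#' (per-dimension lengthscales, signal and noise standard deviations) are
#' optimised by L-BFGS-B on the log marginal likelihood unless supplied.
#' Degenerate optimisations fall back to the default hyperparameters with a
#' warning.
#'
#' @param X numeric matrix `n x D` of inputs (mode weights).
#' @param y numeric response vector (one phenotype).
#' @param hyper optional list with `log_ls` (length D), `log_sf`, `log_sn`;
#'   when given, no optimisation is performed.
#' @param optim_control passed to [stats::optim()].
#' @return object of class `gpe`.
#' @export
gpe_fit <- function(X, y, hyper = NULL,
                    optim_control = list(maxit = 80)) {
  X <- as.matrix(X)
  D <- ncol(X)
  mu_y <- mean(y)
  sd_y <- stats::sd(y)
  if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
  ys <- (y - mu_y) / sd_y
  span <- apply(X, 2, function(v) diff(range(v)))
  span[span == 0] <- 1
  par0 <- c(log(span / 2), 0, log(0.05))
  if (is.null(hyper)) {
    lower <- c(log(span * 1e-2), log(1e-2), log(1e-4))
    upper <- c(log(span * 1e3), log(1e2), log(1))
    fit <- tryCatch(
      stats::optim(par0, gp_nll, X = X, y = ys, method = "L-BFGS-B",
                   lower = lower, upper = upper, control = optim_control),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e10) {
      warning("GP hyperparameter optimisation degenerate; ",
              "falling back to default hyperparameters")
      par <- par0
    } else {
      par <- fit$par
    }
    hyper <- list(log_ls = par[seq_len(D)], log_sf = par[D + 1],
                  log_sn = par[D + 2])
  }
  ls <- exp(hyper$log_ls)
  sf2 <- exp(2 * hyper$log_sf)
  sn2 <- exp(2 * hyper$log_sn)
  K <- gp_kernel(X, X, ls, sf2) + diag(sn2, nrow(X))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  structure(list(X = X, y = y, mu_y = mu_y, sd_y = sd_y, hyper = hyper,
                 L = L, alpha = alpha),
            class = "gpe")
}

#' Predictive mean and variance of a fitted emulator
#'
#' @param object a [gpe_fit()] model.
#' @param newdata numeric matrix `m x D`.
#' @param ... unused.
#' @return tibble with `.pred` (mean) and `.pred_var` (predictive variance,
#'   original output scale).
#' @export
predict.gpe <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  ls <- exp(object$hyper$log_ls)
  sf2 <- exp(2 * object$hyper$log_sf)
  Ks <- gp_kernel(object$X, newdata, ls, sf2)
  mean_s <- drop(crossprod(Ks, object$alpha))
  v <- forwardsolve(t(object$L), Ks)
  var_s <- pmax(0, sf2 - colSums(v^2))
  tibble::tibble(.pred = mean_s * object$sd_y + object$mu_y,
                 .pred_var = var_s * object$sd_y^2)
}

#' @export
print.gpe <- function(x, ...) {
  cat("gpe:", nrow(x$X), "training points,", ncol(x$X), "inputs\n")
  cat("  lengthscales:", paste(signif(exp(x$hyper$log_ls), 3),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Train a phenotype emulator by leave-one-out cross-validation
#'
#' One LOO split per observed (CT-like) case; the synthetic cases are always
#' part of the training set. Each split records the squared error on the
#' left-out case. The returned model is refit on all data with the
#' hyperparameters of the split with the smallest left-out error (the
#' "best-scoring" emulator); `mean_mse` is the mean LOO squared error.
#'
#' @param weights tibble with `case` and one numeric column per mode.
#' @param phenos tibble with `case`, a `completed` flag and phenotype
#'   columns.
#' @param phenotype name of the phenotype column to emulate.
#' @param synthetic logical vector (or character vector of case names)
#'   marking synthetic cases, which are never left out.
#' @return object of class `gpe_loo`: list with `model` ([gpe_fit()]),
#'   `loo` tibble (`case`, `sq_error`), `mean_mse`, `phenotype`.
#' @export
train_gpes_loo <- function(weights, phenos, phenotype, synthetic = FALSE) {
  df <- dplyr::inner_join(weights, phenos, by = "case")
  if (is.character(synthetic)) synthetic <- df$case %in% synthetic
  if (length(synthetic) == 1) synthetic <- rep(synthetic, nrow(df))
  keep <- (if ("completed" %in% names(df)) df$completed else TRUE) &
    is.finite(df[[phenotype]])
  df <- df[keep, , drop = FALSE]
  synthetic <- synthetic[keep]
  mode_cols <- grep("^mode_", names(df), value = TRUE)
  X <- as.matrix(df[, mode_cols])
  y <- df[[phenotype]]
  ct_idx <- which(!synthetic)
  if (length(ct_idx) < 4) {
    stop("need at least 4 observed (non-synthetic) completed cases for ",
         "leave-one-out training", call. = FALSE)
  }
  splits <- purrr::map(ct_idx, function(i) {
    m <- gpe_fit(X[-i, , drop = FALSE], y[-i])
    pr <- predict(m, X[i, , drop = FALSE])
    list(case = df$case[i], sq_error = (pr$.pred - y[i])^2, hyper = m$hyper)
  })
  loo <- tibble::tibble(case = purrr::map_chr(splits, "case"),
                        sq_error = purrr::map_dbl(splits, "sq_error"))
  best <- which.min(loo$sq_error)
  model <- gpe_fit(X, y, hyper = splits[[best]]$hyper)
  structure(list(model = model, loo = loo, mean_mse = mean(loo$sq_error),
                 best_case = loo$case[best], best_hyper = splits[[best]]$hyper,
                 phenotype = phenotype, mode_cols = mode_cols),
            class = "gpe_loo")
}

#' @export
print.gpe_loo <- function(x, ...) {
  cat("gpe_loo emulator for", x$phenotype, "- mean LOO MSE",
      signif(x$mean_mse, 4), "over", nrow(x$loo), "splits\n")
  invisible(x)
}

#' @export
glance.gpe_loo <- function(x, ...) {
  tibble::tibble(phenotype = x$phenotype, n_train = nrow(x$model$X),
                 n_splits = nrow(x$loo), mean_mse = x$mean_mse,
                 best_case = x$loo$case[which.min(x$loo$sq_error)])
}
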