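#' Interaction-term structure of the fourth-degree polynomial model
#'
#' The glucose regression uses the four predictors x1 = H (metabolic heat,
#' W/m^2), x2 = SpO2 (%), x3 = HR (bpm), x4 = BF (perfusion units), and
#' exactly the 15 products of distinct predictors — all subsets of size 1 to
#' 4, no squared or higher pure powers (interaction-only, to limit
#' collinearity). Term order is fixed and stable:
#' x1, x2, x3, x4, x1x2, x1x3, x1x4, x2x3, x2x4, x3x4, x1x2x3, x1x2x4,
#' x1x3x4, x2x3x4, x1x2x3x4.
#'
#' @return A list of integer index subsets, one per term, in model order.
#' @export
mpr4_terms <- function() {
  list(1L, 2L, 3L, 4L,
       c(1L, 2L), c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L), c(3L, 4L),
       c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 3L, 4L), c(2L, 3L, 4L),
       c(1L, 2L, 3L, 4L))
}

feature_matrix <- function(records) {
  if (is.data.frame(records)) {
    cols <- if (all(c("H", "SpO2", "HR", "BF") %in% names(records))) {
      c("H", "SpO2", "HR", "BF")
    } else if (all(paste0("x", 1:4) %in% names(records))) {
      paste0("x", 1:4)
    } else {
      stop("records need columns (H, SpO2, HR, BF) or (x1..x4)",
           call. = FALSE)
    }
    x <- as.matrix(records[cols])
  } else {
    x <- as.matrix(records)
  }
  if (ncol(x) != 4L) stop("exactly 4 predictors required", call. = FALSE)
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-finite feature: row %d, predictor x%d",
                 bad[1, 1], bad[1, 2]), call. = FALSE)
  }
  colnames(x) <- paste0("x", 1:4)
  x
}

#' Build the 15-column interaction design matrix
#'
#' @param records A data.frame with columns `H`, `SpO2`, `HR`, `BF` (or
#'   `x1`..`x4`), or a numeric matrix with 4 columns.
#' @return An `n x 15` matrix, columns named by their term (e.g. `x1:x3`),
#'   in the order of [mpr4_terms()].
#' @examples
#' build_design_matrix(matrix(c(1, 2, 3, 4), nrow = 1))
#' @export
build_design_matrix <- function(records) {
  x <- feature_matrix(records)
  terms <- mpr4_terms()
  d <- vapply(terms, function(ix) {
    apply(x[, ix, drop = FALSE], 1L, prod)
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) d <- matrix(d, nrow = 1L)
  colnames(d) <- vapply(terms, function(ix) {
    paste(paste0("x", ix), collapse = ":")
  }, character(1))
  d
}

#' Fit the fourth-degree interaction-only polynomial glucose model (MPR4)
#'
#' Ordinary least squares of reference blood glucose on the 15 interaction
#' terms plus an intercept (the "compensation parameter" a0), solved by QR
#' decomposition on the raw (unscaled) features so the coefficients keep
#' their physical meaning. Fitting is refused when the sample size is not
#' greater than three times the number of model variables (n > 45), the
#' model's own adequacy rule; a rank-deficient design is rejected with the
#' collinear columns named.
#'
#' @param records Feature records (see [build_design_matrix()]).
#' @param bg Reference blood glucose, mmol/L (length = rows of `records`);
#'   alternatively a `bg_ref` column of `records`.
#' @return An object of class `mpr4`: coefficients a0..a15 (named by term),
#'   term order, and training metadata.
#' @export
fit_mpr4 <- function(records, bg = NULL) {
  if (is.null(bg)) {
    if (is.data.frame(records) && "bg_ref" %in% names(records)) {
      bg <- records$bg_ref
    } else stop("reference glucose `bg` required for fitting", call. = FALSE)
  }
  X <- build_design_matrix(records)
  n <- nrow(X)
  if (length(bg) != n) stop("length(bg) must match nrow(records)",
                            call. = FALSE)
  if (any(!is.finite(bg)) || any(bg <= 0)) {
    stop("reference glucose must be finite and > 0 mmol/L", call. = FALSE)
  }
  if (n <= 3 * ncol(X)) {
    stop(sprintf(paste0("n = %d refused: the model is justifiable only when ",
                        "the sample size exceeds three times the number of ",
                        "variables (n > %d)"), n, 3 * ncol(X)),
         call. = FALSE)
  }
  Xi <- cbind(`(Intercept)` = 1, X)
  qx <- qr(Xi)
  if (qx$rank < ncol(Xi)) {
    dropped <- colnames(Xi)[qx$pivot[(qx$rank + 1L):ncol(Xi)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qx, bg)
  structure(list(coefficients = beta,
                 terms = colnames(X),
                 n = n),
            class = "mpr4")
}

#' @export
print.mpr4 <- function(x, ...) {
  cat("MPR4 interaction-only polynomial glucose model\n")
  cat(sprintf("  fitted on n = %d records; 15 terms + intercept\n", x$n))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Predict blood glucose from a fitted MPR4 model
#'
#' @param object A fitted [fit_mpr4()] model.
#' @param newdata Feature records (see [build_design_matrix()]).
#' @param ... Unused.
#' @return Predicted blood glucose, mmol/L.
#' @export
predict.mpr4 <- function(object, newdata, ...) {
  X <- build_design_matrix(newdata)
  as.vector(cbind(1, X) %*% object$coefficients)
}

bpnn_unpack <- function(par, nin, nhid) {
  i <- 0L
  W1 <- matrix(par[i + seq_len(nhid * nin)], nhid, nin); i <- i + nhid * nin
  b1 <- par[i + seq_len(nhid)]; i <- i + nhid
  w2 <- par[i + seq_len(nhid)]; i <- i + nhid
  b2 <- par[i + 1L]
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
}

bpnn_forward_scaled <- function(Xs, W1, b1, w2, b2) {
  A <- tanh(sweep(Xs %*% t(W1), 2L, b1, "+"))
  drop(A %*% w2 + b2)
}

#' Fit the back-propagation neural network glucose model
#'
#' A three-layer feedforward network sized by the Kolmogorov rule
#' `Nhid = 2*Nin + 1` (so 4 inputs give 9 hidden units), with
#' hyperbolic-tangent sigmoid ("tansig") hidden activations and a linear
#' output, trained as a nonlinear least-squares problem by the
#' Levenberg-Marquardt algorithm with an analytic Jacobian. Predictors and
#' target are standardized to the training split's mean and standard
#' deviation before optimization; the scaling is stored with the model so
#' prediction is self-contained. Weight initialization is drawn from a
#' seeded uniform distribution, making a fit bit-reproducible for a given
#' (data, seed) pair.
#'
#' With 55 free weights, the network can memorize measurement noise on
#' cohort-sized training sets; by default a seeded fifth of the training
#' records is held out as a validation set and optimization stops early at
#' the weights with the lowest validation error (the standard safeguard for
#' Levenberg-Marquardt network training). Set `validation_fraction = 0` to
#' optimize the training loss alone. Because the loss surface of a tansig
#' network is multimodal, the optimization is restarted from `n_starts`
#' seeded initializations and the restart with the lowest validation error
#' (training error when validation is disabled) is kept.
#'
#' @param records Feature records (see [build_design_matrix()]).
#' @param bg Reference blood glucose, mmol/L (or a `bg_ref` column).
#' @param seed Integer seed for weight initialization.
#' @param max_epochs Maximum Levenberg-Marquardt iterations.
#' @param tolerance Relative convergence tolerance on the sum of squares.
#' @param validation_fraction Fraction of records held out for early
#'   stopping, in `[0, 0.5]`; 0 disables early stopping.
#' @param patience Early-stopping patience: optimization halts after this
#'   many consecutive epochs without a validation improvement.
#' @param n_starts Number of seeded random restarts.
#' @return An object of class `bpnn`: weights, biases, input/target scaling,
#'   convergence flag and training metadata. A non-converged fit is returned
#'   (best iterate) with `converged = FALSE` and a warning.
#' @export
fit_bpnn <- function(records, bg = NULL, seed = 1L, max_epochs = 200L,
                     tolerance = 1e-8, validation_fraction = 0.2,
                     patience = 25L, n_starts = 5L) {
  if (is.null(bg)) {
    if (is.data.frame(records) && "bg_ref" %in% names(records)) {
      bg <- records$bg_ref
    } else stop("reference glucose `bg` required for fitting", call. = FALSE)
  }
  X <- feature_matrix(records)
  n <- nrow(X)
  if (n < 20) stop("at least 20 training records required", call. = FALSE)
  if (length(bg) != n) stop("length(bg) must match nrow(records)",
                            call. = FALSE)
  if (validation_fraction < 0 || validation_fraction > 0.5) {
    stop("`validation_fraction` must lie in [0, 0.5]", call. = FALSE)
  }

  nin <- 4L
  nhid <- 2L * nin + 1L
  x_center <- colMeans(X)
  x_scale <- apply(X, 2L, stats::sd)
  x_scale[x_scale == 0] <- 1
  y_center <- mean(bg)
  y_scale <- stats::sd(bg)
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  Xs_all <- sweep(sweep(X, 2L, x_center), 2L, x_scale, "/")
  ys_all <- (bg - y_center) / y_scale

  npar <- nhid * nin + nhid + nhid + 1L
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  set.seed(as.integer(seed))
  inits <- lapply(seq_len(max(1L, n_starts)),
                  function(s) stats::runif(npar, -0.5, 0.5))
  n_val <- floor(validation_fraction * n)
  val_idx <- if (n_val >= 1L) sort(sample.int(n, n_val)) else integer(0)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)

  fit_idx <- setdiff(seq_len(n), val_idx)
  Xs <- Xs_all[fit_idx, , drop = FALSE]
  ys <- ys_all[fit_idx]
  nfit <- length(fit_idx)

  resid_fn <- function(par) {
    w <- bpnn_unpack(par, nin, nhid)
    ys - bpnn_forward_scaled(Xs, w$W1, w$b1, w$w2, w$b2)
  }
  jac_fn <- function(par) {
    w <- bpnn_unpack(par, nin, nhid)
    Z <- sweep(Xs %*% t(w$W1), 2L, w$b1, "+")
    A <- tanh(Z)
    D <- (1 - A^2) * matrix(w$w2, nfit, nhid, byrow = TRUE)  # nfit x nhid
    J <- matrix(0, nfit, length(par))
    for (k in seq_len(nin)) {
      J[, (k - 1L) * nhid + seq_len(nhid)] <- -D * Xs[, k]
    }
    J[, nhid * nin + seq_len(nhid)] <- -D
    J[, nhid * nin + nhid + seq_len(nhid)] <- -A
    J[, length(par)] <- -1
    J
  }
  val_sse <- function(par) {
    w <- bpnn_unpack(par, nin, nhid)
    e <- ys_all[val_idx] -
      bpnn_forward_scaled(Xs_all[val_idx, , drop = FALSE],
                          w$W1, w$b1, w$w2, w$b2)
    sum(e^2)
  }
  run_lm <- function(par, iters) {
    withCallingHandlers(
      minpack.lm::nls.lm(
        par = par, fn = resid_fn, jac = jac_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = as.integer(iters), ftol = tolerance, ptol = tolerance)),
      warning = function(w) {
        if (grepl("maxiter", conditionMessage(w))) {
          invokeRestart("muffleWarning")  # reported via `converged` instead
        }
      })
  }

  one_start <- function(par0) {
    if (length(val_idx)) {
      # chunked optimization, early stopping at the best validation error
      chunk <- 5L
      best_par <- par <- par0
      best_val <- val_sse(par0)
      stall <- 0L
      epochs <- 0L
      info <- -1L
      while (epochs < max_epochs && stall < patience) {
        fit <- run_lm(par, min(chunk, max_epochs - epochs))
        par <- fit$par
        epochs <- epochs + fit$niter
        info <- fit$info
        v <- val_sse(par)
        if (v < best_val - 1e-12) {
          best_val <- v
          best_par <- par
          stall <- 0L
        } else {
          stall <- stall + chunk
        }
        if (info %in% 1:4 || fit$deviance < 1e-10 * nfit) break
      }
      deviance <- sum(resid_fn(best_par)^2)
      list(par = best_par, deviance = deviance, score = best_val,
           converged = info %in% 1:4 || stall >= patience ||
             deviance < 1e-10 * nfit,
           niter = epochs)
    } else {
      fit <- run_lm(par0, max_epochs)
      # info 1-4 are the optimizer's convergence codes; a residual at
      # machine zero on the standardized scale is converged regardless
      list(par = fit$par, deviance = fit$deviance, score = fit$deviance,
           converged = fit$info %in% 1:4 || fit$deviance < 1e-10 * nfit,
           niter = fit$niter)
    }
  }
  starts <- lapply(inits, one_start)
  best <- starts[[which.min(vapply(starts, `[[`, numeric(1), "score"))]]
  final_par <- best$par
  deviance <- best$deviance
  converged <- best$converged
  niter <- best$niter
  if (!converged) {
    warning("Levenberg-Marquardt did not converge within max_epochs; ",
            "returning best iterate", call. = FALSE)
  }
  w <- bpnn_unpack(final_par, nin, nhid)
  structure(list(W1 = w$W1, b1 = w$b1, w2 = w$w2, b2 = w$b2,
                 nin = nin, nhid = nhid,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 x_range = apply(X, 2L, range),
                 seed = as.integer(seed),
                 validation_fraction = validation_fraction,
                 epochs = niter, converged = converged,
                 sse = deviance, n = n),
            class = "bpnn")
}

#' @export
print.bpnn <- function(x, ...) {
  cat(sprintf("BPNN glucose model: %d-%d-1, tansig hidden, linear output\n",
              x$nin, x$nhid))
  cat(sprintf("  n = %d, %d LM iterations, converged: %s, seed %d\n",
              x$n, x$epochs, x$converged, x$seed))
  invisible(x)
}

#' Predict blood glucose from a fitted BPNN model
#'
#' Deterministic forward pass through the stored weights using the model's
#' own training-split scaling. Features beyond ten times the training range
#' trigger an extrapolation warning (not an error).
#'
#' @param object A fitted [fit_bpnn()] model.
#' @param newdata Feature records (see [build_design_matrix()]).
#' @param ... Unused.
#' @return Predicted blood glucose, mmol/L.
#' @export
predict.bpnn <- function(object, newdata, ...) {
  X <- feature_matrix(newdata)
  rng <- object$x_range
  span <- pmax(rng[2, ] - rng[1, ], 1e-12)
  lo <- rng[1, ] - 10 * span
  hi <- rng[2, ] + 10 * span
  if (any(sweep(X, 2L, lo) < 0) || any(sweep(X, 2L, hi) > 0)) {
    warning("feature(s) far outside the training range: extrapolating",
            call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2L, object$x_center), 2L, object$x_scale, "/")
  ys <- bpnn_forward_scaled(Xs, object$W1, object$b1, object$w2, object$b2)
  as.vector(ys * object$y_scale + object$y_center)
}

#' Seeded hold-out split
#'
#' Random partition of the records into disjoint training and test sets
#' whose union is the input, reproducible by seed. The default training
#' fraction is 118/211, the study protocol's hold-out (kept as a fraction so
#' other cohort sizes scale; the protocol's own counts are internally
#' inconsistent — 118 + 63 is 181, not 211 — and that inconsistency is left
#' visible rather than resolved).
#'
#' @param records A data.frame (split by row) or a single integer count.
#' @param train_fraction Fraction of records assigned to training, in (0,1).
#' @param seed Integer seed.
#' @return A list with `train` and `test` (data.frames, or integer index
#'   vectors when `records` was a count) and the index vectors as
#'   `train_idx` / `test_idx`.
#' @export
holdout_split <- function(records, train_fraction = 118 / 211, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- if (is.data.frame(records)) nrow(records) else as.integer(records)
  n_train <- max(1L, min(n - 1L, round(train_fraction * n)))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  set.seed(as.integer(seed))
  train_idx <- sort(sample.int(n, n_train))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  test_idx <- setdiff(seq_len(n), train_idx)
  if (is.data.frame(records)) {
    list(train = records[train_idx, , drop = FALSE],
         test = records[test_idx, , drop = FALSE],
         train_idx = train_idx, test_idx = test_idx)
  } else {
    list(train = train_idx, test = test_idx,
         train_idx = train_idx, test_idx = test_idx)
  }
}

#' Save or load a fitted glucose model as structured text
#'
#' Models are serialized as YAML — coefficients, weights, scaling, seed and
#' term order all human-readable — so fits are auditable, diffable and
#' portable across machines.
#'
#' @param model A fitted `mpr4` or `bpnn` model.
#' @param path File path.
#' @return `write_model` returns `path` invisibly; `read_model` returns the
#'   model object.
#' @export
write_model <- function(model, path) {
  cls <- class(model)[1]
  if (!cls %in% c("mpr4", "bpnn")) {
    stop("only mpr4 and bpnn models can be serialized", call. = FALSE)
  }
  payload <- lapply(unclass(model), function(v) {
    if (is.matrix(v)) {
      list(matrix = TRUE, nrow = nrow(v), data = as.numeric(v))
    } else v
  })
  yaml::write_yaml(list(model_class = cls, fields = payload), path,
                   precision = 17L)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$model_class)) stop("not a glucoheat model file",
                                     call. = FALSE)
  fields <- lapply(raw$fields, function(v) {
    if (is.list(v) && isTRUE(v$matrix)) {
      matrix(as.numeric(unlist(v$data)), nrow = v$nrow)
    } else if (is.list(v)) unlist(v) else v
  })
  structure(fields, class = raw$model_class)
}
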