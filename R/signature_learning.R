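# Per-drug response-prediction models: feedforward regression network
# (ReLU hidden layers, Adam optimizer, L1/L2 penalties, optional dropout)
# fitted on per-gene z-scored expression, hyperparameters grid-searched by
# cross-validated RMSE, gene signatures from permutation feature
# importance.

#' Hyperparameter grid for drug-response models
#'
#' @param hidden list of integer vectors — hidden-layer sizes (e.g.
#'   `list(c(32), c(64, 32))`); `integer(0)` means a linear model.
#' @param dropout dropout rates on hidden activations.
#' @param l1,l2 penalty weights on all connection weights.
#' @param epochs full-batch training epochs.
#' @param folds cross-validation folds (>= 2).
#' @param lr Adam learning rate.
#' @return list classed `lp_model_grid`. Grid points are enumerated with
#'   `hidden` varying fastest, then `dropout`, `l1`, `l2`, `epochs`; RMSE
#'   ties during model selection are broken by this order.
#' @export
model_grid <- function(hidden = list(c(16L)), dropout = 0,
                       l1 = c(1e-3, 3e-3), l2 = 1e-3, epochs = 150L,
                       folds = 5L, lr = 0.01) {
  stopifnot(length(hidden) >= 1, folds >= 2, all(epochs >= 1),
            all(dropout >= 0 & dropout < 1), all(l1 >= 0), all(l2 >= 0))
  points <- list()
  for (ep in epochs) for (pl2 in l2) for (pl1 in l1) for (dr in dropout)
    for (h in hidden) {
      points[[length(points) + 1]] <- list(hidden = as.integer(h),
                                           dropout = dr, l1 = pl1, l2 = pl2,
                                           epochs = as.integer(ep))
    }
  structure(list(points = points, folds = as.integer(folds), lr = lr),
            class = "lp_model_grid")
}

relu <- function(x) x * (x > 0)

init_mlp <- function(p, hidden) {
  sizes <- c(p, hidden, 1L)
  L <- length(sizes) - 1
  W <- list(); b <- list()
  for (l in seq_len(L)) {
    # He initialization for ReLU layers; the output layer starts at zero so
    # the initial model is exactly the mean predictor and weight norm grows
    # only as the signal warrants
    W[[l]] <- if (l == L) {
      matrix(0, nrow = sizes[l], ncol = sizes[l + 1])
    } else {
      matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
             nrow = sizes[l])
    }
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X, dropout_masks = NULL) {
  L <- length(par$W)
  A <- list(X)
  Z <- list()
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% par$W[[l]], 2, par$b[[l]], `+`)
    if (l < L) {
      act <- relu(Z[[l]])
      if (!is.null(dropout_masks) && !is.null(dropout_masks[[l]])) {
        act <- act * dropout_masks[[l]]
      }
      A[[l + 1]] <- act
    } else {
      A[[l + 1]] <- Z[[l]]
    }
  }
  list(A = A, Z = Z, yhat = drop(A[[L + 1]]))
}

# Full-batch Adam on MSE + l1*|W| + l2*W^2. Deterministic given seed.
mlp_train <- function(X, y, hidden, l1 = 0, l2 = 0, dropout = 0,
                      epochs = 150L, lr = 0.01, seed = 1L) {
  set.seed(as.integer(seed))
  n <- nrow(X); p <- ncol(X)
  y_center <- mean(y)
  y <- y - y_center
  par <- init_mlp(p, hidden)
  L <- length(par$W)
  mW <- vW <- lapply(par$W, function(w) w * 0)
  mb <- vb <- lapply(par$b, function(bb) bb * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  for (t in seq_len(epochs)) {
    masks <- NULL
    if (dropout > 0 && L > 1) {
      masks <- lapply(seq_len(L - 1), function(l) {
        keep <- matrix(stats::runif(n * length(par$b[[l]])) >= dropout,
                       nrow = n)
        keep / (1 - dropout)   # inverted dropout
      })
    }
    fw <- mlp_forward(par, X, masks)
    err <- fw$yhat - y                    # dLoss/dyhat * n/2
    delta <- matrix(2 * err / n, ncol = 1)
    for (l in rev(seq_len(L))) {
      gW <- crossprod(fw$A[[l]], delta) + 2 * l2 * par$W[[l]] +
        l1 * sign(par$W[[l]])
      gb <- colSums(delta)
      if (l > 1) {
        back <- delta %*% t(par$W[[l]])
        dact <- (fw$Z[[l - 1]] > 0) * 1
        if (!is.null(masks) && !is.null(masks[[l - 1]])) {
          dact <- dact * masks[[l - 1]]
        }
        delta <- back * dact
      }
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
      mW_hat <- mW[[l]] / (1 - beta1^t); vW_hat <- vW[[l]] / (1 - beta2^t)
      mb_hat <- mb[[l]] / (1 - beta1^t); vb_hat <- vb[[l]] / (1 - beta2^t)
      par$W[[l]] <- par$W[[l]] - lr * mW_hat / (sqrt(vW_hat) + eps)
      par$b[[l]] <- par$b[[l]] - lr * mb_hat / (sqrt(vb_hat) + eps)
    }
  }
  par$y_center <- y_center
  par
}

mlp_predict <- function(par, X) {
  mlp_forward(par, X)$yhat + if (is.null(par$y_center)) 0 else par$y_center
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

# z-score per gene; zero-variance genes become all-zero columns.
standardize_expr <- function(expr) {
  mu <- rowMeans(expr)
  sdv <- apply(expr, 1, stats::sd)
  if (all(sdv == 0)) stop("degenerate expression: all genes have zero variance")
  sdv[sdv == 0] <- 1
  t((expr - mu) / sdv)    # samples x genes
}

#' Grid-searched drug-response model
#'
#' For each hyperparameter point, k-fold cross-validated RMSE of a
#' feedforward regression network predicting drug AUC from per-gene
#' z-scored expression; the model is refit on all samples at the argmin
#' point (ties broken by grid enumeration order). Fully deterministic
#' given `seed`.
#'
#' @param expr genes x samples expression matrix.
#' @param auc named numeric vector of AUC per sample (names matched
#'   against `colnames(expr)`), or a samples x drugs matrix together with
#'   `drug`.
#' @param drug drug name (column of `auc` when `auc` is a matrix).
#' @param grid [model_grid()].
#' @param seed integer seed (weight initialization, fold assignment,
#'   dropout).
#' @return list classed `lp_drug_model`: `drug`, `chosen`
#'   (hyperparameters), `cv_rmse` (per grid point), `best_rmse`, `par`
#'   (trained weights), `genes`, `center`/`scale` used for
#'   standardization.
#' @export
grid_search_fit <- function(expr, auc, drug = NULL, grid = model_grid(),
                            seed = 1L) {
  if (is.matrix(auc)) {
    if (is.null(drug)) stop("drug must be named when auc is a matrix")
    auc <- auc[, drug]
  }
  common <- intersect(colnames(expr), names(auc))
  if (length(common) < grid$folds) stop("fewer samples than folds")
  if (length(common) < 20) {
    warning("only ", length(common), " samples with both expression and AUC")
  }
  expr <- expr[, common, drop = FALSE]
  y <- unname(auc[common])
  X <- standardize_expr(expr)
  n <- nrow(X)
  set.seed(as.integer(seed))
  fold_id <- sample(rep(seq_len(grid$folds), length.out = n))
  cv_rmse <- vapply(seq_along(grid$points), function(gi) {
    gp <- grid$points[[gi]]
    sq_err <- numeric(0)
    for (f in seq_len(grid$folds)) {
      tr <- fold_id != f
      par <- mlp_train(X[tr, , drop = FALSE], y[tr], gp$hidden, gp$l1,
                       gp$l2, gp$dropout, gp$epochs, grid$lr,
                       seed = child_seed(seed, paste0("cv", gi, "_", f)))
      pred <- mlp_predict(par, X[!tr, , drop = FALSE])
      sq_err <- c(sq_err, (y[!tr] - pred)^2)
    }
    sqrt(mean(sq_err))
  }, numeric(1))
  best <- which.min(cv_rmse)     # first minimum = grid-order tie-break
  gp <- grid$points[[best]]
  par <- mlp_train(X, y, gp$hidden, gp$l1, gp$l2, gp$dropout, gp$epochs,
                   grid$lr, seed = child_seed(seed, "refit"))
  structure(list(drug = if (is.null(drug)) "drug" else drug, chosen = gp,
                 cv_rmse = cv_rmse, best_rmse = cv_rmse[best], par = par,
                 genes = rownames(expr), mu = rowMeans(expr),
                 sdv = {s <- apply(expr, 1, stats::sd); s[s == 0] <- 1; s},
                 samples = common, lr = grid$lr),
            class = "lp_drug_model")
}

#' @export
print.lp_drug_model <- function(x, ...) {
  cat(sprintf("Drug-response model for %s: %d genes, %d samples\n",
              x$drug, length(x$genes), length(x$samples)))
  cat(sprintf("  chosen: hidden [%s], dropout %.2g, l1 %.2g, l2 %.2g, epochs %d\n",
              paste(x$chosen$hidden, collapse = ","), x$chosen$dropout,
              x$chosen$l1, x$chosen$l2, x$chosen$epochs))
  cat(sprintf("  cross-validated RMSE %.4f (over %d grid points)\n",
              x$best_rmse, length(x$cv_rmse)))
  invisible(x)
}

#' Predict AUC for new samples
#' @param object an `lp_drug_model`.
#' @param expr genes x samples matrix covering the model's genes.
#' @param ... unused.
#' @return named numeric predictions.
#' @export
predict.lp_drug_model <- function(object, expr, ...) {
  expr <- expr[object$genes, , drop = FALSE]
  X <- t((expr - object$mu) / object$sdv)
  stats::setNames(mlp_predict(object$par, X), colnames(expr))
}

#' Permutation feature importance
#'
#' `importance(g)` = mean over `n_repeats` of (RMSE with gene g's column
#' permuted minus baseline RMSE), floored at 0. One sample permutation is
#' drawn per repeat and applied to every gene, and first-layer
#' pre-activations are cached so each gene costs only a rank-one update.
#' Deterministic given `seed`.
#'
#' @param model fitted `lp_drug_model`.
#' @param expr,auc the data the model was fit on (or an evaluation set).
#' @param n_repeats permutation repeats per gene.
#' @param seed integer seed.
#' @return named numeric vector of importances (>= 0), one per model gene.
#' @export
feature_importance <- function(model, expr, auc, n_repeats = 5L, seed = 1L) {
  if (is.matrix(auc)) auc <- auc[, model$drug]
  common <- intersect(colnames(expr), names(auc))
  expr <- expr[model$genes, common, drop = FALSE]
  y <- unname(auc[common])
  X <- t((expr - model$mu) / model$sdv)
  n <- nrow(X)
  par <- model$par
  base_pred <- mlp_predict(par, X)
  base_rmse <- rmse(y, base_pred)
  Z1 <- sweep(X %*% par$W[[1]], 2, par$b[[1]], `+`)
  L <- length(par$W)
  offset <- if (is.null(par$y_center)) 0 else par$y_center
  forward_from_z1 <- function(Z) {
    if (L == 1) return(drop(Z) + offset)
    A <- relu(Z)
    for (l in 2:L) {
      Z <- sweep(A %*% par$W[[l]], 2, par$b[[l]], `+`)
      if (l < L) A <- relu(Z)
    }
    drop(Z) + offset
  }
  set.seed(as.integer(seed))
  imp <- matrix(0, nrow = length(model$genes), ncol = n_repeats,
                dimnames = list(model$genes, NULL))
  for (r in seq_len(n_repeats)) {
    perm <- sample.int(n)
    for (gi in seq_along(model$genes)) {
      dx <- X[perm, gi] - X[, gi]
      Zg <- Z1 + outer(dx, par$W[[1]][gi, ])
      imp[gi, r] <- rmse(y, forward_from_z1(Zg)) - base_rmse
    }
  }
  pmax(rowMeans(imp), 0)
}

#' Extract a top-K drug gene signature from importances
#'
#' @param importances named numeric vector (gene -> importance).
#' @param K signature size (default 100); if larger than the number of
#'   genes, all genes are returned. Ties are broken by gene symbol
#'   (lexicographically smaller first).
#' @param drug optional drug label.
#' @return data.frame classed `lp_signature`: `rank`, `gene`,
#'   `importance` (sorted descending).
#' @export
extract_signature <- function(importances, K = 100L, drug = NULL) {
  if (K <= 0) stop("K must be positive")
  if (is.null(names(importances))) stop("importances must be named by gene")
  ord <- order(-importances, names(importances))
  k <- min(K, length(importances))
  sel <- ord[seq_len(k)]
  out <- data.frame(rank = seq_len(k), gene = names(importances)[sel],
                    importance = unname(importances[sel]),
                    stringsAsFactors = FALSE)
  if (!is.null(drug)) out$drug <- drug
  class(out) <- c("lp_signature", "data.frame")
  out
}
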