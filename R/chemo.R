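# Chemometrics on the common-peak matrix: preprocessing, PCA, OPLS-DA
# (orthogonal projections to latent structures discriminant analysis),
# VIP, S-plot, label-permutation validation and marker selection.

#' Column-wise scaling of a peak table
#'
#' @param x A [peak_table()] or numeric matrix.
#' @param scaling `"autoscale"` (centre, unit variance; the chemometric
#'   default), `"center"`, or `"pareto"` (centre, divide by sqrt(sd)).
#' @return Scaled matrix with attributes `center`, `scale` and
#'   `scaling`, so the transformation can be re-applied or inverted.
#' @export
preprocess <- function(x, scaling = c("autoscale", "center", "pareto")) {
  scaling <- match.arg(scaling)
  X <- if (inherits(x, "peak_table")) x$areas else as.matrix(x)
  if (anyNA(X)) stop("matrix has missing cells", call. = FALSE)
  ctr <- colMeans(X)
  sds <- apply(X, 2L, stats::sd)
  scl <- switch(scaling,
                autoscale = sds,
                center = rep(1, ncol(X)),
                pareto = sqrt(sds))
  if (scaling != "center" && any(sds == 0)) {
    bad <- colnames(X)[sds == 0]
    stop("zero-variance column(s) under ", scaling, " scaling: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  attr(out, "scaling") <- scaling
  out
}

#' Apply stored preprocessing parameters to new data
#'
#' @param x New matrix with the same columns.
#' @param params A matrix returned by [preprocess()] (its attributes are
#'   used).
#' @return Scaled matrix.
#' @export
apply_preprocess <- function(x, params) {
  sweep(sweep(as.matrix(x), 2L, attr(params, "center")), 2L,
        attr(params, "scale"), "/")
}

.new_latent_model <- function(...) {
  structure(list(...), class = "latent_model")
}

#' @export
print.latent_model <- function(x, ...) {
  if (x$kind == "pca") {
    cat(sprintf("<latent_model: pca> %d components, R2X(cum) = %.3f\n",
                ncol(x$scores), x$R2X_cum))
  } else {
    cat(sprintf(
      "<latent_model: oplsda> 1 predictive + %d orthogonal, R2X = %.3f, R2Y = %.3f, Q2 = %.3f\n",
      x$n_orthogonal, x$R2X_cum, x$R2Y, x$Q2))
  }
  invisible(x)
}

#' Principal component analysis by singular value decomposition
#'
#' @param X Preprocessed matrix (see [preprocess()]; PCA itself does no
#'   scaling beyond what it is given).
#' @param n_components Number of components, at most `min(n - 1, p)` and
#'   the matrix rank.
#' @return A `latent_model` with `scores`, `loadings`, per-component
#'   explained variance fractions (`explained`), their cumulative sum
#'   `R2X_cum` and the 95% Hotelling T-squared ellipse semi-axes for the
#'   first two components.
#' @export
pca_fit <- function(X, n_components = 2) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_components > min(n - 1L, ncol(X))) {
    stop("n_components exceeds min(rows - 1, cols)", call. = FALSE)
  }
  sv <- svd(X)
  rank <- sum(sv$d > sv$d[1] * 1e-12)
  if (n_components > rank) {
    stop("n_components exceeds the matrix rank (", rank, ")",
         call. = FALSE)
  }
  a <- seq_len(n_components)
  scores <- sv$u[, a, drop = FALSE] %*% diag(sv$d[a], n_components)
  loadings <- sv$v[, a, drop = FALSE]
  rownames(scores) <- rownames(X)
  rownames(loadings) <- colnames(X)
  colnames(scores) <- colnames(loadings) <- paste0("PC", a)
  explained <- sv$d[a]^2 / sum(sv$d^2)
  # 95% Hotelling T2 ellipse for the first two score dimensions
  ell <- if (n_components >= 2L && n > 2L) {
    t2 <- 2 * (n - 1) / (n - 2) * stats::qf(0.95, 2, n - 2)
    sqrt(t2 * apply(scores[, 1:2, drop = FALSE], 2L, stats::var))
  } else {
    NULL
  }
  .new_latent_model(kind = "pca", scores = scores, loadings = loadings,
                    explained = explained, R2X_cum = sum(explained),
                    hotelling_95 = ell)
}

# code a two-class label vector as +1 / -1 (first sorted level is +1)
.code_y <- function(y) {
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2L) {
    stop("exactly two classes required, got ", length(lev), call. = FALSE)
  }
  counts <- table(as.character(y))
  if (any(counts < 3L)) {
    stop("each class needs at least 3 samples", call. = FALSE)
  }
  coded <- ifelse(as.character(y) == lev[1], 1, -1)
  list(coded = coded, levels = stats::setNames(c(1, -1), lev))
}

# single OPLS fit on already-scaled X and centred y; no validation here
.opls_core <- function(X, y, n_orthogonal) {
  p <- ncol(X)
  W_o <- matrix(0, p, max(n_orthogonal, 1L))[, seq_len(n_orthogonal),
                                             drop = FALSE]
  P_o <- W_o
  T_o <- matrix(0, nrow(X), n_orthogonal)
  Xd <- X
  if (n_orthogonal > 0L) {
    for (a in seq_len(n_orthogonal)) {
      w <- drop(crossprod(Xd, y))
      w <- w / sqrt(sum(w^2))
      t <- drop(Xd %*% w)
      pl <- drop(crossprod(Xd, t)) / sum(t^2)
      w_o <- pl - sum(w * pl) * w
      nw <- sqrt(sum(w_o^2))
      if (nw < 1e-12) {
        # no orthogonal variation left; keep zero component
        break
      }
      w_o <- w_o / nw
      t_o <- drop(Xd %*% w_o)
      p_o <- drop(crossprod(Xd, t_o)) / sum(t_o^2)
      W_o[, a] <- w_o
      P_o[, a] <- p_o
      T_o[, a] <- t_o
      Xd <- Xd - tcrossprod(t_o, p_o)
    }
  }
  w <- drop(crossprod(Xd, y))
  w <- w / sqrt(sum(w^2))
  t <- drop(Xd %*% w)
  pl <- drop(crossprod(Xd, t)) / sum(t^2)
  cc <- sum(t * y) / sum(t^2)
  list(w = w, t = t, p = pl, c = cc, W_o = W_o, P_o = P_o, T_o = T_o)
}

# predict centred-y response for new scaled rows
.opls_predict <- function(fit, Xnew) {
  Xnew <- as.matrix(Xnew)
  if (ncol(fit$W_o) > 0L) {
    for (a in seq_len(ncol(fit$W_o))) {
      if (all(fit$W_o[, a] == 0)) next
      t_o <- drop(Xnew %*% fit$W_o[, a])
      Xnew <- Xnew - tcrossprod(t_o, fit$P_o[, a])
    }
  }
  drop(Xnew %*% fit$w) * fit$c
}

# deterministic stratified fold assignment (SIMCA-style 1..k cycling
# within each class)
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- ((seq_along(idx) - 1L) %% k) + 1L
  }
  fold
}

#' Fit an OPLS-DA model
#'
#' One predictive component plus `n_orthogonal` orthogonal components by
#' the orthogonal-projections-to-latent-structures algorithm (NIPALS
#' PLS1 weight vector, orthogonal variation deflated before the
#' predictive fit). The class vector is coded +1/-1 (alphabetically
#' first level +1) and centred. R2X and R2Y come from fitted sums of
#' squares; Q2 = 1 - PRESS/TSS by stratified k-fold cross-validation
#' with deterministic fold cycling, so repeated fits are identical.
#' With `n_orthogonal = 0` the model is exactly a one-component PLS1.
#'
#' @param X Preprocessed matrix (rows = samples).
#' @param y Two-class label vector (>= 3 samples per class).
#' @param n_orthogonal Number of orthogonal components (default 1).
#' @param cv_folds Cross-validation folds (default 7).
#' @return A `latent_model` with predictive scores/weights/loadings,
#'   orthogonal counterparts, `R2X` (per component), `R2X_cum`, `R2Y`,
#'   `Q2`, per-peak `vip` and the class coding.
#' @export
oplsda <- function(X, y, n_orthogonal = 1, cv_folds = 7) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), n_orthogonal >= 0, cv_folds >= 2)
  cd <- .code_y(y)
  yc <- cd$coded - mean(cd$coded)
  if (sum(yc^2) == 0) stop("degenerate class vector", call. = FALSE)
  fit <- .opls_core(X, yc, n_orthogonal)
  ssx <- sum(X^2)
  r2x_pred <- sum(fit$t^2) * sum(fit$p^2) / ssx
  r2x_orth <- if (ncol(fit$T_o) > 0L) {
    vapply(seq_len(ncol(fit$T_o)), function(a) {
      sum(fit$T_o[, a]^2) * sum(fit$P_o[, a]^2) / ssx
    }, numeric(1))
  } else {
    numeric(0)
  }
  y_hat <- fit$t * fit$c
  r2y <- 1 - sum((yc - y_hat)^2) / sum(yc^2)
  # cross-validated predictive ability
  folds <- .stratified_folds(cd$coded, cv_folds)
  press <- 0
  for (k in sort(unique(folds))) {
    tr <- folds != k
    if (length(unique(cd$coded[tr])) < 2L) {
      stop("cross-validation fold with a single class", call. = FALSE)
    }
    ytr <- cd$coded[tr] - mean(cd$coded[tr])
    f <- .opls_core(X[tr, , drop = FALSE], ytr, n_orthogonal)
    pred <- .opls_predict(f, X[!tr, , drop = FALSE]) + mean(cd$coded[tr])
    press <- press + sum((cd$coded[!tr] - pred)^2)
  }
  q2 <- 1 - press / sum(yc^2)
  p <- ncol(X)
  vip_vals <- sqrt(p) * abs(fit$w)
  names(vip_vals) <- colnames(X)
  scores <- cbind(predictive = fit$t)
  rownames(scores) <- rownames(X)
  .new_latent_model(kind = "oplsda", scores = scores,
                    scores_orth = fit$T_o, weights = fit$w,
                    loadings = fit$p, weights_orth = fit$W_o,
                    loadings_orth = fit$P_o, c = fit$c,
                    n_orthogonal = n_orthogonal,
                    R2X = c(predictive = r2x_pred, orthogonal = r2x_orth),
                    R2X_cum = r2x_pred + sum(r2x_orth),
                    R2Y = r2y, Q2 = q2, vip = vip_vals,
                    y = y, y_coded = cd$coded, class_coding = cd$levels,
                    cv_folds = cv_folds)
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(p * sum_a w_ja^2 SSY_a / sum_a SSY_a)` over the
#' predictive component(s); with one predictive component this is
#' `sqrt(p) * |w_j|`, and the mean of `VIP^2` is exactly 1.
#'
#' @param model An OPLS-DA `latent_model`.
#' @return Named per-peak VIP vector.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "latent_model"))
  if (model$kind != "oplsda") {
    stop("VIP is defined for OPLS-DA models", call. = FALSE)
  }
  if (all(model$weights == 0)) {
    stop("degenerate model: zero predictive weights", call. = FALSE)
  }
  model$vip
}

#' S-plot coordinates
#'
#' For every peak j, the covariance `cov_j = t'x_j/(N-1)` and
#' correlation `corr_j = cov_j/(sd(t) sd(x_j))` between the predictive
#' scores and the (scaled) peak vector. Discriminating peaks sit at the
#' extremes of both.
#'
#' @param model An OPLS-DA `latent_model`.
#' @param X The matrix the model was fitted on.
#' @return Data frame with `peak_id`, `covariance`, `correlation`;
#'   zero-variance peaks get `NA` correlation.
#' @export
s_plot <- function(model, X) {
  stopifnot(inherits(model, "latent_model"), model$kind == "oplsda")
  X <- as.matrix(X)
  t <- model$scores[, "predictive"]
  n <- nrow(X)
  cv <- drop(crossprod(X, t - mean(t))) / (n - 1)
  sds <- apply(X, 2L, stats::sd)
  cr <- ifelse(sds > 0, cv / (stats::sd(t) * sds), NA_real_)
  if (any(sds == 0)) {
    warning("zero-variance peak(s): correlation undefined", call. = FALSE)
  }
  data.frame(peak_id = colnames(X) %||% seq_len(ncol(X)),
             covariance = cv, correlation = cr,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Label-permutation validation of an OPLS-DA model
#'
#' Refits the model on `n_perm` random permutations of the class labels
#' and regresses the permuted R2Y and Q2 on the absolute correlation
#' between permuted and original labels (including the unpermuted point
#' at correlation 1). The regression intercepts estimate the R2/Q2 a
#' label-free model would achieve; an intercept well below the original
#' Q2 (and all permuted Q2 below the original) indicates the model is
#' not overfitted.
#'
#' @param X Preprocessed matrix.
#' @param y Two-class labels.
#' @param n_perm Number of permutations (>= 20, default 200).
#' @param seed Integer seed (permutation order is fully reproducible).
#' @param n_orthogonal,cv_folds Passed to [oplsda()].
#' @return List with `r2_intercept`, `q2_intercept`, the `original`
#'   (correlation 1) point and a `permutations` data frame
#'   (`correlation`, `R2Y`, `Q2`).
#' @export
permutation_test <- function(X, y, n_perm = 200, seed = 0,
                             n_orthogonal = 1, cv_folds = 7) {
  stopifnot(n_perm >= 20)
  original <- oplsda(X, y, n_orthogonal, cv_folds)
  set.seed(as.integer(seed))
  y0 <- original$y_coded
  rows <- vector("list", n_perm)
  for (i in seq_len(n_perm)) {
    perm <- sample(length(y0))
    yp <- y[perm]
    m <- oplsda(X, yp, n_orthogonal, cv_folds)
    rows[[i]] <- data.frame(correlation = abs(stats::cor(y0, y0[perm])),
                            R2Y = m$R2Y, Q2 = m$Q2)
  }
  perms <- do.call(rbind, rows)
  all_pts <- rbind(perms,
                   data.frame(correlation = 1, R2Y = original$R2Y,
                              Q2 = original$Q2))
  r2_fit <- stats::lm(R2Y ~ correlation, data = all_pts)
  q2_fit <- stats::lm(Q2 ~ correlation, data = all_pts)
  list(r2_intercept = unname(stats::coef(r2_fit)[1]),
       q2_intercept = unname(stats::coef(q2_fit)[1]),
       original = list(R2Y = original$R2Y, Q2 = original$Q2),
       permutations = perms)
}

#' Select region markers by VIP and Welch t-test
#'
#' A peak is a marker when its OPLS-DA VIP exceeds 1 and the two-sided
#' Welch t-test on the raw (unscaled) areas between the two regions
#' gives p < 0.05. p-values are reported raw by default, matching the
#' usual chemometric practice; Benjamini-Hochberg adjustment is
#' available.
#'
#' @param ptable A [peak_table()] with exactly two region labels.
#' @param model The OPLS-DA `latent_model` fitted on the (preprocessed)
#'   table.
#' @param vip_threshold VIP cut-off (default 1).
#' @param alpha Significance level (default 0.05).
#' @param adjust Apply Benjamini-Hochberg correction to the p-values
#'   before thresholding (default `FALSE`).
#' @return Data frame sorted by VIP (descending): `peak_id`, `vip`,
#'   `p_value`, one mean column per region, `selected`.
#' @export
select_markers <- function(ptable, model, vip_threshold = 1,
                           alpha = 0.05, adjust = FALSE) {
  stopifnot(inherits(ptable, "peak_table"),
            inherits(model, "latent_model"), model$kind == "oplsda")
  regions <- unique(ptable$regions)
  if (length(regions) != 2L || anyNA(regions)) {
    stop("peak table must carry exactly two region labels", call. = FALSE)
  }
  if (any(table(ptable$regions) < 2L)) {
    stop("each region needs at least 2 batches", call. = FALSE)
  }
  v <- vip(model)
  if (!identical(sort(names(v)), sort(ptable$peak_ids))) {
    stop("model variables do not match the peak table columns",
         call. = FALSE)
  }
  g1 <- ptable$areas[ptable$regions == regions[1], , drop = FALSE]
  g2 <- ptable$areas[ptable$regions == regions[2], , drop = FALSE]
  pvals <- vapply(ptable$peak_ids, function(p) {
    stats::t.test(g1[, p], g2[, p])$p.value
  }, numeric(1))
  p_use <- if (adjust) stats::p.adjust(pvals, "BH") else pvals
  out <- data.frame(peak_id = ptable$peak_ids,
                    vip = unname(v[ptable$peak_ids]),
                    p_value = unname(p_use),
                    mean1 = colMeans(g1), mean2 = colMeans(g2),
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[names(out) == "mean1"] <- paste0("mean_", regions[1])
  names(out)[names(out) == "mean2"] <- paste0("mean_", regions[2])
  out$selected <- out$vip > vip_threshold & out$p_value < alpha
  out[order(-out$vip), , drop = FALSE]
}
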