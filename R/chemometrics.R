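# Chemometrics on the common-peak area matrix: scaling, PCA with
# cross-validated Q2, hierarchical clustering with silhouette-selected k,
# OPLS-DA with VIP scores and permutation validation.

#' Column scaling for chemometric models
#'
#' Applies one of the standard column transforms: `center` (mean only),
#' `uv` (unit variance: mean 0, sd 1), `pareto` (mean 0, divided by the
#' square root of the sd), or `none`. The transform is invertible via
#' [unscale()].
#'
#' @param x numeric matrix, samples x variables, >= 2 rows, no missing
#'   values.
#' @param scaling one of `"uv"`, `"center"`, `"pareto"`, `"none"`.
#' @return object of class `scaled_matrix`: list with `values`, `center`,
#'   `scale`, `scaling`.
#' @export
preprocess <- function(x, scaling = c("uv", "center", "pareto", "none")) {
  scaling <- match.arg(scaling)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("at least 2 rows required")
  if (anyNA(x)) stop("missing values are not handled here")
  ctr <- if (scaling == "none") rep(0, ncol(x)) else colMeans(x)
  sds <- apply(x, 2, stats::sd)
  scl <- switch(scaling,
                uv = sds,
                pareto = sqrt(sds),
                center = rep(1, ncol(x)),
                none = rep(1, ncol(x)))
  if (scaling %in% c("uv", "pareto")) {
    zero <- which(sds <= .Machine$double.eps * 100)
    if (length(zero))
      stop("zero-variance column(s) under ", scaling, " scaling: ",
           paste(colnames(x)[zero] %||% zero, collapse = ", "))
  }
  values <- sweep(sweep(x, 2, ctr, `-`), 2, scl, `/`)
  structure(list(values = values, center = ctr, scale = scl,
                 scaling = scaling),
            class = "scaled_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Invert a [preprocess()] transform
#' @param scaled a `scaled_matrix`.
#' @param values matrix in the scaled space; default the stored values.
#' @return matrix on the original scale.
#' @export
unscale <- function(scaled, values = scaled$values) {
  sweep(sweep(values, 2, scaled$scale, `*`), 2, scaled$center, `+`)
}

as_scaled <- function(x) {
  if (inherits(x, "scaled_matrix")) x else preprocess(x, "none")
}

#' Principal component analysis with cross-validated Q2
#'
#' SVD-based PCA of the scaled matrix. Explained-variance fractions are
#' `d_i^2 / sum(d^2)`; the cumulative predictive fraction Q2 is estimated by
#' row-wise k-fold cross-validation (refit on the training rows, reconstruct
#' held-out rows from their projection onto the training loadings) — an
#' approximation to vendor element-wise schemes, and labelled as such.
#'
#' @param scaled a `scaled_matrix` (or plain matrix, used as-is).
#' @param k number of components; `k <= min(nrow - 1, ncol)`.
#' @param nfold folds for Q2 (default 7, round-robin by row order).
#' @return object of class `pca_result`: `scores` (n x k), `loadings`
#'   (p x k, orthonormal columns), `r2` (per component), `r2cum`, `q2`.
#' @export
pca_fit <- function(scaled, k = 2, nfold = 7) {
  scaled <- as_scaled(scaled)
  x <- scaled$values
  n <- nrow(x); p <- ncol(x)
  if (k > min(n - 1, p)) stop("k too large: need k <= min(nrow-1, ncol)")
  sv <- svd(x)
  ev <- sv$d^2 / sum(sv$d^2)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  rownames(scores) <- rownames(x)
  rownames(loadings) <- colnames(x)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  nfold <- min(nfold, n)
  fold <- (seq_len(n) - 1L) %% nfold + 1L
  press <- 0
  for (f in seq_len(nfold)) {
    tr <- fold != f
    if (sum(tr) <= k) next
    svt <- svd(x[tr, , drop = FALSE])
    v <- svt$v[, seq_len(k), drop = FALSE]
    xe <- x[!tr, , drop = FALSE]
    press <- press + sum((xe - xe %*% v %*% t(v))^2)
  }
  q2 <- 1 - press / sum(x^2)
  structure(list(scores = scores, loadings = loadings,
                 r2 = ev[seq_len(k)], r2cum = cumsum(ev)[seq_len(k)],
                 eigenfractions = ev, q2 = q2, k = k,
                 scaling = scaled$scaling),
            class = "pca_result")
}

# mean silhouette width for labels on a full distance matrix
silhouette_mean <- function(labels, dmat) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- mean(dmat[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g)
      mean(dmat[i, labels == g]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Hierarchical cluster analysis on squared Euclidean distances
#'
#' Agglomerative clustering (Ward by default; average linkage by flag) of
#' the scaled sample matrix using squared Euclidean distances. The number of
#' clusters is either given or selected by maximal mean silhouette width
#' over `k_range`; a leaf-ordered matrix is returned for heatmap export.
#'
#' @param scaled a `scaled_matrix` or matrix.
#' @param k number of clusters, or NULL for silhouette selection.
#' @param linkage `"ward"` (Ward on squared Euclidean distances) or
#'   `"average"`.
#' @param k_range candidate k values when `k` is NULL (default 2:6).
#' @return object of class `hca_result`: `hclust` (merge tree), `k`,
#'   `labels` (named cluster labels), `silhouette` (data.frame over
#'   `k_range`), `heatmap` (scaled matrix, rows in leaf order).
#' @export
hca_fit <- function(scaled, k = NULL, linkage = c("ward", "average"),
                    k_range = 2:6) {
  linkage <- match.arg(linkage)
  scaled <- as_scaled(scaled)
  x <- scaled$values
  n <- nrow(x)
  if (n < 2) stop("at least 2 rows required")
  if (!is.null(k) && k > n) stop("k cannot exceed the number of samples")
  d2 <- stats::dist(x)^2
  hc <- stats::hclust(d2, method = if (linkage == "ward") "ward.D"
                      else "average")
  dmat <- as.matrix(d2)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  sil <- data.frame(k = k_range,
                    width = vapply(k_range, function(kk)
                      silhouette_mean(stats::cutree(hc, kk), dmat),
                      numeric(1)))
  if (is.null(k))
    k <- if (nrow(sil)) sil$k[which.max(sil$width)] else 1L
  labels <- stats::cutree(hc, k)
  structure(list(hclust = hc, k = k, labels = labels, silhouette = sil,
                 heatmap = x[hc$order, , drop = FALSE], linkage = linkage),
            class = "hca_result")
}

#' Newick-like text serialization of an hclust tree
#' @param hc an `hclust` object.
#' @return single string, parenthesized with merge heights as branch
#'   lengths.
#' @export
hclust_to_newick <- function(hc) {
  lab <- hc$labels %||% as.character(seq_along(hc$order))
  rec <- function(i, parent_h) {
    if (i < 0) return(sprintf("%s:%.6g", lab[-i], parent_h))
    sprintf("(%s,%s):%.6g", rec(hc$merge[i, 1], hc$height[i]),
            rec(hc$merge[i, 2], hc$height[i]), parent_h - hc$height[i])
  }
  top <- nrow(hc$merge)
  paste0(sprintf("(%s,%s);", rec(hc$merge[top, 1], hc$height[top]),
                 rec(hc$merge[top, 2], hc$height[top])), "")
}

# ---- OPLS-DA ----

code_classes <- function(y) {
  f <- factor(y)
  if (nlevels(f) != 2) stop("y must have exactly 2 non-empty classes")
  num <- ifelse(as.integer(f) == 1L, -1, 1)
  list(y = num - mean(num), levels = levels(f), raw = num)
}

# one OPLS round: strip n_ortho orthogonal components, then one predictive
# component. X rows x cols, y centered numeric.
opls_core <- function(x, y, n_ortho) {
  wo_all <- po_all <- NULL
  to_all <- NULL
  xd <- x
  for (a in seq_len(n_ortho)) {
    w <- drop(crossprod(xd, y)); w <- w / sqrt(sum(w^2))
    tt <- drop(xd %*% w)
    p <- drop(crossprod(xd, tt)) / sum(tt^2)
    wo <- p - drop(crossprod(w, p)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break
    wo <- wo / nwo
    to <- drop(xd %*% wo)
    po <- drop(crossprod(xd, to)) / sum(to^2)
    xd <- xd - tcrossprod(to, po)
    wo_all <- cbind(wo_all, wo); po_all <- cbind(po_all, po)
    to_all <- cbind(to_all, to)
  }
  w <- drop(crossprod(xd, y)); w <- w / sqrt(sum(w^2))
  tt <- drop(xd %*% w)
  p <- drop(crossprod(xd, tt)) / sum(tt^2)
  cc <- sum(y * tt) / sum(tt^2)
  list(w = w, t = tt, p = p, c = cc, Wo = wo_all, Po = po_all,
       To = to_all, Xfiltered = xd)
}

opls_predict <- function(core, xnew) {
  if (!is.null(core$Wo)) {
    for (a in seq_len(ncol(core$Wo))) {
      to <- xnew %*% core$Wo[, a]
      xnew <- xnew - tcrossprod(to, core$Po[, a])
    }
  }
  drop(xnew %*% core$w) * core$c
}

#' Orthogonal partial least squares discriminant analysis
#'
#' Fits the standard OPLS sequence on a two-class response: `n_orthogonal`
#' y-orthogonal components are estimated and removed from X, then a single
#' predictive component is fitted on the filtered matrix. With
#' `n_orthogonal = 0` this reduces to one-component PLS. Q2 is estimated by
#' k-fold cross-validation with round-robin fold assignment by row order
#' (per-fold recentering of X and y).
#'
#' @param scaled a `scaled_matrix` or matrix (samples x variables).
#' @param y two-class vector (factor, character or numeric) of length
#'   `nrow`.
#' @param n_orthogonal number of orthogonal components (default 1).
#' @param nfold cross-validation folds (default 7).
#' @return object of class `oplsda_result`: predictive scores `t`, weights
#'   `w`, loadings `p`, y-loading `c`, orthogonal `To`/`Wo`/`Po`, fit
#'   indices `r2x`, `r2y`, `q2`, `vip` (one per variable), coded response
#'   `y`, `levels`.
#' @export
oplsda_fit <- function(scaled, y, n_orthogonal = 1, nfold = 7) {
  scaled <- as_scaled(scaled)
  x <- scaled$values
  if (length(y) != nrow(x)) stop("y must match rows of X")
  if (n_orthogonal < 0) stop("n_orthogonal must be >= 0")
  cls <- code_classes(y)
  yc <- cls$y
  if (sum(yc^2) == 0) stop("constant y rejected")
  core <- opls_core(x, yc, n_orthogonal)
  ssx <- sum(x^2)
  expl <- sum(core$t^2) * sum(core$p^2)
  if (!is.null(core$To))
    expl <- expl + sum(vapply(seq_len(ncol(core$To)), function(a)
      sum(core$To[, a]^2) * sum(core$Po[, a]^2), numeric(1)))
  r2x <- expl / ssx
  yhat <- core$t * core$c
  r2y <- 1 - sum((yc - yhat)^2) / sum(yc^2)
  n <- nrow(x)
  nfold <- min(nfold, n)
  fold <- (seq_len(n) - 1L) %% nfold + 1L
  press <- 0
  for (f in seq_len(nfold)) {
    tr <- fold != f
    if (length(unique(yc[tr])) < 2) next
    xm <- colMeans(x[tr, , drop = FALSE])
    ym <- mean(yc[tr])
    ctr <- sweep(x[tr, , drop = FALSE], 2, xm)
    cf <- opls_core(ctr, yc[tr] - ym, n_orthogonal)
    xe <- sweep(x[!tr, , drop = FALSE], 2, xm)
    press <- press + sum((yc[!tr] - (opls_predict(cf, xe) + ym))^2)
  }
  q2 <- 1 - press / sum(yc^2)
  # VIP over the predictive component(s); weights are unit-norm, so the
  # mean of VIP^2 is exactly 1
  p_ <- ncol(x)
  vip <- sqrt(p_ * core$w^2 / sum(core$w^2))
  names(vip) <- colnames(x)
  structure(list(w = core$w, t = core$t, p = core$p, c = core$c,
                 Wo = core$Wo, Po = core$Po, To = core$To,
                 r2x = r2x, r2y = r2y, q2 = q2, vip = vip,
                 y = yc, levels = cls$levels,
                 n_orthogonal = n_orthogonal, nfold = nfold),
            class = "oplsda_result")
}

#' Variable importance in projection
#'
#' VIP over the predictive component(s):
#' \eqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{aj}/\|w_a\|)^2 / \sum_a SSY_a}}.
#' Satisfies `mean(vip^2) == 1`. Variables with VIP > 1 are the
#' conventional differential-marker candidates.
#'
#' @param model an `oplsda_result`.
#' @return named numeric vector, one VIP per variable, with attribute
#'   `flagged` (ids with VIP > 1, ranked by VIP).
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "oplsda_result"))
  v <- model$vip
  if (is.null(names(v))) names(v) <- as.character(seq_along(v))
  fl <- sort(v[v > 1], decreasing = TRUE)
  attr(v, "flagged") <- names(fl) %||% character(0)
  v
}

#' Permutation validation of an OPLS-DA model
#'
#' Refits the model on `n_perm` random permutations of the class labels,
#' recording R2Y, Q2 and the absolute correlation of the permuted with the
#' original response. Intercepts of the least-squares lines of R2Y and Q2
#' against |corr| (the vendor plot convention, original model included at
#' |corr| = 1) summarize overfitting: a Q2 intercept below zero, with the
#' original R2Y/Q2 exceeding at least `threshold` of the permuted values,
#' gives the verdict `"valid"`.
#'
#' @param scaled a `scaled_matrix` or matrix.
#' @param y two-class response.
#' @param n_perm number of permutations (>= 20; default 200).
#' @param seed integer seed.
#' @param n_orthogonal,nfold passed to [oplsda_fit()].
#' @param threshold fraction of permuted values the original statistics must
#'   exceed (default 0.95).
#' @return object of class `permutation_record`: `record` (data.frame
#'   perm_id, corr, r2y, q2; perm_id 0 is the unpermuted model),
#'   `r2y_intercept`, `q2_intercept`, `verdict`, `n_perm`.
#' @export
permutation_test <- function(scaled, y, n_perm = 200, seed = 1,
                             n_orthogonal = 1, nfold = 7,
                             threshold = 0.95) {
  if (n_perm < 20) stop("n_perm must be >= 20")
  scaled <- as_scaled(scaled)
  n <- nrow(scaled$values)
  if (lgamma(n + 1) < log(n_perm))
    warning("fewer distinct permutations than n_perm exist; ",
            "permutations will repeat")
  orig <- oplsda_fit(scaled, y, n_orthogonal, nfold)
  yc <- orig$y
  rec <- data.frame(perm_id = 0L, corr = 1,
                    r2y = orig$r2y, q2 = orig$q2)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      yp <- sample(y)
      fit <- tryCatch(oplsda_fit(scaled, yp, n_orthogonal, nfold),
                      error = function(e) NULL)
      if (is.null(fit)) next
      rec <- rbind(rec, data.frame(
        perm_id = b, corr = abs(stats::cor(fit$y, yc)),
        r2y = fit$r2y, q2 = fit$q2))
    }
    r2fit <- stats::lm(r2y ~ corr, data = rec)
    q2fit <- stats::lm(q2 ~ corr, data = rec)
    perm <- rec[rec$perm_id > 0, ]
    verdict <- if (stats::coef(q2fit)[1] < 0 &&
                   mean(orig$r2y > perm$r2y) >= threshold &&
                   mean(orig$q2 > perm$q2) >= threshold) "valid"
      else "suspect"
    structure(list(record = rec,
                   r2y_intercept = unname(stats::coef(r2fit)[1]),
                   q2_intercept = unname(stats::coef(q2fit)[1]),
                   verdict = verdict, n_perm = n_perm,
                   threshold = threshold),
              class = "permutation_record")
  })
}
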