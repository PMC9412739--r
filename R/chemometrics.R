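# run expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Two-group LC-MS feature table
#'
#' Samples-by-features intensity matrix with group labels, the unit of
#' all chemometric operations.
#'
#' @param intensities Numeric matrix, n samples x p features,
#'   nonnegative.
#' @param groups Group label per sample (factor or character); both
#'   groups need >= 2 samples for model fitting.
#' @param sample_ids,feature_ids Optional identifiers.
#' @return A `feature_table` list with elements `X`, `groups`,
#'   `sample_ids`, `feature_ids`.
#' @export
feature_table <- function(intensities, groups, sample_ids = NULL,
                          feature_ids = NULL) {
  X <- as.matrix(intensities)
  if (any(is.na(X))) stop("missing intensities not supported")
  groups <- as.factor(groups)
  if (length(groups) != nrow(X)) stop("one group label per sample required")
  if (any(is.na(groups))) stop("missing group labels")
  if (ncol(X) < 1) stop("need at least one feature")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(X)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(X)))
  }
  if (is.null(feature_ids)) {
    feature_ids <- colnames(X)
    if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(ncol(X)))
  }
  dimnames(X) <- list(sample_ids, feature_ids)
  structure(list(X = X, groups = groups, sample_ids = sample_ids,
                 feature_ids = feature_ids),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features; groups: %s\n",
              nrow(x$X), ncol(x$X),
              paste(sprintf("%s (n=%d)", levels(x$groups),
                            table(x$groups)), collapse = ", ")))
  invisible(x)
}

#' Read / write a feature table CSV
#'
#' Layout: first column sample id, second column group label, remaining
#' columns one feature each (named e.g. `"mz@rt"`).
#'
#' @param path CSV path.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("feature table needs sample, group, >=1 feature")
  feature_table(as.matrix(df[, -(1:2), drop = FALSE]), df[[2]],
                sample_ids = as.character(df[[1]]))
}

#' @rdname read_feature_table
#' @param table A `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(sample = table$sample_ids, group = table$groups,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(signif(table$X, 7)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Preprocess a feature table for multivariate modelling
#'
#' Optional log2 transform, column mean-centering, and scaling:
#' `"uv"` (unit variance, the SIMCA-style default), `"pareto"`
#' (divide by sqrt(sd)), or `"ctr"` (centering only). Zero-variance
#' features are dropped with a warning under uv/pareto scaling.
#'
#' @param table A `feature_table` or numeric matrix.
#' @param log_transform Apply `log2(x + 1)` first.
#' @param scaling One of `"uv"`, `"pareto"`, `"ctr"`.
#' @return List: `X` (processed matrix), `center`, `scale`, `dropped`
#'   (feature ids removed), `settings`.
#' @export
preprocess <- function(table, log_transform = FALSE,
                       scaling = c("uv", "pareto", "ctr")) {
  scaling <- match.arg(scaling)
  X <- if (inherits(table, "feature_table")) table$X else as.matrix(table)
  if (log_transform) X <- log2(X + 1)
  ctr <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  dropped <- character(0)
  if (scaling != "ctr") {
    zero <- sds < .Machine$double.eps^0.5
    if (any(zero)) {
      dropped <- colnames(X)[zero]
      warning("dropping ", sum(zero), " zero-variance feature(s): ",
              paste(utils::head(dropped, 5), collapse = ", "))
      X <- X[, !zero, drop = FALSE]
      ctr <- ctr[!zero]; sds <- sds[!zero]
    }
  }
  scl <- switch(scaling, uv = sds, pareto = sqrt(sds),
                ctr = rep(1, ncol(X)))
  Xp <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  list(X = Xp, center = ctr, scale = scl, dropped = dropped,
       settings = list(log_transform = log_transform, scaling = scaling))
}

# apply a stored preprocessing record to new data
apply_preprocess <- function(prep, X) {
  if (prep$settings$log_transform) X <- log2(X + 1)
  X <- X[, names(prep$center), drop = FALSE]
  sweep(sweep(X, 2, prep$center), 2, prep$scale, "/")
}

#' Principal component analysis with cross-validated Q2
#'
#' SVD-based PCA on the preprocessed matrix. R2X(cum) is the cumulative
#' explained fraction of total sum of squares; Q2 is estimated by k-fold
#' row-wise cross-validation (held-out samples projected onto training
#' loadings).
#'
#' @param table `feature_table` or matrix.
#' @param n_components Number of components (truncated with a warning if
#'   the rank is lower).
#' @param log_transform,scaling Passed to [preprocess()].
#' @param cv_folds Folds for Q2 (set 0 to skip).
#' @param seed Seed for fold assignment.
#' @return List: `scores`, `loadings` (orthonormal columns),
#'   `explained` (per-component R2X), `r2x_cum`, `q2`, `prep`.
#' @export
pca <- function(table, n_components = 2, log_transform = FALSE,
                scaling = c("uv", "pareto", "ctr"), cv_folds = 7,
                seed = 1) {
  scaling <- match.arg(scaling)
  prep <- preprocess(table, log_transform, scaling)
  X <- prep$X
  maxc <- min(nrow(X) - 1L, ncol(X))
  if (n_components > maxc) {
    warning("n_components reduced to rank limit ", maxc)
    n_components <- maxc
  }
  sv <- svd(X, nu = n_components, nv = n_components)
  d <- sv$d[seq_len(n_components)]
  scores <- sv$u %*% diag(d, n_components)
  loadings <- sv$v
  rownames(scores) <- rownames(X)
  rownames(loadings) <- colnames(X)
  ssx <- sum(X^2)
  explained <- d^2 / ssx
  q2 <- NA_real_
  if (cv_folds >= 2) {
    n <- nrow(X)
    folds <- with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
    press <- 0
    for (f in unique(folds)) {
      tr <- X[folds != f, , drop = FALSE]
      te <- X[folds == f, , drop = FALSE]
      k <- min(n_components, nrow(tr) - 1L, ncol(tr))
      V <- svd(tr, nu = 0, nv = k)$v
      press <- press + sum((te - te %*% V %*% t(V))^2)
    }
    q2 <- 1 - press / ssx
  }
  list(scores = scores, loadings = loadings, explained = explained,
       r2x_cum = cumsum(explained), q2 = q2, prep = prep)
}

# stratified, seeded fold assignment: round-robin within each class
stratified_folds <- function(groups, k, seed) {
  folds <- integer(length(groups))
  with_seed(seed, {
    for (lv in levels(groups)) {
      idx <- which(groups == lv)
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# core O-PLS fit on a preprocessed matrix and centered y; Trygg & Wold
# orthogonal signal correction followed by a single predictive component
opls_core <- function(X, yc, n_orthogonal) {
  ssx <- sum(X^2)
  W_o <- NULL; P_o <- NULL; T_o <- NULL
  Xf <- X
  for (k in seq_len(n_orthogonal)) {
    w <- drop(crossprod(Xf, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- drop(Xf %*% w)
    p <- drop(crossprod(Xf, t)) / sum(t^2)
    wo <- p - sum(w * p) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10) break
    wo <- wo / nwo
    to <- drop(Xf %*% wo)
    po <- drop(crossprod(Xf, to)) / sum(to^2)
    Xf <- Xf - tcrossprod(to, po)
    W_o <- cbind(W_o, wo); P_o <- cbind(P_o, po); T_o <- cbind(T_o, to)
  }
  w <- drop(crossprod(Xf, yc))
  w <- w / sqrt(sum(w^2))
  t <- drop(Xf %*% w)
  p <- drop(crossprod(Xf, t)) / sum(t^2)
  q <- sum(yc * t) / sum(t^2)
  list(w = w, t = t, p = p, q = q, W_o = W_o, P_o = P_o, T_o = T_o,
       ssx = ssx)
}

# orthogonal-filter new preprocessed data and predict centered y
opls_predict_core <- function(fit, Xnew) {
  if (!is.null(fit$W_o)) {
    for (k in seq_len(ncol(fit$W_o))) {
      to <- drop(Xnew %*% fit$W_o[, k])
      Xnew <- Xnew - tcrossprod(to, fit$P_o[, k])
    }
  }
  drop(Xnew %*% fit$w) * fit$q
}

#' Fit an OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis for
#' a binary class vector: NIPALS-style orthogonal signal correction
#' (`n_orthogonal` components) followed by one predictive component.
#' R2X is the cumulative fraction of X sum of squares captured by all
#' components; R2Y the explained class variance; Q2 the k-fold
#' cross-validated predicted class variance with seeded, class-stratified
#' folds. Setting `n_orthogonal = 0` gives a plain one-component PLS-DA.
#'
#' @param table `feature_table` (or matrix, with `labels` supplied).
#' @param labels Binary labels; defaults to the table's groups.
#' @param n_orthogonal Number of orthogonal components (default 1).
#' @param log_transform,scaling Passed to [preprocess()]; unit-variance
#'   scaling is the general default, `scaling = "ctr"` is the documented
#'   choice for VIP-threshold marker screening.
#' @param cv_folds Cross-validation folds for Q2 (default 7).
#' @param seed Seed for fold assignment.
#' @return An `opls_model`: scores/weights/loadings for predictive
#'   (`t`, `w`, `p`, `q`) and orthogonal (`T_o`, `W_o`, `P_o`)
#'   components, `r2x`, `r2y`, `q2`, `vip`, `prep`, `groups`.
#' @export
fit_oplsda <- function(table, labels = NULL, n_orthogonal = 1,
                       log_transform = FALSE,
                       scaling = c("uv", "pareto", "ctr"),
                       cv_folds = 7, seed = 1) {
  scaling <- match.arg(scaling)
  if (inherits(table, "feature_table")) {
    if (is.null(labels)) labels <- table$groups
  }
  groups <- as.factor(labels)
  if (nlevels(groups) != 2) stop("OPLS-DA needs exactly two classes")
  if (any(table(groups) < 2)) stop("both classes need >= 2 samples")
  n <- length(groups)
  if (n < 4) stop("need at least 4 samples")
  prep <- preprocess(table, log_transform, scaling)
  X <- prep$X
  y <- as.numeric(groups == levels(groups)[1])
  yc <- y - mean(y)
  ssy <- sum(yc^2)

  fit <- opls_core(X, yc, n_orthogonal)
  resid <- yc - fit$t * fit$q
  r2y <- 1 - sum(resid^2) / ssy
  comp_ss <- sum(fit$t^2) * sum(fit$p^2)
  if (!is.null(fit$T_o)) {
    for (k in seq_len(ncol(fit$T_o))) {
      comp_ss <- comp_ss + sum(fit$T_o[, k]^2) * sum(fit$P_o[, k]^2)
    }
  }
  r2x <- comp_ss / fit$ssx

  q2 <- NA_real_
  if (cv_folds >= 2) {
    folds <- stratified_folds(groups, cv_folds, seed)
    press <- 0
    for (f in sort(unique(folds))) {
      tr <- folds != f
      if (length(unique(groups[tr])) < 2) next
      prep_tr <- preprocess(
        if (inherits(table, "feature_table")) table$X[tr, , drop = FALSE]
        else as.matrix(table)[tr, , drop = FALSE],
        log_transform, scaling)
      ytr <- yc[tr] - mean(yc[tr])
      fit_tr <- opls_core(prep_tr$X, ytr, n_orthogonal)
      Xte <- apply_preprocess(
        prep_tr,
        if (inherits(table, "feature_table")) table$X[!tr, , drop = FALSE]
        else as.matrix(table)[!tr, , drop = FALSE])
      yhat <- opls_predict_core(fit_tr, Xte) + mean(yc[tr])
      press <- press + sum((yc[!tr] - yhat)^2)
    }
    q2 <- 1 - press / ssy
  }

  model <- structure(list(
    t = fit$t, w = fit$w, p = fit$p, q = fit$q,
    T_o = fit$T_o, W_o = fit$W_o, P_o = fit$P_o,
    r2x = r2x, r2y = r2y, q2 = q2,
    n_orthogonal = if (is.null(fit$T_o)) 0L else ncol(fit$T_o),
    prep = prep, groups = groups, y = y, seed = seed,
    cv_folds = cv_folds,
    feature_ids = colnames(X)), class = "opls_model")
  model$vip <- vip(model)
  model
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(paste0("<opls_model> 1 predictive + %d orthogonal components\n",
                     "  R2X = %.3f  R2Y = %.3f  Q2 = %.3f\n"),
              x$n_orthogonal, x$r2x, x$r2y, x$q2))
  invisible(x)
}

#' Variable importance in projection
#'
#' VIP_j = sqrt(p * sum_a w_ja^2 SSY_a / sum_a SSY_a) over the predictive
#' component(s); with weights normalized the squared VIPs average to 1.
#'
#' @param model An `opls_model`.
#' @return Named numeric vector of VIP scores.
#' @export
vip <- function(model) {
  if (!inherits(model, "opls_model")) stop("vip() needs a fitted opls_model")
  w <- model$w
  p <- length(w)
  v <- sqrt(p * w^2 / sum(w^2))
  names(v) <- model$feature_ids
  v
}

#' Permutation test for OPLS-DA model validity
#'
#' Refits the model under `n_permutations` random relabelings and
#' reports the permuted (R2Y, Q2) distribution, the empirical p-value
#' `(1 + #{Q2_perm >= Q2_obs}) / (n + 1)`, and the intercepts of the
#' R2Y and Q2 regressions on the absolute label correlation (the
#' SIMCA-style validation plot summary).
#'
#' @param table `feature_table`.
#' @param labels Optional labels (default table groups).
#' @param n_permutations Number of permutations (warning below 20).
#' @param seed RNG seed; permutation `i` uses `seed + i` for fold
#'   assignment, so the identity relabeling reproduces the original
#'   statistics exactly.
#' @inheritParams fit_oplsda
#' @return List: `r2y`, `q2` (observed), `perm` (data frame
#'   `correlation`, `r2y`, `q2`), `p_value`, `r2y_intercept`,
#'   `q2_intercept`.
#' @export
permutation_test <- function(table, labels = NULL, n_permutations = 200,
                             n_orthogonal = 1, log_transform = FALSE,
                             scaling = c("uv", "pareto", "ctr"),
                             cv_folds = 7, seed = 1) {
  scaling <- match.arg(scaling)
  if (n_permutations < 20) warning("fewer than 20 permutations")
  if (inherits(table, "feature_table") && is.null(labels)) {
    labels <- table$groups
  }
  groups <- as.factor(labels)
  obs <- fit_oplsda(table, groups, n_orthogonal, log_transform, scaling,
                    cv_folds, seed)
  y <- as.numeric(groups == levels(groups)[1])
  perms <- with_seed(seed, lapply(seq_len(n_permutations),
                                  function(i) sample(seq_along(y))))
  res <- lapply(seq_along(perms), function(i) {
    gp <- groups[perms[[i]]]
    m <- tryCatch(
      fit_oplsda(table, gp, n_orthogonal, log_transform, scaling,
                 cv_folds, seed + i),
      error = function(e) NULL)
    if (is.null(m)) return(c(NA_real_, NA_real_, NA_real_))
    yp <- as.numeric(gp == levels(groups)[1])
    c(abs(stats::cor(y, yp)), m$r2y, m$q2)
  })
  perm <- as.data.frame(do.call(rbind, res))
  names(perm) <- c("correlation", "r2y", "q2")
  perm <- perm[stats::complete.cases(perm), , drop = FALSE]
  p_value <- (1 + sum(perm$q2 >= obs$q2)) / (nrow(perm) + 1)
  # intercepts of the validation-plot regressions through the observed point
  fitline <- function(stat, obs_stat) {
    co <- stats::coef(stats::lm(c(perm[[stat]], obs_stat) ~
                                  c(perm$correlation, 1)))
    unname(co[1])
  }
  list(r2y = obs$r2y, q2 = obs$q2, perm = perm, p_value = p_value,
       r2y_intercept = fitline("r2y", obs$r2y),
       q2_intercept = fitline("q2", obs$q2))
}

#' Per-feature univariate tests
#'
#' Welch's t-test (Satterthwaite degrees of freedom) for two groups, or
#' one-way ANOVA with Tukey HSD post-hoc for two or more groups.
#'
#' @param table `feature_table`.
#' @param method `"welch_t"` or `"anova_tukey"`.
#' @return For `welch_t`: data frame `feature`, `statistic`, `df`, `p`.
#'   For `anova_tukey`: data frame `feature`, `statistic` (F), `p`, plus
#'   attribute `"tukey"` — a list of pairwise p-value matrices.
#' @export
univariate <- function(table, method = c("welch_t", "anova_tukey")) {
  method <- match.arg(method)
  stopifnot(inherits(table, "feature_table"))
  g <- table$groups
  if (any(table(g) < 2)) stop("every group needs >= 2 samples")
  if (method == "welch_t") {
    if (nlevels(g) != 2) stop("welch_t needs exactly two groups")
    res <- apply(table$X, 2, function(x) {
      ht <- stats::t.test(x[g == levels(g)[1]], x[g == levels(g)[2]])
      c(ht$statistic, ht$parameter, ht$p.value)
    })
    data.frame(feature = table$feature_ids, statistic = res[1, ],
               df = res[2, ], p = res[3, ], row.names = NULL)
  } else {
    tukey <- vector("list", ncol(table$X))
    stat <- numeric(ncol(table$X)); pv <- numeric(ncol(table$X))
    for (j in seq_len(ncol(table$X))) {
      fit <- stats::aov(table$X[, j] ~ g)
      an <- summary(fit)[[1]]
      stat[j] <- an[["F value"]][1]; pv[j] <- an[["Pr(>F)"]][1]
      tukey[[j]] <- stats::TukeyHSD(fit)$g
    }
    out <- data.frame(feature = table$feature_ids, statistic = stat, p = pv,
                      row.names = NULL)
    names(tukey) <- table$feature_ids
    attr(out, "tukey") <- tukey
    out
  }
}

#' Signed percent change between group means
#'
#' `100 * (mean_case - mean_reference) / mean_reference` per feature; a
#' zero reference mean yields `Inf`/`-Inf` with `undefined = TRUE`.
#'
#' @param table `feature_table` with two groups.
#' @param reference Reference group label (denominator); default the
#'   second factor level.
#' @return Data frame: `feature`, the two group means, `percent_change`,
#'   `undefined`.
#' @export
percent_change <- function(table, reference = NULL) {
  stopifnot(inherits(table, "feature_table"), nlevels(table$groups) == 2)
  lv <- levels(table$groups)
  if (is.null(reference)) reference <- lv[2]
  if (!reference %in% lv) stop("unknown reference group: ", reference)
  case <- setdiff(lv, reference)
  m_case <- colMeans(table$X[table$groups == case, , drop = FALSE])
  m_ref <- colMeans(table$X[table$groups == reference, , drop = FALSE])
  pc <- 100 * (m_case - m_ref) / m_ref
  out <- data.frame(feature = table$feature_ids, row.names = NULL)
  out[[paste0("mean_", case)]] <- unname(m_case)
  out[[paste0("mean_", reference)]] <- unname(m_ref)
  out$percent_change <- unname(pc)
  out$undefined <- !is.finite(pc)
  out
}

#' Marker selection by VIP and p-value thresholds
#'
#' A feature is selected iff `VIP > vip_threshold` and `p < alpha`
#' (both strict, the conventional VIP > 2, p < 0.05 rule).
#'
#' @param model Fitted `opls_model` (source of the table is its
#'   preprocessing record; pass `table` explicitly for group means).
#' @param pvalues Per-feature p-value vector aligned with the model's
#'   features (e.g. from [univariate()]).
#' @param table Optional `feature_table` for group means and percent
#'   change columns.
#' @param vip_threshold,alpha Selection thresholds.
#' @return Data frame: `feature`, `vip`, `p`, (optional means and
#'   percent change), `selected`.
#' @export
select_markers <- function(model, pvalues, table = NULL, vip_threshold = 2,
                           alpha = 0.05) {
  v <- vip(model)
  if (is.data.frame(pvalues)) pvalues <- stats::setNames(pvalues$p,
                                                         pvalues$feature)
  if (length(pvalues) != length(v)) {
    stop("length mismatch between VIP (", length(v), ") and p-values (",
         length(pvalues), ")")
  }
  if (!is.null(names(pvalues))) pvalues <- pvalues[names(v)]
  out <- data.frame(feature = names(v), vip = unname(v),
                    p = unname(pvalues), row.names = NULL)
  if (!is.null(table)) {
    pc <- percent_change(table)
    out <- merge(out, pc, by = "feature", sort = FALSE)
  }
  out$selected <- out$vip > vip_threshold & out$p < alpha
  out[order(-out$vip), , drop = FALSE]
}

#' Hierarchical cluster analysis for heatmap export
#'
#' Agglomerative clustering of samples and features with euclidean or
#' correlation (1 - r) distance and Ward/average/complete linkage;
#' returns the dendrograms and leaf orderings used to lay out a heatmap.
#'
#' @param table `feature_table` or matrix.
#' @param distance `"euclidean"` or `"correlation"`.
#' @param linkage `"ward"` (ward.D2), `"average"`, `"complete"`.
#' @param scale_features Autoscale features before clustering.
#' @return List: `samples` and `features`, each an `hclust`;
#'   `sample_order`, `feature_order`.
#' @export
hca <- function(table, distance = c("euclidean", "correlation"),
                linkage = c("ward", "average", "complete"),
                scale_features = TRUE) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  X <- if (inherits(table, "feature_table")) table$X else as.matrix(table)
  if (nrow(X) < 2 || ncol(X) < 2) stop("need >= 2 samples and >= 2 features")
  if (scale_features) {
    sds <- apply(X, 2, stats::sd)
    sds[sds == 0] <- 1
    X <- scale(X, scale = sds)
  }
  meth <- c(ward = "ward.D2", average = "average", complete = "complete")[linkage]
  dfun <- function(M) {
    if (distance == "euclidean") stats::dist(M)
    else stats::as.dist(1 - stats::cor(t(M)))
  }
  hs <- stats::hclust(dfun(X), method = meth)
  hf <- stats::hclust(dfun(t(X)), method = meth)
  list(samples = hs, features = hf,
       sample_order = hs$order, feature_order = hf$order)
}

#' Hotelling's T2 outlier flags for a score matrix
#'
#' Flags samples outside the (1 - alpha) T2 ellipse of a 2-component
#' score plot. Flagged samples are reported, never removed.
#'
#' @param scores n x 2 score matrix.
#' @param alpha Significance level (default 0.05, the 95% ellipse).
#' @return Logical vector, `TRUE` = outside the ellipse.
#' @export
hotelling_t2 <- function(scores, alpha = 0.05) {
  S <- as.matrix(scores)[, 1:2, drop = FALSE]
  n <- nrow(S)
  t2 <- rowSums(sweep(S, 2, colMeans(S))^2 %*%
                  diag(1 / apply(S, 2, stats::var)))
  crit <- 2 * (n - 1) / (n - 2) * stats::qf(1 - alpha, 2, n - 2)
  unname(t2 > crit)
}
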