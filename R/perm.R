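# Permutation-based linear-model inference.
#
# Collinearity between timing covariates is handled before model fitting by
# group-centring (subtracting group means) or residualization (keeping
# least-squares residuals of a covariate on earlier terms); VIF screening
# verifies the result. Significance of model terms is assessed by
# Freedman-Lane permutation of reduced-model residuals, with sequential
# (type-I) sums of squares in the order the terms appear in the formula.

#' Centre values within groups
#'
#' Subtracts from each value the mean of its group; per-group means of the
#' output are zero. Singleton groups are centred to zero.
#'
#' @param values numeric vector
#' @param groups vector of group labels, same length
#' @return centred numeric vector
#' @export
group_centre <- function(values, groups) {
  stopifnot(length(values) > 0, length(values) == length(groups))
  values - stats::ave(values, groups)
}

#' Residualize a variable on a set of predictors
#'
#' Returns least-squares residuals of `y` on `predictors` (with intercept);
#' the residuals are orthogonal to every predictor and to the intercept.
#'
#' @param y numeric response
#' @param predictors data frame, matrix or vector of predictors
#' @return numeric vector of residuals
#' @export
residualize <- function(y, predictors) {
  X <- stats::model.matrix(~ ., data = as.data.frame(predictors))
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("predictor matrix is rank deficient")
  qr.resid(qx, y)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing covariate `j` on the others.
#'
#' @param design data frame or matrix of two or more covariates
#' @return named numeric vector of VIFs
#' @export
vif <- function(design) {
  X <- as.matrix(as.data.frame(design))
  stopifnot(ncol(X) >= 2)
  vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 > 1 - 1e-10) stop("perfect collinearity involving covariate ", j)
    1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(colnames(X))
}

#' Permutation test for linear-model terms (Freedman-Lane)
#'
#' Fits `formula` by least squares and computes a sequential (type-I) F
#' statistic for each term in formula order. The null distribution of each
#' term's F is built by the Freedman-Lane scheme: residuals of the model
#' containing only the preceding terms are permuted, added back to that
#' model's fitted values, and the statistic recomputed. The p-value uses
#' the add-one convention `p = (1 + #(F* >= F_obs)) / (1 + n_perm)`, so the
#' smallest attainable p is `1 / (n_perm + 1)`.
#'
#' @param formula model formula; covariate transforms (centring,
#'   residualization) are applied by the caller beforehand
#' @param data data frame
#' @param n_perm number of permutations (default 10000)
#' @param seed integer seed for reproducibility
#' @return a `perm_lm` object: data frame `table` (term, df, F, p_perm,
#'   null mean/sd), the underlying `lm` `fit`, `n_perm`, `seed`
#' @export
permutation_lm <- function(formula, data, n_perm = 10000, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  mm <- stats::model.matrix(attr(mf, "terms"), mf)
  assign <- attr(mm, "assign")
  n <- nrow(mm); p <- ncol(mm)
  if (n < p + 2) stop("too few observations for the model")
  qx <- qr(mm)
  if (qx$rank < p) stop("design matrix is rank deficient")
  Q <- qr.Q(qx)
  term_labels <- attr(attr(mf, "terms"), "term.labels")
  n_terms <- length(term_labels)
  df_res <- n - p

  seq_F <- function(yy) {
    z <- crossprod(Q, yy)              # p x 1
    z2 <- z^2
    rss <- sum(yy^2) - sum(z2)
    vapply(seq_len(n_terms), function(j) {
      cols <- which(assign == j)
      (sum(z2[cols]) / length(cols)) / (rss / df_res)
    }, numeric(1))
  }
  F_obs <- seq_F(y)

  # fitted values / residuals of each reduced model (terms before j)
  z_full <- crossprod(Q, y)
  reduced <- lapply(seq_len(n_terms), function(j) {
    cols <- which(assign < j)
    fitted <- Q[, cols, drop = FALSE] %*% z_full[cols]
    list(fitted = as.numeric(fitted), resid = y - as.numeric(fitted))
  })

  set.seed(seed)
  exceed <- numeric(n_terms)
  null_sum <- numeric(n_terms); null_sumsq <- numeric(n_terms)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    for (j in seq_len(n_terms)) {
      y_star <- reduced[[j]]$fitted + reduced[[j]]$resid[idx]
      z <- crossprod(Q, y_star); z2 <- z^2
      rss <- sum(y_star^2) - sum(z2)
      cols <- which(assign == j)
      f_star <- (sum(z2[cols]) / length(cols)) / (rss / df_res)
      if (f_star >= F_obs[j]) exceed[j] <- exceed[j] + 1
      null_sum[j] <- null_sum[j] + f_star
      null_sumsq[j] <- null_sumsq[j] + f_star^2
    }
  }
  p_perm <- (1 + exceed) / (1 + n_perm)
  tab <- data.frame(
    term = term_labels,
    df = vapply(seq_len(n_terms), function(j) sum(assign == j), numeric(1)),
    df_res = df_res,
    F = F_obs,
    p_perm = p_perm,
    null_mean = null_sum / n_perm,
    null_sd = sqrt(pmax(0, null_sumsq / n_perm - (null_sum / n_perm)^2)))
  structure(list(table = tab, fit = stats::lm(formula, data),
                 n_perm = n_perm, seed = seed),
            class = "perm_lm")
}

#' @export
print.perm_lm <- function(x, ...) {
  cat(sprintf("Permutation linear model (%d permutations, seed %d)\n",
              x$n_perm, x$seed))
  print(x$table[, c("term", "df", "F", "p_perm")], row.names = FALSE)
  invisible(x)
}

#' Test whether a regression slope differs from one
#'
#' `t = (slope - 1) / se`, two-sided p from the t distribution. Used for
#' carry-over slopes where a slope of 1 means full transmission of a delay
#' to the next annual-cycle stage.
#'
#' @param slope estimated slope
#' @param se its standard error (> 0)
#' @param df residual degrees of freedom (>= 1)
#' @return list with `t` and `p`
#' @export
slope_vs_one_test <- function(slope, se, df) {
  if (se <= 0) stop("se must be positive")
  if (df < 1) stop("df must be >= 1")
  t <- (slope - 1) / se
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}
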