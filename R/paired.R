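# Paired (post- vs pre-breeding) comparisons of migration features.
#
# Each individual contributes exactly two observations, one per migration
# period. With two observations per individual a random-intercept +
# random-slope structure is not identifiable beyond a single paired
# covariance, so the model is a compound-symmetry (paired) linear mixed
# model fitted by maximum likelihood. The orthonormal within/between
# transform (pair difference and pair sum, each scaled by 1/sqrt(2)) turns
# the ML fit into a two-block heteroscedastic regression that can be
# iterated to convergence cheaply - important because the permutation test
# refits the model thousands of times.

#' Maximum-likelihood fit of a paired compound-symmetry model
#'
#' @param y response vector (2 rows per individual)
#' @param X model matrix (same rows)
#' @param id individual identifier (each level exactly twice)
#' @return list with `beta`, `sigma2_d`, `sigma2_s` (variances of the
#'   scaled pair difference and pair sum), `logLik`
#' @keywords internal
fit_paired_cs <- function(y, X, id, max_iter = 50, tol = 1e-8) {
  id <- as.character(id)
  split_idx <- split(seq_along(id), id)
  if (any(lengths(split_idx) != 2L))
    stop("every individual must contribute exactly two observations")
  i1 <- vapply(split_idx, `[`, integer(1), 1L)
  i2 <- vapply(split_idx, `[`, integer(1), 2L)
  s2 <- sqrt(2)
  yd <- (y[i2] - y[i1]) / s2
  ys <- (y[i2] + y[i1]) / s2
  Xd <- (X[i2, , drop = FALSE] - X[i1, , drop = FALSE]) / s2
  Xs <- (X[i2, , drop = FALSE] + X[i1, , drop = FALSE]) / s2
  Xall <- rbind(Xd, Xs)
  yall <- c(yd, ys)
  m <- length(yd)
  blk <- rep(c(1L, 2L), each = m)

  v <- c(1, 1)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    w <- 1 / v[blk]
    fit <- stats::lm.wfit(Xall, yall, w)
    res <- yall - Xall %*% fit$coefficients
    sse <- c(sum(res[blk == 1L]^2), sum(res[blk == 2L]^2))
    v <- pmax(sse / m, 1e-12)
    ll <- -0.5 * (2 * m * log(2 * pi) + m * log(v[1]) + m * log(v[2]) + 2 * m)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(beta = fit$coefficients, sigma2_d = v[1], sigma2_s = v[2], logLik = ll)
}

build_paired_design <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  mm <- stats::model.matrix(attr(mf, "terms"), mf)
  list(y = y, X = mm, assign = attr(mm, "assign"),
       terms = attr(attr(mf, "terms"), "term.labels"))
}

lrt_per_term <- function(y, X, assign, id, term_ids) {
  full <- fit_paired_cs(y, X, id)
  vapply(term_ids, function(j) {
    Xr <- X[, assign != j, drop = FALSE]
    red <- fit_paired_cs(y, Xr, id)
    lrt <- 2 * (full$logLik - red$logLik)
    # convergence noise below this is an exact tie at zero
    if (lrt < 1e-7) lrt <- 0
    lrt
  }, numeric(1))
}

#' Two-step paired permutation test for post/pre differences
#'
#' Tests fixed effects of a paired model (response measured once per
#' migration period per individual) with a permutation scheme that respects
#' the paired structure: first, post- and pre-breeding values are randomly
#' swapped within individuals; second, each individual's (possibly swapped)
#' value pair is randomly reassigned to a different individual, preserving
#' the correlated nature of the data. At each permutation the
#' likelihood-ratio statistic of every term (full model vs the model
#' without that term, both fitted by ML) is recomputed, and significance is
#' the rank of the observed LRT in the permutation distribution (add-one
#' convention).
#'
#' @param formula model formula; must involve the `period` column plus
#'   individual-level covariates
#' @param data data frame with one row per individual x period; must contain
#'   `individual` and `period` (`"post"`/`"pre"`) columns, complete pairs only
#' @param n_perm number of permutations (default 10000)
#' @param seed integer seed
#' @return a `perm_paired` object: data frame `table` (term, LRT, p_perm,
#'   null mean/sd), `n_perm`, `seed`, `n_individuals`
#' @export
paired_two_step_perm <- function(formula, data, n_perm = 10000, seed = 1L) {
  if (!all(c("individual", "period") %in% names(data)))
    stop("data must contain 'individual' and 'period' columns")
  tab <- table(data$individual)
  if (any(tab != 2L))
    stop("unpaired individuals present: ",
         paste(names(tab)[tab != 2L], collapse = ", "))
  data <- data[order(data$individual, data$period), , drop = FALSE]
  des <- build_paired_design(formula, data)
  term_ids <- seq_along(des$terms)
  id <- data$individual
  obs <- lrt_per_term(des$y, des$X, des$assign, id, term_ids)

  # value pairs per individual, in (post, pre) order
  ids <- unique(as.character(id))
  n_ind <- length(ids)
  idx <- split(seq_along(id), as.character(id))[ids]
  i_post <- vapply(idx, `[`, integer(1), 1L)
  i_pre <- vapply(idx, `[`, integer(1), 2L)

  set.seed(seed)
  exceed <- numeric(length(term_ids))
  null_sum <- numeric(length(term_ids)); null_sumsq <- numeric(length(term_ids))
  for (b in seq_len(n_perm)) {
    swap <- stats::runif(n_ind) < 0.5        # step 1: within-individual shuffle
    reassign <- sample.int(n_ind)            # step 2: across-individual shuffle
    y_star <- des$y
    src_post <- ifelse(swap[reassign], i_pre[reassign], i_post[reassign])
    src_pre <- ifelse(swap[reassign], i_post[reassign], i_pre[reassign])
    y_star[i_post] <- des$y[src_post]
    y_star[i_pre] <- des$y[src_pre]
    lrt_star <- lrt_per_term(y_star, des$X, des$assign, id, term_ids)
    exceed <- exceed + (lrt_star >= obs)
    null_sum <- null_sum + lrt_star
    null_sumsq <- null_sumsq + lrt_star^2
  }
  p_perm <- (1 + exceed) / (1 + n_perm)
  structure(list(
    table = data.frame(term = des$terms, LRT = obs, p_perm = p_perm,
                       null_mean = null_sum / n_perm,
                       null_sd = sqrt(pmax(0, null_sumsq / n_perm -
                                             (null_sum / n_perm)^2))),
    n_perm = n_perm, seed = seed, n_individuals = n_ind),
    class = "perm_paired")
}

#' @export
print.perm_paired <- function(x, ...) {
  cat(sprintf("Paired two-step permutation test (%d individuals, %d permutations)\n",
              x$n_individuals, x$n_perm))
  print(x$table[, c("term", "LRT", "p_perm")], row.names = FALSE)
  invisible(x)
}
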