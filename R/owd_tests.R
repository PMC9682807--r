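# Permutation tests on OWD matrices: route consistency within individuals
# and seasonal differences in route spread.

# Assemble a full route-by-route OWD lookup (2n x 2n, routes ordered
# post_1..post_n, pre_1..pre_n) from the three cohort matrices.
route_owd_lookup <- function(post_mat, pre_mat, cross_mat) {
  ids <- post_mat$ids
  if (!identical(sort(ids), sort(pre_mat$ids)) ||
      !identical(sort(ids), sort(cross_mat$ids)))
    stop("post, pre and cross matrices must cover the same individuals")
  n <- length(ids)
  O <- matrix(0, 2 * n, 2 * n)
  pos <- function(id, season)
    match(id, ids) + if (season == "pre") n else 0L
  fill <- function(mat) {
    for (r in seq_len(nrow(mat$pairs))) {
      p <- mat$pairs[r, ]
      i <- pos(p$id_a, p$season_a); j <- pos(p$id_b, p$season_b)
      O[i, j] <<- p$owd; O[j, i] <<- p$owd
    }
  }
  fill(post_mat); fill(pre_mat); fill(cross_mat)
  list(ids = ids, n = n, O = O)
}

mean_offdiag <- function(M) {
  n <- nrow(M)
  (sum(M) - sum(diag(M))) / (n * (n - 1))
}

#' Within- vs among-individual OWD permutation test
#'
#' Tests whether the mean within-individual OWD (each bird's post- vs
#' pre-breeding route) is smaller than the mean among-individual OWD
#' (post-route of one bird vs pre-route of another) - i.e. whether
#' individuals keep private migration corridors across seasons. The
#' statistic is `mean(within) - mean(among)`; the one-sided null (small
#' values extreme) is built by permuting which pre-route is assigned to
#' which individual and recomputing both means.
#'
#' @param cross_mat a cross-season [owd_matrix()]
#' @param n_perm number of permutations (default 10000)
#' @param seed integer seed
#' @return a `perm_test` list: `statistic`, `observed`, `p`, `n_perm`,
#'   `seed`, `null_mean`, `null_sd`, plus `within_mean`, `among_mean`
#' @export
owd_within_vs_among_test <- function(cross_mat, n_perm = 10000, seed = 1L) {
  ids <- cross_mat$ids
  n <- length(ids)
  if (n < 3) stop("need at least 3 complete individuals")
  M <- matrix(NA_real_, n, n)  # M[i, j] = OWD(post_i, pre_j)
  ia <- match(cross_mat$pairs$id_a, ids)
  jb <- match(cross_mat$pairs$id_b, ids)
  M[cbind(ia, jb)] <- cross_mat$pairs$owd
  obs <- mean(diag(M)) - mean_offdiag(M)

  set.seed(seed)
  total <- sum(M)
  stat_null <- vapply(seq_len(n_perm), function(b) {
    sigma <- sample.int(n)
    w <- mean(M[cbind(seq_len(n), sigma)])
    a <- (total - sum(M[cbind(seq_len(n), sigma)])) / (n * (n - 1))
    w - a
  }, numeric(1))
  p <- (1 + sum(stat_null <= obs)) / (1 + n_perm)
  structure(list(statistic = "mean(within) - mean(among) OWD",
                 observed = obs, p = p, n_perm = n_perm, seed = seed,
                 null_mean = mean(stat_null), null_sd = stats::sd(stat_null),
                 within_mean = mean(diag(M)), among_mean = mean_offdiag(M),
                 n = n),
            class = "perm_test")
}

#' Seasonal route-spread OWD permutation test
#'
#' Tests whether pre-breeding routes are more variable across individuals
#' than post-breeding routes: the statistic is the mean pairwise OWD among
#' pre-breeding routes minus the mean pairwise OWD among post-breeding
#' routes. The one-sided null (large values extreme) is built by a paired
#' label swap: each individual's post/pre route labels are independently
#' flipped and both means recomputed, which requires the cross-season OWD
#' values as well.
#'
#' @param post_mat,pre_mat within-season [owd_matrix()]s over the same
#'   individuals
#' @param cross_mat the cross-season [owd_matrix()] for the same individuals
#' @param n_perm number of permutations (default 10000)
#' @param seed integer seed
#' @return a `perm_test` list (see [owd_within_vs_among_test()]) with
#'   `post_mean` and `pre_mean`
#' @export
owd_season_spread_test <- function(post_mat, pre_mat, cross_mat,
                                   n_perm = 10000, seed = 1L) {
  lk <- route_owd_lookup(post_mat, pre_mat, cross_mat)
  n <- lk$n; O <- lk$O
  post_idx <- seq_len(n); pre_idx <- n + seq_len(n)
  obs <- mean_offdiag(O[pre_idx, pre_idx]) - mean_offdiag(O[post_idx, post_idx])

  set.seed(seed)
  stat_null <- vapply(seq_len(n_perm), function(b) {
    flip <- stats::runif(n) < 0.5
    po <- ifelse(flip, pre_idx, post_idx)
    pr <- ifelse(flip, post_idx, pre_idx)
    mean_offdiag(O[pr, pr]) - mean_offdiag(O[po, po])
  }, numeric(1))
  p <- (1 + sum(stat_null >= obs)) / (1 + n_perm)
  structure(list(statistic = "mean(pre) - mean(post) pairwise OWD",
                 observed = obs, p = p, n_perm = n_perm, seed = seed,
                 null_mean = mean(stat_null), null_sd = stats::sd(stat_null),
                 post_mean = mean_offdiag(O[post_idx, post_idx]),
                 pre_mean = mean_offdiag(O[pre_idx, pre_idx]),
                 n = n),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s\n  observed = %.4f, p = %.4g (%d permutations, n = %d)\n",
              x$statistic, x$observed, x$p, x$n_perm, x$n))
  invisible(x)
}
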