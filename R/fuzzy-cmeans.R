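#' Fuzzy c-means soft clustering of expression profiles
#'
#' Standard Bezdek fuzzy c-means with fuzzifier `m`: profiles are
#' standardized per feature (zero mean, unit variance) unless
#' `standardize = FALSE`, memberships are initialized from a seeded random
#' matrix with rows normalized to 1, and centroids/memberships alternate
#' until the objective J = sum_ik u_ik^m ||x_i - c_k||^2 improves by less
#' than `tol` or `max_iter` is reached. The objective sequence is
#' non-increasing by construction and is returned for inspection. A
#' feature sitting exactly on a centroid gets membership 1 there.
#'
#' @param x numeric matrix, features in rows.
#' @param c number of clusters (must not exceed the number of features).
#' @param m fuzzifier (> 1), default 2.
#' @param tol absolute convergence tolerance on the objective.
#' @param max_iter iteration cap.
#' @param seed RNG seed for the membership initialization.
#' @param standardize standardize rows before clustering.
#' @return list with `membership` (features x c, rows sum to 1),
#'   `centers`, `objective` (per-iteration values), `iterations`,
#'   `cluster` (top-membership assignment, ties to the lowest cluster
#'   index).
#' @export
fuzzy_cmeans <- function(x, c = 6L, m = 2, tol = 1e-8, max_iter = 200L,
                         seed = 1L, standardize = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (c > n) stop("more clusters (", c, ") than features (", n, ")")
  if (m <= 1) stop("fuzzifier m must exceed 1")
  if (standardize) {
    mu <- rowMeans(x)
    sdv <- apply(x, 1, stats::sd)
    sdv[sdv == 0] <- 1  # flat profiles stay flat at zero
    x <- (x - mu) / sdv
  }
  set.seed(seed)
  u <- matrix(stats::runif(n * c), n, c)
  u <- u / rowSums(u)
  obj <- numeric(0)
  for (it in seq_len(max_iter)) {
    um <- u^m
    centers <- t(um) %*% x / colSums(um)
    d2 <- outer(rowSums(x^2), rep(1, c)) - 2 * x %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    d2[d2 < 0] <- 0
    obj <- c(obj, sum(um * d2))
    exact <- d2 < 1e-12
    pw <- d2^(-1 / (m - 1))
    u_new <- pw / rowSums(pw)
    hit <- rowSums(exact) > 0
    if (any(hit)) {
      u_new[hit, ] <- 0
      for (i in which(hit)) u_new[i, which(exact[i, ])[1]] <- 1
    }
    if (it > 1 && abs(obj[it - 1] - obj[it]) < tol) { u <- u_new; break }
    u <- u_new
  }
  cl <- apply(u, 1, which.max)  # which.max takes the lowest index on ties
  rownames(u) <- rownames(x)
  list(membership = u, centers = centers, objective = obj,
       iterations = length(obj), cluster = cl)
}
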