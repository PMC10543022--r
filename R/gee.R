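## Gaussian generalized estimating equations with an exchangeable (or
## independence) working correlation and cluster-robust sandwich covariance.
## The exchangeable inverse V_i^{-1} = s [I - c_i J], s = 1/(sigma^2 (1-rho)),
## c_i = rho / (1 + (n_i - 1) rho), has closed form, so all cluster sums
## reduce to rowsum() calls; the scalar s cancels from both the estimating
## equations and the sandwich, and clusters enter only through their sizes.

#' Fit a Gaussian GEE with cluster-robust standard errors
#'
#' Marginal linear model estimated by generalized estimating equations with
#' an exchangeable (default) or independence working correlation, and
#' robust (sandwich) standard errors clustered on `cluster`. With all
#' clusters of size 1, or under the independence working correlation, the
#' coefficients equal ordinary least squares.
#'
#' @param y Numeric response vector.
#' @param x Design matrix (including intercept column).
#' @param cluster Cluster labels (e.g. family ids), same length as `y`.
#' @param corstr `"exchangeable"` or `"independence"`.
#' @param maxit,tol Iteration control for the working-correlation updates.
#' @return List with `coef`, `se` (sandwich), `z`, `p` (Wald, normal
#'   reference), `vcov`, `rho` (estimated working correlation), `sigma2`,
#'   `n`, `n_clusters`, `converged`.
#' @export
fit_gee_gaussian <- function(y, x, cluster,
                             corstr = c("exchangeable", "independence"),
                             maxit = 25, tol = 1e-8) {
  corstr <- match.arg(corstr)
  x <- as.matrix(x)
  n <- length(y)
  p <- ncol(x)
  stopifnot(nrow(x) == n, length(cluster) == n)
  qrx <- qr(x)
  if (qrx$rank < p) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    stop("rank-deficient design; collinear term(s): ",
         paste(colnames(x)[setdiff(seq_len(p), keep)], collapse = ", "))
  }
  if (n < 30) warning("fewer than 30 usable rows (n = ", n, ")")
  cl <- as.integer(factor(cluster))
  n_clusters <- max(cl)
  if (n_clusters < 2) stop("need at least 2 clusters")
  sizes <- tabulate(cl)
  n_i <- sizes[cl]                       # per-row cluster size
  max_size <- max(sizes)

  beta <- qr.coef(qrx, y)
  xtx <- crossprod(x)
  rho <- 0
  sigma2 <- NA_real_
  converged <- FALSE
  for (it in seq_len(maxit)) {
    r <- y - drop(x %*% beta)
    sigma2 <- sum(r^2) / (n - p)
    if (corstr == "exchangeable" && max_size > 1) {
      e <- r / sqrt(sigma2)
      t_i <- rowsum(e, cl)
      ss_i <- rowsum(e^2, cl)
      n_pairs <- sum(sizes * (sizes - 1) / 2)
      denom <- max(n_pairs - p, 1)
      rho <- sum((t_i^2 - ss_i) / 2) / denom
      rho <- min(max(rho, -1 / (max_size - 1) + 1e-6), 1 - 1e-6)
    }
    c_size <- rho / (1 + (sizes - 1) * rho)   # per cluster
    s_mat <- rowsum(x, cl)                    # cluster column sums of X
    ty <- rowsum(y, cl)
    a <- xtx - crossprod(s_mat, s_mat * c_size)
    b <- crossprod(x, y) - crossprod(s_mat, c_size * ty)
    beta_new <- drop(solve(a, b))
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
    if (corstr == "independence") { converged <- TRUE; break }
  }
  r <- y - drop(x %*% beta)
  sigma2 <- sum(r^2) / (n - p)
  c_size <- rho / (1 + (sizes - 1) * rho)
  s_mat <- rowsum(x, cl)
  a <- xtx - crossprod(s_mat, s_mat * c_size)
  g <- rowsum(x * r, cl) - (c_size * drop(rowsum(r, cl))) * s_mat
  a_inv <- solve(a)
  vcov <- a_inv %*% crossprod(g) %*% a_inv
  se <- sqrt(diag(vcov))
  z <- beta / se
  pval <- 2 * stats::pnorm(-abs(z))
  names(beta) <- names(se) <- names(z) <- names(pval) <- colnames(x)
  list(coef = beta, se = se, z = z, p = pval, vcov = vcov,
       rho = rho, sigma2 = sigma2, n = n, n_clusters = n_clusters,
       converged = converged)
}
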