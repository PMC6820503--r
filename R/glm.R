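#' Standardize marker columns for cell-level regression
#'
#' Centers and scales each marker to mean 0, sd 1 over all cells supplied
#' (population-sd convention, divisor `n`), so that logistic-regression
#' log-odds are per 1 SD of transformed expression and comparable across
#' markers on one forest plot. Zero-variance markers cannot be scaled and
#' are dropped with a warning; the scaling record allows mapping
#' coefficients back to the original scale.
#'
#' @param table an arcsinh-scale `cell_tbl` with at least 2 cells.
#' @param markers character vector of predictor markers.
#' @return List with `x` (standardized matrix, retained markers only) and
#'   `scaling` (tibble: `marker`, `center`, `scale`, `dropped`).
#' @export
standardize_markers <- function(table, markers) {
  if (nrow(table) < 2) {
    stop("need at least 2 cells to standardize", call. = FALSE)
  }
  missing <- setdiff(markers, names(table))
  if (length(missing)) {
    stop("markers missing from the data: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- channel_matrix(table, markers)
  n <- nrow(x)
  ctr <- colMeans(x)
  sc <- sqrt(colMeans(x^2) - ctr^2)  # population sd (divisor n)
  dropped <- sc <= .Machine$double.eps^0.5 * pmax(abs(ctr), 1)
  scaling <- tibble::tibble(marker = markers, center = ctr, scale = sc,
                            dropped = dropped)
  if (all(dropped)) {
    stop("all markers have zero variance; nothing to model", call. = FALSE)
  }
  if (any(dropped)) {
    warning("dropping zero-variance markers: ",
            paste(markers[dropped], collapse = ", "), call. = FALSE)
  }
  keep <- !dropped
  z <- sweep(sweep(x[, keep, drop = FALSE], 2, ctr[keep]), 2, sc[keep], "/")
  list(x = z, scaling = scaling)
}

#' Apply a previously computed scaling to new rows
#' @param table arcsinh-scale `cell_tbl`.
#' @param scaling the `scaling` tibble from [standardize_markers()].
#' @return Standardized matrix over the retained markers.
#' @export
apply_scaling <- function(table, scaling) {
  keep <- scaling[!scaling$dropped, , drop = FALSE]
  x <- channel_matrix(table, keep$marker)
  sweep(sweep(x, 2, keep$center), 2, keep$scale, "/")
}

#' Maximum-likelihood logistic regression by Newton-Raphson
#'
#' Fits `logit P(y = 1) = X b` by Newton-Raphson with step-halving on the
#' Bernoulli log-likelihood. Convergence: `max |gradient| < 1e-8` or 100
#' iterations. Complete or quasi-complete separation — coefficients
#' diverging without the gradient vanishing — is detected and flagged; the
#' last stable iterate is returned. An optional ridge penalty on the slopes
#' (never the intercept) turns the flagged fit into a finite penalized one.
#'
#' @param x design matrix WITHOUT intercept column (added internally),
#'   columns named.
#' @param y 0/1 outcome vector (or logical / two-level factor).
#' @param ridge nonnegative L2 penalty applied to slope coefficients only.
#' @param max_iter,tol Newton-Raphson controls.
#' @return A list of class `cyto_logit`: `coef` (named, first element
#'   `(Intercept)`), `converged`, `separated`, `iterations`,
#'   `gradient_norm`, `loglik`, `n`.
#' @export
fit_logistic <- function(x, y, ridge = 0, max_iter = 100L, tol = 1e-8) {
  y <- as_binary_outcome(y)
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("x and y sizes differ", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("outcome has a single class; a contrast needs both", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, x)
  p <- ncol(X)
  pen <- c(0, rep(ridge, p - 1L))
  beta <- numeric(p)
  loglik <- function(b) {
    eta <- drop(X %*% b)
    # log(1 + exp(eta)) computed without overflow at large |eta|
    sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))) -
      0.5 * sum(pen * b^2)
  }
  ll <- loglik(beta)
  separated <- FALSE
  last_stable <- beta
  iter <- 0L
  gnorm <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- stats::plogis(drop(X %*% beta))
    grad <- drop(crossprod(X, y - mu)) - pen * beta
    gnorm <- max(abs(grad))
    if (gnorm < tol) break
    w <- mu * (1 - mu)
    H <- crossprod(X * w, X)
    diag(H) <- diag(H) + pen
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) {
      separated <- TRUE
      beta <- last_stable
      break
    }
    # step-halving: insist the (penalized) log-likelihood does not decrease
    cand <- beta + step
    ll_new <- loglik(cand)
    halvings <- 0L
    while ((!is.finite(ll_new) || ll_new < ll - 1e-12) && halvings < 30L) {
      step <- step / 2
      cand <- beta + step
      ll_new <- loglik(cand)
      halvings <- halvings + 1L
    }
    if (!is.finite(ll_new) || ll_new < ll - 1e-12) {
      separated <- TRUE
      beta <- last_stable
      break
    }
    last_stable <- beta
    beta <- cand
    ll <- ll_new
    if (max(abs(beta)) > 15 && ridge == 0) {
      # log-odds beyond +-15 on standardized predictors cannot arise from
      # overlapping data: the likelihood has no interior maximum
      # ((quasi-)separation; the gradient can still vanish along the
      # divergent path, so a gradient criterion alone is not enough)
      separated <- TRUE
      break
    }
  }
  if (iter == max_iter && gnorm >= tol && !separated) {
    mu <- stats::plogis(drop(X %*% beta))
    gnorm <- max(abs(drop(crossprod(X, y - mu)) - pen * beta))
    if (gnorm >= tol) separated <- max(abs(beta)) > 15
  }
  structure(list(coef = stats::setNames(drop(beta), colnames(X)),
                 converged = gnorm < tol && !separated,
                 separated = separated,
                 iterations = iter,
                 gradient_norm = gnorm,
                 loglik = ll,
                 n = length(y)),
            class = "cyto_logit")
}

as_binary_outcome <- function(y) {
  if (is.logical(y)) return(as.integer(y))
  if (is.factor(y)) {
    if (nlevels(y) > 2L) stop("outcome must be binary", call. = FALSE)
    return(as.integer(y) - 1L)
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be 0/1", call. = FALSE)
  as.integer(y)
}

#' @export
print.cyto_logit <- function(x, ...) {
  cat("Logistic fit:", x$n, "cells,", length(x$coef) - 1, "predictors\n")
  if (x$separated) cat("  ** separation detected **\n")
  print(round(x$coef, 4))
  invisible(x)
}
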