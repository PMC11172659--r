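#' Multi-kernel REML variance components
#'
#' Fits `y ~ N(X beta, sum_k sigma_k K_k + sigma_e^2 I)` by restricted
#' maximum likelihood using average-information (AI) updates with an EM
#' fallback whenever an AI step fails to improve the restricted
#' log-likelihood. Variance coefficients are constrained nonnegative by
#' boundary projection, except that the coefficient of an `HRM_CG` kernel
#' is an unconstrained covariance parameter (the kernel itself may be
#' indefinite). If the converged covariance matrix V is not positive
#' definite, the HRM_CG coefficient is shrunk toward zero until the
#' smallest eigenvalue exceeds `1e-8 * mean(diag(V))`.
#'
#' Parameters are initialized at equal shares of the phenotypic variance
#' (covariance terms at zero); convergence is declared when the restricted
#' log-likelihood changes by less than `tol` (default 1e-6) or after
#' `max_iter` iterations.
#'
#' @param y numeric trait vector (length n).
#' @param X covariate design matrix (n x c, full column rank; include the
#'   intercept column).
#' @param kernels list of [rel_matrix()] objects or plain n x n matrices;
#'   may be empty, in which case the fit reduces to the ordinary residual
#'   variance estimate.
#' @param tol convergence tolerance on the restricted log-likelihood.
#' @param max_iter iteration cap.
#' @param verbose print per-iteration progress.
#' @return object of class `variance_components`: list with `components`
#'   (named estimates, residual last), `reml_loglik`, `n_iter`,
#'   `converged`, `V` (fitted covariance), `constrained` flags.
#' @export
fit_variance_components <- function(y, X, kernels = list(), tol = 1e-6,
                                    max_iter = 100L, verbose = FALSE) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop_hw("nrow(X) != length(y)")
  if (qr(X)$rank < ncol(X))
    stop_hw("covariate matrix X is rank deficient")
  c_ <- ncol(X)
  Ks <- lapply(kernels, as_kernel_values)
  nk <- length(Ks)
  if (n < c_ + nk + 2)
    stop_hw("too few samples for the number of covariates and variance parameters")
  knames <- names(kernels)
  if (is.null(knames) || any(!nzchar(knames)))
    knames <- vapply(seq_along(kernels), function(i) {
      if (inherits(kernels[[i]], "rel_matrix")) kernels[[i]]$kind
      else paste0("K", i)
    }, character(1))
  knames <- make.unique(c(knames, "residual"))
  ## constraint: nonnegative unless the kernel is the HRM_CG covariance term
  unconstrained <- c(vapply(kernels, function(k)
    inherits(k, "rel_matrix") && k$kind == "HRM_CG", logical(1)), FALSE)

  ## base residual variance from the fixed-effect fit
  qrX <- qr(X)
  rss <- sum(qr.resid(qrX, y)^2)
  vp <- rss / (n - c_)

  if (nk == 0L) {
    ll <- reml_loglik_direct(y, X, diag(vp, n))
    return(structure(list(
      components = stats::setNames(vp, "residual"),
      reml_loglik = ll, n_iter = 0L, converged = TRUE,
      V = diag(vp, n), constrained = !unconstrained,
      kernel_names = knames,
      mean_diag = stats::setNames(1, "residual")), class = "variance_components"))
  }

  np <- nk + 1L
  theta <- rep(vp / np, np)
  theta[unconstrained] <- 0
  Ilist <- c(Ks, list(diag(1, n)))

  build_V <- function(th) {
    V <- diag(th[np], n)
    for (k in seq_len(nk)) V <- V + th[k] * Ks[[k]]
    V
  }
  floor_e <- 1e-8 * vp

  ## make V(theta) PD: shrink unconstrained coefficients, then floor residual
  make_feasible <- function(th) {
    th[!unconstrained] <- pmax(th[!unconstrained], 0)
    th[np] <- max(th[np], floor_e)
    for (tries in 1:60) {
      if (!inherits(try(chol(build_V(th)), silent = TRUE), "try-error"))
        return(th)
      if (any(unconstrained) && any(th[unconstrained] != 0))
        th[unconstrained] <- th[unconstrained] * 0.5
      else
        th[np] <- th[np] * 2 + 1e-6 * vp
    }
    stop_hw("could not produce a positive-definite covariance matrix")
  }

  reml_parts <- function(th) {
    V <- build_V(th)
    ch <- chol(V)
    Vi <- chol2inv(ch)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    chx <- chol(XtViX)
    P <- Vi - ViX %*% chol2inv(chx) %*% t(ViX)
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                    sum(y * Py))
    list(P = P, Py = Py, loglik = ll)
  }

  theta <- make_feasible(theta)
  parts <- reml_parts(theta)
  ll <- parts$loglik
  converged <- FALSE
  warned_ident <- FALSE
  it <- 0L

  for (it in seq_len(max_iter)) {
    P <- parts$P; Py <- parts$Py
    A <- matrix(0, n, np)              # columns K_k P y
    trPK <- numeric(np)
    for (k in seq_len(np)) {
      if (k == np) {
        A[, k] <- Py
        trPK[k] <- sum(diag(P))
      } else {
        A[, k] <- Ks[[k]] %*% Py
        trPK[k] <- sum(P * Ks[[k]])   # tr(P K), both symmetric
      }
    }
    yPKPy <- as.numeric(crossprod(A, Py))
    score <- -0.5 * (trPK - yPKPy)
    AI <- 0.5 * crossprod(A, P %*% A)

    ## active set: constrained parameters pinned at zero with a negative
    ## score stay fixed this iteration (boundary of the parameter space)
    at_bound <- !unconstrained & theta <= floor_e * 2 & score < 0
    free <- which(!at_bound)
    theta[at_bound & theta > 0] <- 0

    em_step <- function(th) {
      d <- th^2 * (yPKPy - trPK) / n
      d[at_bound] <- 0
      make_feasible(th + d)
    }

    cand <- NULL
    ai_ok <- length(free) > 0 &&
      !inherits(try(d_free <- solve(AI[free, free, drop = FALSE], score[free]),
                    silent = TRUE), "try-error")
    if (!ai_ok && !warned_ident) {
      warning("AI matrix is singular; variance parameters may not all be ",
              "identifiable - reporting boundary estimates")
      warned_ident <- TRUE
    }
    if (ai_ok) {
      d_ai <- numeric(np)
      d_ai[free] <- d_free
      step <- 1
      for (h in 1:8) {
        th_try <- make_feasible(theta + step * d_ai)
        p_try <- reml_parts(th_try)
        if (p_try$loglik >= ll - 1e-10) {
          cand <- list(theta = th_try, parts = p_try); break
        }
        step <- step / 2
      }
    }
    if (is.null(cand)) {                # EM fallback
      th_try <- em_step(theta)
      p_try <- reml_parts(th_try)
      cand <- list(theta = th_try, parts = p_try)
    }
    delta <- cand$parts$loglik - ll
    dtheta <- max(abs(cand$theta - theta))
    theta <- cand$theta
    parts <- cand$parts
    ll <- parts$loglik
    if (verbose)
      message(sprintf("iter %3d  loglik %.6f  theta %s", it, ll,
                      paste(format(theta, digits = 4), collapse = " ")))
    if (abs(delta) < tol || dtheta < 1e-8 * vp) { converged <- TRUE; break }
  }

  ## final PD guarantee (shrink HRM_CG coefficient if necessary)
  if (any(unconstrained)) {
    for (tries in 1:100) {
      V <- build_V(theta)
      ev_min <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
      if (ev_min > 1e-8 * mean(diag(V))) break
      theta[unconstrained] <- theta[unconstrained] * 0.8
    }
  }
  V <- build_V(theta)

  structure(list(
    components = stats::setNames(theta, knames),
    reml_loglik = ll, n_iter = it, converged = converged,
    V = V, constrained = !unconstrained, kernel_names = knames,
    mean_diag = stats::setNames(c(vapply(Ks, function(k) mean(diag(k)),
                                         numeric(1)), 1), knames)),
    class = "variance_components")
}

#' Variance fractions from a fitted model
#'
#' Converts per-kernel variance coefficients into shares of phenotypic
#' variance: `theta_k * mean(diag(K_k)) / sum_j theta_j * mean(diag(K_j))`
#' (residual kernel diagonal is 1). For an unconstrained covariance
#' coefficient (HRM_CG) the signed contribution is reported.
#'
#' @param vc a `variance_components` object.
#' @return named numeric vector of fractions summing to 1.
#' @export
variance_fractions <- function(vc) {
  contrib <- vc$components * vc$mean_diag
  contrib / sum(contrib)
}

#' @export
print.variance_components <- function(x, ...) {
  cat("<variance_components>\n")
  print(round(x$components, 6))
  cat(sprintf("REML loglik %.4f after %d iteration(s); converged: %s\n",
              x$reml_loglik, x$n_iter, x$converged))
  invisible(x)
}

## Restricted log-likelihood of y ~ N(X beta, V), up to the usual constant.
## Shared by the fitter and usable as a standalone evaluator.
reml_loglik_direct <- function(y, X, V) {
  ch <- chol(V)
  Vi <- chol2inv(ch)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  chx <- chol(XtViX)
  beta <- chol2inv(chx) %*% crossprod(ViX, y)
  r <- y - X %*% beta
  -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
            sum(r * (Vi %*% r)))
}
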