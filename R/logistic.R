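#' Ridge-penalised logistic regression
#'
#' Newton/IRLS maximisation of the binomial log-likelihood minus
#' `ridge/2 * sum(beta_j^2)` over the non-intercept coefficients. With
#' `ridge = 0` this is plain maximum-likelihood logistic regression; the small
#' default ridge used elsewhere in the package (1e-4) only stabilises fits
#' near separation. The fit is deterministic given its inputs.
#'
#' @param X Numeric design matrix (no intercept column), or a data frame of
#'   numeric columns.
#' @param y Binary response (0/1, logical, or `"AD"`/`"HC"` with AD = 1).
#' @param ridge Non-negative penalty; the intercept is never penalised.
#' @param max_iter,tol Newton iteration controls.
#' @return A list of class `logistic_fit` with `intercept`, `coefficients`
#'   (named), `converged`, `log_lik`, `n_iter`.
#' @export
fit_logistic <- function(X, y, ridge = 0, max_iter = 100, tol = 1e-10) {
  X <- as.matrix(X)
  if (is.character(y)) y <- diagnosis_to_binary(y)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) abort("y must be binary (0/1)")
  if (nrow(X) != length(y)) abort("X and y disagree on sample count")
  if (ridge < 0) abort("ridge must be non-negative")
  if (length(unique(y)) < 2 && ridge == 0) {
    abort("constant response needs ridge > 0")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  beta <- numeric(p)
  pen <- c(0, rep(ridge, p - 1L))
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- plogis(eta)
    grad <- drop(crossprod(Xd, y - mu)) - pen * beta
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(Xd * w, Xd)
    diag(H) <- diag(H) + pen + 1e-12   # step damping only; optimum unchanged
    step <- tryCatch(solve(H, grad), error = function(e) {
      abort("singular information matrix; consider ridge > 0")
    })
    # Halve overshooting steps (keeps IRLS monotone near separation).
    while (max(abs(step)) > 10) step <- step / 2
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  if (!converged && ridge == 0) {
    eta <- drop(Xd %*% beta)
    if (all((eta > 0) == (y == 1))) {
      abort("perfect separation: the unpenalised logistic MLE does not exist; set ridge > 0")
    }
  }
  eta <- drop(Xd %*% beta)
  ll <- sum(y * eta - pmax(eta, 0) - log1p(exp(-abs(eta))))
  structure(list(intercept = unname(beta[1]),
                 coefficients = setNames(beta[-1], colnames(X)),
                 converged = converged, log_lik = ll, n_iter = it,
                 ridge = ridge),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> intercept %.4f, %d coefficient(s), ridge %g\n",
              x$intercept, length(x$coefficients), x$ridge))
  print(x$coefficients)
  invisible(x)
}

predict_logistic <- function(fit, X) {
  X <- as.matrix(X)
  plogis(fit$intercept + drop(X %*% fit$coefficients))
}
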