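# Independent REML oracle for the univariate animal model: direct
# maximization of the restricted log-likelihood over the four variance
# components, with the covariance V = Va Z G Z' + Vs Z2 Z2' + Vi Z3 Z3' +
# Ve I assembled explicitly. Intended for small instances (<= ~100 plants).
reml_loglik <- function(logv, y, X, V_parts) {
  v <- exp(logv)
  V <- v[length(v)] * diag(length(y))
  for (k in seq_along(V_parts)) V <- V + v[k] * V_parts[[k]]
  cv <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cv)) return(-1e10)
  logdetV <- 2 * sum(log(diag(cv)))
  Vi_y <- backsolve(cv, forwardsolve(t(cv), y))
  Vi_X <- backsolve(cv, forwardsolve(t(cv), X))
  XtViX <- crossprod(X, Vi_X)
  cx <- chol(XtViX)
  beta <- backsolve(cx, forwardsolve(t(cx), crossprod(X, Vi_y)))
  r <- y - X %*% beta
  Vi_r <- backsolve(cv, forwardsolve(t(cv), r))
  -0.5 * (logdetV + 2 * sum(log(diag(cx))) + sum(r * Vi_r))
}

reml_fit_animal <- function(bundle) {
  y <- bundle$y
  X <- bundle$X
  Z1 <- bundle$Z1
  parts <- list(additive = Z1 %*% bundle$G %*% t(Z1))
  if (!is.null(bundle$Z2)) parts$site <- tcrossprod(bundle$Z2)
  parts$perm_env <- tcrossprod(bundle$Z3)
  vy <- stats::var(as.numeric(y))
  start <- log(rep(vy / 4, length(parts) + 1))
  opt <- stats::optim(start, function(lv) -reml_loglik(lv, y, X, parts),
                      method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-10))
  v <- exp(opt$par)
  names(v) <- c(names(parts), "residual")
  list(V_a = unname(v["additive"]),
       V_s = if ("site" %in% names(v)) unname(v["site"]) else 0,
       V_i = unname(v["perm_env"]),
       V_error = unname(v["residual"]),
       loglik = -opt$value, convergence = opt$convergence)
}
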