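# Independent oracles used across the suite.

# brute-force OLS via the normal equations (independent of fit_ols)
normal_equations_ols <- function(y, x) {
  xi <- cbind(`(Intercept)` = 1, as.matrix(x))
  xtx <- t(xi) %*% xi
  beta <- solve(xtx, t(xi) %*% y)
  resid <- y - xi %*% beta
  s2 <- sum(resid^2) / (length(y) - ncol(xi))
  list(coef = drop(beta), se = sqrt(diag(solve(xtx)) * s2))
}

# one huge-N replicate with rank-based deletion: the brute-force
# empirical counterpart of the closed-form truncation estimands
empirical_truncation_fit <- function(spec, rate, method, n, seed) {
  s <- generate_sample(spec, n, seed)
  s <- apply_attrition(s, rate)
  if (method == "mr") fit_mr(s) else fit_change_score(s)
}

canonical_scenarios <- c("mcar", "mar", "mnar-weak", "mnar-strong")
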