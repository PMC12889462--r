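#' Maximum-likelihood population effects (MLPE) mixed model
#'
#' Regression between pairwise distance matrices with a random effect per
#' population accounting for the non-independence of pairs:
#' `y_ij = beta0 + sum_k beta_k x_k,ij + u_i + u_j + e_ij` with
#' `u ~ N(0, sigma_u2 I)` over populations and i.i.d. residuals. Two pairs
#' sharing one population have covariance `sigma_u2`; disjoint pairs are
#' uncorrelated. Variance components are estimated by REML over the ratio
#' `lambda = sigma_u2 / sigma_e2` (Woodbury identities keep each
#' evaluation at population-level cost); a parallel ML fit supplies the
#' log-likelihood used for AIC/AICc model comparison.
#'
#' @param pairs Pair-indexed tibble (one row per unordered pair).
#' @param response Name of the response distance column.
#' @param predictors Character vector of predictor distance columns.
#' @param pop_cols Names of the two population id columns (default
#'   `c("pop1", "pop2")`).
#' @param lambda Fix the variance ratio instead of estimating it
#'   (`lambda = 0` reduces exactly to OLS on the pair table).
#' @return An `mlpe_fit`: coefficients with `se`, `statistic` (t, with
#'   `n_pairs - k` df), `p.value`, `sigma_u2`, `sigma_e2`, REML and ML
#'   log-likelihoods, `AIC`, `AICc`, `converged`.
#' @export
mlpe_fit <- function(pairs, response = "y", predictors = "x",
                     pop_cols = c("pop1", "pop2"), lambda = NULL) {
  pops <- sort(unique(c(as.character(pairs[[pop_cols[1]]]),
                        as.character(pairs[[pop_cols[2]]]))))
  np <- length(pops)
  n <- nrow(pairs)
  if (n != np * (np - 1) / 2)
    warning("pair table does not contain all ", np * (np - 1) / 2,
            " unordered pairs")
  i1 <- match(as.character(pairs[[pop_cols[1]]]), pops)
  i2 <- match(as.character(pairs[[pop_cols[2]]]), pops)
  Z <- matrix(0, n, np)
  Z[cbind(seq_len(n), i1)] <- 1
  Z[cbind(seq_len(n), i2)] <- 1
  X <- cbind(`(Intercept)` = 1,
             as.matrix(pairs[, predictors, drop = FALSE]))
  k <- ncol(X)
  if (qr(X)$rank < k)
    stop("predictors are rank deficient (duplicated or constant columns)",
         call. = FALSE)
  y <- pairs[[response]]
  ZtZ <- crossprod(Z)

  # profiled deviances given lambda (W = I + lambda Z Z'); Woodbury
  profile <- function(lam, reml) {
    if (lam <= 0) {
      fit <- stats::lm.fit(X, y)
      rss <- sum(fit$residuals^2)
      if (reml) {
        s2 <- rss / (n - k)
        ll <- -0.5 * ((n - k) * (log(2 * pi * s2) + 1) +
                      determinant(crossprod(X), logarithm = TRUE)$modulus)
      } else {
        s2 <- rss / n
        ll <- -0.5 * n * (log(2 * pi * s2) + 1)
      }
      return(list(ll = as.numeric(ll), beta = fit$coefficients, s2 = s2,
                  XtWiX = crossprod(X)))
    }
    A <- ZtZ + diag(1 / lam, np)
    cA <- chol(A)
    solveW <- function(M) {
      ZtM <- crossprod(Z, M)
      M - Z %*% backsolve(cA, backsolve(cA, ZtM, transpose = TRUE))
    }
    logdetW <- 2 * sum(log(diag(cA))) + np * log(lam)
    WiX <- solveW(X)
    Wiy <- solveW(y)
    XtWiX <- crossprod(X, WiX)
    beta <- solve(XtWiX, crossprod(X, Wiy))
    r <- y - X %*% beta
    q <- sum(r * solveW(r))
    if (reml) {
      s2 <- q / (n - k)
      ll <- -0.5 * ((n - k) * (log(2 * pi * s2) + 1) + logdetW +
                    determinant(XtWiX, logarithm = TRUE)$modulus)
    } else {
      s2 <- q / n
      ll <- -0.5 * (n * (log(2 * pi * s2) + 1) + logdetW)
    }
    list(ll = as.numeric(ll), beta = beta, s2 = s2, XtWiX = XtWiX)
  }

  converged <- TRUE
  if (is.null(lambda)) {
    opt <- optimize(function(ll) profile(exp(ll), reml = TRUE)$ll,
                    interval = c(-12, 12), maximum = TRUE)
    lam_hat <- exp(opt$maximum)
    if (profile(0, reml = TRUE)$ll >= opt$objective) lam_hat <- 0
    if (abs(opt$maximum) > 11.5) converged <- FALSE # boundary of search box
  } else {
    lam_hat <- lambda
  }
  reml <- profile(lam_hat, reml = TRUE)
  ml_lam <- if (is.null(lambda)) {
    optml <- optimize(function(ll) profile(exp(ll), reml = FALSE)$ll,
                      interval = c(-12, 12), maximum = TRUE)
    if (profile(0, reml = FALSE)$ll >= optml$objective) 0 else
      exp(optml$maximum)
  } else lambda
  ml <- profile(ml_lam, reml = FALSE)

  beta <- as.numeric(reml$beta)
  names(beta) <- colnames(X)
  vcov_beta <- reml$s2 * solve(reml$XtWiX)
  se <- sqrt(pmax(diag(vcov_beta), 0))
  tstat <- beta / se
  pval <- 2 * pt(-abs(tstat), df = n - k)
  n_par <- k + 2 # fixed effects + sigma_u2 + sigma_e2
  aic <- -2 * ml$ll + 2 * n_par
  structure(list(
    coefficients = beta, se = setNames(se, colnames(X)),
    statistic = setNames(tstat, colnames(X)),
    p.value = setNames(pval, colnames(X)),
    sigma_u2 = lam_hat * reml$s2, sigma_e2 = reml$s2,
    lambda = lam_hat,
    logLik_REML = reml$ll, logLik = ml$ll,
    AIC = aic, AICc = aic + 2 * n_par * (n_par + 1) / (n - n_par - 1),
    n = n, k = k, n_par = n_par, n_pops = np,
    response = response, predictors = predictors,
    converged = converged),
    class = "mlpe_fit")
}

#' @export
print.mlpe_fit <- function(x, ...) {
  cat("<mlpe_fit> ", x$n, " pairs / ", x$n_pops, " populations",
      if (!x$converged) "  [NOT CONVERGED]", "\n",
      "sigma_u2 = ", signif(x$sigma_u2, 4),
      ", sigma_e2 = ", signif(x$sigma_e2, 4),
      ", AICc = ", round(x$AICc, 3), "\n", sep = "")
  print(cbind(estimate = x$coefficients, se = x$se, t = x$statistic,
              p = x$p.value))
  invisible(x)
}

#' Model selection by finite-sample corrected AIC
#'
#' Ranks candidate fits by `AICc = AIC + 2k(k+1)/(n-k-1)` (k the number of
#' estimated parameters, n the common sample size). All candidates must be
#' fitted to the same response; candidates with `n <= k + 1` are dropped
#' with a warning.
#'
#' @param fits Named list of fits carrying `AIC`, `n_par` and `n` elements
#'   (e.g. [mlpe_fit()] or [gls_fit()] objects).
#' @return A list with `best` (the winning fit), `best_name`, and `table`
#'   (tibble ranked by AICc with delta and Akaike weights).
#' @export
aicc_model_selection <- function(fits) {
  if (is.null(names(fits)))
    names(fits) <- paste0("model", seq_along(fits))
  ok <- vapply(fits, function(f) f$n > f$n_par + 1, logical(1))
  if (any(!ok)) {
    warning("dropping candidate(s) with n <= k + 1: ",
            paste(names(fits)[!ok], collapse = ", "))
    fits <- fits[ok]
  }
  if (length(fits) == 0) stop("no admissible candidates", call. = FALSE)
  tab <- tibble::tibble(
    model = names(fits),
    k = vapply(fits, `[[`, numeric(1), "n_par"),
    n = vapply(fits, `[[`, numeric(1), "n"),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"))
  tab$AICc <- tab$AIC + 2 * tab$k * (tab$k + 1) / (tab$n - tab$k - 1)
  tab <- tab[order(tab$AICc), ]
  tab$delta_AICc <- tab$AICc - tab$AICc[1]
  w <- exp(-tab$delta_AICc / 2)
  tab$weight <- w / sum(w)
  list(best = fits[[tab$model[1]]], best_name = tab$model[1], table = tab)
}
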