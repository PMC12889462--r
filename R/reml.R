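# ---- REML variance-component engines -------------------------------------
#
# One-component model: V = sigma_e2 (I + lambda K). The REML log-likelihood
# is profiled over lambda after a single eigendecomposition of K, so each
# candidate lambda costs O(n) — bootstrap refits reuse the decomposition.
# Two-component model: V = sigma_e2 (I + l1 K1 + l2 K2), optimized by
# Nelder-Mead over (log l1, log l2) with a Cholesky per evaluation.

reml_loglik_rotated <- function(loglam, d, yt, Xt) {
  lam <- exp(loglam)
  w <- 1 + lam * d
  n <- length(yt)
  p <- ncol(Xt)
  XtWiX <- crossprod(Xt, Xt / w)
  XtWiy <- crossprod(Xt, yt / w)
  beta <- solve(XtWiX, XtWiy)
  r <- yt - Xt %*% beta
  q <- sum(r^2 / w)
  s2 <- q / (n - p)
  ll <- -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + sum(log(w)) +
                determinant(XtWiX, logarithm = TRUE)$modulus)
  list(ll = as.numeric(ll), beta = beta, s2 = s2, lam = lam)
}

# Profile REML over lambda for y = X beta + u + e with cov(u) = sigma_u2 K.
# `eig` may carry a precomputed eigen(K, symmetric = TRUE).
reml_one_component <- function(y, X, K, eig = NULL, interval = c(-15, 15)) {
  if (is.null(eig)) eig <- eigen(K, symmetric = TRUE)
  if (min(eig$values) < -1e-6 * max(abs(eig$values)))
    stop("covariance structure is not positive semidefinite", call. = FALSE)
  yt <- crossprod(eig$vectors, y)
  Xt <- crossprod(eig$vectors, X)
  d <- pmax(eig$values, 0)
  opt <- optimize(function(l) reml_loglik_rotated(l, d, yt, Xt)$ll,
                  interval = interval, maximum = TRUE)
  best <- reml_loglik_rotated(opt$maximum, d, yt, Xt)
  # compare against the boundary lambda -> 0 (no strain variance)
  low <- reml_loglik_rotated(interval[1], d, yt, Xt)
  boundary <- FALSE
  if (low$ll >= best$ll - 1e-8) {
    best <- low
    best$lam <- 0
    boundary <- TRUE
  }
  if (opt$maximum > interval[2] - 0.5) boundary <- TRUE
  list(sigma_u2 = best$lam * best$s2, sigma_e2 = best$s2,
       lambda = best$lam, logLik_REML = best$ll,
       beta = as.numeric(best$beta), boundary = boundary, eig = eig)
}

#' REML heritability of a replicated strain trait
#'
#' Fits the linear mixed model `y_ij = m + u_i + e_ij` with strain effects
#' `u ~ N(0, M sigma_u2)` by restricted maximum likelihood and returns
#' heritability `sigma_u2 / (sigma_u2 + sigma_e2)`: broad-sense H2 when
#' `M` is the identity (strains exchangeable), narrow-sense h2 when `M` is
#' a [vanraden_kinship()] genomic relationship matrix (additive genetic
#' variance only). Confidence intervals come from a two-stage percentile
#' bootstrap: strains are resampled with replacement (the dominant,
#' between-strain sampling level), then replicates within each drawn
#' strain, and the model is refit on each resample.
#'
#' @param table Tibble with columns `strain` and the trait column.
#' @param trait Trait column name (default `"value"`).
#' @param kinship `NULL` for H2, or a kinship matrix /
#'   [vanraden_kinship()] object (strains matched by name) for h2.
#' @param n_boot Bootstrap resamples (default 500; 0 skips the CI).
#' @param level CI level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return A `heritability_fit`: `estimate`, `ci`, `sigma_u2`, `sigma_e2`,
#'   `kind` ("broad" or "narrow"), `boot` (bootstrap draws), `boundary`
#'   convergence flag.
#' @export
reml_heritability <- function(table, trait = "value", kinship = NULL,
                              n_boot = 500, level = 0.95, seed = 1) {
  strains <- unique(as.character(table$strain))
  if (length(strains) < 2) stop("need at least 2 strains", call. = FALSE)
  y <- table[[trait]]
  si <- match(as.character(table$strain), strains)
  n <- length(y)
  Z <- matrix(0, n, length(strains))
  Z[cbind(seq_len(n), si)] <- 1
  if (is.null(kinship)) {
    M <- diag(length(strains))
    kind <- "broad"
  } else {
    Mfull <- as.matrix(kinship)
    miss <- setdiff(strains, rownames(Mfull))
    if (length(miss) > 0)
      stop("kinship missing strains: ", paste(miss, collapse = ", "),
           call. = FALSE)
    M <- Mfull[strains, strains]
    kind <- "narrow"
  }
  K <- Z %*% M %*% t(Z)
  X <- matrix(1, n, 1)
  fit <- reml_one_component(y, X, K)
  h2 <- fit$sigma_u2 / (fit$sigma_u2 + fit$sigma_e2)
  boot <- numeric(0)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    idx_by_strain <- split(seq_len(n), si)
    ns <- length(strains)
    boot <- with_local_seed(seed, vapply(seq_len(n_boot), function(b) {
      pick <- sample.int(ns, ns, replace = TRUE)
      idx <- unlist(lapply(pick, function(s) {
        ii <- idx_by_strain[[s]]
        ii[sample.int(length(ii), length(ii), replace = TRUE)]
      }))
      sib <- rep(seq_len(ns), vapply(pick, function(s)
        length(idx_by_strain[[s]]), integer(1)))
      nb <- length(idx)
      Zb <- matrix(0, nb, ns)
      Zb[cbind(seq_len(nb), sib)] <- 1
      Kb <- Zb %*% M[pick, pick] %*% t(Zb)
      f <- reml_one_component(y[idx], matrix(1, nb, 1), Kb)
      f$sigma_u2 / (f$sigma_u2 + f$sigma_e2)
    }, numeric(1)))
    alpha <- (1 - level) / 2
    ci <- unname(quantile(boot, c(alpha, 1 - alpha)))
  }
  structure(list(estimate = h2, ci = ci, level = level,
                 sigma_u2 = fit$sigma_u2, sigma_e2 = fit$sigma_e2,
                 logLik_REML = fit$logLik_REML, kind = kind,
                 n_strains = length(strains), n_obs = n,
                 boot = boot, boundary = fit$boundary),
            class = "heritability_fit")
}

#' @export
print.heritability_fit <- function(x, ...) {
  lab <- if (x$kind == "broad") "H2 (broad-sense)" else "h2 (narrow-sense)"
  cat("<heritability_fit> ", lab, " = ", sprintf("%.2f%%", 100 * x$estimate),
      if (!anyNA(x$ci)) sprintf("  CI[%g%%]: [%.2f%%, %.2f%%]",
                                100 * x$level, 100 * x$ci[1], 100 * x$ci[2]),
      if (x$boundary) "  [boundary]", "\n", sep = "")
  invisible(x)
}

#' QTL variance partitioning with two genomic random effects
#'
#' Fits `y = m + u + v + e` with a QTL-region random effect
#' `u ~ N(0, A_qtl sigma_u2)` and a genome-background additive effect
#' `v ~ N(0, Q sigma_v2)`, by REML over the two variance ratios
#' (Nelder-Mead on the log scale). Returns the fraction of phenotypic
#' variance explained by the QTL, `sigma_u2 / (sigma_u2 + sigma_v2 +
#' sigma_e2)`.
#'
#' @param table Tibble with `strain` and the trait column (one or more
#'   rows per strain).
#' @param A_qtl Kinship built from markers inside the QTL region
#'   ([vanraden_kinship()] object or matrix with strain dimnames).
#' @param Q Kinship from the remaining genome-wide markers.
#' @param trait Trait column name (default `"value"`).
#' @return A `qtl_variance_fit`: `fraction`, the three variance
#'   components, `logLik_REML`, `converged`.
#' @export
qtl_variance <- function(table, A_qtl, Q, trait = "value") {
  strains <- unique(as.character(table$strain))
  y <- table[[trait]]
  n <- length(y)
  si <- match(as.character(table$strain), strains)
  Z <- matrix(0, n, length(strains))
  Z[cbind(seq_len(n), si)] <- 1
  align <- function(M) {
    M <- as.matrix(M)
    if (!is.null(rownames(M)) && all(strains %in% rownames(M)))
      M <- M[strains, strains]
    if (!all(dim(M) == length(strains)))
      stop("kinship dimensions do not match the strain set", call. = FALSE)
    M
  }
  K1 <- Z %*% align(A_qtl) %*% t(Z)
  K2 <- Z %*% align(Q) %*% t(Z)
  o1 <- K1[upper.tri(K1)]; o2 <- K2[upper.tri(K2)]
  if (stats::sd(o1) > 0 && stats::sd(o2) > 0 &&
      stats::cor(o1, o2) > 0.99)
    warning("QTL and background kinships are nearly collinear; ",
            "variance partition may not be identifiable")
  X <- matrix(1, n, 1)
  p <- ncol(X)
  negll <- function(par) {
    l1 <- exp(par[1]); l2 <- exp(par[2])
    W <- diag(n) + l1 * K1 + l2 * K2
    cW <- tryCatch(chol(W), error = function(e) NULL)
    if (is.null(cW)) return(1e10)
    WiX <- backsolve(cW, backsolve(cW, X, transpose = TRUE))
    Wiy <- backsolve(cW, backsolve(cW, y, transpose = TRUE))
    XtWiX <- crossprod(X, WiX)
    beta <- solve(XtWiX, crossprod(X, Wiy))
    r <- y - X %*% beta
    q <- sum(r * backsolve(cW, backsolve(cW, r, transpose = TRUE)))
    s2 <- q / (n - p)
    0.5 * ((n - p) * (log(2 * pi * s2) + 1) + 2 * sum(log(diag(cW))) +
           as.numeric(determinant(XtWiX, logarithm = TRUE)$modulus))
  }
  opt <- optim(c(0, 0), negll, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-10))
  # boundary candidates: each component switched off
  cands <- list(opt$par,
                c(-20, opt$par[2]), c(opt$par[1], -20), c(-20, -20))
  vals <- vapply(cands, negll, numeric(1))
  best <- cands[[which.min(vals)]]
  l1 <- exp(best[1]); l2 <- exp(best[2])
  if (best[1] <= -19) l1 <- 0
  if (best[2] <= -19) l2 <- 0
  W <- diag(n) + l1 * K1 + l2 * K2
  cW <- chol(W)
  WiX <- backsolve(cW, backsolve(cW, X, transpose = TRUE))
  Wiy <- backsolve(cW, backsolve(cW, y, transpose = TRUE))
  beta <- solve(crossprod(X, WiX), crossprod(X, Wiy))
  r <- y - X %*% beta
  q <- sum(r * backsolve(cW, backsolve(cW, r, transpose = TRUE)))
  s2 <- q / (n - p)
  structure(list(
    fraction = l1 / (1 + l1 + l2),
    sigma_u2 = l1 * s2, sigma_v2 = l2 * s2, sigma_e2 = s2,
    logLik_REML = -min(vals), converged = opt$convergence == 0),
    class = "qtl_variance_fit")
}

#' @export
print.qtl_variance_fit <- function(x, ...) {
  cat("<qtl_variance_fit> QTL variance fraction = ",
      sprintf("%.2f%%", 100 * x$fraction),
      " (sigma_u2 = ", signif(x$sigma_u2, 4),
      ", sigma_v2 = ", signif(x$sigma_v2, 4),
      ", sigma_e2 = ", signif(x$sigma_e2, 4), ")",
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  invisible(x)
}
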