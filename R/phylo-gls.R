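#' Brownian-motion phylogenetic covariance matrix
#'
#' Expected trait covariance among tips under Brownian evolution on a
#' rooted tree: entry (i, j) is the shared root-to-MRCA branch length, the
#' diagonal the root-to-tip path lengths.
#'
#' @param tree An [ape::phylo] rooted tree with branch lengths, or a path /
#'   Newick string readable by [ape::read.tree()].
#' @return A symmetric PSD matrix with tip labels as dimnames.
#' @export
brownian_covariance <- function(tree) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree)
      else ape::read.tree(text = tree)
  }
  if (!inherits(tree, "phylo")) stop("not a phylogenetic tree", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("negative branch lengths", call. = FALSE)
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels", call. = FALSE)
  ape::vcv(tree)
}

#' Generalized least squares with a fixed residual covariance
#'
#' Fits `y = X beta + eps`, `Cov(eps) = sigma^2 Omega`, by the closed form
#' `beta = (X' Omega^-1 X)^-1 X' Omega^-1 y`. The residual scale is
#' estimated by maximum likelihood (`sigma^2 = RSS_gls / n`); standard
#' errors use `sigma^2 (X' Omega^-1 X)^-1`, and t statistics are referred
#' to a t distribution with `n - k` degrees of freedom. With
#' `Omega = I` this reduces exactly to ordinary least squares.
#'
#' @param y Response vector.
#' @param X Design matrix (with intercept column if wanted).
#' @param omega Residual correlation/covariance matrix (default identity),
#'   e.g. from [brownian_covariance()].
#' @param ridge Added to the diagonal (times mean diagonal) if `omega` is
#'   numerically singular (default 1e-8 fallback).
#' @return A `gls_fit` object: coefficients, standard errors, t and p
#'   values, `sigma2`, fitted values, residuals, ML log-likelihood, `AIC`,
#'   `n`, `k`, `n_par`.
#' @export
gls_fit <- function(y, X, omega = NULL, ridge = 1e-8) {
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("dimensions of y and X disagree", call. = FALSE)
  k <- ncol(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(k - 1)))[seq_len(k)]
  qrX <- qr(X)
  if (qrX$rank < k) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):k]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(omega)) omega <- diag(n)
  if (!all(dim(omega) == n)) stop("omega dimension mismatch", call. = FALSE)
  L <- tryCatch(chol(omega), error = function(e) {
    chol(omega + diag(ridge * mean(diag(omega)), n))
  })
  # whiten: solve L' z = v  =>  z' z = v' Omega^-1 v
  wy <- backsolve(L, y, transpose = TRUE)
  wX <- backsolve(L, X, transpose = TRUE)
  fit <- stats::lm.fit(wX, wy)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n
  logdet <- 2 * sum(log(diag(L)))
  loglik <- -0.5 * (n * (log(2 * pi) + 1 + log(max(sigma2, 1e-300))) + logdet)
  XtWX_inv <- chol2inv(qr.R(qr(wX)))
  se <- sqrt(pmax(sigma2 * diag(XtWX_inv), 0))
  tstat <- beta / se
  pval <- 2 * pt(-abs(tstat), df = n - k)
  structure(list(
    coefficients = setNames(as.numeric(beta), colnames(X)),
    se = setNames(se, colnames(X)),
    statistic = setNames(tstat, colnames(X)),
    p.value = setNames(pval, colnames(X)),
    sigma2 = sigma2, fitted = as.numeric(X %*% beta),
    residuals = as.numeric(y - X %*% beta),
    logLik = loglik, AIC = -2 * loglik + 2 * (k + 1),
    n = n, k = k, n_par = k + 1, df_residual = n - k),
    class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat("<gls_fit> n =", x$n, " logLik =", round(x$logLik, 3),
      " AIC =", round(x$AIC, 3), "\n")
  print(cbind(estimate = x$coefficients, se = x$se, t = x$statistic,
              p = x$p.value))
  invisible(x)
}

#' Phylogenetic GLS with exhaustive predictor subset selection
#'
#' Fits the trait against every nonempty subset of the environmental
#' predictors by GLS with a Brownian phylogenetic residual covariance, and
#' ranks models by ML-based AIC. Strains absent from either the trait
#' table or the covariance matrix are dropped (and listed in the result).
#' Replicate rows are averaged to strain means before fitting. The best
#' model's projected phenotype `y_hat = X beta_hat` — the trait's
#' projection onto environmental space, free of the phylogenetic random
#' effect — is returned per strain.
#'
#' @param table Trait/environment tibble with a `strain` column, the trait
#'   column, and the predictor columns.
#' @param trait Name of the trait column (e.g. `"mu_A"` or `"tau_A"`).
#' @param omega Phylogenetic covariance from [brownian_covariance()] (or
#'   any PSD matrix with strain dimnames).
#' @param predictors Character vector of predictor columns; defaults to
#'   the seven environmental variables `elevation`, `mu_temp`,
#'   `sigma_temp`, `mu_humid`, `sigma_humid`, `mu_moist`, `sigma_moist`.
#' @return A `pgls_selection` object: `best` (`gls_fit`), `ranking` tibble
#'   (one row per subset, AIC ascending), `projected` tibble
#'   (`strain`, `fitted`), `dropped` strains.
#' @export
pgls_model_selection <- function(table, trait, omega,
                                 predictors = c("elevation", "mu_temp",
                                                "sigma_temp", "mu_humid",
                                                "sigma_humid", "mu_moist",
                                                "sigma_moist")) {
  predictors <- intersect(predictors, names(table))
  if (length(predictors) < 1) stop("no predictors found", call. = FALSE)
  dat <- table %>%
    dplyr::group_by(.data$strain) %>%
    dplyr::summarise(dplyr::across(dplyr::all_of(c(trait, predictors)),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  common <- intersect(dat$strain, rownames(omega))
  dropped <- setdiff(union(dat$strain, rownames(omega)), common)
  if (length(dropped) > 0)
    message("dropping ", length(dropped), " unmatched strain(s): ",
            paste(dropped, collapse = ", "))
  dat <- dat[match(common, dat$strain), ]
  om <- omega[common, common]
  n <- nrow(dat)
  if (n <= length(predictors) + 2)
    stop("too few strains for subset selection", call. = FALSE)
  y <- dat[[trait]]
  subsets <- unlist(lapply(seq_along(predictors), function(m)
    utils::combn(predictors, m, simplify = FALSE)), recursive = FALSE)
  fits <- lapply(subsets, function(ss) {
    X <- cbind(`(Intercept)` = 1, as.matrix(dat[ss]))
    gls_fit(y, X, om)
  })
  ranking <- tibble::tibble(
    predictors = vapply(subsets, paste, character(1), collapse = "+"),
    k = lengths(subsets),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"))
  ord <- order(ranking$AIC)
  ranking <- ranking[ord, ]
  ranking$delta_AIC <- ranking$AIC - ranking$AIC[1]
  best <- fits[[ord[1]]]
  structure(list(
    best = best,
    best_predictors = subsets[[ord[1]]],
    ranking = ranking,
    projected = tibble::tibble(strain = common, fitted = best$fitted),
    trait = trait, dropped = dropped),
    class = "pgls_selection")
}

#' @export
print.pgls_selection <- function(x, ...) {
  cat("<pgls_selection> trait:", x$trait, "| best subset:",
      paste(x$best_predictors, collapse = "+"), "\n")
  print(head(x$ranking, 5))
  invisible(x)
}
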