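strain_names <- function(n) sprintf("S%03d", seq_len(n))

# Lower-triangular PSD square root via eigendecomposition (tolerant of
# semidefinite matrices; errors on genuinely indefinite input).
psd_sqrt <- function(K) {
  e <- eigen(K, symmetric = TRUE)
  tol <- -1e-8 * max(abs(e$values))
  if (any(e$values < tol))
    stop("kinship matrix is not positive semidefinite", call. = FALSE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(K))
}

#' Simulate replicated strain traits with known heritability
#'
#' Draws trait values under the variance-component model
#' `y_ij = m + u_i + e_ij` with strain effects
#' `u ~ N(0, K sigma_u2)` (K the kinship matrix, identity if omitted) and
#' i.i.d. residuals `e ~ N(0, sigma_e2)`. The generating broad-sense
#' heritability `sigma_u2 / (sigma_u2 + sigma_e2)` is recorded in the
#' attribute `"true_H2"`.
#'
#' @param n_strains,reps Number of strains and replicates per strain.
#' @param sigma_u2,sigma_e2 Strain and residual variances (>= 0).
#' @param kinship Optional covariance structure of the strain effects: a
#'   symmetric PSD matrix or a [vanraden_kinship()] object.
#' @param mean Grand mean `m` (default 0).
#' @param seed Integer seed.
#' @return A tibble `strain`, `replicate`, `value`.
#' @export
simulate_traits <- function(n_strains, reps, sigma_u2 = 1, sigma_e2 = 1,
                            kinship = NULL, mean = 0, seed = 1) {
  if (sigma_u2 < 0 || sigma_e2 < 0)
    stop("variances must be non-negative", call. = FALSE)
  K <- if (is.null(kinship)) diag(n_strains) else as.matrix(kinship)
  if (nrow(K) != n_strains) stop("kinship dimension != n_strains", call. = FALSE)
  strains <- rownames(K) %||% strain_names(n_strains)
  with_local_seed(seed, {
    L <- psd_sqrt(K)
    u <- as.numeric(L %*% rnorm(n_strains)) * sqrt(sigma_u2)
    out <- tibble::tibble(
      strain = rep(strains, each = reps),
      replicate = rep(seq_len(reps), n_strains),
      value = mean + rep(u, each = reps) +
        rnorm(n_strains * reps, 0, sqrt(sigma_e2)))
    attr(out, "true_H2") <- if (sigma_u2 + sigma_e2 > 0)
      sigma_u2 / (sigma_u2 + sigma_e2) else NA_real_
    attr(out, "params") <- list(sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
                                mean = mean, seed = seed)
    out
  })
}

#' Simulate genotypes of selfing homozygous strains
#'
#' Biallelic dosages in `{0, 2}` (near-complete homozygosity of selfing
#' C. elegans strains), with per-site alternate-allele frequencies drawn
#' uniformly from `maf_range`. With `n_founders` set, strains descend from
#' that many founder haplotypes (each strain copies a random founder with
#' per-site mutation probability `mut`), giving the genomic relationship
#' matrix the family-block structure needed for variance components on
#' kinship to be identifiable; without it sites are i.i.d. across strains
#' and kinship is near identity.
#'
#' @param n_strains,n_snps Dimensions of the genotype matrix.
#' @param maf_range Interval within (0, 0.5] for allele frequencies.
#' @param seed Integer seed.
#' @param n_founders Optional number of founder haplotypes.
#' @param mut Per-site mutation probability when copying a founder
#'   (default 0.05).
#' @return An `n_strains x n_snps` matrix of 0/2 dosages, with strain row
#'   names and marker column names.
#' @export
simulate_genotypes <- function(n_strains, n_snps,
                               maf_range = c(0.05, 0.5), seed = 1,
                               n_founders = NULL, mut = 0.05) {
  if (n_snps < 1) stop("n_snps must be >= 1", call. = FALSE)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  with_local_seed(seed, {
    p <- runif(n_snps, maf_range[1], maf_range[2])
    if (is.null(n_founders)) {
      g <- matrix(2 * (runif(n_strains * n_snps) <
                         rep(p, each = n_strains)), n_strains, n_snps)
    } else {
      founders <- matrix(2 * (runif(n_founders * n_snps) <
                                rep(p, each = n_founders)),
                         n_founders, n_snps)
      fam <- sample.int(n_founders, n_strains, replace = TRUE)
      g <- founders[fam, , drop = FALSE]
      flip <- matrix(runif(n_strains * n_snps) < mut, n_strains, n_snps)
      g[flip] <- 2 - g[flip]
    }
    dimnames(g) <- list(strain_names(n_strains),
                        sprintf("M%05d", seq_len(n_snps)))
    g
  })
}

#' Simulate strain habitat environments with an elevational gradient
#'
#' Per-strain isolation-site data mimicking the structure of the field
#' panel: GPS coordinates, habitat elevation, and mean/standard deviation
#' of near-surface temperature, relative humidity and upper-column soil
#' moisture. Temperature decreases with elevation (a 6.5 degC/km lapse
#' rate) and its fluctuation sigma_temp is negatively correlated with
#' elevation, reproducing the collinearity pattern relevant for predictor
#' subset selection.
#'
#' @param n_strains Number of strains.
#' @param seed Integer seed.
#' @param elevation_range Elevation range in metres (default 0-2000).
#' @return A tibble keyed by `strain` with columns `latitude`, `longitude`,
#'   `elevation`, `mu_temp`, `sigma_temp`, `mu_humid`, `sigma_humid`,
#'   `mu_moist`, `sigma_moist`.
#' @export
simulate_strain_environment <- function(n_strains, seed = 1,
                                        elevation_range = c(0, 2000)) {
  with_local_seed(seed, {
    H <- runif(n_strains, elevation_range[1], elevation_range[2])
    tibble::tibble(
      strain = strain_names(n_strains),
      latitude = runif(n_strains, -40, 60),
      longitude = runif(n_strains, -120, 150),
      elevation = H,
      mu_temp = 18 - 6.5 * H / 1000 + rnorm(n_strains, 0, 2),
      sigma_temp = pmax(0.5, 6 - 2 * H / 1000 + rnorm(n_strains, 0, 1)),
      mu_humid = pmin(100, pmax(10, 70 + rnorm(n_strains, 0, 10))),
      sigma_humid = pmax(0.5, 8 + rnorm(n_strains, 0, 2)),
      mu_moist = pmin(0.6, pmax(0.01, 0.25 + rnorm(n_strains, 0, 0.07))),
      sigma_moist = pmax(0.005, 0.05 + rnorm(n_strains, 0, 0.01)))
  })
}

#' Simulate pairwise-distance data under the MLPE model
#'
#' Generates pair-indexed observations
#' `y_ij = beta0 + beta x_ij + u_i + u_j + e_ij` with i.i.d. population
#' effects `u ~ N(0, sigma_u2)` and residuals `e ~ N(0, sigma_e2)`. The
#' predictor is the absolute difference of a latent per-population value,
#' so it carries genuine pairwise-distance structure.
#'
#' @param n_pops Number of populations.
#' @param beta Slope on the pairwise predictor.
#' @param beta0 Intercept (default 0).
#' @param sigma_u2,sigma_e2 Population-effect and residual variances.
#' @param seed Integer seed.
#' @return A tibble `pop1`, `pop2`, `x`, `y` over all `n(n-1)/2` pairs.
#' @export
simulate_mlpe_pairs <- function(n_pops, beta = 0.5, beta0 = 0,
                                sigma_u2 = 1, sigma_e2 = 0.5, seed = 1) {
  with_local_seed(seed, {
    z <- rnorm(n_pops)
    u <- rnorm(n_pops, 0, sqrt(sigma_u2))
    idx <- which(upper.tri(matrix(0, n_pops, n_pops)), arr.ind = TRUE)
    i <- idx[, 1]; j <- idx[, 2]
    x <- abs(z[i] - z[j])
    y <- beta0 + beta * x + u[i] + u[j] +
      rnorm(length(i), 0, sqrt(sigma_e2))
    tibble::tibble(pop1 = strain_names(n_pops)[i],
                   pop2 = strain_names(n_pops)[j], x = x, y = y)
  })
}
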