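#' VanRaden genomic relationship matrix
#'
#' Additive genetic relationship matrix `A = M M' / sum(2 p_i q_i)` where
#' `M` is the dosage matrix with column means `2 p_i` subtracted (allele
#' frequencies `p_i` estimated from the data, `q_i = 1 - p_i`).
#' Monomorphic markers carry no information and are dropped with a
#' message. Dosages are 0/2 for homozygous selfing strains; rare
#' heterozygotes coded 1 are accepted.
#'
#' @param genotypes Dosage matrix (strains x markers, values in 0..2).
#' @return A `kinship_matrix` object: `A`, centered `M`, `allele_freqs`,
#'   `strains`. `as.matrix()` returns `A`.
#' @export
vanraden_kinship <- function(genotypes) {
  g <- as.matrix(genotypes)
  if (nrow(g) < 2) stop("need at least 2 strains", call. = FALSE)
  p <- colMeans(g) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers are monomorphic", call. = FALSE)
  if (any(!poly))
    message("dropping ", sum(!poly), " monomorphic marker(s)")
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  M <- sweep(g, 2, 2 * p)
  denom <- sum(2 * p * (1 - p))
  A <- tcrossprod(M) / denom
  dimnames(A) <- list(rownames(g), rownames(g))
  structure(list(A = A, M = M, allele_freqs = p,
                 strains = rownames(g)),
            class = "kinship_matrix")
}

#' @export
as.matrix.kinship_matrix <- function(x, ...) x$A

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("<kinship_matrix>", nrow(x$A), "strains,", length(x$allele_freqs),
      "markers; mean diagonal", round(mean(diag(x$A)), 4), "\n")
  invisible(x)
}
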