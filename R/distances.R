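#' Pairwise population distance matrices
#'
#' Builds the distance matrices entering the MLPE analysis:
#' trait and elevation values are z-scored across populations (after
#' averaging replicates to population means) and turned into pairwise
#' Euclidean distances; geographic distances are great-circle kilometres on
#' a 6371-km sphere, scaled to `[0, 1]` by the maximum pairwise value;
#' genetic distances are p-distances, the fraction of genotyped sites at
#' which two strains differ. Strains missing coordinates are excluded and
#' listed in the result.
#'
#' @param table Trait tibble with `strain` and trait columns.
#' @param traits Character vector of trait columns (default any of
#'   `mu_A`, `tau_A`, `elevation` present).
#' @param coords Optional tibble `strain`, `latitude`, `longitude`.
#' @param genotypes Optional dosage matrix with strain rownames.
#' @param earth_radius_km Sphere radius (default 6371).
#' @return A `pairwise_distances` object: `populations`, `matrices` (named
#'   list of symmetric zero-diagonal matrices), `pairs` (long tibble, one
#'   row per unordered pair with one column per matrix), `dropped`.
#' @export
pairwise_distances <- function(table, traits = NULL, coords = NULL,
                               genotypes = NULL, earth_radius_km = 6371) {
  if (is.null(traits))
    traits <- intersect(c("mu_A", "tau_A", "elevation"), names(table))
  dat <- table %>%
    dplyr::group_by(.data$strain) %>%
    dplyr::summarise(dplyr::across(dplyr::all_of(traits),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  pops <- dat$strain
  dropped <- character(0)
  if (!is.null(coords)) {
    ok <- pops %in% coords$strain[stats::complete.cases(
      coords[c("latitude", "longitude")])]
    dropped <- pops[!ok]
    if (length(dropped) > 0)
      message("excluding ", length(dropped),
              " strain(s) without coordinates: ",
              paste(dropped, collapse = ", "))
    pops <- pops[ok]
    dat <- dat[ok, ]
  }
  mats <- list()
  for (tr in traits) {
    z <- as.numeric(scale(dat[[tr]]))
    m <- as.matrix(dist(z))
    dimnames(m) <- list(pops, pops)
    mats[[tr]] <- m
  }
  if (!is.null(coords)) {
    cc <- coords[match(pops, coords$strain), ]
    pts <- cbind(cc$longitude, cc$latitude)
    ij <- which(upper.tri(diag(length(pops))), arr.ind = TRUE)
    dkm <- geosphere::distHaversine(pts[ij[, 1], , drop = FALSE],
                                    pts[ij[, 2], , drop = FALSE],
                                    r = earth_radius_km * 1000) / 1000
    gm <- matrix(0, length(pops), length(pops))
    gm[ij] <- dkm
    gm <- gm + t(gm)
    m <- gm / max(gm)
    dimnames(m) <- list(pops, pops)
    mats[["geographic"]] <- m
  }
  if (!is.null(genotypes)) {
    missing_g <- setdiff(pops, rownames(genotypes))
    if (length(missing_g) > 0)
      stop("genotype matrix missing strains present in the trait table: ",
           paste(missing_g, collapse = ", "), call. = FALSE)
    g <- genotypes[match(pops, rownames(genotypes)), , drop = FALSE]
    m <- p_distance(g)
    dimnames(m) <- list(pops, pops)
    mats[["genetic"]] <- m
  }
  idx <- which(upper.tri(diag(length(pops))), arr.ind = TRUE)
  pairs <- tibble::tibble(pop1 = pops[idx[, 1]], pop2 = pops[idx[, 2]])
  for (nm in names(mats)) pairs[[nm]] <- mats[[nm]][idx]
  structure(list(populations = pops, matrices = mats, pairs = pairs,
                 dropped = dropped),
            class = "pairwise_distances")
}

#' Genetic p-distance matrix
#'
#' Fraction of genotyped sites at which two strains' dosages differ.
#'
#' @param genotypes Dosage matrix (strains x markers).
#' @return Symmetric matrix of pairwise p-distances.
#' @export
p_distance <- function(genotypes) {
  n <- nrow(genotypes)
  m <- matrix(0, n, n, dimnames = list(rownames(genotypes),
                                       rownames(genotypes)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- mean(genotypes[i, ] != genotypes[j, ])
    }
  }
  m
}

#' @export
print.pairwise_distances <- function(x, ...) {
  cat("<pairwise_distances>", length(x$populations), "populations;",
      "matrices:", paste(names(x$matrices), collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pairwise_distances <- function(x, ...) x$pairs
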