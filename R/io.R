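# Pixel sets are serialized as run-length strings: runs of consecutive
# columns within one row, "row:colstart+len" joined by ";" (0-based in the
# file, 1-based in memory).
rle_encode_pixels <- function(px) {
  if (is.null(px) || nrow(px) == 0) return("")
  ord <- order(px[, 1], px[, 2])
  r <- px[ord, 1]; cc <- px[ord, 2]
  brk <- c(TRUE, diff(r) != 0 | diff(cc) != 1)
  starts <- which(brk)
  lens <- diff(c(starts, length(r) + 1))
  paste(sprintf("%d:%d+%d", r[starts] - 1L, cc[starts] - 1L, lens),
        collapse = ";")
}

rle_decode_pixels <- function(s) {
  if (is.na(s) || s == "") return(matrix(integer(0), 0, 2))
  runs <- strsplit(s, ";", fixed = TRUE)[[1]]
  m <- regmatches(runs, regexec("^(\\d+):(\\d+)\\+(\\d+)$", runs))
  out <- lapply(m, function(g) {
    r <- as.integer(g[2]); c0 <- as.integer(g[3]); len <- as.integer(g[4])
    cbind(rep(r + 1L, len), c0 + seq_len(len))
  })
  do.call(rbind, out)
}

#' Write / read a blob table
#'
#' CSV serialization of the segmentation output, the interchange format
#' between segmentation and cluster-size estimation (pre-segmented data can
#' enter the pipeline through it). Frame indices and pixel coordinates are
#' 0-based in the file and 1-based in memory; pixel sets are run-length
#' encoded.
#'
#' @param blobs Blob tibble (from [segment_frames()] etc.).
#' @param path CSV file path.
#' @return `write_blob_table` returns `path` invisibly; `read_blob_table`
#'   the blob tibble.
#' @export
write_blob_table <- function(blobs, path) {
  out <- tibble::tibble(
    frame = blobs$frame - 1L, blob_id = blobs$blob_id,
    x = blobs$x - 1, y = blobs$y - 1, area = blobs$area,
    boundary = vapply(blobs$boundary, rle_encode_pixels, character(1)))
  if ("pixels" %in% names(blobs))
    out$pixels <- vapply(blobs$pixels, rle_encode_pixels, character(1))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_blob_table
#' @export
read_blob_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("frame", "blob_id", "x", "y", "area", "boundary")
  miss <- setdiff(required, names(tab))
  if (length(miss) > 0)
    stop("blob table schema violation: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!stats::complete.cases(tab[c("frame", "blob_id", "area")]))
  if (length(bad) > 0)
    stop("blob table schema violation: missing values in row ", bad[1],
         call. = FALSE)
  out <- tibble::tibble(
    frame = as.integer(tab$frame) + 1L, blob_id = as.integer(tab$blob_id),
    x = tab$x + 1, y = tab$y + 1, area = tab$area,
    boundary = lapply(tab$boundary, rle_decode_pixels))
  if ("pixels" %in% names(tab))
    out$pixels <- lapply(tab$pixels, rle_decode_pixels)
  out
}

#' Write ground truth to CSV
#'
#' @param truth Output of [simulate_worms()].
#' @param path CSV path (frames written 0-based).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- truth
  out$frame <- out$frame - 1L
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  tab$frame <- as.integer(tab$frame) + 1L
  tab
}

#' Write rendered frames as PNG files
#'
#' @param frames Named list of 0/1 matrices (as from [render_frames()]).
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Paths, invisibly.
#' @export
write_frames_png <- function(frames, dir, prefix = "frame") {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to write PNG frames", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(frames), function(i) {
    p <- file.path(dir, sprintf("%s_%05d.png", prefix,
                                as.integer(names(frames)[i]) - 1L))
    png::writePNG(frames[[i]] * 1.0, p)
    p
  }, character(1))
  invisible(paths)
}

# GT field of one VCF sample -> dosage (count of non-reference alleles).
gt_to_dosage <- function(gt) {
  al <- strsplit(sub(":.*$", "", gt), "[/|]")
  vapply(al, function(a) {
    a <- suppressWarnings(as.integer(a))
    if (anyNA(a)) return(NA_real_)
    sum(a > 0)
  }, numeric(1))
}

#' Read a genotype matrix from VCF or TSV
#'
#' VCF input (GT field; diploid calls collapsed to 0/1/2 dosage, selfing
#' strains are effectively 0/2) or a plain TSV matrix with a `strain`
#' first column and one column per marker.
#'
#' @param path File path (`.vcf`/`.vcf.gz` or `.tsv`).
#' @return Strains x markers dosage matrix.
#' @export
read_genotype_matrix <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    d <- apply(gt, 2, gt_to_dosage)
    d <- t(d)  # strains x markers
    colnames(d) <- rownames(gt)
    d
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE)
    m <- as.matrix(tab[, -1])
    rownames(m) <- as.character(tab[[1]])
    storage.mode(m) <- "numeric"
    m
  }
}

#' Read and align genetic inputs
#'
#' Reads a Newick phylogeny and/or a genotype matrix and aligns them (and
#' an optional trait table) on the intersection of strain names; unmatched
#' strains are reported.
#'
#' @param tree_path Newick file (optional).
#' @param genotype_path VCF or TSV genotype file (optional).
#' @param traits Optional trait tibble with a `strain` column.
#' @return A list `tree`, `genotypes`, `traits`, `strains` (the common
#'   set), `unmatched`.
#' @export
read_genetic_inputs <- function(tree_path = NULL, genotype_path = NULL,
                                traits = NULL) {
  tree <- NULL
  genotypes <- NULL
  sets <- list()
  if (!is.null(tree_path)) {
    tree <- tryCatch(ape::read.tree(tree_path), error = function(e)
      stop("malformed Newick file '", tree_path, "': ", conditionMessage(e),
           call. = FALSE))
    if (is.null(tree)) stop("malformed Newick file '", tree_path, "'",
                            call. = FALSE)
    sets$tree <- tree$tip.label
  }
  if (!is.null(genotype_path)) {
    genotypes <- read_genotype_matrix(genotype_path)
    sets$genotypes <- rownames(genotypes)
  }
  if (!is.null(traits)) sets$traits <- unique(as.character(traits$strain))
  strains <- Reduce(intersect, sets)
  unmatched <- setdiff(unique(unlist(sets)), strains)
  if (length(unmatched) > 0)
    message("strains not present in all inputs (excluded): ",
            paste(unmatched, collapse = ", "))
  if (!is.null(tree))
    tree <- ape::keep.tip(tree, intersect(tree$tip.label, strains))
  if (!is.null(genotypes))
    genotypes <- genotypes[intersect(rownames(genotypes), strains), ,
                           drop = FALSE]
  if (!is.null(traits))
    traits <- traits[as.character(traits$strain) %in% strains, ]
  list(tree = tree, genotypes = genotypes, traits = traits,
       strains = strains, unmatched = unmatched)
}
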