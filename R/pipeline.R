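#' Run the full synthetic pipeline to disk
#'
#' Simulate a recording, segment it, estimate cluster sizes, compute the
#' aggregation traits, and write every stage's output (CSV) plus a run
#' manifest (JSON with the full configuration, seed, package version and a
#' configuration hash) into `out_dir`. Runs with identical configuration
#' and seed are byte-identical.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [sim_config()].
#' @param window,offset,min_area Segmentation parameters (see
#'   [segment_recording()]).
#' @param max_link_distance Linking radius for [build_temporal_graph()].
#' @param max_lag_fraction See [autocorrelation()].
#' @param strain,replicate Labels recorded in the trait table.
#' @return Invisibly, a list with the stage results and output paths.
#' @export
run_pipeline <- function(out_dir, config = sim_config(),
                         window = 65, offset = 0.2, min_area = NULL,
                         max_link_distance = 15,
                         max_lag_fraction = 1,
                         strain = "SIM", replicate = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulate_worms(config)
  write_ground_truth(truth, file.path(out_dir, "ground_truth.csv"))
  blobs <- segment_recording(truth, config, window, offset, min_area)
  write_blob_table(blobs, file.path(out_dir, "blobs.csv"))
  res <- estimate_cluster_sizes(blobs, config$n_worms, max_link_distance)
  readr::write_csv(
    tibble::tibble(frame = res$estimates$frame - 1L,
                   blob_id = res$estimates$blob_id,
                   status = res$estimates$status,
                   size = res$estimates$size,
                   min = res$estimates$min_size,
                   max = res$estimates$max_size),
    file.path(out_dir, "sizes.csv"))
  fs <- res$frame_sizes
  readr::write_csv(
    tibble::tibble(frame = fs$frame - 1L,
                   sizes = vapply(fs$sizes, paste, character(1),
                                  collapse = " "),
                   total = fs$total, flagged = fs$flagged),
    file.path(out_dir, "frame_sizes.csv"))
  qc <- attr(fs, "qc")
  dt <- 1 / config$frame_rate
  traits <- aggregation_traits(fs, config$n_worms, dt,
                               max_lag_fraction = max_lag_fraction)
  if (!is.null(traits$series) && nrow(traits$series) > 0)
    readr::write_csv(traits$series, file.path(out_dir, "series.csv"))
  trait_tab <- tibble::tibble(strain = strain, replicate = replicate,
                              mu_A = traits$mu_A, tau_A = traits$tau_A,
                              qc_excluded = isTRUE(qc$excluded))
  readr::write_csv(trait_tab, file.path(out_dir, "traits.csv"))
  manifest <- list(
    tool = "wormagg", version = as.character(utils::packageVersion("wormagg")),
    seed = config$rng_seed,
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    qc = qc[c("excluded", "flagged_fraction")])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(truth = truth, blobs = blobs, sizes = res,
                 traits = trait_tab,
                 paths = file.path(out_dir,
                                   c("ground_truth.csv", "blobs.csv",
                                     "sizes.csv", "frame_sizes.csv",
                                     "traits.csv", "manifest.json"))))
}

cli_usage <- function() {
  paste(
    "usage: wormagg <subcommand> [--key value ...]",
    "",
    "subcommands:",
    "  simulate     --out DIR [--seed N --n-worms N --duration S --arena-radius PX]",
    "  segment      --truth ground_truth.csv --out DIR [--window N --offset X]",
    "  track        --blobs blobs.csv --n-worms N --out DIR",
    "  metrics      --frame-sizes frame_sizes.csv --n-worms N --dt S --out DIR",
    "  pgls         --traits traits.csv --tree tree.nwk --trait mu_A --out fit.json",
    "  mlpe         --pairs pairs.csv --response y --predictors x1,x2 --out fit.json",
    "  heritability --traits traits.csv [--genotypes g.tsv|g.vcf] --trait value --out fit.json",
    "  qtlvar       --traits traits.csv --qtl qtl.tsv --background bg.tsv --out fit.json",
    "  all          --out DIR [simulate options]",
    "",
    "Each stage writes a manifest next to its outputs; identical",
    "configuration and seed give byte-identical outputs.",
    sep = "\n")
}

cli_parse_args <- function(argv) {
  opts <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(argv) || startsWith(argv[i + 1L], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      opts[[key]] <- argv[i + 1L]
      i <- i + 2L
    }
  }
  opts
}

cli_config_from_opts <- function(opts) {
  sim_config(
    n_worms = as.integer(opts$n_worms %||% 40),
    arena_radius = as.numeric(opts$arena_radius %||% 500),
    patch_radius = as.numeric(opts$patch_radius %||%
                                (as.numeric(opts$arena_radius %||% 500) / 2)),
    duration = as.numeric(opts$duration %||% 2700),
    frame_rate = as.numeric(opts$frame_rate %||% 8.33),
    leave_rate = as.numeric(opts$leave_rate %||% 0.005),
    rng_seed = as.integer(opts$seed %||% 1))
}

write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(tidy = tidy(fit), glance = glance(fit)),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands (see `cli_pipeline(c("--help"))`
#' for usage). Designed to be driven by the thin Rscript wrapper installed
#' under `inst/cli/wormagg`; returns the exit status instead of quitting so
#' it can be tested in-process.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
cli_pipeline <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0 || argv[1] %in% c("--help", "-h", "help")) {
    cat(cli_usage(), "\n")
    return(invisible(0L))
  }
  sub <- argv[1]
  known <- c("simulate", "segment", "track", "metrics", "pgls", "mlpe",
             "heritability", "qtlvar", "all")
  if (!sub %in% known) {
    message("unknown subcommand: ", sub, "\n", cli_usage())
    return(invisible(2L))
  }
  opts <- tryCatch(cli_parse_args(argv[-1]), error = function(e) e)
  if (inherits(opts, "error")) {
    message(conditionMessage(opts), "\n", cli_usage())
    return(invisible(2L))
  }
  status <- tryCatch({
    switch(sub,
      simulate = {
        cfg <- cli_config_from_opts(opts)
        dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
        truth <- simulate_worms(cfg)
        write_ground_truth(truth, file.path(opts$out, "ground_truth.csv"))
        jsonlite::write_json(
          list(config = unclass(cfg), config_hash = rlang::hash(unclass(cfg))),
          file.path(opts$out, "manifest.json"), auto_unbox = TRUE,
          pretty = TRUE, digits = NA)
      },
      segment = {
        cfg <- cli_config_from_opts(opts)
        truth <- read_ground_truth(opts$truth)
        blobs <- segment_recording(truth, cfg,
                                   window = as.integer(opts$window %||% 65),
                                   offset = as.numeric(opts$offset %||% 0.2))
        dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
        write_blob_table(blobs, file.path(opts$out, "blobs.csv"))
      },
      track = {
        blobs <- read_blob_table(opts$blobs)
        res <- estimate_cluster_sizes(blobs, as.integer(opts$n_worms))
        dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
        readr::write_csv(
          tibble::tibble(frame = res$estimates$frame - 1L,
                         blob_id = res$estimates$blob_id,
                         status = res$estimates$status,
                         size = res$estimates$size,
                         min = res$estimates$min_size,
                         max = res$estimates$max_size),
          file.path(opts$out, "sizes.csv"))
        fs <- res$frame_sizes
        readr::write_csv(
          tibble::tibble(frame = fs$frame - 1L,
                         sizes = vapply(fs$sizes, paste, character(1),
                                        collapse = " "),
                         total = fs$total, flagged = fs$flagged),
          file.path(opts$out, "frame_sizes.csv"))
      },
      metrics = {
        tab <- readr::read_csv(opts$frame_sizes, show_col_types = FALSE)
        sizes <- lapply(strsplit(tab$sizes, " ", fixed = TRUE), as.numeric)
        n <- as.integer(opts$n_worms)
        dt <- as.numeric(opts$dt %||% 0.12)
        tr <- aggregation_traits(sizes, n, dt)
        dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
        readr::write_csv(tibble::tibble(mu_A = tr$mu_A, tau_A = tr$tau_A),
                         file.path(opts$out, "traits.csv"))
      },
      pgls = {
        traits <- readr::read_csv(opts$traits, show_col_types = FALSE)
        omega <- brownian_covariance(opts$tree)
        sel <- pgls_model_selection(traits, opts$trait %||% "mu_A", omega)
        write_fit_json(sel$best, opts$out)
      },
      mlpe = {
        pairs <- readr::read_csv(opts$pairs, show_col_types = FALSE)
        preds <- strsplit(opts$predictors %||% "x", ",")[[1]]
        fit <- mlpe_fit(pairs, opts$response %||% "y", preds)
        write_fit_json(fit, opts$out)
      },
      heritability = {
        traits <- readr::read_csv(opts$traits, show_col_types = FALSE)
        kin <- if (!is.null(opts$genotypes))
          vanraden_kinship(read_genotype_matrix(opts$genotypes)) else NULL
        fit <- reml_heritability(traits, opts$trait %||% "value", kin,
                                 n_boot = as.integer(opts$n_boot %||% 500),
                                 seed = as.integer(opts$seed %||% 1))
        write_fit_json(fit, opts$out)
      },
      qtlvar = {
        traits <- readr::read_csv(opts$traits, show_col_types = FALSE)
        fit <- qtl_variance(
          traits,
          vanraden_kinship(read_genotype_matrix(opts$qtl)),
          vanraden_kinship(read_genotype_matrix(opts$background)),
          trait = opts$trait %||% "value")
        write_fit_json(fit, opts$out)
      },
      all = {
        cfg <- cli_config_from_opts(opts)
        run_pipeline(opts$out, cfg)
      })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
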