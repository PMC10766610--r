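# Screen pipeline: normalize -> score -> randomized runs -> call ------------

#' Validate a screen run configuration
#'
#' A run configuration holds everything that affects results: input/output
#' paths, the QC and hit-calling thresholds, the permutation count and the
#' seed. Thresholds are checked against their documented ranges; the seed is
#' mandatory because the randomized-activity null is stochastic.
#'
#' @param config Named list (typically from a YAML file, see
#'   [run_pipeline()]). Recognized fields: `plate_table`, `library_table`,
#'   `output_dir`, `min_log10_ratio` (default log10(1.25)),
#'   `threshold_log10p` (default -3), `strong_threshold` (default -4),
#'   `viability_floor` (default 0.25), `n_perm` (default 100), `seed`,
#'   `robustify` (default TRUE), `z_scope` (`"plate"`/`"global"`),
#'   `perm_scope` (`"per_plate"`/`"global"`), `direction`, `min_wells`.
#' @return The config with defaults filled in, class `run_config`.
#' @export
run_config <- function(config = list()) {
  defaults <- list(plate_table = NULL, library_table = NULL,
                   output_dir = ".",
                   min_log10_ratio = log10(1.25),
                   threshold_log10p = -3,
                   strong_threshold = -4,
                   viability_floor = 0.25,
                   n_perm = 100L,
                   seed = NULL,
                   robustify = TRUE,
                   z_scope = "plate",
                   perm_scope = "per_plate",
                   direction = "up",
                   min_wells = 2L)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  check_threshold(cfg$threshold_log10p)
  check_threshold(cfg$strong_threshold)
  if (!is.numeric(cfg$min_log10_ratio) || cfg$min_log10_ratio < 0) {
    stop("min_log10_ratio must be non-negative")
  }
  if (cfg$viability_floor < 0 || cfg$viability_floor > 1) {
    stop("viability_floor must lie in [0, 1]")
  }
  if (cfg$n_perm < 1) stop("n_perm must be >= 1")
  if (is.null(cfg$seed)) stop("seed is mandatory")
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_perm <- as.integer(cfg$n_perm)
  stopifnot(cfg$z_scope %in% c("plate", "global"),
            cfg$perm_scope %in% c("per_plate", "global"),
            cfg$direction %in% c("up", "down"))
  class(cfg) <- "run_config"
  cfg
}

# Hash of the result-affecting configuration (paths excluded, so the same
# analysis written to a different location carries the same stamp).
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg <- cfg[setdiff(names(cfg), c("plate_table", "library_table",
                                   "output_dir"))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg[order(names(cfg))], tmp)
  unname(tools::md5sum(tmp))
}

#' Analyze a screen in memory
#'
#' Runs the full deconvolution on a plate-well table: Firefly QC gate,
#' per-plate polynomial normalization, robust z-scoring, gene-level RSA
#' scoring, the randomized-activity permutation null, and hit calling with
#' the plug-in empirical FDR.
#'
#' @param wells Plate-well data frame.
#' @param library Optional `screen_library`.
#' @param min_log10_ratio Firefly QC threshold.
#' @param threshold_log10p,strong_threshold Hit-calling thresholds.
#' @param n_perm Permutations for the null.
#' @param seed Integer seed for the permutation null.
#' @param robustify Robust re-fit pass for the plate polynomials.
#' @param z_scope,perm_scope,direction,min_wells See the stage functions.
#' @return List of class `screen_analysis`: `normalized`, `polynomials`,
#'   `scores`, `null`, `result` (a `hit_call_result`).
#' @export
analyze_screen <- function(wells, library = NULL,
                           min_log10_ratio = log10(1.25),
                           threshold_log10p = -3, strong_threshold = -4,
                           n_perm = 100L, seed = 1L, robustify = TRUE,
                           z_scope = "plate", perm_scope = "per_plate",
                           direction = "up", min_wells = 2L) {
  norm <- normalize_screen(wells, min_log10_ratio = min_log10_ratio,
                           robustify = robustify, z_scope = z_scope)
  scores <- score_genes(norm$wells, library = library,
                        direction = direction, min_wells = min_wells)
  null <- randomized_runs(norm$wells, library = library, n_perm = n_perm,
                          seed = seed, scope = perm_scope,
                          direction = direction, min_wells = min_wells)
  result <- estimate_fdr(scores, null, threshold_log10p = threshold_log10p)
  result$strong_threshold <- strong_threshold
  result$hits$strength <- ifelse(result$hits$rsa_log10p < strong_threshold,
                                 "strong", "weaker")
  structure(list(normalized = norm$wells, polynomials = norm$polynomials,
                 scores = scores, null = null, result = result),
            class = "screen_analysis")
}

#' @export
print.screen_analysis <- function(x, ...) {
  cat("screen_analysis:", nrow(x$normalized), "wells,",
      nrow(x$scores), "genes\n")
  print(x$result)
  invisible(x)
}

#' Run the screen pipeline from a configuration file
#'
#' Executes normalize, score, randomized runs and call in order, writing
#' `normalized_wells.csv`, `plate_polynomials.csv`, `gene_scores.csv`,
#' `hits.csv` and `fdr_report.json` to the configured output directory.
#' Every artifact carries the configuration hash and seed in `#` header
#' comments, and the run is byte-identical under a fixed configuration.
#' Per-stage counts (wells read, QC failures, genes scored, hits) are
#' reported as messages.
#'
#' @param config A `run_config`, a named list, or the path of a YAML file.
#' @return The `screen_analysis`, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "run_config")) config <- run_config(config)
  if (is.null(config$plate_table)) stop("config$plate_table is required")
  hash <- config_hash(config)
  stamp <- c(paste0("config_hash: ", hash),
             paste0("seed: ", config$seed))

  wells <- read_plate_table(config$plate_table)
  message("read ", nrow(wells), " wells from ", config$plate_table)
  library <- if (!is.null(config$library_table)) {
    read_library(config$library_table)
  }
  analysis <- analyze_screen(
    wells, library = library,
    min_log10_ratio = config$min_log10_ratio,
    threshold_log10p = config$threshold_log10p,
    strong_threshold = config$strong_threshold,
    n_perm = config$n_perm, seed = config$seed,
    robustify = config$robustify, z_scope = config$z_scope,
    perm_scope = config$perm_scope, direction = config$direction,
    min_wells = config$min_wells)
  message(sum(!analysis$normalized$qc_pass), " wells failed QC; ",
          nrow(analysis$scores), " genes scored; ",
          analysis$result$n_hits, " hits")

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  norm_cols <- c(PLATE_WELL_COLUMNS, "firefly_log10_ratio", "qc_pass",
                 "qc_reason", "predicted_hibit", "rel_change", "robust_z")
  write_csv_commented(analysis$normalized[norm_cols],
                      out("normalized_wells.csv"), stamp)
  polys <- do.call(rbind, lapply(analysis$polynomials, function(p) {
    data.frame(plate_id = p$plate_id, replicate_id = p$replicate_id,
               c0 = p$coefficients[1], c1 = p$coefficients[2],
               c2 = p$coefficients[3], c3 = p$coefficients[4],
               domain_min = p$fit_domain[1], domain_max = p$fit_domain[2],
               n_points_used = p$n_points_used, stringsAsFactors = FALSE)
  }))
  write_csv_commented(polys, out("plate_polynomials.csv"), stamp)
  write_gene_scores(analysis$scores, out("gene_scores.csv"), stamp)
  hits <- analysis$result$hits
  write_csv_commented(hits, out("hits.csv"), stamp)
  report <- c(sprintf("# config_hash: %s", hash),
              sprintf("# seed: %d", config$seed),
              "{",
              sprintf('  "n_hits": %d,', analysis$result$n_hits),
              sprintf('  "n_strong_hits": %d,',
                      sum(hits$strength == "strong")),
              sprintf('  "n_qc_excluded_genes": %d,',
                      analysis$result$n_qc_excluded_genes),
              sprintf('  "threshold_log10p": %.6g,', config$threshold_log10p),
              sprintf('  "mean_null_exceedance": %.10g,',
                      analysis$result$mean_null_exceedance),
              sprintf('  "fdr_percent": %.10g', analysis$result$fdr_percent),
              "}")
  writeLines(report, out("fdr_report.json"))
  invisible(analysis)
}
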