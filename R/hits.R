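# Randomized-activity permutation null, thresholding, empirical FDR ---------

#' Build a randomized-activity permutation null
#'
#' Shuffles the robust z-scores among QC-passing library wells (within each
#' assay plate for `scope = "per_plate"`, preserving plate structure the
#' normalization may not fully remove) and re-scores every gene with the RSA
#' statistic, `n_perm` times. The resulting per-permutation gene score
#' vectors calibrate the P-value threshold and the empirical FDR.
#'
#' @param normalized Normalized-well data frame ([normalize_wells()]).
#' @param library Optional `screen_library`, passed to [score_genes()].
#' @param n_perm Number of randomizations (>= 1).
#' @param seed Integer seed; the null is deterministic given it.
#' @param scope `"per_plate"` (default) shuffles within each assay plate;
#'   `"global"` shuffles across the whole screen.
#' @param direction Ranking direction, see [rank_wells()].
#' @param min_wells Passed to [score_genes()].
#' @return Object of class `permutation_null`: matrix `log10p` of dimension
#'   `n_perm x n_genes` (NA for QC-excluded genes), `gene_id`, `n_perm`,
#'   `seed`.
#' @export
randomized_runs <- function(normalized, library = NULL, n_perm = 100L,
                            seed = 1L, scope = c("per_plate", "global"),
                            direction = c("up", "down"), min_wells = 2L) {
  scope <- match.arg(scope)
  direction <- match.arg(direction)
  stopifnot(n_perm >= 1)
  scorable <- normalized$qc_pass & normalized$well_class == "library" &
    is.finite(normalized$robust_z)
  if (!any(scorable)) stop("no QC-passing library wells to permute")
  key <- plate_key(normalized)
  groups <- if (scope == "per_plate") {
    split(which(scorable), key[scorable])
  } else {
    list(which(scorable))
  }
  set.seed(as.integer(seed))
  perm <- normalized
  res <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    for (g in groups) {
      perm$robust_z[g] <- normalized$robust_z[g][sample.int(length(g))]
    }
    sc <- score_genes(perm, library = library, direction = direction,
                      min_wells = min_wells)
    res[[b]] <- stats::setNames(sc$rsa_log10p, sc$gene_id)
  }
  gene_id <- names(res[[1]])
  structure(list(log10p = do.call(rbind, res),
                 gene_id = gene_id,
                 n_perm = as.integer(n_perm),
                 scope = scope,
                 seed = as.integer(seed)),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("permutation_null:", x$n_perm, "randomization(s) of",
      length(x$gene_id), "genes (scope:", x$scope, ", seed:", x$seed, ")\n")
  invisible(x)
}

check_threshold <- function(threshold_log10p) {
  if (!is.numeric(threshold_log10p) || threshold_log10p >= 0) {
    stop("threshold_log10p must be negative (a log10 P value)")
  }
  threshold_log10p
}

#' Plug-in empirical FDR from the permutation null
#'
#' `FDR = mean over permutations of #(null log10 P < threshold) /
#' max(1, #(observed log10 P < threshold))`, reported as a percentage
#' alongside the hit list (observed genes below threshold, ordered by
#' `rsa_log10p`, ties broken by descending `max_rel_change` then gene).
#'
#' @param observed Gene-score data frame ([score_genes()]).
#' @param null A `permutation_null` from [randomized_runs()] covering the
#'   same gene set.
#' @param threshold_log10p Negative log10 P threshold (default -3).
#' @return Object of class `hit_call_result`; see [call_hits()] for the
#'   fields, plus `fdr_percent` and `mean_null_exceedance`.
#' @export
estimate_fdr <- function(observed, null, threshold_log10p = -3) {
  check_threshold(threshold_log10p)
  stopifnot(inherits(null, "permutation_null"))
  if (!setequal(observed$gene_id, null$gene_id)) {
    stop("observed scores and permutation null cover different gene sets")
  }
  result <- call_hits(observed, threshold_log10p = threshold_log10p)
  null_exceed <- rowSums(null$log10p < threshold_log10p, na.rm = TRUE)
  result$mean_null_exceedance <- mean(null_exceed)
  result$fdr_percent <- if (result$n_hits == 0L) {
    0
  } else {
    100 * result$mean_null_exceedance / result$n_hits
  }
  result$n_perm <- null$n_perm
  result
}

#' Call screen hits at a log10 P threshold
#'
#' Genes with `rsa_log10p` below `threshold_log10p` are hits, annotated
#' `"strong"` below `strong_threshold` and `"weaker"` otherwise. Genes with
#' `qc_pass = FALSE` are counted in `n_qc_excluded_genes` and never called.
#'
#' @param observed Gene-score data frame ([score_genes()]).
#' @param threshold_log10p Negative log10 P hit threshold (default -3).
#' @param strong_threshold Stricter threshold separating strong hits
#'   (default -4).
#' @return Object of class `hit_call_result`: `hits` (gene-score rows with a
#'   `strength` column, sorted), `n_hits`, `n_qc_excluded_genes`,
#'   `threshold_log10p`.
#' @export
call_hits <- function(observed, threshold_log10p = -3, strong_threshold = -4) {
  check_threshold(threshold_log10p)
  check_threshold(strong_threshold)
  ok <- observed$qc_pass & !is.na(observed$rsa_log10p)
  is_hit <- ok & observed$rsa_log10p < threshold_log10p
  hits <- observed[is_hit, , drop = FALSE]
  ord <- order(hits$rsa_log10p, -hits$max_rel_change, hits$gene_id)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  hits$strength <- ifelse(hits$rsa_log10p < strong_threshold,
                          "strong", "weaker")
  structure(list(hits = hits,
                 n_hits = nrow(hits),
                 n_qc_excluded_genes = sum(!observed$qc_pass),
                 threshold_log10p = threshold_log10p,
                 strong_threshold = strong_threshold,
                 fdr_percent = NA_real_,
                 mean_null_exceedance = NA_real_),
            class = "hit_call_result")
}

#' @export
print.hit_call_result <- function(x, ...) {
  cat(sprintf("hit_call_result: %d hit(s) at log10 P < %g (%d strong), %d QC-excluded gene(s)\n",
              x$n_hits, x$threshold_log10p,
              sum(x$hits$strength == "strong"), x$n_qc_excluded_genes))
  if (!is.na(x$fdr_percent)) {
    cat(sprintf("  empirical FDR: %.1f%% (mean null exceedance %.2f over %d permutations)\n",
                x$fdr_percent, x$mean_null_exceedance, x$n_perm))
  }
  invisible(x)
}
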