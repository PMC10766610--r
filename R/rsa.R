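# Gene-level RSA statistic ---------------------------------------------------
#
# Wells are ranked screen-wide by their robust z-score (rank 1 = strongest
# rescue). A gene with N wells at ranks r_1 < ... < r_N among M ranked wells
# is scored by the minimum over j of the hypergeometric upper-tail
# probability P(X >= j) for X ~ Hypergeometric(M, N, r_j): the chance that a
# random placement of the gene's N wells puts at least j of them within the
# top r_j ranks. The minimum is taken over all head subsets, so the score
# rewards genes whose wells are collectively, not just singly, high-ranked.

#' Rank normalized wells for the RSA statistic
#'
#' Sorts QC-passing library wells by robust z-score (descending for
#' `direction = "up"`, the rescue direction). Tied wells all receive the
#' largest (most conservative) rank of the tied block; the stored well order
#' breaks ties by plate and well identifier for determinism.
#'
#' @param normalized Normalized-well data frame ([normalize_wells()]);
#'   only rows with `qc_pass`, `well_class == "library"` and finite
#'   `robust_z` are ranked.
#' @param direction `"up"` scores signal increase (rescue), `"down"` signal
#'   decrease.
#' @return Object of class `ranked_activity`: a data frame `wells` (keys,
#'   `robust_z`, `rel_change`, conservative `rank`), the total count `M`,
#'   and `gene_ranks` (named list of sorted per-gene rank vectors).
#' @export
rank_wells <- function(normalized, direction = c("up", "down")) {
  direction <- match.arg(direction)
  use <- normalized$qc_pass & normalized$well_class == "library" &
    is.finite(normalized$robust_z)
  w <- normalized[use, c("plate_id", "replicate_id", "well_id", "gene_id",
                         "robust_z", "rel_change")]
  if (nrow(w) == 0L) stop("no QC-passing library wells to rank")
  z <- if (direction == "up") w$robust_z else -w$robust_z
  # conservative tie handling: every tied well takes the block's worst rank
  w$rank <- rank(-z, ties.method = "max")
  ord <- order(w$rank, w$plate_id, w$replicate_id, w$well_id)
  w <- w[ord, ]
  rownames(w) <- NULL
  gene_ranks <- lapply(split(w$rank, w$gene_id), sort)
  structure(list(wells = w, M = nrow(w), direction = direction,
                 gene_ranks = gene_ranks),
            class = "ranked_activity")
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= j)` for `X ~ Hypergeometric(M, N, r)`: drawing `r` of `M` wells
#' without replacement, the probability that at least `j` of the `N` special
#' wells are drawn. Computed in log space via [stats::phyper()], so it is
#' accurate for screen-sized `M` (thousands of wells) where direct
#' factorials overflow.
#'
#' @param j Minimum number of special wells drawn (1 <= j <= N).
#' @param M Population size (total ranked wells).
#' @param N Number of special wells (the gene's wells); N <= M.
#' @param r Number of draws (the rank cutoff); j <= r <= M.
#' @return The upper-tail probability; vectorized over its arguments.
#' @examples
#' hypergeom_sf(2, 10, 2, 2)  # C(2,2) / C(10,2) = 1/45
#' @export
hypergeom_sf <- function(j, M, N, r) {
  n <- max(length(j), length(M), length(N), length(r))
  j <- rep_len(as.numeric(j), n); M <- rep_len(as.numeric(M), n)
  N <- rep_len(as.numeric(N), n); r <- rep_len(as.numeric(r), n)
  if (any(j < 1 | j > N | N > M | r < j | r > M)) {
    stop("require 1 <= j <= N <= M and j <= r <= M")
  }
  stats::phyper(j - 1, N, M - N, r, lower.tail = FALSE)
}

log10_hypergeom_sf <- function(j, M, N, r) {
  stats::phyper(j - 1, N, M - N, r, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Gene-level RSA score from ranks
#'
#' `log10` of the minimum over `j` of [hypergeom_sf()]`(j, M, N, r_j)`,
#' where `r_1 <= ... <= r_N` are the gene's well ranks among `M` ranked
#' wells. No multiplicity correction is applied; calibration is supplied by
#' the permutation (randomized-activity) null.
#'
#' @param ranks Integer vector of the gene's well ranks (1-based).
#' @param M Total number of ranked wells.
#' @return Non-positive real, `log10` of the RSA P value.
#' @examples
#' rsa_log10p(c(1, 2), 10)     # log10(1/45)
#' rsa_log10p(c(9, 10), 10)    # 0 (P = 1)
#' @export
rsa_log10p <- function(ranks, M) {
  r <- sort(as.numeric(ranks))
  N <- length(r)
  if (N < 1L) stop("ranks must be non-empty")
  if (any(r < 1) || any(r > M) || N > M) {
    stop("ranks must lie in 1..M and N <= M")
  }
  min(log10_hypergeom_sf(seq_len(N), M, N, r))
}

# Vectorized scoring of all genes from a ranked activity object; used by both
# score_genes and the permutation engine. Returns named vector of log10 P.
score_from_ranks <- function(ranked) {
  gr <- ranked$gene_ranks
  n_per <- lengths(gr)
  r <- unlist(gr, use.names = FALSE)
  j <- sequence(n_per)
  N <- rep(n_per, times = n_per)
  lp <- log10_hypergeom_sf(j, ranked$M, N, r)
  gene <- rep(names(gr), times = n_per)
  vapply(split(lp, gene), min, numeric(1))[names(gr)]
}

#' Score genes with the RSA statistic
#'
#' Ranks QC-passing library wells and computes, per gene, the RSA
#' `rsa_log10p` plus the maximum `rel_change` across the gene's passing
#' wells. Genes with fewer than `min_wells` passing wells (e.g. infection
#' failure of the guide pool) are reported with `qc_pass = FALSE` and an
#' absent (`NA`) score rather than a score of zero.
#'
#' @param normalized Normalized-well data frame ([normalize_wells()]).
#' @param library Optional `screen_library`; when supplied, every well gene
#'   must be in the library (mismatches abort with the offenders listed) and
#'   all library genes are reported, including those with no passing wells.
#' @param direction Ranking direction, see [rank_wells()].
#' @param min_wells Minimum QC-passing wells for a gene to be scored.
#' @return Data frame of class `gene_scores` with columns `gene_id`,
#'   `rsa_log10p`, `max_rel_change`, `n_wells_used`, `qc_pass`.
#' @export
score_genes <- function(normalized, library = NULL,
                        direction = c("up", "down"), min_wells = 2L) {
  direction <- match.arg(direction)
  lib_wells <- normalized$well_class == "library"
  well_genes <- unique(normalized$gene_id[lib_wells])
  if (!is.null(library)) {
    stopifnot(inherits(library, "screen_library"))
    offenders <- setdiff(well_genes, names(library$genes))
    if (length(offenders) > 0L) {
      stop("well gene_id(s) not in library: ",
           paste(offenders, collapse = ", "))
    }
    all_genes <- names(library$genes)
  } else {
    all_genes <- sort(well_genes)
  }
  ranked <- rank_wells(normalized, direction = direction)
  lp <- score_from_ranks(ranked)
  n_used <- lengths(ranked$gene_ranks)
  max_rel <- vapply(split(ranked$wells$rel_change, ranked$wells$gene_id),
                    max, numeric(1))

  scores <- data.frame(gene_id = all_genes,
                       rsa_log10p = NA_real_,
                       max_rel_change = NA_real_,
                       n_wells_used = 0L,
                       qc_pass = FALSE,
                       stringsAsFactors = FALSE)
  idx <- match(names(lp), scores$gene_id)
  scores$n_wells_used[idx] <- unname(n_used)
  scores$max_rel_change[idx] <- unname(max_rel[names(lp)])
  ok <- scores$n_wells_used >= min_wells
  scores$qc_pass <- ok
  scores$rsa_log10p[idx] <- ifelse(ok[idx], unname(lp), NA_real_)
  scores$rsa_log10p[!ok] <- NA_real_
  class(scores) <- c("gene_scores", "data.frame")
  scores
}
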