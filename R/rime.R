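#' @importFrom stats pbinom
NULL

#' Nominate interactors by per-replicate count threshold and IgG exclusion
#'
#' A protein is a hit iff its spectral count is at least `min_count` in
#' every bait replicate and it does not pass the same threshold in any IgG
#' replicate (membership in the IgG-passing set disqualifies, mirroring a
#' Venn-diagram exclusion against the control arm).
#'
#' @param table a `spectral_counts` object
#' @param min_count per-replicate spectral-count threshold (default 5)
#' @return data frame of hits: `protein_id`, `mode` (`"venn"`),
#'   `n_bait_replicates_detected`, `min_bait_count`
#' @export
nominate_venn <- function(table, min_count = 5) {
  stopifnot(inherits(table, "spectral_counts"))
  bait <- table$counts[, table$arms$arm == "bait", drop = FALSE]
  igg <- table$counts[, table$arms$arm == "IgG", drop = FALSE]
  if (ncol(bait) < 2) stop("venn nomination needs >= 2 bait replicates")
  if (ncol(igg) < 1) stop("venn nomination needs IgG control replicates")
  pass_bait <- rowSums(bait >= min_count) == ncol(bait)
  pass_igg <- rowSums(igg >= min_count) > 0
  hit <- pass_bait & !pass_igg
  min_bait <- do.call(pmin, as.data.frame(bait))
  out <- data.frame(protein_id = rownames(table$counts),
                    mode = "venn",
                    n_bait_replicates_detected = rowSums(bait > 0),
                    min_bait_count = min_bait,
                    stringsAsFactors = FALSE)[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nominate interactors by FDR-controlled enrichment over IgG
#'
#' Per protein, bait and IgG counts are summed across replicates and
#' enrichment of the bait rate over the IgG rate is tested one-sided with
#' a Poisson rate-ratio test conditional on the protein total (a binomial
#' test with success probability equal to the bait arm's share of total
#' counts, the per-arm offset). P-values are Benjamini-Hochberg adjusted
#' across tested proteins. A hit must satisfy `q <= q_max`, be detected
#' (count > 0) in at least `min_detected` of the bait samples, and have
#' bait rate exceeding IgG rate. Proteins with zero counts in both arms
#' are untested.
#'
#' @param table a `spectral_counts` object
#' @param q_max FDR cutoff (default 0.1)
#' @param min_detected minimum number of bait samples with detection
#'   (default 2)
#' @param n_samples number of bait samples expected (default 4); detection
#'   is assessed over the bait columns present
#' @return data frame over tested proteins, hits first, sorted by q:
#'   `protein_id`, `mode` (`"fdr"`), `n_bait_replicates_detected`,
#'   `bait_sum`, `igg_sum`, `rate_ratio`, `p`, `q`, `hit`
#' @export
nominate_fdr <- function(table, q_max = 0.1, min_detected = 2, n_samples = 4) {
  stopifnot(inherits(table, "spectral_counts"))
  bait <- table$counts[, table$arms$arm == "bait", drop = FALSE]
  igg <- table$counts[, table$arms$arm == "IgG", drop = FALSE]
  if (ncol(bait) < n_samples) {
    stop(sprintf("fdr nomination expects >= %d bait replicates", n_samples))
  }
  if (ncol(igg) < 1) stop("fdr nomination needs >= 1 IgG replicate")
  if (sum(table$counts) == 0) stop("all-zero spectral-count table")
  bait_sum <- rowSums(bait)
  igg_sum <- rowSums(igg)
  t_bait <- sum(bait_sum)
  t_igg <- sum(igg_sum)
  tested <- bait_sum + igg_sum > 0
  p0 <- t_bait / (t_bait + t_igg)
  n_tot <- bait_sum + igg_sum
  p <- rep(NA_real_, length(bait_sum))
  p[tested] <- stats::pbinom(bait_sum[tested] - 1, n_tot[tested], p0,
                             lower.tail = FALSE)
  q <- rep(NA_real_, length(p))
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  n_det <- rowSums(bait > 0)
  rate_bait <- bait_sum / t_bait
  rate_igg <- if (t_igg > 0) igg_sum / t_igg else rep(0, length(igg_sum))
  hit <- tested & q <= q_max & n_det >= min_detected & rate_bait > rate_igg
  hit[is.na(hit)] <- FALSE
  out <- data.frame(protein_id = rownames(table$counts),
                    mode = "fdr",
                    n_bait_replicates_detected = n_det,
                    bait_sum = bait_sum, igg_sum = igg_sum,
                    rate_ratio = ifelse(rate_igg > 0, rate_bait / rate_igg, Inf),
                    p = p, q = q, hit = hit,
                    stringsAsFactors = FALSE)
  out <- out[tested, , drop = FALSE]
  out <- out[order(!out$hit, out$q, out$p, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split two conditions' interactor lists into shared and specific sets
#'
#' @param hits_cond1,hits_cond2 hit data frames from the same nomination
#'   mode ([nominate_venn()] or [nominate_fdr()]; for fdr mode only rows
#'   with `hit == TRUE` are used)
#' @return list with `cond1_only`, `cond2_only`, `shared` — three disjoint
#'   protein id sets whose union is the union of both hit lists
#' @export
compare_conditions <- function(hits_cond1, hits_cond2) {
  mode1 <- unique(hits_cond1$mode); mode2 <- unique(hits_cond2$mode)
  if (length(mode1) > 1 || length(mode2) > 1 ||
      (length(mode1) && length(mode2) && !identical(mode1, mode2))) {
    stop("hit lists must come from the same nomination mode")
  }
  ids <- function(h) {
    if ("hit" %in% names(h)) h$protein_id[h$hit] else h$protein_id
  }
  a <- unique(ids(hits_cond1)); b <- unique(ids(hits_cond2))
  list(cond1_only = setdiff(a, b), cond2_only = setdiff(b, a),
       shared = intersect(a, b))
}
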