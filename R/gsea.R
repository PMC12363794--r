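# Pre-ranked GSEA with gene-label permutations.
#
# The enrichment score is the maximum deviation of the running sum that
# adds |statistic|^p (normalized to sum 1 over the set) at member genes
# and subtracts 1/(N - n) at non-members; |ES| <= 1 by construction.
# When the positive and negative deviations tie exactly in magnitude the
# positive one is reported (documented tie-break).

gsea_es <- function(stat_abs, hit_idx, weight_p = 1,
                    return_peak = FALSE) {
  N <- length(stat_abs)
  n <- length(hit_idx)
  hit_idx <- sort(hit_idx)
  w <- stat_abs[hit_idx]^weight_p
  sw <- sum(w)
  if (sw == 0) w <- rep(1, n) else w <- w / sw
  if (sw == 0) w <- w / n
  cumw <- cumsum(w)
  miss_unit <- 1 / (N - n)
  # running sum just after each hit, and just before each hit
  after <- cumw - (hit_idx - seq_len(n)) * miss_unit
  before <- c(0, cumw[-n]) - (hit_idx - seq_len(n)) * miss_unit
  hi <- max(0, after)
  lo <- min(0, before)
  # ties between the positive and negative deviation (possible exactly,
  # e.g. symmetric hit placements) resolve to the positive side; the
  # comparison allows for floating-point noise in the running sums
  es <- if (hi + lo >= -1e-9 * max(hi, -lo, 1)) hi else lo
  if (!return_peak) return(es)
  if (es >= 0) {
    peak <- which.max(after)
    leading <- hit_idx[seq_len(peak)]
  } else {
    peak <- which.min(before)
    leading <- hit_idx[peak:n]
  }
  list(es = es, leading = leading)
}

#' Pre-ranked gene set enrichment analysis with permutation FDR
#'
#' Computes the weighted Kolmogorov-Smirnov-style enrichment score for
#' each gene set against a signed ranking, normalizes against a null of
#' gene-label permutations (random sets of matching size drawn from the
#' ranked list), and estimates FDR q-values with the standard NES-based
#' ratio estimator. NES is ES divided by the mean |permutation ES| of
#' matching sign; the nominal p-value is the fraction of same-sign
#' permutation scores at least as extreme. Permutation null distributions
#' are shared between gene sets of equal size (under gene-label
#' permutation the null depends only on set size).
#'
#' @param ranking named numeric vector of signed ranking statistics; names
#'   are gene ids, no duplicates (it is sorted internally)
#' @param genesets named list of gene id vectors
#' @param n_perm number of gene-label permutations (>= 100; the study
#'   default for bulk contrasts is 10000)
#' @param seed integer seed making the permutations reproducible
#' @param weight_p exponent on |statistic| for hit increments (default 1)
#' @return data frame, one row per set, sorted by q then nominal p:
#'   `set`, `size`, `es`, `nes`, `p`, `q`, `leading_edge` (comma-joined
#'   gene ids); `n_perm` and `seed` are attached as attributes
#' @export
gsea_preranked <- function(ranking, genesets, n_perm = 1000L, seed = 1L,
                           weight_p = 1) {
  if (anyDuplicated(names(ranking))) stop("duplicate genes in ranking")
  if (n_perm < 100) stop("n_perm must be >= 100")
  stopifnot(length(genesets) >= 1, !is.null(names(genesets)))
  ranking <- sort(ranking, decreasing = TRUE)
  genes <- names(ranking)
  N <- length(ranking)
  stat_abs <- abs(ranking)

  hit_lists <- lapply(genesets, function(gs) {
    gs <- unique(gs)
    if (length(gs) > N) stop("gene set larger than the ranked list")
    idx <- which(genes %in% gs)
    if (!length(idx)) stop("gene set has no genes in the ranked list")
    idx
  })
  sizes <- lengths(hit_lists)

  obs <- lapply(hit_lists, gsea_es, stat_abs = stat_abs,
                weight_p = weight_p, return_peak = TRUE)
  es <- vapply(obs, `[[`, numeric(1), "es")

  set.seed(as.integer(seed))
  perm_by_size <- list()
  for (n in sort(unique(sizes))) {
    perm_by_size[[as.character(n)]] <- vapply(seq_len(n_perm), function(i) {
      gsea_es(stat_abs, sample.int(N, n), weight_p = weight_p)
    }, numeric(1))
  }

  nes <- numeric(length(es)); p <- numeric(length(es))
  perm_nes_all <- vector("list", length(es))
  for (i in seq_along(es)) {
    pe <- perm_by_size[[as.character(sizes[i])]]
    pos_mean <- mean(pe[pe >= 0])
    neg_mean <- mean(abs(pe[pe < 0]))
    norm_perm <- ifelse(pe >= 0,
                        if (is.nan(pos_mean)) NA_real_ else pe / pos_mean,
                        if (is.nan(neg_mean)) NA_real_ else pe / neg_mean)
    if (es[i] >= 0) {
      same <- pe[pe >= 0]
      nes[i] <- if (is.nan(pos_mean) || pos_mean == 0) 0 else es[i] / pos_mean
    } else {
      same <- pe[pe < 0]
      nes[i] <- if (is.nan(neg_mean) || neg_mean == 0) 0 else es[i] / neg_mean
    }
    p[i] <- if (length(same)) {
      (1 + sum(abs(same) >= abs(es[i]))) / (1 + length(same))
    } else 1
    perm_nes_all[[i]] <- norm_perm[!is.na(norm_perm)]
  }

  pool <- unlist(perm_nes_all)
  q <- vapply(seq_along(nes), function(i) {
    if (nes[i] >= 0) {
      num_den <- sum(pool >= 0)
      num <- if (num_den) sum(pool >= nes[i]) / num_den else 0
      obs_den <- sum(nes >= 0)
      den <- if (obs_den) sum(nes >= nes[i]) / obs_den else 1
    } else {
      num_den <- sum(pool < 0)
      num <- if (num_den) sum(pool <= nes[i]) / num_den else 0
      obs_den <- sum(nes < 0)
      den <- if (obs_den) sum(nes <= nes[i]) / obs_den else 1
    }
    if (den == 0) return(0)
    min(1, num / den)
  }, numeric(1))

  out <- data.frame(set = names(genesets), size = as.integer(sizes),
                    es = es, nes = nes, p = p, q = q,
                    leading_edge = vapply(obs, function(o) {
                      paste(genes[o$leading], collapse = ",")
                    }, character(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$q, out$p, -abs(out$nes)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_perm") <- as.integer(n_perm)
  attr(out, "seed") <- as.integer(seed)
  out
}
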