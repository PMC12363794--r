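#' @importFrom stats median sd pnorm predict smooth.spline var
NULL

#' Depth-normalize and log-transform a count matrix
#'
#' Each cell's counts are scaled to the median cell total, then log1p
#' transformed. Cells with zero total counts are dropped with a warning.
#'
#' @param counts genes x cells matrix (sparse or dense, non-negative)
#' @return sparse genes x cells matrix of log1p-normalized expression;
#'   the per-cell scaling factors are attached as attribute
#'   `"size_factors"`
#' @export
normalize_log <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  totals <- Matrix::colSums(counts)
  zero <- totals == 0
  if (any(zero)) {
    warning(sprintf("dropping %d cell(s) with zero total counts", sum(zero)))
    counts <- counts[, !zero, drop = FALSE]
    totals <- totals[!zero]
  }
  target <- stats::median(totals)
  sf <- totals / target
  norm <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  norm@x <- norm@x / rep.int(sf, diff(norm@p))
  norm@x <- log1p(norm@x)
  attr(norm, "size_factors") <- sf
  norm
}

#' Score a gene signature per cell as a mean of per-gene z-scores
#'
#' Every member gene is z-scored across cells (mean 0, SD 1), and the
#' per-cell score is the mean z over member genes. Genes with zero
#' variance carry no ranking information and are excluded with a warning;
#' a set whose overlap with the matrix is empty (or entirely constant)
#' is an error.
#'
#' @param norm_expr normalized genes x cells matrix (see [normalize_log()])
#' @param geneset character vector of member gene ids
#' @param name gene-set name used in messages (default
#'   `deparse(substitute(geneset))`)
#' @return numeric vector of per-cell scores (Z-score units), named by cell
#' @export
score_signature <- function(norm_expr, geneset, name = NULL) {
  if (is.null(name)) name <- "geneset"
  members <- intersect(unique(geneset), rownames(norm_expr))
  if (!length(members)) {
    stop(sprintf("gene set '%s' has no overlap with the expression matrix", name))
  }
  x <- as.matrix(norm_expr[members, , drop = FALSE])
  mu <- rowMeans(x)
  s <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  constant <- s == 0 | !is.finite(s)
  if (all(constant)) {
    stop(sprintf("gene set '%s' contains only zero-variance genes", name))
  }
  if (any(constant)) {
    warning(sprintf("excluding %d zero-variance gene(s) from set '%s'",
                    sum(constant), name))
    x <- x[!constant, , drop = FALSE]
    mu <- mu[!constant]
    s <- s[!constant]
  }
  z <- (x - mu) / s
  colMeans(z)
}

#' Score several gene sets into a cells x sets matrix
#'
#' @param norm_expr normalized genes x cells matrix
#' @param genesets named list of gene id vectors (e.g. from [read_gmt()])
#' @return cells x sets numeric matrix of signature scores
#' @export
score_signatures <- function(norm_expr, genesets) {
  stopifnot(length(genesets) >= 1, !is.null(names(genesets)))
  scores <- vapply(names(genesets), function(nm) {
    score_signature(norm_expr, genesets[[nm]], name = nm)
  }, numeric(ncol(norm_expr)))
  rownames(scores) <- colnames(norm_expr)
  scores
}

argmax_with_margin <- function(score_row, tie_tol = .Machine$double.eps^0.5) {
  o <- order(score_row, decreasing = TRUE)
  top <- o[1]; second <- o[2]
  margin <- score_row[top] - score_row[second]
  ambiguous <- margin <= tie_tol
  list(label = names(score_row)[top],
       runner_up = names(score_row)[second],
       margin = unname(margin), ambiguous = ambiguous)
}

#' Assign epithelial subtype labels from marker-set scores
#'
#' At cell level, each cell is labelled with the marker set of maximal
#' score; at cluster level (the default analysis granularity) scores are
#' first averaged within clusters and each cluster is labelled by argmax
#' of the cluster means, which all member cells inherit. The margin (top
#' minus runner-up score) is reported; ties at machine precision are
#' labelled `"ambiguous"` with both candidates listed.
#'
#' @param scores cells x marker-sets matrix from [score_signatures()]
#' @param level `"cluster"` or `"cell"`
#' @param clusters cluster label per cell (required for cluster level)
#' @return data frame with `cell_id`, `subtype`, `margin`, `ambiguous`,
#'   `runner_up` and (cluster level) `cluster`
#' @export
assign_subtype <- function(scores, level = c("cluster", "cell"),
                           clusters = NULL) {
  level <- match.arg(level)
  if (ncol(scores) < 2) stop("subtype assignment needs >= 2 marker sets")
  if (level == "cell") {
    res <- apply(scores, 1, argmax_with_margin)
    out <- data.frame(cell_id = rownames(scores),
                      subtype = vapply(res, `[[`, character(1), "label"),
                      runner_up = vapply(res, `[[`, character(1), "runner_up"),
                      margin = vapply(res, `[[`, numeric(1), "margin"),
                      ambiguous = vapply(res, `[[`, logical(1), "ambiguous"),
                      stringsAsFactors = FALSE)
    out$subtype[out$ambiguous] <- "ambiguous"
    rownames(out) <- NULL
    return(out)
  }
  if (is.null(clusters)) stop("cluster-level assignment needs cluster labels")
  stopifnot(length(clusters) == nrow(scores))
  cl_means <- apply(scores, 2, function(col) tapply(col, clusters, mean))
  if (is.null(dim(cl_means))) cl_means <- matrix(cl_means, nrow = 1,
                                                 dimnames = list(unique(clusters), colnames(scores)))
  res <- apply(cl_means, 1, argmax_with_margin)
  cl_lab <- vapply(res, `[[`, character(1), "label")
  cl_amb <- vapply(res, `[[`, logical(1), "ambiguous")
  cl_lab[cl_amb] <- "ambiguous"
  idx <- match(as.character(clusters), rownames(cl_means))
  out <- data.frame(cell_id = rownames(scores),
                    cluster = as.character(clusters),
                    subtype = cl_lab[idx],
                    runner_up = vapply(res, `[[`, character(1), "runner_up")[idx],
                    margin = vapply(res, `[[`, numeric(1), "margin")[idx],
                    ambiguous = cl_amb[idx],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assign master-regulator transcription-factor modules per cell
#'
#' Each cell is assigned to the TF group of maximal signature score, with
#' the field's module numbering: NEPC-associated TFs are module 0,
#' transition-associated module 1, adenocarcinoma-associated module 2.
#' Exact ties are resolved deterministically in that fixed group order and
#' flagged `ambiguous`. Per-module mean pseudotime and subtype composition
#' are attached as diagnostics (attribute `"module_summary"`) when the
#' corresponding metadata is given.
#'
#' @param scores cells x 3 matrix with columns `NEPC_TFs`,
#'   `transition_TFs`, `adeno_TFs`
#' @param pseudotime optional per-cell pseudotime
#' @param subtype optional per-cell subtype labels
#' @return data frame `cell_id`, `module` (0/1/2), `ambiguous`; module
#'   summary diagnostics in attribute `"module_summary"`
#' @export
mrtf_modules <- function(scores, pseudotime = NULL, subtype = NULL) {
  groups <- c("NEPC_TFs", "transition_TFs", "adeno_TFs")
  if (!all(groups %in% colnames(scores))) {
    stop("scores must contain the three TF group sets: ",
         paste(groups, collapse = ", "))
  }
  s <- scores[, groups, drop = FALSE]
  best <- apply(s, 1, max)
  # ties resolved by fixed group order: NEPC, transition, adeno
  module <- apply(s, 1, which.max) - 1L
  n_at_max <- rowSums(s == best)
  out <- data.frame(cell_id = rownames(s), module = module,
                    ambiguous = n_at_max > 1L, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  summ <- data.frame(module = 0:2,
                     group = groups,
                     n_cells = as.integer(table(factor(module, levels = 0:2))))
  if (!is.null(pseudotime)) {
    summ$mean_pseudotime <- as.numeric(
      tapply(pseudotime, factor(module, levels = 0:2), mean))
  }
  if (!is.null(subtype)) {
    comp <- table(module = factor(module, levels = 0:2), subtype = subtype)
    attr(summ, "subtype_composition") <- comp
  }
  attr(out, "module_summary") <- summ
  out
}

#' Smooth a per-cell score along pseudotime
#'
#' Fits a cubic smoothing spline of score against pseudotime at the given
#' degrees of freedom and evaluates it on 100 evenly spaced grid points
#' spanning the observed pseudotime range.
#'
#' @param score numeric per-cell score
#' @param pseudotime numeric per-cell pseudotime (>= 10 cells required)
#' @param df spline degrees of freedom (>= 3, and < number of distinct
#'   pseudotime values)
#' @param n_grid grid resolution (default 100)
#' @return list with `grid`, `fitted`, `residual_sd` and `df`
#' @export
pseudotime_profile <- function(score, pseudotime, df = 5, n_grid = 100L) {
  stopifnot(length(score) == length(pseudotime))
  ok <- is.finite(score) & is.finite(pseudotime)
  score <- score[ok]; pseudotime <- pseudotime[ok]
  if (length(score) < 10) stop("pseudotime smoothing needs >= 10 cells")
  if (df < 3) stop("df must be >= 3")
  n_distinct <- length(unique(pseudotime))
  if (df >= n_distinct) {
    stop("df must be smaller than the number of distinct pseudotime values")
  }
  grid <- seq(min(pseudotime), max(pseudotime), length.out = n_grid)
  if (stats::var(score) == 0) {
    return(list(grid = grid, fitted = rep(score[1], n_grid),
                residual_sd = 0, df = df))
  }
  fit <- stats::smooth.spline(pseudotime, score, df = df)
  fitted_obs <- stats::predict(fit, pseudotime)$y
  list(grid = grid,
       fitted = stats::predict(fit, grid)$y,
       residual_sd = stats::sd(score - fitted_obs),
       df = df)
}

# Row-wise Wilcoxon rank-sum (normal approximation with tie correction
# and continuity correction), vectorized over genes.
rowwise_wilcox_p <- function(x, idx_a, idx_b) {
  n_a <- length(idx_a); n_b <- length(idx_b); n <- n_a + n_b
  xs <- x[, c(idx_a, idx_b), drop = FALSE]
  p <- numeric(nrow(xs))
  for (g in seq_len(nrow(xs))) {
    r <- rank(xs[g, ])
    u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
    ties <- table(xs[g, ])
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) { p[g] <- 1; next }
    mu <- n_a * n_b / 2
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    p[g] <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
  }
  p
}

#' Rank genes by differential expression between two cell groups
#'
#' Per gene: log2 fold change of group means of normalized expression
#' (pseudocount 1) and a Wilcoxon rank-sum p-value. The ranking statistic
#' is `sign(lfc) * -log10(p)`; exact ties are broken by gene id so the
#' ordering is deterministic.
#'
#' @param norm_expr normalized genes x cells matrix
#' @param group_a,group_b cell id vectors (disjoint, each >= 3 cells)
#' @return data frame sorted by decreasing statistic: `gene_id`, `lfc`,
#'   `p`, `q` (BH), `stat`
#' @export
de_rank <- function(norm_expr, group_a, group_b) {
  if (length(intersect(group_a, group_b))) {
    stop("cell groups must be disjoint")
  }
  if (length(group_a) < 3 || length(group_b) < 3) {
    stop("each group needs >= 3 cells")
  }
  stopifnot(all(c(group_a, group_b) %in% colnames(norm_expr)))
  x <- as.matrix(norm_expr[, c(group_a, group_b), drop = FALSE])
  idx_a <- seq_along(group_a)
  idx_b <- length(group_a) + seq_along(group_b)
  m_a <- rowMeans(x[, idx_a, drop = FALSE])
  m_b <- rowMeans(x[, idx_b, drop = FALSE])
  lfc <- log2((m_a + 1) / (m_b + 1))
  p <- rowwise_wilcox_p(x, idx_a, idx_b)
  p <- pmax(p, .Machine$double.xmin)
  stat <- sign(lfc) * -log10(p)
  out <- data.frame(gene_id = rownames(x), lfc = lfc, p = p,
                    q = stats::p.adjust(p, method = "BH"), stat = stat,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$stat, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
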