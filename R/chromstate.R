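#' @importFrom stats phyper p.adjust
#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits
NULL

peaks_to_granges <- function(peaks) {
  if (!nrow(peaks)) {
    return(GenomicRanges::GRanges())
  }
  # BED is 0-based half-open; GRanges is 1-based closed
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(start = peaks$start + 1L,
                                          end = peaks$end))
}

#' Determine per-promoter mark presence from peak calls
#'
#' A promoter carries a mark iff any peak interval overlaps its window
#' `[tss - window, tss + window)` (0-based half-open, clipped at zero).
#' Strand does not move the window. Promoters on chromosomes absent from
#' a peak set are treated as unmarked there (a message reports how many).
#' With several annotated TSSs per gene the union of windows is used, so
#' presence is the OR over TSSs.
#'
#' @param peaks named list of peak data frames (as from [read_bed()] or
#'   [make_peaks()]) with elements `k4_cond1`, `k27_cond1`, `k4_cond2`,
#'   `k27_cond2`
#' @param promoters promoter data frame (gene_id, chrom, tss, strand)
#' @param window promoter half-width in bp (default 2000)
#' @return data frame with one row per (gene_id, condition):
#'   `gene_id`, `condition`, `has_k4`, `has_k27`
#' @export
assign_mark_presence <- function(peaks, promoters, window = 2000L) {
  if (window <= 0) stop("window must be > 0")
  need <- c("k4_cond1", "k27_cond1", "k4_cond2", "k27_cond2")
  if (!all(need %in% names(peaks))) {
    stop("peaks must contain elements ", paste(need, collapse = ", "))
  }
  genes <- unique(promoters$gene_id)
  win <- GenomicRanges::GRanges(
    promoters$chrom,
    IRanges::IRanges(start = pmax(0L, promoters$tss - as.integer(window)) + 1L,
                     end = promoters$tss + as.integer(window)))
  presence_for <- function(pk) {
    gr <- peaks_to_granges(pk)
    missing_chr <- setdiff(unique(promoters$chrom),
                           unique(as.character(GenomicRanges::seqnames(gr))))
    if (length(missing_chr) && length(gr)) {
      message(sprintf("%d promoter chromosome(s) absent from peak set; treated as no overlap",
                      length(missing_chr)))
    }
    ov <- suppressWarnings(GenomicRanges::findOverlaps(win, gr))
    hit_rows <- unique(S4Vectors::queryHits(ov))
    # union over multiple TSSs of the same gene
    genes %in% promoters$gene_id[hit_rows]
  }
  out <- rbind(
    data.frame(gene_id = genes, condition = "cond1",
               has_k4 = presence_for(peaks$k4_cond1),
               has_k27 = presence_for(peaks$k27_cond1),
               stringsAsFactors = FALSE),
    data.frame(gene_id = genes, condition = "cond2",
               has_k4 = presence_for(peaks$k4_cond2),
               has_k27 = presence_for(peaks$k27_cond2),
               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Call the four-state chromatin classification from mark presence
#'
#' Maps the two-mark truth table onto the four states: H3K4me3 only is
#' Active, H3K27me3 only is Repressed, both marks is Bivalent, neither is
#' Unmarked.
#'
#' @param presence data frame from [assign_mark_presence()] (gene_id,
#'   condition, has_k4, has_k27)
#' @return the same data frame with a `state` column (factor over
#'   Active/Repressed/Bivalent/Unmarked)
#' @export
call_states <- function(presence) {
  if (anyDuplicated(presence[, c("gene_id", "condition")])) {
    stop("duplicate (gene_id, condition) records in presence table")
  }
  state <- ifelse(presence$has_k4,
                  ifelse(presence$has_k27, "Bivalent", "Active"),
                  ifelse(presence$has_k27, "Repressed", "Unmarked"))
  presence$state <- factor(state, levels = CHROMATIN_STATES)
  presence
}

#' Tabulate condition-to-condition chromatin state transitions
#'
#' Counts are computed over genes called in both conditions; genes seen in
#' only one condition are reported separately, never counted.
#'
#' @param states_cond1,states_cond2 state-call data frames from
#'   [call_states()] (or any with gene_id and state columns)
#' @return list of class `transition_table`: `counts` (4x4 matrix, rows
#'   condition 1, columns condition 2), `per_gene` (gene_id, state_cond1,
#'   state_cond2), `only_cond1`, `only_cond2` (gene id vectors)
#' @export
transition_matrix <- function(states_cond1, states_cond2) {
  shared <- intersect(states_cond1$gene_id, states_cond2$gene_id)
  if (!length(shared)) stop("no genes called in both conditions")
  s1 <- states_cond1$state[match(shared, states_cond1$gene_id)]
  s2 <- states_cond2$state[match(shared, states_cond2$gene_id)]
  s1 <- factor(as.character(s1), levels = CHROMATIN_STATES)
  s2 <- factor(as.character(s2), levels = CHROMATIN_STATES)
  counts <- table(cond1 = s1, cond2 = s2)
  counts <- matrix(as.integer(counts), nrow = 4,
                   dimnames = list(CHROMATIN_STATES, CHROMATIN_STATES))
  structure(list(counts = counts,
                 per_gene = data.frame(gene_id = shared,
                                       state_cond1 = as.character(s1),
                                       state_cond2 = as.character(s2),
                                       stringsAsFactors = FALSE),
                 only_cond1 = setdiff(states_cond1$gene_id, shared),
                 only_cond2 = setdiff(states_cond2$gene_id, shared)),
            class = "transition_table")
}

hyper_enrich <- function(k, K, n, N) {
  # P(X >= k) for X ~ Hypergeom(N, K, n)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Rank chromatin transition classes by differential-expression enrichment
#'
#' For each condition-2 state, and for each (state1 -> state2) transition
#' class, counts genes differentially expressed in the requested direction
#' at `q <= q_max` and tests over-representation with a one-sided
#' hypergeometric test against the background of all jointly-called genes.
#' P-values are Benjamini-Hochberg adjusted separately within each level
#' (condition-2 states; transition pairs).
#'
#' @param transitions a `transition_table` from [transition_matrix()]
#' @param de data frame with `gene_id`, `effect` (signed log2 fold change,
#'   treatment vs control), `p`, `q`
#' @param direction `"up"` or `"down"`: sign of `effect` that counts as
#'   differential
#' @param q_max DE significance cutoff on `q` (default 0.05)
#' @return data frame sorted by adjusted p within level: `level`
#'   (`"cond2_state"` or `"pair"`), `class`, `n_genes`, `n_de`, `p`,
#'   `p_adj`
#' @export
integrate_with_de <- function(transitions, de, direction = c("up", "down"),
                              q_max = 0.05) {
  direction <- match.arg(direction)
  if (!is.numeric(q_max) || q_max <= 0 || q_max > 1) {
    stop("q_max must lie in (0, 1]")
  }
  pg <- transitions$per_gene
  de <- de[de$gene_id %in% pg$gene_id, , drop = FALSE]
  sig <- de$gene_id[de$q <= q_max &
                      (if (direction == "up") de$effect > 0 else de$effect < 0)]
  N <- nrow(pg)
  K <- length(unique(sig))
  is_de <- pg$gene_id %in% sig

  enrich_rows <- function(class_ids, level) {
    rows <- lapply(names(class_ids), function(cl) {
      idx <- class_ids[[cl]]
      n <- length(idx)
      k <- sum(is_de[idx])
      data.frame(level = level, class = cl, n_genes = n, n_de = k,
                 p = if (n) hyper_enrich(k, K, n, N) else 1,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out[order(out$p_adj, out$p), , drop = FALSE]
  }

  by_state2 <- split(seq_len(N), pg$state_cond2)
  pair_lab <- paste(pg$state_cond1, pg$state_cond2, sep = "->")
  by_pair <- split(seq_len(N), pair_lab)

  out <- rbind(enrich_rows(by_state2, "cond2_state"),
               enrich_rows(by_pair, "pair"))
  rownames(out) <- NULL
  out
}
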