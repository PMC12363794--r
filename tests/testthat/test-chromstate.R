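toy_promoters <- function() {
  data.frame(gene_id = c("gA", "gB"), chrom = c("chr1", "chr1"),
             tss = c(1500L, 50000L), strand = c("+", "-"),
             stringsAsFactors = FALSE)
}

empty_peaks <- function() {
  data.frame(chrom = character(), start = integer(), end = integer())
}

test_that("window overlap is interval arithmetic on 0-based half-open coordinates", {
  prom <- toy_promoters()
  pk <- list(k4_cond1 = data.frame(chrom = "chr1", start = 100L, end = 200L),
             k27_cond1 = empty_peaks(),
             k4_cond2 = empty_peaks(), k27_cond2 = empty_peaks())
  pres <- assign_mark_presence(pk, prom, window = 2000)
  # TSS 1500 with window 2000 spans [-500, 3500) clipped at 0: overlaps [100, 200)
  expect_true(pres$has_k4[pres$gene_id == "gA" & pres$condition == "cond1"])
  expect_false(pres$has_k4[pres$gene_id == "gB" & pres$condition == "cond1"])
  # a peak ending exactly at the window start does not overlap (half-open)
  pk$k4_cond1 <- data.frame(chrom = "chr1", start = 47000L, end = 48000L)
  pres <- assign_mark_presence(pk, prom, window = 2000)
  expect_false(pres$has_k4[pres$gene_id == "gB" & pres$condition == "cond1"])
  pk$k4_cond1 <- data.frame(chrom = "chr1", start = 47000L, end = 48001L)
  pres <- assign_mark_presence(pk, prom, window = 2000)
  expect_true(pres$has_k4[pres$gene_id == "gB" & pres$condition == "cond1"])
})

test_that("empty peak sets give all-absent marks", {
  pk <- list(k4_cond1 = empty_peaks(), k27_cond1 = empty_peaks(),
             k4_cond2 = empty_peaks(), k27_cond2 = empty_peaks())
  pres <- assign_mark_presence(pk, toy_promoters(), window = 2000)
  expect_false(any(pres$has_k4) || any(pres$has_k27))
  st <- call_states(pres)
  expect_true(all(st$state == "Unmarked"))
})

test_that("the two-mark truth table maps bijectively onto the four states", {
  pres <- data.frame(gene_id = paste0("g", 1:4), condition = "cond1",
                     has_k4 = c(TRUE, FALSE, TRUE, FALSE),
                     has_k27 = c(FALSE, TRUE, TRUE, FALSE))
  st <- call_states(pres)
  expect_identical(as.character(st$state),
                   c("Active", "Repressed", "Bivalent", "Unmarked"))
  expect_identical(sort(as.character(unique(st$state))),
                   sort(c("Active", "Repressed", "Bivalent", "Unmarked")))
  dup <- rbind(pres, pres[1, ])
  expect_error(call_states(dup), "duplicate")
})

test_that("transition counts match a hand count and conserve totals", {
  s1 <- data.frame(gene_id = c("g1", "g2", "g3"),
                   state = c("Active", "Active", "Unmarked"))
  s2 <- data.frame(gene_id = c("g1", "g2", "g3"),
                   state = c("Bivalent", "Bivalent", "Unmarked"))
  tt <- transition_matrix(s1, s2)
  expect_equal(tt$counts["Active", "Bivalent"], 2L)
  expect_equal(tt$counts["Unmarked", "Unmarked"], 1L)
  expect_equal(sum(tt$counts), 3L)
  # swapping condition order transposes the matrix
  tt_rev <- transition_matrix(s2, s1)
  expect_identical(tt_rev$counts, t(tt$counts))
  # identical calls give a diagonal matrix
  tt_id <- transition_matrix(s1, s1)
  expect_true(all(tt_id$counts[upper.tri(tt_id$counts)] == 0))
  expect_true(all(tt_id$counts[lower.tri(tt_id$counts)] == 0))
  # genes present in only one condition are reported, not counted
  s2b <- rbind(s2, data.frame(gene_id = "g9", state = "Active"))
  tt_b <- transition_matrix(s1, s2b)
  expect_equal(sum(tt_b$counts), 3L)
  expect_identical(tt_b$only_cond2, "g9")
  expect_error(transition_matrix(s1, data.frame(gene_id = "gX", state = "Active")),
               "no genes")
})

test_that("empirical transition matrix recovers a planted kernel", {
  cfg <- sim_config(seed = 21, n_promoters = 10000,
                    state_mix = rep(0.25, 4))
  pr <- make_promoters(cfg)
  tab <- table(factor(pr$truth$state_cond1, rownames(cfg$transition_kernel)),
               factor(pr$truth$state_cond2, rownames(cfg$transition_kernel)))
  emp <- tab / rowSums(tab)
  k <- cfg$transition_kernel
  se <- sqrt(k * (1 - k) / rowSums(tab))
  expect_true(all(abs(emp - k) <= 3 * pmax(se, 1e-12)))
})

test_that("hypergeometric enrichment agrees with exhaustive enumeration on a toy universe", {
  # 12 genes: 4 DE; a class of 5 genes containing 3 DE genes
  genes <- paste0("g", 1:12)
  state1 <- rep(c("Active", "Unmarked"), 6)
  state2 <- c(rep("Bivalent", 5), rep("Active", 7))
  s1 <- data.frame(gene_id = genes, state = state1)
  s2 <- data.frame(gene_id = genes, state = state2)
  tt <- transition_matrix(s1, s2)
  de <- data.frame(gene_id = genes,
                   effect = c(rep(1, 3), rep(0, 8), 1),
                   p = c(rep(0.001, 3), rep(1, 8), 0.001),
                   q = c(rep(0.01, 3), rep(1, 8), 0.01))
  res <- integrate_with_de(tt, de, direction = "up", q_max = 0.05)
  biv <- res[res$level == "cond2_state" & res$class == "Bivalent", ]
  # brute force: all size-5 draws from 12 genes of which 4 are DE
  draws <- combn(12, 5)
  n_de_in_draw <- colSums(matrix(draws %in% c(1, 2, 3, 12), nrow = 5))
  p_brute <- mean(n_de_in_draw >= 3)
  expect_equal(biv$p, p_brute, tolerance = 1e-12)
  expect_equal(biv$n_de, 3L)
})

test_that("enrichment degenerates gracefully with no DE genes", {
  s1 <- data.frame(gene_id = paste0("g", 1:8),
                   state = rep(c("Active", "Bivalent"), 4))
  s2 <- s1
  tt <- transition_matrix(s1, s2)
  de <- data.frame(gene_id = s1$gene_id, effect = 1, p = 1, q = 1)
  res <- integrate_with_de(tt, de, direction = "up", q_max = 0.05)
  expect_true(all(res$p == 1))
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_error(integrate_with_de(tt, de, q_max = 0), "q_max")
  # gene order invariance
  de_shuf <- de[sample(nrow(de)), ]
  expect_equal(integrate_with_de(tt, de_shuf, direction = "up", q_max = 0.05)$p,
               res$p)
})

test_that("peak round trip recovers planted states for every promoter", {
  cfg <- sim_config(seed = 8, n_promoters = 800)
  pr <- make_promoters(cfg)
  pk <- make_peaks(pr$promoters, pr$truth, window = 1000)
  st <- call_states(assign_mark_presence(pk, pr$promoters, window = 2000))
  got1 <- st$state[st$condition == "cond1"][match(pr$truth$gene_id,
                                                  st$gene_id[st$condition == "cond1"])]
  got2 <- st$state[st$condition == "cond2"][match(pr$truth$gene_id,
                                                  st$gene_id[st$condition == "cond2"])]
  expect_identical(as.character(got1), pr$truth$state_cond1)
  expect_identical(as.character(got2), pr$truth$state_cond2)
})
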