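make_norm <- function(mat) {
  normalize_log(Matrix::Matrix(mat, sparse = TRUE))
}

test_that("depth normalization scales to the median total and is scale invariant", {
  m <- matrix(c(2, 4, 6,
                2, 4, 6,
                2, 4, 6), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  norm <- make_norm(m)
  expect_equal(attr(norm, "size_factors"),
               setNames(c(1, 1, 1) * colSums(m) / median(colSums(m)),
                        colnames(m)))
  # doubling a non-median cell's counts leaves its normalized profile unchanged
  m2 <- m
  m2[, 3] <- m2[, 3] * 2
  norm2 <- make_norm(m2)
  expect_equal(as.matrix(norm2)[, 3], as.matrix(norm)[, 3])
  # single cell: factor 1, values are log1p of raw counts
  single <- matrix(c(0, 1, 3), ncol = 1,
                   dimnames = list(paste0("g", 1:3), "c1"))
  expect_equal(unname(as.matrix(make_norm(single))[, 1]), log1p(c(0, 1, 3)))
  # zero-total cells are dropped with a warning
  m3 <- cbind(m, c4 = 0)
  expect_warning(norm3 <- make_norm(m3), "zero total")
  expect_equal(ncol(norm3), 3)
})

test_that("signature scores are means of per-gene z-scores", {
  set.seed(42)
  m <- matrix(rpois(200, 5), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("c", 1:20)))
  norm <- make_norm(m)
  # singleton set: score equals that gene's z-score
  x <- as.matrix(norm)["g1", ]
  expect_equal(unname(score_signature(norm, "g1")),
               unname((x - mean(x)) / sd(x)))
  # constant genes are excluded with a warning; all-constant set errors
  withconst <- Matrix::Matrix(rbind(as.matrix(norm), gc = 5), sparse = TRUE)
  expect_warning(s <- score_signature(withconst, c("g1", "gc")), "zero-variance")
  expect_equal(s, score_signature(norm, "g1"))
  expect_error(score_signature(withconst, "gc"), "zero-variance")
  expect_error(score_signature(norm, "nope"), "no overlap")
  # gene order invariance
  expect_equal(score_signature(norm, c("g1", "g2", "g3")),
               score_signature(norm, c("g3", "g1", "g2")))
})

test_that("planted program scores separate their cluster (AUROC > 0.9)", {
  cfg <- sim_config(seed = 13, n_cells = 600, n_genes = 300, n_clusters = 3,
                    program_effect = 1)
  sc <- make_sc_counts(cfg)
  norm <- normalize_log(sc$counts)
  s <- score_signature(norm, sc$truth$program_cluster2)
  expect_gt(auroc(s, sc$cellmeta$cluster == "cluster2"), 0.9)
})

test_that("subtype assignment is argmax with margin and handles ties", {
  sc <- matrix(c(2.0, -1.0, 0.3), nrow = 1,
               dimnames = list("c1", c("BL", "L2", "L1.1")))
  expect_error(assign_subtype(sc[, 1, drop = FALSE], level = "cell"),
               ">= 2 marker sets")
  out <- assign_subtype(sc, level = "cell")
  expect_equal(out$subtype, "BL")
  expect_equal(out$margin, 1.7)
  tie <- matrix(c(1, 1, 0), nrow = 1,
                dimnames = list("c1", c("BL", "L2", "L1.1")))
  out_tie <- assign_subtype(tie, level = "cell")
  expect_equal(out_tie$subtype, "ambiguous")
  expect_true(out_tie$ambiguous)
})

test_that("cluster-planted marker programs give perfect cluster-level subtyping", {
  cfg <- sim_config(seed = 17, n_cells = 600, n_genes = 300, n_clusters = 3,
                    program_effect = 1)
  sc <- make_sc_counts(cfg)
  norm <- normalize_log(sc$counts)
  scores <- score_signatures(norm, sc$truth)
  out <- assign_subtype(scores, level = "cluster", clusters = sc$cellmeta$cluster)
  expected <- paste0("program_", sc$cellmeta$cluster)
  expect_identical(out$subtype, expected)
})

test_that("MR-TF modules map group argmax to modules 0-2 and partition cells", {
  s <- matrix(c(2, 0, 0,
                0, 2, 0,
                0, 0, 2,
                1, 1, 1), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("c", 1:4),
                              c("NEPC_TFs", "transition_TFs", "adeno_TFs")))
  out <- mrtf_modules(s, pseudotime = c(0.1, 0.5, 0.9, 0.5))
  expect_equal(out$module[1:3], 0:2)
  expect_true(out$ambiguous[4])
  expect_equal(out$module[4], 0)  # fixed tie-break order
  expect_equal(nrow(out), 4)     # partition: one row per scored cell
  expect_error(mrtf_modules(s[, 1:2]), "group sets")
  summ <- attr(out, "module_summary")
  expect_equal(summ$n_cells, c(2L, 1L, 1L))
})

test_that("vehicle-planted NEPC program enriches module 0 in vehicle cells", {
  cfg <- sim_config(seed = 23, n_cells = 900, n_genes = 300, n_clusters = 3,
                    program_effect = 1)
  sc <- make_sc_counts(cfg)
  norm <- normalize_log(sc$counts)
  sets <- list(NEPC_TFs = sc$truth$program_cluster1,      # cluster 1 = vehicle
               transition_TFs = sc$truth$program_cluster2,
               adeno_TFs = sc$truth$program_cluster3)
  mods <- mrtf_modules(score_signatures(norm, sets))
  veh <- sc$cellmeta$treatment == "vehicle"
  tab <- table(vehicle = veh, module0 = mods$module == 0)
  pt <- prop.test(c(tab["TRUE", "TRUE"], tab["FALSE", "TRUE"]),
                  c(sum(veh), sum(!veh)), alternative = "greater")
  expect_lt(pt$p.value, 0.01)
})

test_that("pseudotime smoothing reproduces curves in the spline span", {
  pt <- seq(0, 1, length.out = 50)
  const <- pseudotime_profile(rep(2.5, 50), pt, df = 3)
  expect_true(all(abs(const$fitted - 2.5) < 1e-12))
  ident <- pseudotime_profile(pt, pt, df = 3)
  expect_true(all(abs(ident$fitted - ident$grid) < 1e-6))
  expect_error(pseudotime_profile(pt, pt, df = 50), "distinct")
  expect_error(pseudotime_profile(pt[1:5], pt[1:5], df = 3), ">= 10 cells")
  # planted monotone trend plus noise is recovered
  set.seed(31)
  pt2 <- runif(2000)
  truth <- function(x) 2 * x^2
  y <- truth(pt2) + rnorm(2000, sd = 0.5)
  fit <- pseudotime_profile(y, pt2, df = 5)
  expect_gt(cor(fit$fitted, truth(fit$grid), method = "spearman"), 0.95)
})

test_that("differential ranking is deterministic hand-checkable arithmetic", {
  m <- matrix(c(4, 4, 4, 0, 0, 0,
                1, 2, 3, 1, 2, 3,
                0, 0, 0, 0, 0, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("up", "flat", "zero"), paste0("c", 1:6)))
  norm <- Matrix::Matrix(m, sparse = TRUE)  # use raw values as "normalized"
  de <- de_rank(norm, paste0("c", 1:3), paste0("c", 4:6))
  z <- de[match(c("up", "flat", "zero"), de$gene_id), ]
  expect_equal(z$lfc[1], log2((4 + 1) / (0 + 1)))
  expect_equal(z$lfc[2], 0)
  expect_equal(z$lfc[3], 0)
  expect_equal(z$p[3], 1)       # all-zero gene: no information
  expect_equal(z$stat[3], 0)
  expect_true(de$gene_id[1] == "up")
  expect_error(de_rank(norm, paste0("c", 1:3), paste0("c", 3:6)), "disjoint")
  expect_error(de_rank(norm, paste0("c", 1:2), paste0("c", 4:6)), ">= 3 cells")
})
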