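test_that("identity kernel leaves every promoter's state unchanged", {
  states <- c("Active", "Repressed", "Bivalent", "Unmarked")
  ident <- diag(4)
  dimnames(ident) <- list(states, states)
  cfg <- quick_cfg(transition_kernel = ident)
  pr <- make_promoters(cfg)
  expect_identical(pr$truth$state_cond1, pr$truth$state_cond2)
})

test_that("degenerate state mixture puts every promoter in that state", {
  cfg <- quick_cfg(state_mix = c(Active = 1, Repressed = 0, Bivalent = 0,
                                 Unmarked = 0))
  pr <- make_promoters(cfg)
  expect_true(all(pr$truth$state_cond1 == "Active"))
})

test_that("uniform mixture yields fractions within 3 binomial SE of 0.25", {
  cfg <- sim_config(seed = 11, n_promoters = 10000,
                    state_mix = rep(0.25, 4))
  pr <- make_promoters(cfg)
  frac <- table(factor(pr$truth$state_cond1,
                       c("Active", "Repressed", "Bivalent", "Unmarked"))) / 10000
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(frac - 0.25) <= 3 * se))
})

test_that("invalid configurations are rejected", {
  expect_error(quick_cfg(state_mix = c(0.5, 0.5, 0.1, 0)), "sum to 1")
  expect_error(quick_cfg(nb_dispersion = 0), "nb_dispersion")
  k <- matrix(0.3, 4, 4)
  expect_error(quick_cfg(transition_kernel = k), "row-stochastic")
  pr <- make_promoters(quick_cfg())
  expect_error(make_peaks(pr$promoters, pr$truth, window = 0), "window")
})

test_that("peak emission follows the mark semantics of each state", {
  pr <- make_promoters(quick_cfg(seed = 3))
  pk <- make_peaks(pr$promoters, pr$truth, window = 1000)
  biv <- pr$promoters$gene_id[pr$truth$state_cond1 == "Bivalent"]
  unm <- pr$promoters$gene_id[pr$truth$state_cond1 == "Unmarked"]
  expect_true(all(biv %in% pk$k4_cond1$name))
  expect_true(all(biv %in% pk$k27_cond1$name))
  expect_false(any(unm %in% c(pk$k4_cond1$name, pk$k27_cond1$name)))
  # sorted, 0-based, half-open
  for (p in pk) {
    expect_false(is.unsorted(p$start[p$chrom == p$chrom[1]]))
    expect_true(all(p$start >= 0) && all(p$end > p$start))
  }
})

test_that("fixed seed gives byte-identical outputs and generators are independent", {
  a <- make_sc_counts(quick_cfg(seed = 5))
  b <- make_sc_counts(quick_cfg(seed = 5))
  expect_identical(a$counts, b$counts)
  expect_identical(a$cellmeta, b$cellmeta)
  # drawing promoters first must not perturb the count stream (child seeds)
  invisible(make_promoters(quick_cfg(seed = 5)))
  c_ <- make_sc_counts(quick_cfg(seed = 5))
  expect_identical(a$counts, c_$counts)
  expect_false(identical(a$counts, make_sc_counts(quick_cfg(seed = 6))$counts))
})

test_that("null program effect leaves planted genes indistinguishable", {
  n_sig <- 0
  n_sims <- 40
  for (s in seq_len(n_sims)) {
    cfg <- sim_config(seed = 100 + s, n_cells = 150, n_genes = 120,
                      n_clusters = 3, program_effect = 0)
    sc <- make_sc_counts(cfg, program_size = 20)
    genes <- sc$truth$program_cluster1
    in_cl <- sc$cellmeta$cluster == "cluster1"
    m <- Matrix::colMeans(sc$counts[genes, , drop = FALSE])
    p <- t.test(m[in_cl], m[!in_cl])$p.value
    if (p < 0.01) n_sig <- n_sig + 1
  }
  expect_lte(n_sig / n_sims, 0.05)
})

test_that("single-cluster data with no shift has near-zero group fold change", {
  cfg <- sim_config(seed = 9, n_cells = 300, n_genes = 150, n_clusters = 2,
                    program_effect = 0)
  sc <- make_sc_counts(cfg)
  norm <- normalize_log(sc$counts)
  half <- colnames(norm)[1:150]
  rest <- setdiff(colnames(norm), half)
  de <- de_rank(norm, half, rest)
  expect_lt(mean(abs(de$lfc)), 0.05)
})

test_that("noise-free dose-response plates reconstruct their planted delta", {
  surf0 <- synergy_surface(normalize_plate(
    make_dose_response(quick_cfg(bliss_delta = 0, noise_cv = 0))$plate))
  expect_equal(surf0$summary_score, 0)
  surf15 <- synergy_surface(normalize_plate(
    make_dose_response(quick_cfg(bliss_delta = 15, noise_cv = 0))$plate))
  expect_equal(surf15$summary_score, 15, tolerance = 1e-10)
})

test_that("spectral-count generator controls its planted enrichment", {
  cfg <- quick_cfg(n_bait_enriched = 10, bait_rate_ratio = 20)
  # 20x over background 5: planted proteins clear the >=5 filter essentially always
  for (s in 1:20) {
    out <- make_spectral_counts(quick_cfg(seed = s, n_bait_enriched = 10,
                                          bait_rate_ratio = 20),
                                n_proteins = 100, background_rate = 5)
    bait <- out$table$counts[out$truth, out$table$arms$arm == "bait"]
    expect_true(all(bait >= 5))
  }
  # a protein with zero background never appears, hence is never nominated
  out <- make_spectral_counts(quick_cfg(seed = 2, n_bait_enriched = 5),
                              n_proteins = 50, background_rate = 0)
  expect_true(all(out$table$counts[-(1:5), ] == 0))
  hits <- nominate_venn(out$table)
  expect_true(all(hits$protein_id %in% out$truth))
})

test_that("generated files round-trip losslessly through the module readers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 4, n_promoters = 200, n_cells = 60, n_genes = 80,
                    n_clusters = 2)
  paths <- simulate_all(cfg, dir)
  prom <- read_tsv(paths[["promoters"]])
  expect_identical(prom$gene_id, make_promoters(cfg)$promoters$gene_id)
  counts <- read_counts_mtx(dirname(paths[["mtx"]]))
  truth <- make_promoters(cfg)$truth
  expr_genes <- head(prom$gene_id, cfg$n_genes)
  biv <- intersect(expr_genes, truth$gene_id[truth$state_cond2 == "Bivalent"])
  sc <- make_sc_counts(cfg, gene_ids = expr_genes, treatment_genes = biv,
                       treatment_effect = cfg$program_effect)
  expect_equal(as.matrix(counts), as.matrix(sc$counts))
  bed <- read_bed(paths[["k4_cond1"]])
  expect_true(all(bed$end - bed$start == 2000))
  plate <- read_plate_csv(paths[["plate"]])
  expect_length(plate$replicates, 3)
  tab <- read_spectral_counts(paths[["spectral"]])
  expect_identical(tab$counts, make_spectral_counts(cfg)$table$counts)
})

test_that("treatment-program planting shifts designated genes only in EZH2i cells", {
  cfg <- sim_config(seed = 19, n_cells = 400, n_genes = 200, n_clusters = 2,
                    program_effect = 0)
  tg <- sprintf("gene%05d", 150:170)
  sc <- make_sc_counts(cfg, treatment_genes = tg, treatment_effect = 1)
  tr <- sc$cellmeta$treatment == "EZH2i"
  ratio <- mean(as.matrix(sc$counts[tg, tr])) / mean(as.matrix(sc$counts[tg, !tr]))
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
  other <- setdiff(rownames(sc$counts), tg)[1:100]
  lfc_other <- log2(mean(as.matrix(sc$counts[other, tr])) /
                      mean(as.matrix(sc$counts[other, !tr])))
  expect_lt(abs(lfc_other), 0.2)
  expect_identical(sc$truth$treatment_program, tg)
  expect_error(make_sc_counts(cfg, treatment_genes = "nope",
                              treatment_effect = 1), "subset")
})
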