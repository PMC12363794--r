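#' @importFrom stats rnbinom rpois rlnorm runif rmultinom setNames
NULL

CHROMATIN_STATES <- c("Active", "Repressed", "Bivalent", "Unmarked")

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. Defaults encode the
#' study conditions the downstream analyses assume: a promoter compendium
#' dominated by Active states with a substantial Bivalent fraction, a
#' mostly-diagonal state transition kernel with net bivalency gain in the
#' second genotype, negative-binomial single-nucleus counts over five
#' epithelial clusters, a +10-point planted Bliss interaction with 5%
#' plate noise, and 20x bait enrichment over a Poisson IgG background.
#'
#' @param seed integer master seed; fanned out to per-generator child seeds
#'   (see [child_seed()])
#' @param n_promoters number of promoters
#' @param state_mix length-4 probability vector over
#'   Active/Repressed/Bivalent/Unmarked for condition 1
#' @param transition_kernel 4x4 row-stochastic matrix taking condition-1
#'   states to condition-2 states
#' @param n_cells,n_genes,n_clusters single-cell matrix dimensions and
#'   cluster count
#' @param program_effect log2 fold shift applied to planted program genes
#'   in their designated cluster
#' @param nb_dispersion negative-binomial dispersion
#'   (variance = mu + mu^2 * dispersion)
#' @param bliss_delta planted drug-interaction term, percentage points of
#'   inhibition added to the Bliss expectation on combination wells
#' @param noise_cv coefficient of variation of multiplicative
#'   (lognormal) plate noise
#' @param n_bait_enriched number of truly bait-enriched proteins
#' @param bait_rate_ratio Poisson rate multiplier for enriched proteins in
#'   the bait arm
#' @return object of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       n_promoters = 10000L,
                       state_mix = c(Active = 0.45, Repressed = 0.15,
                                     Bivalent = 0.15, Unmarked = 0.25),
                       transition_kernel = default_transition_kernel(),
                       n_cells = 2000L,
                       n_genes = 1000L,
                       n_clusters = 5L,
                       program_effect = 1,
                       nb_dispersion = 0.5,
                       bliss_delta = 10,
                       noise_cv = 0.05,
                       n_bait_enriched = 20L,
                       bait_rate_ratio = 20) {
  cfg <- list(seed = as.integer(seed), n_promoters = as.integer(n_promoters),
              state_mix = state_mix, transition_kernel = transition_kernel,
              n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
              n_clusters = as.integer(n_clusters),
              program_effect = program_effect, nb_dispersion = nb_dispersion,
              bliss_delta = bliss_delta, noise_cv = noise_cv,
              n_bait_enriched = as.integer(n_bait_enriched),
              bait_rate_ratio = bait_rate_ratio)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Default condition-1 to condition-2 chromatin transition kernel
#'
#' Mostly diagonal (states are largely stable between genotypes) with a
#' net gain of bivalency, mirroring Polycomb spreading over active and
#' unmarked promoters in the Rb1-deficient genotype.
#'
#' @return 4x4 row-stochastic matrix with state dimnames
#' @export
default_transition_kernel <- function() {
  k <- matrix(c(0.85, 0.02, 0.10, 0.03,   # Active ->
                0.05, 0.80, 0.10, 0.05,   # Repressed ->
                0.10, 0.10, 0.75, 0.05,   # Bivalent ->
                0.05, 0.05, 0.10, 0.80),  # Unmarked ->
              nrow = 4, byrow = TRUE,
              dimnames = list(CHROMATIN_STATES, CHROMATIN_STATES))
  k
}

validate_sim_config <- function(cfg) {
  if (abs(sum(cfg$state_mix) - 1) > 1e-9) {
    stop("state_mix must sum to 1 (within 1e-9)")
  }
  if (length(cfg$state_mix) != 4 || any(cfg$state_mix < 0)) {
    stop("state_mix must be 4 non-negative probabilities")
  }
  k <- cfg$transition_kernel
  if (!is.matrix(k) || any(dim(k) != 4) || any(k < 0) ||
      any(abs(rowSums(k) - 1) > 1e-9)) {
    stop("transition_kernel must be a 4x4 row-stochastic matrix")
  }
  counts <- c(cfg$n_promoters, cfg$n_cells, cfg$n_genes, cfg$n_clusters)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (cfg$bait_rate_ratio < 1) stop("bait_rate_ratio must be >= 1")
  invisible(cfg)
}

#' Derive a per-generator child seed from the master seed
#'
#' Each generator owns a fixed slot index so adding a generator never
#' perturbs the streams of existing ones. The child seed is
#' `(seed * 48271 + slot) mod (2^31 - 1)` (a Lehmer-style mixing step).
#'
#' @param seed master seed
#' @param slot integer slot: 1 promoters, 2 peaks, 3 single-cell counts,
#'   4 dose-response, 5 spectral counts (6-10 reserved)
#' @return integer child seed
#' @export
child_seed <- function(seed, slot) {
  m <- 2147483647
  as.integer((as.numeric(seed) %% m * 48271 + slot) %% m)
}

#' Generate a promoter annotation with planted chromatin states
#'
#' Condition-1 states are drawn from `state_mix`; condition-2 states evolve
#' each promoter through `transition_kernel`. Coordinates are laid out on
#' the 19 mouse autosomes with TSSs spaced widely enough that promoter
#' windows of different genes never collide.
#'
#' @param cfg a [sim_config()]
#' @return list with `promoters` (data frame: gene_id, chrom, tss, strand;
#'   tss is 0-based) and `truth` (data frame: gene_id, state_cond1,
#'   state_cond2)
#' @export
make_promoters <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(child_seed(cfg$seed, 1L))
  n <- cfg$n_promoters
  gene_id <- sprintf("gene%05d", seq_len(n))
  chrom <- paste0("chr", sample(1:19, n, replace = TRUE))
  # 100 kb spacing within each chromosome keeps promoter windows disjoint
  tss <- integer(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    tss[i] <- 10000L + (seq_along(i) - 1L) * 100000L
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  s1 <- sample(CHROMATIN_STATES, n, replace = TRUE, prob = cfg$state_mix)
  s2 <- vapply(s1, function(s) {
    sample(CHROMATIN_STATES, 1, prob = cfg$transition_kernel[s, ])
  }, character(1), USE.NAMES = FALSE)
  list(promoters = data.frame(gene_id = gene_id, chrom = chrom, tss = tss,
                              strand = strand, stringsAsFactors = FALSE),
       truth = data.frame(gene_id = gene_id, state_cond1 = s1, state_cond2 = s2,
                          stringsAsFactors = FALSE))
}

#' Emit per-mark, per-condition peak sets from planted promoter states
#'
#' A peak spanning TSS +/- `window` is emitted for H3K4me3 iff the state is
#' Active or Bivalent, and for H3K27me3 iff the state is Repressed or
#' Bivalent (Bivalent promoters therefore appear in both files). Peaks are
#' 0-based half-open and sorted.
#'
#' @param promoters promoter data frame from [make_promoters()]
#' @param truth planted state data frame from [make_promoters()]
#' @param window half-width of emitted peaks in bp (default 1000)
#' @return named list of four peak data frames:
#'   `k4_cond1`, `k27_cond1`, `k4_cond2`, `k27_cond2`
#' @export
make_peaks <- function(promoters, truth, window = 1000L) {
  if (window <= 0) stop("window must be > 0")
  stopifnot(identical(promoters$gene_id, truth$gene_id))
  peak_for <- function(states, marked) {
    i <- which(states %in% marked)
    p <- data.frame(chrom = promoters$chrom[i],
                    start = pmax(0L, promoters$tss[i] - as.integer(window)),
                    end = promoters$tss[i] + as.integer(window),
                    name = promoters$gene_id[i], stringsAsFactors = FALSE)
    p[order(p$chrom, p$start, p$end), , drop = FALSE]
  }
  list(k4_cond1 = peak_for(truth$state_cond1, c("Active", "Bivalent")),
       k27_cond1 = peak_for(truth$state_cond1, c("Repressed", "Bivalent")),
       k4_cond2 = peak_for(truth$state_cond2, c("Active", "Bivalent")),
       k27_cond2 = peak_for(truth$state_cond2, c("Repressed", "Bivalent")))
}

#' Simulate a single-cell count matrix with planted gene programs
#'
#' Counts are negative binomial (variance = mu + mu^2 * dispersion). Cells
#' are split over `n_clusters` clusters; each cluster owns a disjoint block
#' of program genes whose mean is shifted by `program_effect` log2 units in
#' that cluster. Treatment labels follow the study design: the first
#' cluster is predominantly vehicle, the remainder predominantly EZH2i.
#' Pseudotime is planted as cluster ordinal plus uniform jitter, rescaled
#' to [0, 1].
#'
#' @param cfg a [sim_config()]
#' @param gene_ids optional gene id vector of length `cfg$n_genes` (e.g.
#'   promoter gene ids, to link expression to chromatin states)
#' @param program_size genes per planted cluster program (default 25);
#'   with `program_effect = 0` no cluster programs are planted
#' @param base_mu mean count of unshifted genes (default 2)
#' @param p_treat_mix probability a first-cluster cell is vehicle-treated
#'   and a non-first-cluster cell is EZH2i-treated (default 0.9)
#' @param treatment_genes optional gene ids additionally up-shifted by
#'   `treatment_effect` log2 units in every EZH2i-treated cell (e.g. the
#'   genes bivalent in condition 2, to plant a chromatin-state-linked
#'   response to EZH2 inhibition)
#' @param treatment_effect log2 shift applied to `treatment_genes`
#'   (default 0)
#' @return list with sparse `counts` (genes x cells), `cellmeta` (cell_id,
#'   cluster, treatment, pseudotime) and `truth` (named list of program
#'   gene ids per cluster, plus `treatment_program` when planted)
#' @export
make_sc_counts <- function(cfg, gene_ids = NULL, program_size = 25L,
                           base_mu = 2, p_treat_mix = 0.9,
                           treatment_genes = NULL, treatment_effect = 0) {
  validate_sim_config(cfg)
  if (cfg$n_clusters < 2) stop("n_clusters must be >= 2")
  if (cfg$n_clusters * program_size > cfg$n_genes) {
    stop("not enough genes for the designated cluster programs")
  }
  set.seed(child_seed(cfg$seed, 3L))
  n_g <- cfg$n_genes; n_c <- cfg$n_cells; K <- cfg$n_clusters
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%05d", seq_len(n_g))
  stopifnot(length(gene_ids) == n_g, !anyDuplicated(gene_ids))
  if (!all(treatment_genes %in% gene_ids)) {
    stop("treatment_genes must be a subset of the generated gene ids")
  }
  cell_id <- sprintf("cell%05d", seq_len(n_c))
  cluster <- sort(rep_len(seq_len(K), n_c))
  treatment <- ifelse(runif(n_c) < p_treat_mix,
                      ifelse(cluster == 1L, "vehicle", "EZH2i"),
                      ifelse(cluster == 1L, "EZH2i", "vehicle"))
  pt_raw <- (cluster - 1L) + runif(n_c)
  pseudotime <- (pt_raw - min(pt_raw)) / (max(pt_raw) - min(pt_raw))
  # the designated program blocks exist regardless of effect size, so a
  # zero effect is a true null on the same genes
  truth <- lapply(seq_len(K), function(k) {
    gene_ids[((k - 1L) * program_size + 1L):(k * program_size)]
  })
  names(truth) <- paste0("program_cluster", seq_len(K))
  mu <- matrix(base_mu, nrow = n_g, ncol = K)
  for (k in seq_len(K)) {
    idx <- ((k - 1L) * program_size + 1L):(k * program_size)
    mu[idx, k] <- base_mu * 2^cfg$program_effect
  }
  tg_idx <- match(treatment_genes, gene_ids)
  if (length(tg_idx) && treatment_effect != 0) {
    truth$treatment_program <- treatment_genes
  }
  counts <- matrix(0L, nrow = n_g, ncol = n_c,
                   dimnames = list(gene_ids, cell_id))
  size <- 1 / cfg$nb_dispersion
  treated <- treatment == "EZH2i"
  for (k in seq_len(K)) {
    for (arm in c(FALSE, TRUE)) {
      cells <- which(cluster == k & treated == arm)
      if (!length(cells)) next
      mu_k <- mu[, k]
      if (arm && length(tg_idx) && treatment_effect != 0) {
        mu_k[tg_idx] <- mu_k[tg_idx] * 2^treatment_effect
      }
      counts[, cells] <- rnbinom(n_g * length(cells), mu = mu_k, size = size)
    }
  }
  list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
       cellmeta = data.frame(cell_id = cell_id,
                             cluster = paste0("cluster", cluster),
                             treatment = treatment, pseudotime = pseudotime,
                             stringsAsFactors = FALSE),
       truth = truth)
}

four_pl_inhibition <- function(dose, ec50, hill, emax) {
  ifelse(dose <= 0, 0, emax * dose^hill / (ec50^hill + dose^hill))
}

#' Simulate a dose-response luminescence plate under Bliss plus interaction
#'
#' Monotherapy inhibition follows a four-parameter logistic in dose;
#' combination inhibition is the Bliss expectation plus
#' `bliss_delta`/100 (clamped to [0, 1]). Luminescence is
#' (1 - inhibition) x plate scale x multiplicative lognormal noise with
#' coefficient of variation `noise_cv` (unit mean). Control wells sit at
#' dose (0, 0).
#'
#' @param cfg a [sim_config()]
#' @param doses_a,doses_b dose vectors, each including 0 and sorted
#' @param hill_params list with per-drug `ec50`, `hill`, `emax` entries
#'   `a` and `b`; emax must lie in (0, 1]
#' @param n_replicates replicate plates to simulate (default 1)
#' @param plate_scale raw luminescence of an untreated well (default 10000)
#' @param seed_offset added to the dose-response child seed so independent
#'   plates can be drawn from one config (default 0)
#' @return list with `plate` (a `plate_grid`) and `truth`
#'   (list: bliss_delta, inhibition matrix without noise)
#' @export
make_dose_response <- function(cfg, doses_a = c(0, 0.1, 0.3, 1, 3),
                               doses_b = c(0, 0.1, 0.3, 1, 3),
                               hill_params = list(
                                 a = list(ec50 = 0.5, hill = 1.5, emax = 0.6),
                                 b = list(ec50 = 0.5, hill = 1.5, emax = 0.6)),
                               n_replicates = 1L, plate_scale = 10000,
                               seed_offset = 0L) {
  validate_sim_config(cfg)
  if (!0 %in% doses_a || !0 %in% doses_b) {
    stop("each drug needs a zero dose (control wells)")
  }
  if (length(doses_a) < 2 || length(doses_b) < 2) {
    stop("need >= 2 doses per drug")
  }
  for (hp in hill_params) {
    if (hp$ec50 <= 0 || hp$hill <= 0 || hp$emax <= 0) {
      stop("hill parameters must be positive")
    }
  }
  set.seed(child_seed(cfg$seed, 4L) + as.integer(seed_offset))
  ea <- four_pl_inhibition(doses_a, hill_params$a$ec50, hill_params$a$hill,
                           hill_params$a$emax)
  eb <- four_pl_inhibition(doses_b, hill_params$b$ec50, hill_params$b$hill,
                           hill_params$b$emax)
  inhib <- outer(ea, eb, function(x, y) x + y - x * y)
  combo <- outer(doses_a > 0, doses_b > 0, `&`)
  inhib[combo] <- pmin(1, pmax(0, inhib[combo] + cfg$bliss_delta / 100))
  reps <- lapply(seq_len(n_replicates), function(r) {
    if (cfg$noise_cv > 0) {
      sdlog <- sqrt(log(1 + cfg$noise_cv^2))
      noise <- matrix(rlnorm(length(inhib), meanlog = -sdlog^2 / 2,
                             sdlog = sdlog), nrow = nrow(inhib))
    } else {
      noise <- matrix(1, nrow = nrow(inhib), ncol = ncol(inhib))
    }
    lum <- (1 - inhib) * plate_scale * noise
    dimnames(lum) <- list(format(doses_a, trim = TRUE),
                          format(doses_b, trim = TRUE))
    lum
  })
  list(plate = plate_grid(reps, doses_a, doses_b),
       truth = list(bliss_delta = cfg$bliss_delta, inhibition = inhib))
}

#' Simulate a bait/IgG spectral-count table with planted interactors
#'
#' Counts are Poisson. The first `n_bait_enriched` proteins have bait-arm
#' rate `background_rate * bait_rate_ratio`; everything else, and the IgG
#' arm throughout, sits at `background_rate`.
#'
#' @param cfg a [sim_config()]
#' @param n_proteins number of proteins (default 300)
#' @param n_bait_reps bait replicates (default 4, the study design)
#' @param n_igg_reps IgG replicates (default 2)
#' @param background_rate Poisson background spectral-count rate (default 5)
#' @param sample_label sample tag written into column headers (default "SKO")
#' @param seed_offset added to the spectral child seed (default 0)
#' @return list with `table` (a `spectral_counts`) and `truth`
#'   (character vector of enriched protein ids)
#' @export
make_spectral_counts <- function(cfg, n_proteins = 300L, n_bait_reps = 4L,
                                 n_igg_reps = 2L, background_rate = 5,
                                 sample_label = "SKO", seed_offset = 0L) {
  validate_sim_config(cfg)
  if (cfg$n_bait_enriched > n_proteins) {
    stop("n_bait_enriched cannot exceed n_proteins")
  }
  if (n_proteins <= 0 || n_bait_reps <= 0 || n_igg_reps <= 0) {
    stop("protein and replicate counts must be positive")
  }
  set.seed(child_seed(cfg$seed, 5L) + as.integer(seed_offset))
  protein_id <- sprintf("prot%04d", seq_len(n_proteins))
  enriched <- protein_id[seq_len(cfg$n_bait_enriched)]
  bait_rate <- rep(background_rate, n_proteins)
  bait_rate[seq_len(cfg$n_bait_enriched)] <- background_rate * cfg$bait_rate_ratio
  bait <- matrix(rpois(n_proteins * n_bait_reps, bait_rate),
                 nrow = n_proteins)
  igg <- matrix(rpois(n_proteins * n_igg_reps, background_rate),
                nrow = n_proteins)
  m <- cbind(bait, igg)
  colnames(m) <- c(sprintf("bait:%s:rep%d", sample_label, seq_len(n_bait_reps)),
                   sprintf("IgG:%s:rep%d", sample_label, seq_len(n_igg_reps)))
  rownames(m) <- protein_id
  list(table = spectral_counts(m), truth = enriched)
}

#' Generate and write every pipeline input to a directory
#'
#' Writes promoters.tsv, four peak BED files, the count matrix
#' (counts.mtx + genes.tsv + cells.tsv), cellmeta.tsv, a marker-gene GMT,
#' plate_demo.csv, spectral_counts.tsv and truth.json.
#'
#' @param cfg a [sim_config()]
#' @param outdir output directory (created)
#' @param window peak half-width passed to [make_peaks()]
#' @return named vector of file paths, invisibly
#' @export
simulate_all <- function(cfg, outdir, window = 1000L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prom <- make_promoters(cfg)
  peaks <- make_peaks(prom$promoters, prom$truth, window = window)
  expr_genes <- utils::head(prom$promoters$gene_id, cfg$n_genes)
  # EZH2 inhibition preferentially de-represses bivalent promoters: plant
  # the treatment response in the genes bivalent in condition 2
  biv_genes <- intersect(expr_genes,
                         prom$truth$gene_id[prom$truth$state_cond2 == "Bivalent"])
  sc <- make_sc_counts(cfg, gene_ids = expr_genes,
                       treatment_genes = biv_genes,
                       treatment_effect = cfg$program_effect)
  plate <- make_dose_response(cfg, n_replicates = 3L)
  rime <- make_spectral_counts(cfg)

  paths <- c(promoters = file.path(outdir, "promoters.tsv"))
  write_tsv(prom$promoters, paths["promoters"],
            params = list(seed = cfg$seed, n_promoters = cfg$n_promoters))
  for (nm in names(peaks)) {
    p <- file.path(outdir, sprintf("peaks_%s.bed", nm))
    write_bed(peaks[[nm]], p)
    paths[nm] <- p
  }
  mtx <- write_counts_mtx(sc$counts, outdir)
  paths <- c(paths, mtx)
  paths["cellmeta"] <- file.path(outdir, "cellmeta.tsv")
  write_tsv(sc$cellmeta, paths["cellmeta"], params = list(seed = cfg$seed))
  paths["genesets"] <- file.path(outdir, "programs.gmt")
  write_gmt(sc$truth, paths["genesets"])
  paths["plate"] <- file.path(outdir, "plate_demo.csv")
  write_plate_csv(plate$plate, paths["plate"])
  paths["spectral"] <- file.path(outdir, "spectral_counts.tsv")
  write_spectral_counts(rime$table, paths["spectral"])
  paths["truth"] <- file.path(outdir, "truth.json")
  truth <- list(schema_version = "1.0",
                seed = cfg$seed,
                promoter_states = prom$truth,
                program_gene_ids = sc$truth,
                bliss_delta = cfg$bliss_delta,
                enriched_protein_ids = rime$truth)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
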