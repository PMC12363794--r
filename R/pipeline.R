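#' @importFrom tools md5sum
NULL

default_run_params <- function() {
  list(window = 2000L,        # promoter half-width, bp
       gen_window = 1000L,    # peak half-width used by the simulator, bp
       q_max = 0.05,          # DE significance cutoff for state integration
       de_direction = "up",
       n_perm = 1000L,        # GSEA permutations (study default 10000 for bulk)
       gsea_fdr = 0.25,       # study threshold for bulk contrasts
       spline_df = 5L,
       rime_q = 0.1, rime_min_detected = 2L, rime_n_samples = 4L,
       rime_min_count = 5L)
}

#' Load a pipeline run configuration from YAML
#'
#' The YAML mirrors [sim_config()] under `sim:`, stage toggles under
#' `stages:`, stage parameters under `params:` and (for runs on real
#' data) input file paths under `inputs:`. Missing entries fall back to
#' package defaults; the seed defaults to 1.
#'
#' @param path YAML file path
#' @return `run_config` list
#' @export
run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  stages <- list(synthio = TRUE, chromstate = TRUE, programs = TRUE,
                 synergy = TRUE, rime = TRUE)
  stages[names(cfg$stages)] <- cfg$stages
  cfg$stages <- stages
  params <- default_run_params()
  params[names(cfg$params)] <- cfg$params
  cfg$params <- params
  sim_args <- cfg$sim
  if (!is.null(sim_args$transition_kernel)) {
    sim_args$transition_kernel <- matrix(unlist(sim_args$transition_kernel),
                                         nrow = 4, byrow = TRUE,
                                         dimnames = list(CHROMATIN_STATES,
                                                         CHROMATIN_STATES))
  }
  if (!is.null(sim_args$state_mix)) {
    sim_args$state_mix <- unlist(sim_args$state_mix)
  }
  cfg$sim_config <- do.call(sim_config, c(list(seed = cfg$seed), sim_args))
  structure(cfg, class = "run_config")
}

#' Validate the inputs referenced by a run configuration
#'
#' Checks file existence, sniffs formats (BED column count, MatrixMarket
#' header, GMT shape, plate CSV dialect) and cross-references gene ids
#' between the promoter annotation and the expression matrix. Always
#' returns a report; it never throws.
#'
#' @param config a `run_config` (or path to one)
#' @return data frame with columns `level` (`"error"`/`"warning"`/`"ok"`)
#'   and `message`
#' @export
validate_inputs <- function(config) {
  if (is.character(config)) config <- run_config(config)
  rows <- list()
  note <- function(level, msg) {
    rows[[length(rows) + 1]] <<- data.frame(level = level, message = msg,
                                            stringsAsFactors = FALSE)
  }
  ins <- config$inputs
  if (isTRUE(config$stages$synthio) || is.null(ins)) {
    note("ok", "synthetic inputs will be generated; nothing to validate")
    return(do.call(rbind, rows))
  }
  check_file <- function(key) {
    p <- ins[[key]]
    if (is.null(p)) { note("warning", sprintf("input '%s' not configured", key)); return(NULL) }
    if (!file.exists(p)) { note("error", sprintf("input '%s' missing: %s", key, p)); return(NULL) }
    p
  }
  for (key in c("k4_cond1", "k27_cond1", "k4_cond2", "k27_cond2")) {
    p <- check_file(key)
    if (!is.null(p)) {
      ok <- tryCatch({ read_bed(p); TRUE }, error = function(e) {
        note("error", conditionMessage(e)); FALSE })
      if (ok) note("ok", sprintf("BED '%s' parses", p))
    }
  }
  prom_genes <- NULL
  p <- check_file("promoters")
  if (!is.null(p)) {
    prom <- tryCatch(read_tsv(p), error = function(e) NULL)
    if (is.null(prom) || !all(c("gene_id", "chrom", "tss", "strand") %in% names(prom))) {
      note("error", sprintf("promoter TSV '%s' lacks required columns", p))
    } else {
      prom_genes <- prom$gene_id
      note("ok", sprintf("promoter TSV '%s' has %d records", p, nrow(prom)))
    }
  }
  p <- check_file("counts_dir")
  if (!is.null(p)) {
    mtx <- file.path(p, "counts.mtx")
    if (!file.exists(mtx)) {
      note("error", sprintf("counts.mtx missing under %s", p))
    } else if (!grepl("^%%MatrixMarket", readLines(mtx, n = 1))) {
      note("error", sprintf("'%s' lacks a MatrixMarket header", mtx))
    } else {
      note("ok", sprintf("matrix '%s' sniffs as MatrixMarket", mtx))
      gene_f <- file.path(p, "genes.tsv")
      if (file.exists(gene_f) && !is.null(prom_genes)) {
        ov <- length(intersect(readLines(gene_f), prom_genes))
        if (ov == 0) {
          note("warning", "promoter gene ids disjoint from expression gene ids (overlap 0)")
        } else {
          note("ok", sprintf("%d gene ids shared between promoters and matrix", ov))
        }
      }
    }
  }
  p <- check_file("genesets")
  if (!is.null(p)) {
    ok <- tryCatch({ read_gmt(p); TRUE }, error = function(e) {
      note("error", sprintf("GMT '%s': %s", p, conditionMessage(e))); FALSE })
    if (ok) note("ok", sprintf("GMT '%s' parses", p))
  }
  p <- check_file("plate")
  if (!is.null(p)) {
    ok <- tryCatch({ read_plate_csv(p); TRUE }, error = function(e) {
      note("error", sprintf("plate CSV '%s': %s", p, conditionMessage(e))); FALSE })
    if (ok) note("ok", sprintf("plate CSV '%s' parses", p))
  }
  p <- check_file("spectral")
  if (!is.null(p)) {
    ok <- tryCatch({ read_spectral_counts(p); TRUE }, error = function(e) {
      note("error", sprintf("spectral TSV '%s': %s", p, conditionMessage(e))); FALSE })
    if (ok) note("ok", sprintf("spectral TSV '%s' parses", p))
  }
  do.call(rbind, rows)
}

run_stage <- function(name, fun, report) {
  res <- tryCatch(list(status = "success", value = fun()),
                  error = function(e) list(status = "failed",
                                           error = conditionMessage(e)))
  report$stages[[name]] <- res[names(res) != "value"]
  list(report = report, value = res$value, ok = res$status == "success")
}

#' Run the full pipeline from a configuration
#'
#' Stages run in dependency order (synthio feeds chromstate and programs;
#' synergy and rime are independent). A failing stage halts its dependents
#' but independent stages still complete. Every output file is recorded in
#' a manifest with its MD5 checksum, and the machine-readable report
#' (including headline tables) is written to `report.json` in the output
#' directory.
#'
#' @param config a `run_config`, or path to a YAML config
#' @param outdir output directory (created); stage outputs land in
#'   per-stage subdirectories
#' @return the report list, invisibly; `report$status` is `"success"`
#'   only if every enabled stage succeeded
#' @export
run_all <- function(config, outdir) {
  if (is.character(config)) config <- run_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  params <- config$params
  report <- list(seed = config$seed, parameters = params,
                 stages = list(), headline = list())
  paths <- character(0)
  inputs <- config$inputs

  if (isTRUE(config$stages$synthio)) {
    st <- run_stage("synthio", function() {
      simulate_all(config$sim_config, file.path(outdir, "data"),
                   window = params$gen_window)
    }, report)
    report <- st$report
    if (st$ok) {
      gen <- st$value
      paths <- c(paths, gen)
      inputs <- list(promoters = gen[["promoters"]],
                     k4_cond1 = gen[["k4_cond1"]], k27_cond1 = gen[["k27_cond1"]],
                     k4_cond2 = gen[["k4_cond2"]], k27_cond2 = gen[["k27_cond2"]],
                     counts_dir = dirname(gen[["mtx"]]),
                     cellmeta = gen[["cellmeta"]], genesets = gen[["genesets"]],
                     plate = gen[["plate"]], spectral = gen[["spectral"]],
                     de = inputs$de)
    } else {
      inputs <- NULL
    }
  }

  chrom_ok <- FALSE
  if (isTRUE(config$stages$chromstate)) {
    if (is.null(inputs)) {
      report$stages$chromstate <- list(status = "skipped",
                                       reason = "required inputs unavailable")
    } else {
      st <- run_stage("chromstate", function() {
        d <- file.path(outdir, "chromstate")
        dir.create(d, showWarnings = FALSE)
        prom <- read_tsv(inputs$promoters)
        peaks <- list(k4_cond1 = read_bed(inputs$k4_cond1),
                      k27_cond1 = read_bed(inputs$k27_cond1),
                      k4_cond2 = read_bed(inputs$k4_cond2),
                      k27_cond2 = read_bed(inputs$k27_cond2))
        pres <- assign_mark_presence(peaks, prom, window = params$window)
        states <- call_states(pres)
        tt <- transition_matrix(states[states$condition == "cond1", ],
                                states[states$condition == "cond2", ])
        out <- c(states = file.path(d, "states.tsv"),
                 transitions = file.path(d, "transitions.tsv"))
        write_tsv(states, out["states"], params = list(window = params$window))
        long <- as.data.frame(as.table(tt$counts))
        names(long) <- c("state_cond1", "state_cond2", "n_genes")
        write_tsv(long, out["transitions"], params = list(window = params$window))
        if (!is.null(inputs$de) && file.exists(inputs$de)) {
          de <- read_tsv(inputs$de)
          enr <- integrate_with_de(tt, de, direction = params$de_direction,
                                   q_max = params$q_max)
          out["enrichment"] <- file.path(d, "enrichment.tsv")
          write_tsv(enr, out["enrichment"],
                    params = list(q_max = params$q_max,
                                  direction = params$de_direction))
        }
        list(paths = out, counts = tt$counts)
      }, report)
      report <- st$report
      if (st$ok) {
        chrom_ok <- TRUE
        paths <- c(paths, st$value$paths)
        report$headline$transition_matrix <- st$value$counts
      }
    }
  }

  if (isTRUE(config$stages$programs)) {
    if (is.null(inputs)) {
      report$stages$programs <- list(status = "skipped",
                                     reason = "required inputs unavailable")
    } else {
      st <- run_stage("programs", function() {
        d <- file.path(outdir, "programs")
        dir.create(d, showWarnings = FALSE)
        counts <- read_counts_mtx(inputs$counts_dir)
        meta <- read_tsv(inputs$cellmeta)
        sets <- read_gmt(inputs$genesets)
        norm <- normalize_log(counts)
        meta <- meta[meta$cell_id %in% colnames(norm), , drop = FALSE]
        scores <- score_signatures(norm, sets)
        out <- c(scores = file.path(d, "scores.tsv"))
        write_tsv(data.frame(cell_id = rownames(scores), scores,
                             check.names = FALSE), out["scores"])
        sub <- assign_subtype(scores, level = "cluster",
                              clusters = meta$cluster[match(rownames(scores),
                                                            meta$cell_id)])
        out["subtypes"] <- file.path(d, "subtypes.tsv")
        write_tsv(sub, out["subtypes"])
        grpA <- meta$cell_id[meta$treatment == "EZH2i"]
        grpB <- meta$cell_id[meta$treatment == "vehicle"]
        de <- de_rank(norm, grpA, grpB)
        out["de"] <- file.path(d, "de.tsv")
        names(de)[names(de) == "lfc"] <- "effect"
        write_tsv(de, out["de"])
        ranking <- stats::setNames(de$stat, de$gene_id)
        gsea <- gsea_preranked(ranking, sets, n_perm = params$n_perm,
                               seed = config$seed)
        out["gsea"] <- file.path(d, "gsea.tsv")
        write_tsv(gsea, out["gsea"],
                  params = list(n_perm = params$n_perm, seed = config$seed,
                                fdr = params$gsea_fdr))
        prof_paths <- character(0)
        if ("pseudotime" %in% names(meta)) {
          pt <- meta$pseudotime[match(rownames(scores), meta$cell_id)]
          prof <- do.call(rbind, lapply(colnames(scores), function(nm) {
            pr <- pseudotime_profile(scores[, nm], pt, df = params$spline_df)
            data.frame(set = nm, pseudotime = pr$grid, fitted = pr$fitted,
                       residual_sd = pr$residual_sd)
          }))
          out["profiles"] <- file.path(d, "profiles.tsv")
          write_tsv(prof, out["profiles"], params = list(df = params$spline_df))
        }
        list(paths = out,
             top_gsea = utils::head(gsea[, c("set", "size", "nes", "q")], 5))
      }, report)
      report <- st$report
      if (st$ok) {
        paths <- c(paths, st$value$paths)
        report$headline$top_gsea <- st$value$top_gsea
      }
    }
  }

  if (isTRUE(config$stages$synergy)) {
    st <- run_stage("synergy", function() {
      d <- file.path(outdir, "synergy")
      dir.create(d, showWarnings = FALSE)
      plate <- read_plate_csv(inputs$plate)
      surf <- synergy_surface(normalize_plate(plate))
      out <- c(summary = file.path(d, "summary.tsv"),
               surface = file.path(d, "surface.tsv"))
      write_tsv(data.frame(summary_score = surf$summary_score,
                           replicate_sd = surf$replicate_sd,
                           n_wells = surf$n_wells), out["summary"])
      long <- as.data.frame(as.table(surf$delta))
      names(long) <- c("dose_a", "dose_b", "delta")
      write_tsv(long[!is.na(long$delta), ], out["surface"])
      list(paths = out, summary = surf$summary_score)
    }, report)
    report <- st$report
    if (st$ok) {
      paths <- c(paths, st$value$paths)
      report$headline$synergy_summary <- st$value$summary
    }
  }

  if (isTRUE(config$stages$rime)) {
    st <- run_stage("rime", function() {
      d <- file.path(outdir, "rime")
      dir.create(d, showWarnings = FALSE)
      tab <- read_spectral_counts(inputs$spectral)
      fdr <- nominate_fdr(tab, q_max = params$rime_q,
                          min_detected = params$rime_min_detected,
                          n_samples = params$rime_n_samples)
      venn <- nominate_venn(tab, min_count = params$rime_min_count)
      out <- c(fdr = file.path(d, "hits_fdr.tsv"),
               venn = file.path(d, "hits_venn.tsv"))
      write_tsv(fdr, out["fdr"], params = list(q = params$rime_q))
      write_tsv(venn, out["venn"], params = list(min_count = params$rime_min_count))
      list(paths = out,
           n_hits = c(fdr = sum(fdr$hit), venn = nrow(venn)))
    }, report)
    report <- st$report
    if (st$ok) {
      paths <- c(paths, st$value$paths)
      report$headline$rime_hits <- st$value$n_hits
    }
  }

  statuses <- vapply(report$stages, `[[`, character(1), "status")
  report$status <- if (all(statuses %in% c("success"))) "success" else "failed"
  manifest <- data.frame(path = unname(paths),
                         md5 = unname(tools::md5sum(unname(paths))),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$path), , drop = FALSE]
  report$manifest <- manifest
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       matrix = "rowmajor")
  invisible(report)
}
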