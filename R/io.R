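#' @importFrom utils read.table write.table head packageVersion
#' @importFrom methods as is
NULL

# Tabular outputs carry a single '#' provenance line (version + parameters)
# so every file records how it was produced; readers skip comment lines.

format_provenance <- function(params = list()) {
  ver <- as.character(utils::packageVersion("plastichrom"))
  kv <- if (length(params)) {
    paste(names(params), vapply(params, function(x) paste(format(x), collapse = ","),
                                character(1)), sep = "=", collapse = " ")
  } else ""
  trimws(paste0("# plastichrom v", ver, " ", kv))
}

#' Write a data frame as TSV with a provenance comment line
#'
#' @param df data frame to write
#' @param path output path
#' @param params named list echoed into the provenance header
#' @return `path`, invisibly
#' @export
write_tsv <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format_provenance(params), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()] (comment lines are skipped)
#'
#' @param path input path
#' @return data frame
#' @export
read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a BED / narrowPeak file of peak calls
#'
#' Requires at least three columns (chrom, start, end); extra columns are
#' ignored. Coordinates are BED-style 0-based half-open and are kept that
#' way in the returned data frame. Malformed lines raise an error naming
#' the file and line number.
#'
#' @param path BED file path
#' @return data frame with columns `chrom`, `start`, `end` (0-based half-open)
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    bad <- idx[which(nf < 3)[1]]
    stop(sprintf("malformed BED line (fewer than 3 columns) in '%s' at line %d",
                 path, bad))
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | end < start)
  if (length(bad)) {
    stop(sprintf("malformed BED coordinates in '%s' at line %d", path, idx[bad[1]]))
  }
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Write peak intervals as a sorted BED file
#'
#' Intervals are written 0-based half-open and sorted by (chrom, start, end).
#'
#' @param peaks data frame with `chrom`, `start`, `end` and optionally `name`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed <- function(peaks, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)))
  ord <- order(peaks$chrom, peaks$start, peaks$end)
  peaks <- peaks[ord, , drop = FALSE]
  cols <- c("chrom", "start", "end", intersect("name", names(peaks)))
  write.table(peaks[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' @param path GMT file path
#' @return named list of character vectors of gene ids; the `description`
#'   field is attached as the `"desc"` attribute of each element
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3) stop("GMT line needs name, description and >=1 gene")
    structure(f[-(1:2)], desc = f[2])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1)
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    desc <- attr(sets[[i]], "desc")
    if (is.null(desc)) desc <- "na"
    paste(c(names(sets)[i], desc, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a genes x cells count matrix as MTX plus row/column id TSVs
#'
#' @param counts sparse or dense matrix, genes in rows, cells in columns,
#'   with dimnames set
#' @param dir output directory (created if missing)
#' @param prefix file-name prefix, default `"counts"`
#' @return paths of the three files written, invisibly
#' @export
write_counts_mtx <- function(counts, dir, prefix = "counts") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  mtx <- file.path(dir, paste0(prefix, ".mtx"))
  Matrix::writeMM(m, mtx)
  genes <- file.path(dir, "genes.tsv")
  cells <- file.path(dir, "cells.tsv")
  writeLines(rownames(counts), genes)
  writeLines(colnames(counts), cells)
  invisible(c(mtx = mtx, genes = genes, cells = cells))
}

#' Read a genes x cells count matrix written by [write_counts_mtx()]
#'
#' @param dir directory holding `<prefix>.mtx`, `genes.tsv` and `cells.tsv`
#' @param prefix file-name prefix, default `"counts"`
#' @return sparse dgCMatrix with gene ids as rownames and cell ids as colnames
#' @export
read_counts_mtx <- function(dir, prefix = "counts") {
  m <- Matrix::readMM(file.path(dir, paste0(prefix, ".mtx")))
  m <- as(m, "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "genes.tsv"))
  colnames(m) <- readLines(file.path(dir, "cells.tsv"))
  m
}

#' Read a dose-response plate CSV
#'
#' The first row holds doses of drug B, the first column doses of drug A
#' (zero dose first); the body is raw luminescence. Replicate blocks are
#' separated by blank lines, or supplied as separate files.
#'
#' @param path plate CSV path
#' @return object of class `plate_grid`: list with `doses_a`, `doses_b`
#'   and `replicates`, a list of doses_a x doses_b luminescence matrices
#' @export
read_plate_csv <- function(path) {
  lines <- readLines(path)
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(c(TRUE, diff(blank) == -1))[!blank]
  blocks <- split(lines[!blank], grp)
  reps <- lapply(blocks, function(bl) {
    cells <- strsplit(bl, ",", fixed = TRUE)
    header <- suppressWarnings(as.numeric(cells[[1]][-1]))
    body <- cells[-1]
    doses_a <- suppressWarnings(as.numeric(vapply(body, `[[`, character(1), 1)))
    vals <- t(vapply(body, function(r) suppressWarnings(as.numeric(r[-1])),
                     numeric(length(header))))
    if (anyNA(header) || anyNA(doses_a) || anyNA(vals)) {
      stop(sprintf("non-numeric entry in plate CSV '%s'", path))
    }
    dimnames(vals) <- list(format(doses_a, trim = TRUE),
                           format(header, trim = TRUE))
    list(doses_a = doses_a, doses_b = header, values = vals)
  })
  doses_a <- reps[[1]]$doses_a
  doses_b <- reps[[1]]$doses_b
  for (r in reps) {
    if (!identical(r$doses_a, doses_a) || !identical(r$doses_b, doses_b)) {
      stop("replicate blocks have differing dose grids")
    }
  }
  plate_grid(lapply(reps, `[[`, "values"), doses_a, doses_b)
}

#' Construct a plate grid object
#'
#' @param replicates list of doses_a x doses_b luminescence matrices
#' @param doses_a,doses_b numeric dose vectors, zero first, sorted
#' @return `plate_grid` object
#' @export
plate_grid <- function(replicates, doses_a, doses_b) {
  if (is.matrix(replicates)) replicates <- list(replicates)
  if (!0 %in% doses_a || !0 %in% doses_b) {
    stop("plate must include the zero dose of each drug (control wells)")
  }
  if (is.unsorted(doses_a) || is.unsorted(doses_b) ||
      any(doses_a < 0) || any(doses_b < 0)) {
    stop("doses must be non-negative and sorted increasing")
  }
  for (m in replicates) {
    stopifnot(nrow(m) == length(doses_a), ncol(m) == length(doses_b))
  }
  structure(list(replicates = replicates, doses_a = doses_a, doses_b = doses_b),
            class = "plate_grid")
}

#' Write a plate grid back to CSV (replicates separated by blank lines)
#' @param plate `plate_grid` object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_plate_csv <- function(plate, path) {
  out <- character(0)
  for (i in seq_along(plate$replicates)) {
    m <- plate$replicates[[i]]
    header <- paste(c("dose_a\\dose_b", format(plate$doses_b, trim = TRUE)),
                    collapse = ",")
    rows <- vapply(seq_along(plate$doses_a), function(r) {
      paste(c(format(plate$doses_a[r], trim = TRUE),
              format(m[r, ], trim = TRUE, digits = 15)), collapse = ",")
    }, character(1))
    out <- c(out, header, rows, if (i < length(plate$replicates)) "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a protein x replicate spectral-count table
#'
#' Column headers after `protein_id` encode arm, sample and replicate as
#' `arm:sample:rep`, e.g. `bait:SKO:rep1` or `IgG:SKO:rep2`.
#'
#' @param path TSV path
#' @return object of class `spectral_counts`: list with integer matrix
#'   `counts` (proteins x replicates), and data frame `arms` describing
#'   each column (`arm`, `sample`, `rep`)
#' @export
read_spectral_counts <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(names(df)[1] == "protein_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$protein_id
  spectral_counts(m)
}

#' Construct a spectral-count table from a labelled count matrix
#'
#' @param counts proteins x replicates integer matrix; column names must be
#'   `arm:sample:rep` labels with arm in `bait`/`IgG`
#' @return `spectral_counts` object
#' @export
spectral_counts <- function(counts) {
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("spectral counts must be non-negative integers")
  }
  parts <- strsplit(colnames(counts), ":", fixed = TRUE)
  if (any(lengths(parts) != 3)) {
    stop("spectral-count column headers must be 'arm:sample:rep'")
  }
  arms <- data.frame(arm = vapply(parts, `[[`, character(1), 1),
                     sample = vapply(parts, `[[`, character(1), 2),
                     rep = vapply(parts, `[[`, character(1), 3),
                     stringsAsFactors = FALSE)
  if (!all(arms$arm %in% c("bait", "IgG"))) {
    stop("spectral-count arm labels must be 'bait' or 'IgG'")
  }
  if (!all(c("bait", "IgG") %in% arms$arm)) {
    stop("spectral-count table needs at least one replicate per arm")
  }
  structure(list(counts = counts, arms = arms), class = "spectral_counts")
}

#' Write a spectral-count table as TSV
#' @param sc `spectral_counts` object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_spectral_counts <- function(sc, path) {
  df <- data.frame(protein_id = rownames(sc$counts), sc$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
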