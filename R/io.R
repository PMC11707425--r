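# io_model: readers, writers, cohort alignment.
#
# On-disk conventions: expression / mutation / clinical travel as TSV with a
# header; gene sets as GMT; PPI as a 2-column edge list; mutations optionally
# as MAF. Writers prepend one '#' provenance comment line, readers skip '#'
# lines.

DEFAULT_NONSILENT <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
  "Frame_Shift_Ins", "Splice_Site", "In_Frame_Del", "In_Frame_Ins",
  "Translation_Start_Site", "Nonstop_Mutation"
)

#' Read a gene x sample expression matrix
#'
#' Reads a TSV/CSV with gene rows (first column = gene symbol) and sample
#' columns. Duplicate gene rows are collapsed by keeping the row with the
#' highest mean; missing values are imputed by the gene-wise median; genes
#' with zero variance across samples are dropped; an optional
#' `log2(x + 1)` transform is applied last.
#'
#' @param path Path to a delimited text file. `#`-prefixed lines are skipped.
#' @param sep Field separator; guessed from the extension when `NULL`
#'   (`","` for `.csv`, tab otherwise).
#' @param log_transform Apply `log2(x + 1)`? Default `FALSE` (input is
#'   expected to be log-scale normalized already).
#' @param drop_zero_var Drop constant genes? Default `TRUE`.
#' @return Numeric matrix (genes x samples) with unique dimnames.
#' @export
read_expression <- function(path, sep = NULL, log_transform = FALSE,
                            drop_zero_var = TRUE) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) stopf("empty expression matrix: %s", path)
  genes <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
      stopf("non-numeric cell at gene '%s', sample '%s'",
            genes[bad], colnames(vals)[j])
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  m <- collapse_duplicate_genes(m)
  m <- impute_gene_median(m)
  if (drop_zero_var) {
    v <- apply(m, 1, var)
    dropped <- sum(v == 0)
    if (dropped > 0) idicss_log(dropped, " zero-variance genes dropped")
    m <- m[v > 0, , drop = FALSE]
  }
  if (nrow(m) == 0L) stopf("no genes left after filtering: %s", path)
  if (log_transform) m <- log2(m + 1)
  m
}

# Keep, for each duplicated symbol, the row with the highest mean.
#' @noRd
collapse_duplicate_genes <- function(m) {
  if (!anyDuplicated(rownames(m))) return(m)
  mu <- rowMeans(m, na.rm = TRUE)
  ord <- order(rownames(m), -mu)
  m <- m[ord, , drop = FALSE]
  m[!duplicated(rownames(m)), , drop = FALSE]
}

#' @noRd
impute_gene_median <- function(m) {
  if (!anyNA(m)) return(m)
  for (i in which(rowSums(is.na(m)) > 0)) {
    med <- median(m[i, ], na.rm = TRUE)
    if (is.na(med)) med <- 0
    m[i, is.na(m[i, ])] <- med
  }
  m
}

#' Write a matrix as TSV with a provenance comment line
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param id_column Name of the first (row ID) column.
#' @param provenance One-line provenance note written as a `#` comment.
#' @export
write_matrix_tsv <- function(m, path, id_column = "gene",
                             provenance = "idicss") {
  assert_matrix_named(m, "matrix to write")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s | %s", provenance, format(Sys.time(), "%Y-%m-%d")), con)
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Read a MAF into a binary gene x sample mutation matrix
#'
#' A cell is 1 iff the sample carries at least one record of a non-silent
#' variant class in that gene. Sample barcodes are truncated to
#' `barcode_len` characters (TCGA convention).
#'
#' @param path MAF-style TSV with at least `Hugo_Symbol`,
#'   `Tumor_Sample_Barcode`, `Variant_Classification`.
#' @param nonsilent_classes Variant classes counted as mutations.
#' @param barcode_len Barcode truncation length; `NA` disables truncation.
#' @return Binary integer matrix (genes x samples).
#' @export
read_maf <- function(path, nonsilent_classes = DEFAULT_NONSILENT,
                     barcode_len = 15L) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   comment.char = "#", stringsAsFactors = FALSE)
  req <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  missing_cols <- setdiff(req, colnames(df))
  if (length(missing_cols))
    stopf("MAF missing required column(s): %s", paste(missing_cols, collapse = ", "))
  if (!is.na(barcode_len))
    df$Tumor_Sample_Barcode <- substr(df$Tumor_Sample_Barcode, 1L, barcode_len)
  df <- df[df$Variant_Classification %in% nonsilent_classes, , drop = FALSE]
  if (nrow(df) == 0L) {
    warning("MAF contains no non-silent records; returning 0-gene matrix")
    return(matrix(0L, 0, 0, dimnames = list(character(), character())))
  }
  genes <- sort(unique(df$Hugo_Symbol))
  samples <- sort(unique(df$Tumor_Sample_Barcode))
  m <- matrix(0L, length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(match(df$Hugo_Symbol, genes),
          match(df$Tumor_Sample_Barcode, samples))] <- 1L
  m
}

#' Read a precomputed binary mutation matrix from TSV
#'
#' @param path TSV with gene rows and sample columns; entries 0/1.
#' @return Binary integer matrix (genes x samples).
#' @export
read_mutation_matrix <- function(path) {
  m <- read_expression(path, drop_zero_var = FALSE)
  if (!all(m %in% c(0, 1))) stopf("mutation matrix entries must be 0/1")
  storage.mode(m) <- "integer"
  m
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name<TAB>description<TAB>gene1<TAB>...`.
#' @return Named list of unique gene-symbol character vectors, with a
#'   `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) stopf("GMT line %d has fewer than 3 fields", short[1])
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) stopf("duplicate gene-set name: %s", nm[duplicated(nm)][1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  attr(sets, "description") <- setNames(vapply(fields, `[[`, character(1), 2L), nm)
  sets
}

#' Write a gene-set collection as GMT
#' @param sets Named list of gene vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- setNames(rep("idicss", length(sets)), names(sets))
  lines <- vapply(names(sets), function(n) {
    paste(c(n, desc[[n]], sets[[n]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an undirected PPI network from a 2-column edge list
#'
#' Self-loops and duplicate edges are removed.
#'
#' @param path TSV with two columns of gene symbols (header optional; a
#'   header is detected when the first line repeats in no edge).
#' @return An [igraph::graph] object, undirected and simple.
#' @export
read_ppi <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("PPI edge list needs 2 columns")
  g <- igraph::graph_from_data_frame(df[, 1:2], directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a PPI network as a 2-column edge list TSV
#' @param g igraph object.
#' @param path Output path.
#' @export
write_ppi <- function(g, path) {
  el <- igraph::as_edgelist(g)
  df <- data.frame(gene_a = el[, 1], gene_b = el[, 2])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Expected columns: `sample`, `os_time`, `os_event`; optional `pfs_time`,
#' `pfs_event`, `response`. Times are stored in days; when
#' `time_unit = "months"` they are converted by x 30.44.
#'
#' @param path TSV path.
#' @param time_unit `"days"` (default) or `"months"`.
#' @return A tibble, one row per sample.
#' @export
read_clinical <- function(path, time_unit = c("days", "months")) {
  time_unit <- match.arg(time_unit)
  df <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  validate_clinical(tibble::as_tibble(df), convert_months = time_unit == "months")
}

#' @noRd
validate_clinical <- function(df, convert_months = FALSE) {
  req <- c("sample", "os_time", "os_event")
  miss <- setdiff(req, colnames(df))
  if (length(miss)) stopf("clinical table missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample)) stopf("duplicate sample IDs in clinical table")
  tcols <- intersect(c("os_time", "pfs_time"), colnames(df))
  if (convert_months) df[tcols] <- lapply(df[tcols], function(x) x * 30.44)
  for (cc in tcols) if (any(df[[cc]] < 0, na.rm = TRUE))
    stopf("negative times in column %s", cc)
  for (cc in intersect(c("os_event", "pfs_event"), colnames(df)))
    if (!all(df[[cc]] %in% c(0, 1, NA))) stopf("%s must be 0/1", cc)
  tibble::as_tibble(df)
}

#' Assemble and align a cohort bundle
#'
#' Restricts all parts to samples present in both expression and clinical,
#' reorders everything to the expression sample order, and records how many
#' samples were kept or dropped.
#'
#' @param expression Gene x sample matrix.
#' @param clinical Clinical tibble (see [read_clinical()]).
#' @param mutations Optional binary gene x sample matrix.
#' @param metadata Optional named list of free-form labels.
#' @return An object of class `cohort_bundle`: a list with elements
#'   `expression`, `mutations` (or `NULL`), `clinical`, `metadata`,
#'   `alignment` (kept/dropped counts).
#' @export
align_cohort <- function(expression, clinical, mutations = NULL,
                         metadata = list()) {
  assert_matrix_named(expression, "expression")
  clinical <- validate_clinical(tibble::as_tibble(clinical))
  keep <- intersect(colnames(expression), clinical$sample)
  if (length(keep) == 0L) stopf("no samples shared by expression and clinical")
  keep <- colnames(expression)[colnames(expression) %in% keep]
  alignment <- list(
    n_kept = length(keep),
    n_dropped_expression = ncol(expression) - length(keep),
    n_dropped_clinical = nrow(clinical) - length(keep),
    has_mutations = !is.null(mutations)
  )
  expression <- expression[, keep, drop = FALSE]
  clinical <- clinical[match(keep, clinical$sample), , drop = FALSE]
  if (!is.null(mutations)) {
    shared <- intersect(colnames(mutations), keep)
    m <- matrix(0L, nrow(mutations), length(keep),
                dimnames = list(rownames(mutations), keep))
    m[, shared] <- mutations[, shared]
    mutations <- m
    alignment$n_mutation_samples <- length(shared)
  }
  idicss_log("aligned cohort: ", alignment$n_kept, " samples kept")
  structure(
    list(expression = expression, mutations = mutations, clinical = clinical,
         metadata = metadata, alignment = alignment),
    class = "cohort_bundle"
  )
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("<cohort_bundle> %d genes x %d samples; mutations: %s; clinical: %d rows\n",
              nrow(x$expression), ncol(x$expression),
              if (is.null(x$mutations)) "absent"
              else sprintf("%d genes", nrow(x$mutations)),
              nrow(x$clinical)))
  invisible(x)
}

#' Write a cohort bundle to a directory as TSV files
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(bundle$expression, file.path(dir, "expression.tsv"),
                   provenance = "idicss expression")
  if (!is.null(bundle$mutations))
    write_matrix_tsv(bundle$mutations, file.path(dir, "mutations.tsv"),
                     provenance = "idicss mutations")
  write.table(bundle$clinical, file.path(dir, "clinical.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort bundle written by [write_cohort()]
#' @param dir Directory containing `expression.tsv`, `clinical.tsv` and
#'   optionally `mutations.tsv`.
#' @return A `cohort_bundle`.
#' @export
read_cohort <- function(dir) {
  mut_path <- file.path(dir, "mutations.tsv")
  align_cohort(
    expression = read_expression(file.path(dir, "expression.tsv")),
    clinical = read_clinical(file.path(dir, "clinical.tsv")),
    mutations = if (file.exists(mut_path)) read_mutation_matrix(mut_path)
  )
}
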