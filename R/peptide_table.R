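#' Construct a peptide quantitation table
#'
#' The central container of the package: a matrix of log2 peptide abundances
#' (rows = peptides, columns = samples) together with a peptide-to-protein
#' map. Missing intensities are stored as `NA`; non-finite values (the
#' footprint of taking `log2(0)`) are rejected so that no negative-infinity
#' sentinel survives ingestion.
#'
#' @param abundance numeric matrix of log2 intensities with unique rownames
#'   (peptide ids) and unique colnames (sample ids). `NA` entries mark
#'   missing observations.
#' @param protein_map named list (one entry per peptide, in row order) of
#'   character vectors of protein accessions, or a character vector of
#'   `;`-separated accessions. Every peptide must map to at least one
#'   accession. Shared peptides (more than one accession) are allowed and
#'   belong to the set of every protein they map to.
#' @param meta optional list of provenance metadata carried along and
#'   written into output headers.
#'
#' @return an object of class `PeptideQuantTable` with elements
#'   `abundance`, `protein_map`, `peptide_ids`, `sample_ids`, `meta`.
#' @export
peptide_quant_table <- function(abundance, protein_map, meta = list()) {
  if (!is.matrix(abundance) || !is.numeric(abundance))
    stop("'abundance' must be a numeric matrix")
  if ((nrow(abundance) > 0L && is.null(rownames(abundance))) ||
      is.null(colnames(abundance)))
    stop("'abundance' must have peptide rownames and sample colnames")
  if (anyDuplicated(rownames(abundance)))
    stop("duplicate peptide ids in 'abundance'")
  if (anyDuplicated(colnames(abundance)))
    stop("duplicate sample ids in 'abundance'")
  bad <- !is.na(abundance) & !is.finite(abundance)
  if (any(bad))
    stop("non-finite abundance values present (log2 of zero intensities ",
         "must be encoded as NA)")
  if (is.character(protein_map))
    protein_map <- strsplit(protein_map, ";", fixed = TRUE)
  if (!is.list(protein_map) || length(protein_map) != nrow(abundance))
    stop("'protein_map' must have one entry per peptide")
  protein_map <- lapply(protein_map, function(p) {
    p <- unlist(strsplit(as.character(p), ";", fixed = TRUE))
    p <- trimws(p)
    unique(p[nzchar(p)])
  })
  if (any(lengths(protein_map) == 0L))
    stop("every peptide must map to at least one protein accession")
  names(protein_map) <- rownames(abundance)
  structure(
    list(abundance   = abundance,
         protein_map = protein_map,
         peptide_ids = if (is.null(rownames(abundance))) character()
                       else rownames(abundance),
         sample_ids  = colnames(abundance),
         meta        = meta),
    class = "PeptideQuantTable")
}

#' @export
print.PeptideQuantTable <- function(x, ...) {
  n_prot <- length(unique(unlist(x$protein_map, use.names = FALSE)))
  n_miss <- sum(is.na(x$abundance))
  cat(sprintf(
    "PeptideQuantTable: %d peptides x %d samples, %d proteins, %d missing (%.1f%%)\n",
    nrow(x$abundance), ncol(x$abundance), n_prot, n_miss,
    100 * n_miss / length(x$abundance)))
  invisible(x)
}

#' @export
dim.PeptideQuantTable <- function(x) dim(x$abundance)

#' Subset a peptide table by peptide and/or sample
#'
#' @param table a `PeptideQuantTable`.
#' @param peptides character or integer index of peptides to keep.
#' @param samples character or integer index of samples to keep.
#' @return the subsetted `PeptideQuantTable` (row/column order follows the
#'   index).
#' @export
subset_peptides <- function(table, peptides = NULL, samples = NULL) {
  stopifnot(inherits(table, "PeptideQuantTable"))
  ab <- table$abundance
  if (!is.null(peptides)) ab <- ab[peptides, , drop = FALSE]
  if (!is.null(samples)) ab <- ab[, samples, drop = FALSE]
  if (nrow(ab) == 0L && is.null(rownames(ab)))
    rownames(ab) <- character()          # R drops dimnames on empty subsets
  peptide_quant_table(ab, table$protein_map[rownames(ab)], table$meta)
}

#' Map proteins to the peptides assigned to them
#'
#' Inverts the peptide-to-protein map. Shared peptides appear in the index
#' of every protein they map to.
#'
#' @param table a `PeptideQuantTable`.
#' @return named list: for each protein accession, the integer row indices
#'   of its peptides.
#' @export
protein_index <- function(table) {
  stopifnot(inherits(table, "PeptideQuantTable"))
  pm <- table$protein_map
  long_prot <- unlist(pm, use.names = FALSE)
  long_row <- rep.int(seq_along(pm), lengths(pm))
  split(long_row, long_prot)
}

#' Read a wide peptide quantitation table
#'
#' Supports two TSV dialects. The `generic` dialect expects one id column,
#' one protein column (`;`-separated accessions) and one intensity column
#' per sample (optionally sharing a common prefix that is stripped to give
#' sample ids). The `maxquant` dialect applies the MaxQuant `peptides.txt`
#' conventions: `Sequence` ids, `Proteins` accessions, `Intensity <sample>`
#' columns, and removal of rows whose accessions carry the contaminant or
#' reverse decoy prefixes.
#'
#' Raw intensities are log2-transformed on ingestion; zero and empty cells
#' become `NA` (standard MS practice: a zero is a non-detection, not an
#' abundance of one).
#'
#' @param path path to a TSV file. Lines starting with `#` (the YAML
#'   header block written by [write_peptide_table()]) are skipped.
#' @param dialect `"generic"` or `"maxquant"`.
#' @param id_col name of the peptide id column.
#' @param protein_col name of the protein accession column.
#' @param intensity_prefix common prefix of intensity columns, stripped to
#'   obtain sample ids. `""` selects every column other than `id_col` and
#'   `protein_col`.
#' @param contaminant_prefixes accession prefixes whose rows are dropped in
#'   the `maxquant` dialect.
#' @return a [peptide_quant_table()].
#' @export
read_peptide_table <- function(path,
                               dialect = c("generic", "maxquant"),
                               id_col = NULL,
                               protein_col = NULL,
                               intensity_prefix = NULL,
                               contaminant_prefixes = c("CON__", "REV__")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(id_col))
    id_col <- if (dialect == "maxquant") "Sequence" else "peptide"
  if (is.null(protein_col))
    protein_col <- if (dialect == "maxquant") "Proteins" else "protein"
  if (is.null(intensity_prefix))
    intensity_prefix <- if (dialect == "maxquant") "Intensity " else ""
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  for (col in c(id_col, protein_col))
    if (!col %in% names(df))
      stop("format error: required column '", col, "' not found in ", path)
  if (anyDuplicated(df[[id_col]]))
    stop("ingestion error: duplicate peptide ids in column '", id_col, "'")
  if (nzchar(intensity_prefix)) {
    int_cols <- names(df)[startsWith(names(df), intensity_prefix)]
    sample_ids <- substring(int_cols, nchar(intensity_prefix) + 1L)
  } else {
    int_cols <- setdiff(names(df), c(id_col, protein_col))
    sample_ids <- int_cols
  }
  if (length(int_cols) == 0L)
    stop("format error: no intensity columns matching prefix '",
         intensity_prefix, "'")
  prot <- strsplit(as.character(df[[protein_col]]), ";", fixed = TRUE)
  if (dialect == "maxquant") {
    is_decoy <- vapply(prot, function(p) {
      any(vapply(contaminant_prefixes,
                 function(pre) any(startsWith(p, pre)), logical(1)))
    }, logical(1))
    df <- df[!is_decoy, , drop = FALSE]
    prot <- prot[!is_decoy]
  }
  raw <- as.matrix(df[, int_cols, drop = FALSE])
  mode(raw) <- "numeric"
  raw[!is.na(raw) & raw <= 0] <- NA      # zero intensity == missing
  ab <- log2(raw)
  dimnames(ab) <- list(df[[id_col]], sample_ids)
  peptide_quant_table(ab, prot,
                      meta = list(source = path, dialect = dialect))
}

#' Write a peptide table as TSV with a YAML header block
#'
#' Intensities are written on the raw scale (`2^abundance`, the scale a
#' quantitation tool would emit) at full double precision, so that a
#' write/[read_peptide_table()] round trip reproduces the log2 abundance
#' matrix to better than 1e-9.
#'
#' @param table a `PeptideQuantTable`.
#' @param path output path.
#' @param params optional named list recorded in the `#`-commented YAML
#'   header along with the package version.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(table, path, params = list()) {
  stopifnot(inherits(table, "PeptideQuantTable"))
  hdr <- yaml_header(c(list(format = "pepset/peptide-table"), params))
  df <- data.frame(
    peptide = table$peptide_ids,
    protein = vapply(table$protein_map, paste, "", collapse = ";"),
    check.names = FALSE, stringsAsFactors = FALSE)
  raw <- 2^table$abundance
  ab <- format(raw, digits = 17, trim = TRUE, scientific = TRUE)
  ab[is.na(table$abundance)] <- "NA"
  df <- cbind(df, as.data.frame(ab, stringsAsFactors = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Render a named list as a '# '-commented YAML block.
yaml_header <- function(params) {
  txt <- yaml::as.yaml(params)
  c("# ---", paste0("# ", strsplit(txt, "\n", fixed = TRUE)[[1]]), "# ---")
}

#' Filter peptides on per-row missingness
#'
#' Keeps peptides observed (non-missing) in at least a fraction `min_frac`
#' of samples. "At least 70% of samples" is implemented as a count of
#' `ceiling(min_frac * n_samples)`, the conservative reading. Row order of
#' the survivors is preserved.
#'
#' @param table a `PeptideQuantTable`.
#' @param min_frac required fraction of observed samples, in (0, 1].
#'   Default 0.7, the usual rule in label-free proteomics.
#' @return the filtered `PeptideQuantTable`; a warning (not an error) is
#'   raised when nothing survives.
#' @export
filter_missing <- function(table, min_frac = 0.7) {
  stopifnot(inherits(table, "PeptideQuantTable"))
  if (!is.numeric(min_frac) || length(min_frac) != 1L ||
      min_frac <= 0 || min_frac > 1)
    stop("'min_frac' must be a single number in (0, 1]")
  need <- ceiling(min_frac * ncol(table$abundance))
  keep <- rowSums(!is.na(table$abundance)) >= need
  if (!any(keep))
    warning("no peptides pass the ", min_frac * 100, "% missingness filter")
  subset_peptides(table, which(keep))
}

#' Per-sample normalization of a peptide table
#'
#' `median_center` subtracts each sample's observed median and adds back
#' the grand median (the median of the per-sample medians), equalizing
#' column medians while leaving within-sample differences untouched.
#'
#' @param table a `PeptideQuantTable`.
#' @param method `"median_center"` or `"none"`.
#' @return the normalized `PeptideQuantTable` with the method recorded in
#'   `meta$normalization`.
#' @export
normalize_columns <- function(table, method = c("median_center", "none")) {
  stopifnot(inherits(table, "PeptideQuantTable"))
  method <- match.arg(method)
  if (method == "none") return(table)
  ab <- table$abundance
  n_obs <- colSums(!is.na(ab))
  if (any(n_obs == 0L))
    stop("sample(s) with no observed values: ",
         paste(colnames(ab)[n_obs == 0L], collapse = ", "))
  med <- apply(ab, 2L, stats::median, na.rm = TRUE)
  ab <- sweep(ab, 2L, med - stats::median(med))
  meta <- table$meta
  meta$normalization <- method
  peptide_quant_table(ab, table$protein_map, meta)
}
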