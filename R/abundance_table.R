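#' Construct an abundance table
#'
#' The central container of the pipeline: a samples x taxa matrix of
#' non-negative integer counts, with optional rank-labelled taxonomy strings
#' per taxon. All downstream diversity, network and assembly computations
#' consume this object.
#'
#' @param counts numeric matrix, samples in rows, taxa in columns; rownames
#'   are sample ids, colnames taxon ids. Values must be non-negative and
#'   integer-valued.
#' @param taxonomy optional named character vector mapping taxon id to a
#'   lineage string (e.g. `"k__Bacteria;p__Acidobacteria;..."`). Every name
#'   must be a taxon of `counts`.
#' @return an object of class `abundance_table` with elements `counts` and
#'   `taxonomy`.
#' @export
abundance_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample rownames and taxon colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate taxon ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at sample '%s', taxon '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integer-valued")
  storage.mode(counts) <- "double"
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy))) stop("taxonomy must be named by taxon id")
    missing <- setdiff(names(taxonomy), colnames(counts))
    if (length(missing))
      stop("taxonomy refers to taxa absent from the table: ",
           paste(missing, collapse = ", "))
  }
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa, %s reads total\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  if (!is.null(x$taxonomy))
    cat(sprintf("  taxonomy strings for %d taxa\n", length(x$taxonomy)))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

#' Sample ids and taxon ids of an abundance table
#' @param table an [abundance_table()]
#' @return character vector of identifiers
#' @export
sample_ids <- function(table) rownames(table$counts)

#' @rdname sample_ids
#' @export
taxon_ids <- function(table) colnames(table$counts)

#' Relative abundances of an abundance table
#' @param table an [abundance_table()]
#' @return samples x taxa matrix of row-proportions
#' @export
relative_abundance <- function(table) {
  tot <- rowSums(table$counts)
  if (any(tot == 0))
    stop("sample(s) with zero total count: ",
         paste(rownames(table$counts)[tot == 0], collapse = ", "))
  sweep(table$counts, 1, tot, "/")
}

#' Read an abundance table from a tab-separated file
#'
#' Expects taxa in rows: the first column holds taxon ids, the remaining
#' columns one sample each, and an optional final column named `taxonomy`
#' holding lineage strings. This is the orientation OTU tables are usually
#' shipped in; the returned object is transposed to samples x taxa.
#'
#' @param path path to a TSV file with a header row.
#' @return an [abundance_table()].
#' @export
read_abundance_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("abundance table needs at least one sample column")
  taxa <- as.character(df[[1]])
  df <- df[-1]
  taxonomy <- NULL
  if (tolower(names(df)[ncol(df)]) == "taxonomy") {
    taxonomy <- stats::setNames(as.character(df[[ncol(df)]]), taxa)
    df <- df[-ncol(df)]
  }
  num <- vapply(df, is.numeric, logical(1))
  if (!all(num))
    stop("non-numeric count column(s): ", paste(names(df)[!num], collapse = ", "))
  counts <- t(as.matrix(df))
  colnames(counts) <- taxa
  abundance_table(counts, taxonomy)
}

#' Write an abundance table to a tab-separated file
#'
#' Inverse of [read_abundance_table()]: taxa in rows, samples in columns,
#' taxonomy (if present) as the last column. Reading the written file back
#' reproduces the counts exactly.
#'
#' @param table an [abundance_table()]
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  m <- t(table$counts)
  df <- data.frame(taxon_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(table$taxonomy))
    df$taxonomy <- unname(table$taxonomy[rownames(m)])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' @param path CSV with columns `sample_id`, `level` (one of CK, L, M, H) and
#'   `replicate`.
#' @param table optional [abundance_table()]; if given, every sample of the
#'   table must have exactly one metadata row.
#' @return data.frame with `level` as a factor ordered CK < L < M < H.
#' @export
read_metadata <- function(path, table = NULL) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "level", "replicate")
  if (!all(need %in% names(md)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(md$level), c("CK", "L", "M", "H"))
  if (length(bad)) stop("unknown treatment level(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata")
  md$level <- factor(md$level, levels = c("CK", "L", "M", "H"))
  if (!is.null(table)) {
    miss <- setdiff(sample_ids(table), md$sample_id)
    if (length(miss))
      stop("samples without metadata: ", paste(miss, collapse = ", "))
  }
  md
}
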