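#' Count reads per gene
#'
#' Gene-level counting of validated reads: each read contributes one count to
#' its assigned gene; genes with no reads get 0. The column's library size is
#' the total number of retained reads.
#'
#' @param reads An `aligned_reads` data.frame.
#' @param annotation A `gene_annotation` (defines the gene universe and row
#'   order of the result).
#' @param sample_id Column name for the resulting one-sample count table.
#' @return A `count_table`: an integer matrix (genes x samples) with
#'   rownames = gene ids.
#' @export
count_reads <- function(reads, annotation, sample_id = "sample1") {
  counts <- table(factor(reads$gene_id, levels = annotation$gene_id))
  m <- matrix(as.integer(counts), ncol = 1,
              dimnames = list(annotation$gene_id, sample_id))
  as_count_table(m)
}

#' Construct and validate a count table
#'
#' A count table is an integer matrix of non-negative gene x sample counts;
#' library sizes are always derived as column sums, never stored separately.
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @return The validated matrix with class `count_table`.
#' @export
as_count_table <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  if (any(m < 0)) stop("count table validation error: negative counts")
  if (any(m != round(m))) stop("count table validation error: non-integer counts")
  storage.mode(m) <- "integer"
  class(m) <- c("count_table", class(m))
  m
}

#' Library sizes of a count table
#' @param table A `count_table`.
#' @return Named integer vector of per-sample column sums.
#' @export
library_sizes <- function(table) colSums(table)

#' Combine single-sample count tables by column
#' @param ... `count_table` objects sharing the same gene set and order.
#' @return A combined `count_table`.
#' @export
cbind_counts <- function(...) {
  tabs <- list(...)
  genes <- rownames(tabs[[1]])
  for (t in tabs) stopifnot(identical(rownames(t), genes))
  as_count_table(do.call(cbind, lapply(tabs, unclass)))
}

#' Reads-per-million normalization
#'
#' `rpm(g, s) = count(g, s) / library_size(s) * 1e6`. Each column of the
#' result sums to 1e6.
#'
#' @param table A `count_table`.
#' @return A numeric matrix of RPM values with the same dimnames.
#' @export
rpm_normalize <- function(table) {
  ls <- library_sizes(table)
  zero <- ls == 0
  if (any(zero)) {
    stop("rpm_normalize: zero library size for sample(s) ",
         paste(names(ls)[zero], collapse = ", "))
  }
  sweep(unclass(table), 2, ls, "/") * 1e6
}

#' Read a gene x sample count table from TSV
#' @param path TSV with first column `gene_id` and one column per sample.
#' @return A `count_table`.
#' @export
read_count_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "gene_id") {
    stop("count table format error: first column must be gene_id")
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene_id
  as_count_table(m)
}

#' Write a count table to TSV
#' @param table A `count_table`.
#' @param path Output path.
#' @export
write_count_table <- function(table, path) {
  out <- data.frame(gene_id = rownames(table), unclass(table),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
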