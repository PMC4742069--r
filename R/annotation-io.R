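#' Load a gene annotation table
#'
#' Reads a tab-separated annotation of coding sequences in transcript space.
#' Each gene is a CDS reference extended a fixed number of nucleotides
#' upstream of the start codon (default convention: 25 nt), with a flag
#' marking genes carrying a 5'-terminal oligopyrimidine (TOP) motif.
#'
#' Coordinates throughout the package are 0-based with position 0 at the
#' first base of the start codon; upstream positions are negative, so a gene
#' with `upstream_extension = 25` admits aligned 5' ends down to -25.
#'
#' @param path Path to a TSV file with header columns `gene_id`,
#'   `cds_length`, `upstream_extension`, `is_top`.
#' @return A data.frame of class `gene_annotation` with one row per gene.
#' @export
load_annotation <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  required <- c("gene_id", "cds_length", "upstream_extension", "is_top")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("annotation format error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  tab$is_top <- parse_logical_column(tab$is_top, "is_top")
  as_gene_annotation(tab[, required])
}

#' Construct and validate an annotation object
#'
#' @param df data.frame with columns `gene_id`, `cds_length`,
#'   `upstream_extension`, `is_top`.
#' @return The validated data.frame with class `gene_annotation`.
#' @export
as_gene_annotation <- function(df) {
  stopifnot(is.data.frame(df))
  df$gene_id <- as.character(df$gene_id)
  df$cds_length <- as.integer(df$cds_length)
  df$upstream_extension <- as.integer(df$upstream_extension)
  df$is_top <- as.logical(df$is_top)
  if (anyDuplicated(df$gene_id)) {
    dup <- unique(df$gene_id[duplicated(df$gene_id)])
    stop("duplicate gene_id in annotation: ", paste(dup, collapse = ", "))
  }
  if (any(is.na(df$cds_length)) || any(df$cds_length < 3)) {
    stop("annotation validation error: cds_length must be >= 3 for all genes")
  }
  if (any(is.na(df$upstream_extension)) || any(df$upstream_extension < 0)) {
    stop("annotation validation error: upstream_extension must be >= 0")
  }
  rownames(df) <- NULL
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Write an annotation table to TSV
#' @param annotation A `gene_annotation` data.frame.
#' @param path Output file path.
#' @export
write_annotation <- function(annotation, path) {
  out <- as.data.frame(annotation)
  out$is_top <- tolower(as.character(out$is_top))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

parse_logical_column <- function(x, name) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no")] <- FALSE
  if (any(is.na(out))) {
    stop("annotation format error: column '", name,
         "' contains values not interpretable as logical")
  }
  out
}
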