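#' Load aligned reads from a tab-separated file
#'
#' Reads footprint or mRNA-fragment alignments in transcript space. Each
#' record carries the gene it was assigned to, the 0-based position of its
#' 5' end relative to the first base of the start codon (negative =
#' upstream), and its length in nt. Records are validated against the
#' annotation: a read must start at or downstream of `-upstream_extension`
#' and end within the CDS (`five_prime_pos + length <= cds_length`).
#'
#' Multi-mapping is an upstream concern: the loader assumes each record has
#' already been assigned to its single best-hit gene.
#'
#' @param path TSV with columns gene_id, five_prime_pos, length. A header
#'   line is auto-detected and skipped if present.
#' @param annotation A `gene_annotation` object.
#' @param strict If `TRUE`, an unknown gene_id is an error; otherwise such
#'   records are dropped with a warning giving the count.
#' @return A data.frame of class `aligned_reads` with columns `gene_id`,
#'   `five_prime_pos`, `length`. Attribute `n_rejected` holds the number of
#'   out-of-bounds records dropped.
#' @export
load_reads <- function(path, annotation, strict = FALSE) {
  first <- readLines(path, n = 1L)
  has_header <- length(first) == 1L && grepl("gene_id", first, fixed = TRUE)
  tab <- utils::read.delim(path, header = has_header, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("reads format error: expected 3 tab-separated columns")
  names(tab)[1:3] <- c("gene_id", "five_prime_pos", "length")
  validate_reads(tab[, 1:3], annotation, strict = strict)
}

#' Validate aligned-read records against an annotation
#'
#' @inheritParams load_reads
#' @param reads data.frame with columns gene_id, five_prime_pos, length.
#' @return Validated `aligned_reads` data.frame (see [load_reads()]).
#' @export
validate_reads <- function(reads, annotation, strict = FALSE) {
  reads$gene_id <- as.character(reads$gene_id)
  reads$five_prime_pos <- as.integer(reads$five_prime_pos)
  reads$length <- as.integer(reads$length)
  if (any(reads$length < 1, na.rm = TRUE)) {
    stop("read validation error: length must be >= 1")
  }

  idx <- match(reads$gene_id, annotation$gene_id)
  unknown <- is.na(idx)
  if (any(unknown)) {
    if (strict) {
      stop("unknown gene_id in reads: ",
           paste(unique(reads$gene_id[unknown]), collapse = ", "))
    }
    warning(sum(unknown), " read(s) on gene ids absent from the annotation ",
            "were skipped")
    reads <- reads[!unknown, , drop = FALSE]
    idx <- idx[!unknown]
  }

  ext <- annotation$upstream_extension[idx]
  cds <- annotation$cds_length[idx]
  oob <- reads$five_prime_pos < -ext | reads$five_prime_pos + reads$length > cds
  n_rejected <- sum(oob)
  if (n_rejected > 0) {
    warning(n_rejected, " read(s) outside the extended reference bounds ",
            "were rejected")
    reads <- reads[!oob, , drop = FALSE]
  }
  rownames(reads) <- NULL
  class(reads) <- c("aligned_reads", "data.frame")
  attr(reads, "n_rejected") <- n_rejected
  reads
}

#' Write aligned reads to TSV
#' @param reads An `aligned_reads` data.frame.
#' @param path Output path.
#' @param header Write a header line (default `TRUE`).
#' @export
write_reads <- function(reads, path, header = TRUE) {
  utils::write.table(as.data.frame(reads)[, c("gene_id", "five_prime_pos", "length")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = header)
  invisible(path)
}

#' Load aligned reads from a minimal SAM dialect
#'
#' Accepts a restricted SAM subset where each reference sequence is one
#' gene's extended CDS (one `@SQ` line per gene, `SN:` = gene_id) and every
#' alignment line is a mapped, sense-strand record. `POS` (1-based leftmost
#' on the extended reference) is converted to the package's start-codon
#' coordinate as `five_prime_pos = POS - 1 - upstream_extension`; read length
#' is taken from the sequence field (or the sum of M/I/=/X CIGAR operations
#' when SEQ is `*`). Soft/hard clipping beyond that is not interpreted.
#'
#' @inheritParams load_reads
#' @return An `aligned_reads` data.frame.
#' @export
load_sam_reads <- function(path, annotation, strict = FALSE) {
  lines <- readLines(path)
  aln <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(aln) == 0) {
    return(validate_reads(data.frame(gene_id = character(),
                                     five_prime_pos = integer(),
                                     length = integer()), annotation))
  }
  fields <- strsplit(aln, "\t", fixed = TRUE)
  bad <- vapply(fields, length, 1L) < 11L
  if (any(bad)) stop("SAM format error: alignment line with < 11 fields")
  flag <- as.integer(vapply(fields, `[[`, "", 2L))
  rname <- vapply(fields, `[[`, "", 3L)
  pos1 <- as.integer(vapply(fields, `[[`, "", 4L))
  cigar <- vapply(fields, `[[`, "", 6L)
  seq <- vapply(fields, `[[`, "", 10L)

  if (any(bitwAnd(flag, 4L) != 0L)) stop("SAM validation error: unmapped record")
  if (any(bitwAnd(flag, 16L) != 0L)) {
    stop("SAM validation error: antisense (reverse-strand) record; ",
         "references are transcript-space, reads must be sense-strand")
  }
  len <- ifelse(seq == "*", cigar_query_length(cigar), nchar(seq))

  idx <- match(rname, annotation$gene_id)
  ext <- ifelse(is.na(idx), 0L, annotation$upstream_extension[idx])
  reads <- data.frame(gene_id = rname,
                      five_prime_pos = pos1 - 1L - ext,
                      length = as.integer(len),
                      stringsAsFactors = FALSE)
  validate_reads(reads, annotation, strict = strict)
}

cigar_query_length <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    sum(n[op %in% c("M", "I", "=", "X")])
  }, 1L, USE.NAMES = FALSE)
}

#' Remove short reads
#'
#' Standard ribosome-profiling length filter: reads shorter than `min_len`
#' (default 24 nt) are removed; order is preserved.
#'
#' @param reads An `aligned_reads` data.frame.
#' @param min_len Minimum retained length in nt.
#' @return The filtered `aligned_reads`.
#' @export
filter_by_length <- function(reads, min_len = 24L) {
  keep <- reads$length >= min_len
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("aligned_reads", "data.frame")
  out
}
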