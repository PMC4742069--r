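# Small in-code fixtures shared across test files.

toy_annotation <- function() {
  as_gene_annotation(data.frame(
    gene_id = c("g1", "g2", "g3"),
    cds_length = c(300L, 600L, 150L),
    upstream_extension = 25L,
    is_top = c(FALSE, TRUE, FALSE)))
}

toy_reads <- function(gene_id, pos, len = 30L) {
  out <- data.frame(gene_id = gene_id,
                    five_prime_pos = as.integer(pos),
                    length = as.integer(rep_len(len, length(pos))),
                    stringsAsFactors = FALSE)
  class(out) <- c("aligned_reads", "data.frame")
  out
}

write_tsv_tmp <- function(df, ...) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, ...)
  path
}

# Annotation whose genes all span the default metagene window.
wide_annotation <- function(n = 5L, cds = 300L) {
  as_gene_annotation(data.frame(
    gene_id = sprintf("g%02d", seq_len(n)),
    cds_length = cds, upstream_extension = 25L, is_top = FALSE))
}
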