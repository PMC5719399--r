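#' Read and write the pipeline's tabular formats
#'
#' Plain TSV writers/readers for the tables the pipeline exchanges:
#' gene annotations (`gene_id`, `chrom`, `tss`, `strand`), long expression
#' tables (`gene_id`, `sample_id`, `condition`, `value`) and long qPCR Ct
#' tables (`embryo_id`, `gene`, `replicate`, `ct_or_UNDET`, where
#' undetected reactions are written as the literal `UNDET`). All writers
#' round-trip: reading a written file reproduces the input tibble.
#'
#' @param x The tibble to write.
#' @param path File path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_gene_tsv <- function(x, path) {
  readr::write_tsv(as_gene_models(x), path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_gene_tsv <- function(path) {
  as_gene_models(readr::read_tsv(path, show_col_types = FALSE,
                                 col_types = "ccnc"))
}

#' @rdname pipeline_io
#' @export
write_expression_tsv <- function(x, path) {
  readr::write_tsv(x[, c("gene_id", "sample_id", "condition", "value")], path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_expression_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, col_types = "cccn")
}

#' @rdname pipeline_io
#' @export
write_ct_tsv <- function(x, path) {
  out <- x |>
    mutate(ct_or_UNDET = ifelse(is.na(ct), "UNDET", format(ct, digits = 15))) |>
    select(embryo_id, gene, replicate, ct_or_UNDET)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_ct_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, col_types = "ccic")
  ct <- rep(NA_real_, nrow(out))
  det <- out$ct_or_UNDET != "UNDET"
  ct[det] <- as.numeric(out$ct_or_UNDET[det])
  out$ct <- ct
  select(out, embryo_id, gene, replicate, ct)
}
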