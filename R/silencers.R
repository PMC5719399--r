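#' Call candidate lineage-specific silencers
#'
#' A candidate silencer is a TF binding peak that also lies in open
#' chromatin and repressive chromatin: the peak must gap-overlap at least
#' one DNase-I hypersensitive site and at least one H3K27me3-enriched
#' region. The candidate's footprint is the TF peak itself; the nearest
#' qualifying DHS and H3K27me3 intervals are recorded as witnesses.
#' H3K27me3 "enrichment" is membership in the supplied interval set —
#' no signal-level thresholding happens here.
#'
#' @param tf_peaks,dhs,k27 Interval tibbles (TF ChIP peaks; DNase-I
#'   hypersensitive sites; H3K27me3 enriched regions).
#' @param max_gap Border gap tolerance in bp (default 0: touching or
#'   overlapping, the BEDtools-style >= 1 bp reading).
#' @return A tibble of candidates — the qualifying TF peak rows in
#'   coordinate order with witness columns `dhs_*` and `k27_*`.
#' @export
call_silencers <- function(tf_peaks, dhs, k27, max_gap = 0) {
  out <- triple_intersect(tf_peaks, dhs, k27, max_gap = max_gap)
  out |>
    rename(dhs_chrom = b_chrom, dhs_start = b_start, dhs_end = b_end,
           dhs_name = b_name, k27_chrom = c_chrom, k27_start = c_start,
           k27_end = c_end, k27_name = c_name)
}

#' Assign silencer candidates to their nearest gene
#'
#' Each candidate is assigned to the gene whose TSS is closest to the
#' candidate's midpoint (see [nearest_tss()]); candidates on chromosomes
#' without genes keep `assigned_gene = NA`.
#'
#' @param candidates Tibble from [call_silencers()].
#' @param genes Gene-model tibble.
#' @return `candidates` with `midpoint`, `assigned_gene`, `signed_distance`.
#' @export
assign_genes <- function(candidates, genes) {
  if (nrow(candidates) == 0) {
    return(candidates |> mutate(midpoint = numeric(0),
                                assigned_gene = character(0),
                                signed_distance = numeric(0)))
  }
  ann <- nearest_tss(candidates[, c("chrom", "start", "end", "name", "intensity")],
                     genes)
  candidates |>
    left_join(ann |> select(chrom, start, end, name, midpoint,
                            assigned_gene, signed_distance),
              by = c("chrom", "start", "end", "name"))
}

#' Per-gene silencer summary
#'
#' Counts assigned candidates per gene and the minimal absolute
#' midpoint-to-TSS distance; genes with no assigned candidate are omitted,
#' as are unassigned candidates.
#'
#' @param annotated Tibble from [assign_genes()].
#' @return A tibble with `assigned_gene`, `n_candidates`,
#'   `min_abs_distance`, sorted by gene id.
#' @export
silencer_gene_summary <- function(annotated) {
  annotated <- filter(annotated, !is.na(assigned_gene))
  if (nrow(annotated) == 0) {
    return(tibble(assigned_gene = character(), n_candidates = integer(),
                  min_abs_distance = numeric()))
  }
  annotated |>
    group_by(assigned_gene) |>
    summarise(n_candidates = dplyr::n(),
              min_abs_distance = min(abs(signed_distance)),
              .groups = "drop") |>
    arrange(assigned_gene)
}
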