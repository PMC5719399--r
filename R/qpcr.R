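#' Relative expression from a qPCR Ct table
#'
#' Collapses technical replicates to a per-embryo, per-gene mean threshold
#' cycle (over detected replicates only) and converts to expression
#' relative to an endogenous control gene:
#' \deqn{E = 2^{(Ct_{ref} - Ct_{gene})}}
#' so the reference gene itself is exactly 1 in every embryo, one extra
#' cycle means half the expression, and a gene undetected in all
#' replicates is reported as 0. Undetected replicates are `NA` in the `ct`
#' column (written/read as `"UNDET"` in the TSV form).
#'
#' @param ct Long Ct tibble with columns `embryo_id`, `gene`, `replicate`,
#'   `ct` (numeric cycles, `NA` = undetected).
#' @param reference Endogenous control gene (default `"Actb"`); it must be
#'   detected (>= 1 replicate) in every embryo.
#' @return A tibble with `embryo_id`, `gene`, `expression`.
#' @export
relative_expression <- function(ct, reference = "Actb") {
  ct <- as_tibble(ct)
  req <- c("embryo_id", "gene", "replicate", "ct")
  if (!all(req %in% names(ct))) {
    abort(paste0("Ct table needs columns: ", paste(req, collapse = ", ")))
  }
  if (!reference %in% ct$gene) {
    abort(paste0("reference gene ", reference, " absent from panel"))
  }
  mean_ct <- ct |>
    group_by(embryo_id, gene) |>
    summarise(ct = if (all(is.na(ct))) NA_real_ else mean(ct[!is.na(ct)]),
              .groups = "drop")
  ref_ct <- mean_ct |> filter(gene == reference)
  bad <- ref_ct$embryo_id[is.na(ref_ct$ct)]
  if (length(bad) > 0) {
    abort(paste0("reference gene ", reference,
                 " undetected in embryo ", bad[1]))
  }
  mean_ct |>
    left_join(ref_ct |> select(embryo_id, ref_ct = ct), by = "embryo_id") |>
    mutate(expression = ifelse(is.na(ct), 0, 2^(ref_ct - ct))) |>
    select(embryo_id, gene, expression) |>
    arrange(embryo_id, gene)
}

#' Classify single-embryo genotypes from Cdx2 and Neo signals
#'
#' In blastocysts from heterozygous intercrosses where the targeted allele
#' is replaced by a Neo cassette, the mutant-allele dosage is read from Neo
#' and the wild-type allele from Cdx2:
#' * `null` — Cdx2 undetected in all technical replicates and Neo clearly
#'   expressed;
#' * `wt` — Neo negligible (undetected, or below `negligible_frac` of the
#'   cohort median of positive Neo levels);
#' * `het` — everything else (Cdx2 detected, Neo at intermediate dosage);
#' * `ambiguous` — contradictory evidence (Cdx2 fully undetected *and* Neo
#'   negligible), flagged rather than silently assigned.
#'
#' @param expr Relative-expression tibble from [relative_expression()].
#' @param ct The Ct tibble the expression came from (for the undetected
#'   state of Cdx2 replicates).
#' @param cdx2_gene,neo_gene Panel names of the knockout gene and the
#'   cassette (defaults `"Cdx2"`, `"Neo"`).
#' @param negligible_frac Fraction of the cohort median positive Neo level
#'   below which Neo counts as negligible (default 0.01).
#' @return A `genotype_calls` tibble with `embryo_id`, `genotype`
#'   (factor: null/het/wt/ambiguous), `cdx2_detected`, `neo_expression`.
#' @export
classify_genotypes <- function(expr, ct, cdx2_gene = "Cdx2",
                               neo_gene = "Neo", negligible_frac = 0.01) {
  if (!all(c(cdx2_gene, neo_gene) %in% ct$gene)) {
    abort(paste0("panel must contain ", cdx2_gene, " and ", neo_gene))
  }
  cdx2_det <- ct |>
    filter(gene == cdx2_gene) |>
    group_by(embryo_id) |>
    summarise(cdx2_detected = any(!is.na(ct)), .groups = "drop")
  neo <- expr |> filter(gene == neo_gene) |>
    select(embryo_id, neo_expression = expression)
  pos_neo <- neo$neo_expression[neo$neo_expression > 0]
  thr <- if (length(pos_neo) == 0) 0 else negligible_frac * median(pos_neo)
  out <- cdx2_det |>
    left_join(neo, by = "embryo_id") |>
    mutate(
      neo_negligible = neo_expression <= thr,
      genotype = dplyr::case_when(
        !cdx2_detected & neo_negligible ~ "ambiguous",
        !cdx2_detected ~ "null",
        neo_negligible ~ "wt",
        TRUE ~ "het"
      ),
      genotype = factor(genotype, levels = c("null", "het", "wt", "ambiguous"))
    ) |>
    select(embryo_id, genotype, cdx2_detected, neo_expression) |>
    arrange(embryo_id)
  structure(out, class = c("genotype_calls", class(out)),
            negligible_threshold = thr)
}

#' Hierarchical clustering of embryo expression profiles
#'
#' Agglomerative clustering of embryos on `log2(expression + eps)`
#' profiles with distance `1 - Pearson correlation` and average linkage.
#' Embryos with constant profiles get pairwise correlation 0 (with a
#' warning). The merge order is deterministic; on equal heights the
#' lowest-index pair merges first.
#'
#' @param expr Relative-expression tibble (`embryo_id`, `gene`,
#'   `expression`); needs >= 3 embryos.
#' @param eps Offset before logs (default 1e-3; knockouts have exact 0s).
#' @param k Number of flat clusters to cut (default 2, separating
#'   knockouts from the rest in a strong-effect cohort).
#' @return An `embryo_clust` list: `hclust` (the tree), `labels` (tibble
#'   `embryo_id`, `cluster`), `k`.
#' @export
cluster_embryos <- function(expr, eps = 1e-3, k = 2) {
  wide <- tidyr::pivot_wider(expr, id_cols = embryo_id, names_from = gene,
                             values_from = expression)
  m <- log2(as.matrix(wide[, -1]) + eps)
  rownames(m) <- wide$embryo_id
  if (nrow(m) < 3) abort("need at least 3 embryos to cluster")
  const <- apply(m, 1, function(r) stats::sd(r) == 0)
  if (any(const)) {
    warn(paste0("constant expression profile; correlations set to 0 for: ",
                paste(rownames(m)[const], collapse = ", ")))
  }
  cm <- suppressWarnings(cor(t(m)))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 1
  hc <- hclust(as.dist(1 - cm), method = "average")
  labels <- tibble(embryo_id = rownames(m),
                   cluster = unname(cutree(hc, k = k))) |>
    arrange(embryo_id)
  structure(list(hclust = hc, labels = labels, k = k),
            class = "embryo_clust")
}

#' Two-axis anchor-gene correlation map
#'
#' For each panel gene, computes the Pearson correlation of
#' `log2(expression + eps)` with an anchor gene (default Cdx2) twice:
#' across single cells of wild-type embryos (`r_single_cell`) and across
#' whole mutant-cross embryos (`r_embryo`). Genes are then placed in the
#' map's quadrant clusters:
#' * cluster 1 — `r_single_cell > tau` and `r_embryo > tau`: positively
#'   regulated direct targets (track the anchor everywhere);
#' * cluster 2 — `r_single_cell > tau` and `|r_embryo| <= tau`: the
#'   parallel lineage program (co-expressed in single cells but
#'   insensitive to anchor genotype);
#' * cluster 3 — `r_embryo < -tau`: negatively regulated genes (the
#'   ICM/pluripotency pattern, up when the anchor is lost);
#' * `none` otherwise.
#' Zero-variance genes get correlation 0 and are excluded from clusters.
#'
#' @param single_cell_expr Tibble `cell_id`, `gene`, `expression`.
#' @param embryo_expr Tibble `embryo_id`, `gene`, `expression`.
#' @param anchor Anchor gene, present in both matrices (default `"Cdx2"`).
#' @param tau Correlation threshold defining the clusters (default 0.3).
#' @param eps Offset before logs (default 1e-3).
#' @param method Correlation method, `"pearson"` (default) or
#'   `"spearman"`.
#' @return A `correlation_map` tibble: `gene`, `r_single_cell`, `r_embryo`,
#'   `cluster` (factor `1`, `2`, `3`, `none`).
#' @export
cdx2_correlation_map <- function(single_cell_expr, embryo_expr,
                                 anchor = "Cdx2", tau = 0.3, eps = 1e-3,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  cor_with_anchor <- function(expr, id_col) {
    wide <- tidyr::pivot_wider(expr, id_cols = dplyr::all_of(id_col),
                               names_from = gene, values_from = expression)
    m <- log2(as.matrix(wide[, -1]) + eps)
    if (!anchor %in% colnames(m)) {
      abort(paste0("anchor gene ", anchor, " absent from a matrix"))
    }
    av <- m[, anchor]
    vapply(colnames(m), function(g) {
      x <- m[, g]
      if (stats::sd(x) == 0 || stats::sd(av) == 0) return(0)
      cor(x, av, method = method)
    }, numeric(1))
  }
  r_sc <- cor_with_anchor(single_cell_expr, "cell_id")
  r_em <- cor_with_anchor(embryo_expr, "embryo_id")
  genes <- union(names(r_sc), names(r_em))
  out <- tibble(
    gene = genes,
    r_single_cell = unname(r_sc[genes]),
    r_embryo = unname(r_em[genes])
  ) |>
    mutate(
      r_single_cell = ifelse(is.na(r_single_cell), 0, r_single_cell),
      r_embryo = ifelse(is.na(r_embryo), 0, r_embryo),
      zero_var = r_single_cell == 0 & r_embryo == 0,
      cluster = dplyr::case_when(
        zero_var ~ "none",
        r_embryo < -tau ~ "3",
        r_single_cell > tau & r_embryo > tau ~ "1",
        r_single_cell > tau & abs(r_embryo) <= tau ~ "2",
        TRUE ~ "none"
      ),
      cluster = factor(cluster, levels = c("1", "2", "3", "none"))
    ) |>
    select(gene, r_single_cell, r_embryo, cluster) |>
    arrange(gene)
  structure(out, class = c("correlation_map", class(out)),
            anchor = anchor, tau = tau, method = method)
}
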