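#' Fold-change differential expression test
#'
#' For each gene, computes the log2 fold change between two conditions from
#' group means on the linear scale,
#' `log2((mean_A + pseudocount) / (mean_B + pseudocount))`, and a p-value
#' from Welch's unequal-variance two-sample t-test on
#' `log2(value + pseudocount)`. No multiple-testing correction is applied;
#' the downstream selection rule is a plain fold-change cutoff with a
#' per-gene p threshold.
#'
#' @param expr Long-format expression tibble with columns `gene_id`,
#'   `sample_id`, `condition`, `value` (linear scale, non-negative).
#' @param group_a,group_b Condition labels to contrast (fold change is
#'   A over B). Both groups need at least 2 samples.
#' @param pseudocount Added to linear values before ratios and logs
#'   (default 1), guarding zeros.
#' @return A tibble with `gene_id`, `log2fc`, `p_value`.
#' @export
fold_change_test <- function(expr, group_a, group_b, pseudocount = 1.0) {
  expr <- as_tibble(expr)
  req <- c("gene_id", "sample_id", "condition", "value")
  if (!all(req %in% names(expr))) {
    abort(paste0("expression table needs columns: ", paste(req, collapse = ", ")))
  }
  for (g in c(group_a, group_b)) {
    if (!any(expr$condition == g)) abort(paste0("unknown group label: ", g))
  }
  if (any(expr$value < 0)) abort("expression values must be non-negative")
  a <- expr |> filter(condition == group_a)
  b <- expr |> filter(condition == group_b)
  if (length(unique(a$sample_id)) < 2 || length(unique(b$sample_id)) < 2) {
    abort("both groups need at least 2 samples")
  }
  wide_a <- tidyr::pivot_wider(a, id_cols = gene_id, names_from = sample_id,
                               values_from = value)
  wide_b <- tidyr::pivot_wider(b, id_cols = gene_id, names_from = sample_id,
                               values_from = value)
  wide_b <- wide_b[match(wide_a$gene_id, wide_b$gene_id), ]
  ma <- as.matrix(wide_a[, -1]); mb <- as.matrix(wide_b[, -1])
  la <- log2(ma + pseudocount); lb <- log2(mb + pseudocount)
  pvals <- vapply(seq_len(nrow(ma)), function(i) {
    x <- la[i, ]; y <- lb[i, ]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(if (mean(x) == mean(y)) 1 else 0)
    }
    tryCatch(t.test(x, y, var.equal = FALSE)$p.value, error = function(e) 1)
  }, numeric(1))
  tibble(
    gene_id = wide_a$gene_id,
    log2fc = log2((rowMeans(ma) + pseudocount) / (rowMeans(mb) + pseudocount)),
    p_value = pvals
  ) |> arrange(gene_id)
}

#' Select differentially expressed genes
#'
#' Applies the selection rule: up-regulated genes have
#' `log2fc >= log2(fc_cutoff)` (boundary inclusive) and `p < alpha`
#' (boundary exclusive); down-regulated genes symmetrically with
#' `log2fc <= -log2(fc_cutoff)`. Lists are sorted by `|log2fc|` descending.
#'
#' @param results Tibble from [fold_change_test()].
#' @param fc_cutoff Fold-change cutoff on the linear scale (default 2).
#' @param alpha P-value threshold (default 0.05, strict inequality).
#' @return A list with tibbles `up` and `down`.
#' @export
de_genes <- function(results, fc_cutoff = 2, alpha = 0.05) {
  thr <- log2(fc_cutoff)
  up <- results |> filter(log2fc >= thr, p_value < alpha) |>
    arrange(desc(abs(log2fc)), gene_id)
  down <- results |> filter(log2fc <= -thr, p_value < alpha) |>
    arrange(desc(abs(log2fc)), gene_id)
  list(up = up, down = down)
}

#' Rank the genome by expression fold change
#'
#' Orders genes by descending log2 fold change (rank 1 = most
#' up-regulated); ties are broken by ascending `gene_id`. Non-finite fold
#' changes are an error naming the first offending gene.
#'
#' @param results Tibble from [fold_change_test()].
#' @return The input tibble ordered by fold change with a `rank` column.
#' @export
rank_genome <- function(results) {
  bad <- which(!is.finite(results$log2fc))
  if (length(bad) > 0) {
    abort(paste0("non-finite fold change for gene ", results$gene_id[bad[1]]))
  }
  results |> arrange(desc(log2fc), gene_id) |> mutate(rank = row_number())
}

#' Sliding-window association profile over a ranked genome
#'
#' After sorting the genome by expression fold change, averages the
#' TF association scores within a sliding window of `window` genes
#' (default 500, step 1) across the ranked list. The characteristic shape
#' — highest average association at the most up-regulated end, moderate at
#' the most down-regulated end, near zero in the unchanged middle — is the
#' signature of a factor that both activates strong targets and represses
#' moderately bound ones.
#'
#' @param ranked Tibble from [rank_genome()] (or any tibble with `gene_id`
#'   in rank order).
#' @param table An `assoc_tbl` from [association_table()]; every ranked
#'   gene must be present.
#' @param window Window size in genes; must not exceed the genome size.
#' @param step Step between window starts in genes (default 1).
#' @return A `window_profile` tibble with `window_index`, `center` (midpoint
#'   rank of the window) and `mean_score`.
#' @export
sliding_window_profile <- function(ranked, table, window = 500, step = 1) {
  n <- nrow(ranked)
  stopifnot(window >= 1, step >= 1)
  if (window > n) abort("window exceeds the number of ranked genes")
  sc <- setNames(table$score, table$gene_id)[ranked$gene_id]
  if (anyNA(sc)) {
    abort(paste0("gene missing from association table: ",
                 ranked$gene_id[which(is.na(sc))[1]]))
  }
  starts <- seq(1, n - window + 1, by = step)
  cs <- c(0, cumsum(sc))
  means <- unname((cs[starts + window] - cs[starts]) / window)
  out <- tibble(
    window_index = seq_along(starts),
    center = (starts + (starts + window - 1)) / 2,
    mean_score = means
  )
  structure(out, class = c("window_profile", class(out)),
            window = window, step = step, n_genes = n)
}
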