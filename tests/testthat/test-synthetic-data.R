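test_that("genome generation respects counts, bounds, spacing and seeds", {
  g <- gen_genome(1, 1e7, 100, seed = 1)
  expect_equal(nrow(g), 100)
  expect_false(anyDuplicated(g$gene_id) > 0)
  expect_true(all(g$tss >= 0 & g$tss < 1e7))
  expect_true(all(g$strand %in% c("+", "-")))
  expect_true(all(diff(sort(g$tss)) >= 1000))
  expect_identical(g, gen_genome(1, 1e7, 100, seed = 1))
  g2 <- gen_genome(1, 1e7, 100, seed = 2)
  expect_false(identical(g$tss, g2$tss))
  expect_error(gen_genome(0, 1e7, 100, 1), "n_chromosomes")
  expect_error(gen_genome(1, 1e5, 100, 1), "too small")
  # generators leave the caller's RNG stream untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(gen_genome(1, 1e7, 50, seed = 3))
  expect_identical(runif(1), before)
})

test_that("peak planting follows the distance law and intensity contract", {
  g <- gen_genome(1, 1e7, 100, seed = 1)
  # no targets: background only
  bg <- gen_peaks(g, n_targets = 0, seed = 1)
  expect_equal(nrow(bg$truth$planted_targets), 0)
  expect_gt(nrow(bg$peaks), 0)
  # no background: every peak within 1 Mb of a planted target TSS
  pl <- gen_peaks(g, n_targets = 10, background_rate = 0, seed = 2)
  tss <- g$tss[g$gene_id %in% pl$truth$planted_targets$gene_id]
  mids <- floor((pl$peaks$start + pl$peaks$end) / 2)
  expect_true(all(vapply(mids, function(m) min(abs(m - tss)) <= 1e6,
                         logical(1))))
  expect_true(all(pl$peaks$intensity > 0))
  expect_error(gen_peaks(g, n_targets = 5, background_rate = -1),
               "background_rate")
  expect_error(gen_peaks(g, n_targets = 101), "exceeds")
  expect_identical(gen_peaks(g, 10, seed = 3)$peaks,
                   gen_peaks(g, 10, seed = 3)$peaks)
  # negative targets carry the moderate intensity scale on average
  mix <- gen_peaks(g, n_targets = 40, prop_negative = 0.5,
                   background_rate = 0, seed = 4)
  expect_setequal(unique(mix$truth$planted_targets$sign), c("+", "-"))
})

test_that("epigenome planting yields exactly the requested triple loci", {
  g <- gen_genome(2, 1e7, 300, seed = 11)
  pk <- gen_peaks(g, n_targets = 80, background_rate = 6, seed = 11)
  ep <- gen_epigenome(pk$peaks, n_silencers = 20, n_decoys = 40, seed = 11)
  # exhaustive brute-force scan over all TF peaks
  members <- oracle_triple_members(pk$peaks, ep$dhs, ep$k27, 0)
  expect_length(members, 20)
  expect_setequal(members, ep$truth$planted_silencers$name)
  # decoys carry exactly two of the three marks
  expect_equal(nrow(ep$truth$decoy_loci), 40)
  expect_false(any(ep$truth$decoy_loci$name %in% members))
  # planted loci are mutually separated by >= 1 kb
  loci <- dplyr::bind_rows(
    ep$truth$planted_silencers[, c("chrom", "start", "end")],
    ep$truth$decoy_loci[, c("chrom", "start", "end")]) |>
    dplyr::arrange(chrom, start)
  by_chrom <- split(loci, loci$chrom)
  for (blk in by_chrom) {
    if (nrow(blk) > 1) {
      expect_true(all(blk$start[-1] - blk$end[-nrow(blk)] >= 1000))
    }
  }
  expect_identical(gen_epigenome(pk$peaks, 5, 10, seed = 2)$dhs,
                   gen_epigenome(pk$peaks, 5, 10, seed = 2)$dhs)
  # empty plan: the caller returns nothing planted and no triples
  ep0 <- gen_epigenome(pk$peaks, 0, 0, seed = 3)
  expect_equal(nrow(call_silencers(pk$peaks, ep0$dhs, ep0$k27)), 0)
  expect_error(gen_epigenome(pk$peaks[1:10, ], 20, 40), "exceeds")
})

test_that("expression planting is null at zero effect and reproducible", {
  g <- gen_genome(1, 5e6, 120, seed = 21)
  pk <- gen_peaks(g, n_targets = 30, seed = 21)
  e0 <- gen_expression(g, pk$truth, effect_log2fc = 0, noise_sd = 0.1,
                       seed = 21)
  res <- fold_change_test(e0, "A", "B")
  expect_lt(max(abs(res$log2fc)), 0.5)
  expect_true(all(e0$value > 0))
  expect_identical(gen_expression(g, pk$truth, seed = 4),
                   gen_expression(g, pk$truth, seed = 4))
  expect_error(gen_expression(g, pk$truth, noise_sd = -1), "noise_sd")
  expect_error(gen_expression(g, pk$truth, n_reps = 1), "n_reps")
})

test_that("embryo Ct planting matches the cohort design", {
  ec <- gen_embryo_ct(27, 6, 4, seed = 7)
  truth <- ec$truth$embryo_genotypes
  expect_equal(sum(truth$genotype == "null"), 6)
  expect_equal(sum(truth$genotype == "wt"), 4)
  expect_equal(sum(truth$genotype == "het"), 17)
  # nulls: no detectable transcript of the knocked-out gene in any replicate
  cdx <- ec$ct |> dplyr::filter(gene == "Cdx2") |>
    dplyr::group_by(embryo_id) |>
    dplyr::summarise(any_det = any(!is.na(ct)))
  nulls <- truth$embryo_id[truth$genotype == "null"]
  expect_true(all(!cdx$any_det[cdx$embryo_id %in% nulls]))
  expect_true(all(cdx$any_det[!cdx$embryo_id %in% nulls]))
  # wild types: no cassette signal
  neo <- ec$ct |> dplyr::filter(gene == "Neo") |>
    dplyr::group_by(embryo_id) |>
    dplyr::summarise(any_det = any(!is.na(ct)))
  wts <- truth$embryo_id[truth$genotype == "wt"]
  expect_true(all(!neo$any_det[neo$embryo_id %in% wts]))
  # the reference gene is always detected with the lowest Ct variance
  per_gene <- ec$ct |> dplyr::filter(!is.na(ct)) |>
    dplyr::group_by(gene) |> dplyr::summarise(v = stats::var(ct))
  actb <- ec$ct |> dplyr::filter(gene == "Actb")
  expect_false(any(is.na(actb$ct)))
  expect_equal(per_gene$gene[which.min(per_gene$v)], "Actb")
  # no planted nulls -> no fully undetected knockout gene
  ec0 <- gen_embryo_ct(12, 0, 2, seed = 8)
  cdx0 <- ec0$ct |> dplyr::filter(gene == "Cdx2") |>
    dplyr::group_by(embryo_id) |>
    dplyr::summarise(all_undet = all(is.na(ct)))
  expect_false(any(cdx0$all_undet))
  expect_error(gen_embryo_ct(10, 6, 6), "exceeds")
  bad_panel <- default_qpcr_panel()[-2, ]  # drop Cdx2
  expect_error(gen_embryo_ct(panel = bad_panel), "Cdx2")
  expect_identical(gen_embryo_ct(seed = 5)$ct, gen_embryo_ct(seed = 5)$ct)
})

test_that("single-cell planting separates the two lineages", {
  sc <- gen_single_cells(n_cells = 40, seed = 3)
  expect_equal(nrow(sc$truth), 40)
  wide <- tidyr::pivot_wider(sc$expr, names_from = gene,
                             values_from = expression)
  te <- sc$truth$cell_id[sc$truth$lineage == "TE"]
  expect_gt(mean(wide$Cdx2[wide$cell_id %in% te]),
            mean(wide$Cdx2[!wide$cell_id %in% te]))
  expect_gt(mean(wide$Pou5f1[!wide$cell_id %in% te]),
            mean(wide$Pou5f1[wide$cell_id %in% te]))
  expect_identical(gen_single_cells(seed = 6)$expr,
                   gen_single_cells(seed = 6)$expr)
})
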