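ct_fixture <- function() {
  # two embryos, three genes, technical triplicate; E2's target gene has a
  # dropout replicate and its cassette is fully undetected
  tibble::tibble(
    embryo_id = rep(c("E1", "E2"), each = 9),
    gene = rep(rep(c("Actb", "Cdx2", "Neo"), each = 3), 2),
    replicate = rep(1:3, 6),
    ct = c(14, 14, 14, 14, 14, 14, 15, 15, 15,      # E1
           14, 14, 14, 20, 21, NA, NA, NA, NA)      # E2
  )
}

test_that("relative expression implements the delta-Ct rules", {
  expr <- relative_expression(ct_fixture())
  e1 <- expr |> dplyr::filter(embryo_id == "E1")
  # reference gene is exactly 1; one extra cycle halves expression
  expect_equal(e1$expression[e1$gene == "Actb"], 1)
  expect_equal(e1$expression[e1$gene == "Cdx2"], 1)   # same Ct as reference
  expect_equal(e1$expression[e1$gene == "Neo"], 0.5)  # Ct_ref + 1
  e2 <- expr |> dplyr::filter(embryo_id == "E2")
  # mixed replicates: mean over the detected ones (20, 21 -> 20.5)
  expect_equal(e2$expression[e2$gene == "Cdx2"], 2^(14 - 20.5))
  # all replicates undetected -> expression 0
  expect_equal(e2$expression[e2$gene == "Neo"], 0)
  # undetected reference is an error naming the embryo
  bad <- ct_fixture() |>
    dplyr::mutate(ct = ifelse(embryo_id == "E2" & gene == "Actb", NA, ct))
  expect_error(relative_expression(bad), "E2")
})

test_that("genotype rules map Cdx2/Neo evidence to null, het, wt, ambiguous", {
  ct <- tibble::tibble(
    embryo_id = rep(c("N1", "H1", "W1", "X1"), each = 9),
    gene = rep(rep(c("Actb", "Cdx2", "Neo"), each = 3), 4),
    replicate = rep(1:3, 12),
    ct = c(14, 14, 14, NA, NA, NA, 22, 22, 22,   # N1: no Cdx2, Neo high
           14, 14, 14, 21, 21, 21, 23, 23, 23,   # H1: both present
           14, 14, 14, 20, 20, 20, NA, NA, NA,   # W1: no Neo
           14, 14, 14, NA, NA, NA, NA, NA, NA)   # X1: contradictory
  )
  expr <- relative_expression(ct)
  calls <- classify_genotypes(expr, ct)
  got <- setNames(as.character(calls$genotype), calls$embryo_id)
  expect_identical(got[["N1"]], "null")
  expect_identical(got[["H1"]], "het")
  expect_identical(got[["W1"]], "wt")
  expect_identical(got[["X1"]], "ambiguous")
  # invariant to replicate order and to a global per-embryo Ct shift
  ct_shuf <- ct |> dplyr::group_by(embryo_id, gene) |>
    dplyr::mutate(ct = rev(ct)) |> dplyr::ungroup()
  expect_identical(as.character(classify_genotypes(
    relative_expression(ct_shuf), ct_shuf)$genotype),
    as.character(calls$genotype))
  ct_shift <- ct |> dplyr::mutate(ct = ct + ifelse(embryo_id == "H1", 2, 0))
  expect_identical(as.character(classify_genotypes(
    relative_expression(ct_shift), ct_shift)$genotype),
    as.character(calls$genotype))
  expect_error(classify_genotypes(expr, dplyr::filter(ct, gene != "Neo")),
               "Neo")
})

test_that("planted genotypes are recovered exactly across cohorts", {
  for (s in c(7, 8, 9)) {
    ec <- gen_embryo_ct(27, 6, 4, seed = s)
    expr <- relative_expression(ec$ct)
    calls <- classify_genotypes(expr, ec$ct)
    m <- dplyr::left_join(tidy(calls), ec$truth$embryo_genotypes,
                          by = "embryo_id")
    expect_equal(mean(as.character(m$genotype.x) == m$genotype.y), 1)
  }
})

test_that("hierarchical clustering isolates knockouts and is order-invariant", {
  ec <- gen_embryo_ct(27, 6, 4, seed = 7)
  expr <- relative_expression(ec$ct)
  cl <- cluster_embryos(expr, k = 2)
  m <- dplyr::left_join(tidy(cl), ec$truth$embryo_genotypes, by = "embryo_id")
  null_cluster <- unique(m$cluster[m$genotype == "null"])
  expect_length(null_cluster, 1)
  expect_setequal(m$embryo_id[m$cluster == null_cluster],
                  m$embryo_id[m$genotype == "null"])
  # permuting embryo order relabels but does not regroup
  set.seed(1)
  perm <- expr[sample.int(nrow(expr)), ]
  cl2 <- cluster_embryos(perm, k = 2)
  m2 <- dplyr::inner_join(tidy(cl), tidy(cl2), by = "embryo_id")
  expect_equal(length(unique(paste(m2$cluster.x, m2$cluster.y))), 2)
  # identical embryos merge first at height 0
  dup <- tibble::tibble(
    embryo_id = rep(c("A", "B", "C"), each = 2),
    gene = rep(c("g1", "g2"), 3),
    expression = c(1, 8, 1, 8, 5, 1)
  )
  cl3 <- cluster_embryos(dup, k = 2)
  expect_equal(cl3$hclust$height[1], 0, tolerance = 1e-12)
  expect_error(cluster_embryos(dup[1:4, ]), "3 embryos")
  # constant-profile embryo triggers the warning path
  flat <- tibble::tibble(embryo_id = rep(c("A", "B", "C"), each = 2),
                         gene = rep(c("g1", "g2"), 3),
                         expression = c(1, 8, 3, 3, 5, 1))
  expect_warning(cluster_embryos(flat, k = 2), "constant")
})

test_that("correlation map places planted gene classes in their quadrants", {
  ec <- gen_embryo_ct(27, 6, 4, seed = 7)
  expr <- relative_expression(ec$ct)
  sc <- gen_single_cells(seed = 7)
  cm <- cdx2_correlation_map(sc$expr, expr)
  expect_true(all(abs(cm$r_single_cell) <= 1 & abs(cm$r_embryo) <= 1))
  # the anchor correlates perfectly with itself
  expect_equal(cm$r_single_cell[cm$gene == "Cdx2"], 1)
  expect_equal(cm$r_embryo[cm$gene == "Cdx2"], 1)
  panel <- default_qpcr_panel()
  m <- dplyr::inner_join(tidy(cm), panel, by = "gene")
  expected <- c(positive = "1", parallel = "2", negative = "3")
  planted <- m |> dplyr::filter(class %in% names(expected))
  expect_gte(mean(as.character(planted$cluster) ==
                    expected[planted$class]), 0.9)
  # zero-variance genes are excluded from clusters
  expect_identical(as.character(cm$cluster[cm$gene == "Actb"]), "none")
})

test_that("correlation map handles hand-built anchors exactly", {
  emb <- tibble::tibble(
    embryo_id = rep(sprintf("E%d", 1:6), each = 3),
    gene = rep(c("Cdx2", "same", "anti"), 6),
    expression = as.vector(vapply(c(1, 2, 4, 8, 16, 32),
                                  function(v) c(v, v, 32 / v), numeric(3)))
  )
  cells <- tibble::tibble(
    cell_id = rep(sprintf("C%d", 1:6), each = 3),
    gene = rep(c("Cdx2", "same", "anti"), 6),
    expression = as.vector(vapply(c(1, 2, 4, 8, 16, 32),
                                  function(v) c(v, v, 32 / v), numeric(3)))
  )
  cm <- cdx2_correlation_map(cells, emb, eps = 0)
  same <- cm[cm$gene == "same", ]
  expect_equal(same$r_single_cell, 1)
  expect_equal(same$r_embryo, 1)
  expect_identical(as.character(same$cluster), "1")
  anti <- cm[cm$gene == "anti", ]
  expect_equal(anti$r_embryo, -1)
  expect_identical(as.character(anti$cluster), "3")
})
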