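# All generators restore the caller's RNG state, so they behave as pure
# functions of (arguments, seed).
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

new_truth <- function(seed, planted_targets = tibble(gene_id = character(),
                                                     sign = character()),
                      planted_silencers = NULL, decoy_loci = NULL,
                      embryo_genotypes = NULL) {
  structure(list(planted_targets = planted_targets,
                 planted_silencers = planted_silencers,
                 decoy_loci = decoy_loci,
                 embryo_genotypes = embryo_genotypes,
                 rng_seed = seed),
            class = "synthetic_truth")
}

#' Generate a synthetic gene annotation
#'
#' Places `n_genes` genes with unique ids across `n_chromosomes`
#' chromosomes of `chrom_length` bp each. TSS positions are drawn
#' uniformly from distinct 1-kb slots, guaranteeing >= 1 kb spacing;
#' strands are random. Deterministic for a fixed seed. The returned tibble
#' carries a `chrom_lengths` attribute used by the other generators.
#'
#' @param n_chromosomes,chrom_length,n_genes Genome dimensions;
#'   `chrom_length` must be at least `10 * n_genes * 1000 / n_chromosomes`
#'   so placement never saturates.
#' @param seed Integer RNG seed.
#' @return A gene-model tibble (`gene_id`, `chrom`, `tss`, `strand`).
#' @export
gen_genome <- function(n_chromosomes = 1, chrom_length = 1e7,
                       n_genes = 1000, seed = 1) {
  if (n_chromosomes < 1 || chrom_length <= 0 || n_genes < 2) {
    abort("need n_chromosomes >= 1, chrom_length > 0, n_genes >= 2")
  }
  if (chrom_length * n_chromosomes < 10 * n_genes * 1000) {
    abort("chrom_length too small for n_genes (need >= 10 kb of genome per gene)")
  }
  with_seed(seed, {
    chroms <- paste0("chr", seq_len(n_chromosomes))
    per <- diff(floor(seq(0, n_genes, length.out = n_chromosomes + 1)))
    out <- purrr::map2_dfr(chroms, per, function(ch, k) {
      if (k == 0) return(NULL)
      slots <- sort(sample.int(floor(chrom_length / 1000) - 1, k))
      tibble(chrom = ch, tss = slots * 1000,
             strand = sample(c("+", "-"), k, replace = TRUE))
    })
    out <- out |>
      mutate(gene_id = sprintf("g%04d", seq_len(nrow(out)))) |>
      select(gene_id, chrom, tss, strand)
    genes <- as_gene_models(out)
    attr(genes, "chrom_lengths") <- setNames(rep(chrom_length, n_chromosomes),
                                             chroms)
    genes
  })
}

chrom_lengths_of <- function(x, fallback_pad = 1e6) {
  cl <- attr(x, "chrom_lengths")
  if (!is.null(cl)) return(cl)
  pos <- if ("tss" %in% names(x)) x$tss else x$end
  tapply(pos, x$chrom, function(p) max(p) + fallback_pad)
}

# truncated exponential on (0, upper]
rexp_trunc <- function(n, mean, upper) {
  u <- runif(n) * stats::pexp(upper, rate = 1 / mean)
  stats::qexp(u, rate = 1 / mean)
}

#' Generate TF ChIP peaks with planted target genes
#'
#' Plants `n_targets` target genes: each receives 1-5 peaks at
#' exponentially distributed distances from its TSS (mean `mean_dist`,
#' truncated below `max_dist`) with lognormal intensities. A fraction
#' `prop_negative` of targets are planted as negatively regulated; their
#' peaks get intensities scaled by `neg_intensity_scale`, emulating the
#' moderate binding dosage of repressed targets. Background peaks are
#' placed uniformly at `background_rate` peaks per Mb. Every peak has
#' positive intensity.
#'
#' @param genes Gene-model tibble from [gen_genome()].
#' @param n_targets Number of planted target genes (`<= n_genes`).
#' @param prop_negative Fraction of targets planted with a repressive sign.
#' @param intensity_meanlog,intensity_sdlog Lognormal intensity law.
#' @param neg_intensity_scale Intensity multiplier for peaks of negative
#'   targets (default 0.4, "moderate" binding).
#' @param background_rate Background peaks per Mb (>= 0).
#' @param mean_dist Mean planted peak-to-TSS distance, bp (default 20 kb).
#' @param max_dist Truncation of planted distances, bp (default 1 Mb).
#' @param peak_width Width of every emitted peak, bp.
#' @param seed Integer RNG seed.
#' @return A list with `peaks` (interval tibble) and `truth`
#'   (`synthetic_truth` with `planted_targets`: `gene_id`, `sign`).
#' @export
gen_peaks <- function(genes, n_targets = 30, prop_negative = 1 / 3,
                      intensity_meanlog = log(20), intensity_sdlog = 0.5,
                      neg_intensity_scale = 0.4, background_rate = 5,
                      mean_dist = 20000, max_dist = 1e6, peak_width = 300,
                      seed = 1) {
  genes <- as_gene_models(genes)
  if (n_targets > nrow(genes)) abort("n_targets exceeds the number of genes")
  if (background_rate < 0) abort("background_rate must be >= 0")
  cl <- chrom_lengths_of(genes)
  with_seed(seed, {
    target_idx <- sample.int(nrow(genes), n_targets)
    n_neg <- round(n_targets * prop_negative)
    signs <- rep("+", n_targets)
    if (n_neg > 0) signs[seq_len(n_neg)] <- "-"
    signs <- sample(signs)
    planted <- purrr::map_dfr(seq_len(n_targets), function(j) {
      g <- genes[target_idx[j], ]
      npk <- sample(1:5, 1)
      d <- rexp_trunc(npk, mean_dist, max_dist - peak_width)
      side <- sample(c(-1, 1), npk, replace = TRUE)
      mid <- pmin(pmax(round(g$tss + side * d), peak_width),
                  cl[[g$chrom]] - peak_width)
      # intensities on the BED score grid (tenths) so files round-trip exactly
      intens <- pmax(round(rlnorm(npk, intensity_meanlog, intensity_sdlog), 1),
                     0.1)
      if (signs[j] == "-") {
        intens <- pmax(round(intens * neg_intensity_scale, 1), 0.1)
      }
      tibble(chrom = g$chrom, start = mid - peak_width / 2,
             end = mid + peak_width / 2, intensity = intens)
    })
    bg <- purrr::map_dfr(names(cl), function(ch) {
      k <- rpois(1, background_rate * cl[[ch]] / 1e6)
      if (k == 0) return(NULL)
      mid <- round(runif(k, peak_width, cl[[ch]] - peak_width))
      tibble(chrom = ch, start = mid - peak_width / 2,
             end = mid + peak_width / 2,
             intensity = pmax(round(rlnorm(k, intensity_meanlog,
                                           intensity_sdlog), 1), 0.1))
    })
    peaks <- bind_rows(planted, bg)
    peaks$name <- sprintf("peak%05d", seq_len(nrow(peaks)))
    peaks <- as_intervals(peaks)
    attr(peaks, "chrom_lengths") <- cl
    truth <- new_truth(seed, planted_targets = tibble(
      gene_id = genes$gene_id[target_idx], sign = signs))
    list(peaks = peaks, truth = truth)
  })
}

# positions (midpoints) at least `clearance` bp from every interval in `avoid`
sample_clear_positions <- function(k, chrom_lengths, avoid, clearance,
                                   max_tries = 10000) {
  out <- tibble(chrom = character(), pos = numeric())
  tries <- 0
  while (nrow(out) < k) {
    tries <- tries + 1
    if (tries > max_tries) abort("cannot place marks with required clearance")
    ch <- sample(names(chrom_lengths), 1)
    p <- round(runif(1, clearance, chrom_lengths[[ch]] - clearance))
    av <- avoid[avoid$chrom == ch, ]
    ok1 <- nrow(av) == 0 ||
      all(interval_gap(p - 1, p + 1, av$start, av$end) > clearance)
    ok2 <- nrow(out) == 0 ||
      all(out$chrom != ch | abs(out$pos - p) > 2 * clearance)
    if (ok1 && ok2) out <- bind_rows(out, tibble(chrom = ch, pos = p))
  }
  out
}

#' Generate DHS and H3K27me3 marks with planted silencers and decoys
#'
#' Chooses `n_silencers + n_decoys` TF peaks that are mutually separated
#' by at least `separation` bp. Each planted silencer peak gets a DNase
#' hypersensitive interval overlapping it and a broader H3K27me3 domain
#' covering both (the open-chromatin-inside-repressive-domain signature).
#' Decoys carry exactly two of the three marks, cycling through the types
#' TF+DHS, TF+K27 and DHS+K27 (the last placed away from every TF peak).
#' Additional scattered DHS and K27 intervals are placed with the same
#' clearance from all TF peaks, so the planted silencers are exactly the
#' loci where all three marks co-occur — verified by an exhaustive scan
#' before returning.
#'
#' @param tf_peaks Interval tibble (e.g. from [gen_peaks()]).
#' @param n_silencers,n_decoys Counts; their sum must not exceed the
#'   number of TF peaks.
#' @param n_scatter Extra unmatched DHS and K27 intervals each.
#' @param separation Minimum distance between chosen loci, bp (>= 1 kb).
#' @param clearance Minimum distance between scattered/decoy-only marks
#'   and any TF peak, bp.
#' @param seed Integer RNG seed.
#' @return A list with `dhs`, `k27` (interval tibbles) and `truth`
#'   (`planted_silencers` and `decoy_loci` interval tibbles; decoys carry
#'   a `decoy_type` column).
#' @export
gen_epigenome <- function(tf_peaks, n_silencers = 20, n_decoys = 40,
                          n_scatter = 30, separation = 2000,
                          clearance = 2000, seed = 1) {
  tf_peaks <- as_intervals(tf_peaks)
  if (n_silencers + n_decoys > nrow(tf_peaks)) {
    abort("n_silencers + n_decoys exceeds the number of TF peaks")
  }
  if (separation < 1000) abort("separation must be >= 1 kb")
  cl <- chrom_lengths_of(tf_peaks)
  with_seed(seed, {
    # only peaks isolated from every other peak by >= separation qualify:
    # marks planted at a chosen locus then cannot touch any other TF peak
    isolated <- vapply(seq_len(nrow(tf_peaks)), function(i) {
      same <- which(tf_peaks$chrom == tf_peaks$chrom[i])
      same <- setdiff(same, i)
      length(same) == 0 ||
        min(interval_gap(tf_peaks$start[i], tf_peaks$end[i],
                         tf_peaks$start[same], tf_peaks$end[same])) >= separation
    }, logical(1))
    if (sum(isolated) < n_silencers + n_decoys) {
      abort("cannot choose enough mutually separated TF peaks")
    }
    chosen <- sample(which(isolated), n_silencers + n_decoys)
    sil_idx <- chosen[seq_len(n_silencers)]
    dec_idx <- chosen[n_silencers + seq_len(n_decoys)]
    dhs_rows <- list()
    k27_rows <- list()
    dhs_at <- function(pk) tibble(chrom = pk$chrom,
                                  start = floor((pk$start + pk$end) / 2) - 150,
                                  end = floor((pk$start + pk$end) / 2) + 150)
    k27_at <- function(pk) tibble(chrom = pk$chrom, start = pk$start - 500,
                                  end = pk$end + 500)
    if (n_silencers > 0) {
      for (i in sil_idx) {
        dhs_rows[[length(dhs_rows) + 1]] <- dhs_at(tf_peaks[i, ])
        k27_rows[[length(k27_rows) + 1]] <- k27_at(tf_peaks[i, ])
      }
    }
    decoy_type <- character(0)
    if (n_decoys > 0) {
      decoy_type <- rep(c("tf_dhs", "tf_k27", "dhs_k27"),
                        length.out = n_decoys)
      free_idx <- dec_idx[decoy_type == "dhs_k27"]
      for (m in seq_len(n_decoys)) {
        if (decoy_type[m] == "tf_dhs") {
          dhs_rows[[length(dhs_rows) + 1]] <- dhs_at(tf_peaks[dec_idx[m], ])
        } else if (decoy_type[m] == "tf_k27") {
          k27_rows[[length(k27_rows) + 1]] <- k27_at(tf_peaks[dec_idx[m], ])
        }
      }
      if (length(free_idx) > 0) {
        pos <- sample_clear_positions(length(free_idx), cl, tf_peaks,
                                      clearance)
        for (m in seq_len(nrow(pos))) {
          dhs_rows[[length(dhs_rows) + 1]] <-
            tibble(chrom = pos$chrom[m], start = pos$pos[m] - 150,
                   end = pos$pos[m] + 150)
          k27_rows[[length(k27_rows) + 1]] <-
            tibble(chrom = pos$chrom[m], start = pos$pos[m] - 500,
                   end = pos$pos[m] + 500)
        }
      }
    }
    if (n_scatter > 0) {
      pos <- sample_clear_positions(2 * n_scatter, cl,
                                    bind_rows(tf_peaks,
                                              bind_rows(dhs_rows),
                                              bind_rows(k27_rows)),
                                    clearance)
      for (m in seq_len(n_scatter)) {
        dhs_rows[[length(dhs_rows) + 1]] <-
          tibble(chrom = pos$chrom[m], start = pos$pos[m] - 150,
                 end = pos$pos[m] + 150)
      }
      for (m in n_scatter + seq_len(n_scatter)) {
        k27_rows[[length(k27_rows) + 1]] <-
          tibble(chrom = pos$chrom[m], start = pos$pos[m] - 500,
                 end = pos$pos[m] + 500)
      }
    }
    mk <- function(rows, prefix) {
      x <- bind_rows(rows)
      if (nrow(x) == 0) {
        return(as_intervals(tibble(chrom = character(), start = numeric(),
                                   end = numeric())))
      }
      x$start <- pmax(x$start, 0)
      x$name <- sprintf("%s%04d", prefix, seq_len(nrow(x)))
      as_intervals(x)
    }
    dhs <- mk(dhs_rows, "dhs")
    k27 <- mk(k27_rows, "k27")
    # exhaustive verification: the planted loci are exactly the triples
    triple <- triple_intersect(tf_peaks, dhs, k27, max_gap = 0)
    planted <- as_intervals(tf_peaks[sil_idx, , drop = FALSE])
    if (nrow(triple) != n_silencers ||
        !identical(paste(triple$chrom, triple$start, triple$end),
                   paste(planted$chrom, planted$start, planted$end))) {
      abort("placement failed: triple-overlap loci do not equal planted silencers")
    }
    decoys <- tf_peaks[dec_idx, , drop = FALSE]
    decoys$decoy_type <- decoy_type
    truth <- new_truth(seed, planted_silencers = planted,
                       decoy_loci = as_tibble(decoys))
    attr(dhs, "chrom_lengths") <- cl
    attr(k27, "chrom_lengths") <- cl
    list(dhs = dhs, k27 = k27, truth = truth)
  })
}

#' Generate a two-condition expression matrix with planted effects
#'
#' Baseline per-gene levels are lognormal. In condition A, planted `+`
#' targets are shifted up by `effect_log2fc` (log2 units) and `-` targets
#' down; all other genes are null. Per-sample lognormal noise with
#' standard deviation `noise_sd` (log2 scale) is applied; all values stay
#' positive.
#'
#' @param genes Gene-model tibble.
#' @param truth `synthetic_truth` carrying `planted_targets` (from
#'   [gen_peaks()]).
#' @param n_reps Replicates per condition (>= 2).
#' @param effect_log2fc Planted log2 fold change (A over B).
#' @param noise_sd Per-sample noise standard deviation in log2 units
#'   (>= 0).
#' @param base_meanlog,base_sdlog Lognormal law of baseline levels.
#' @param seed Integer RNG seed.
#' @return A long tibble `gene_id`, `sample_id`, `condition` (A/B),
#'   `value`.
#' @export
gen_expression <- function(genes, truth, n_reps = 3, effect_log2fc = 2,
                           noise_sd = 0.25, base_meanlog = log(100),
                           base_sdlog = 1, seed = 1) {
  genes <- as_gene_models(genes)
  if (n_reps < 2) abort("n_reps must be >= 2")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  tg <- truth$planted_targets
  with_seed(seed, {
    base <- rlnorm(nrow(genes), base_meanlog, base_sdlog)
    sign_of <- setNames(tg$sign, tg$gene_id)[genes$gene_id]
    shift <- ifelse(is.na(sign_of), 0,
                    ifelse(sign_of == "+", effect_log2fc, -effect_log2fc))
    samples <- tibble(
      sample_id = c(paste0("A", seq_len(n_reps)), paste0("B", seq_len(n_reps))),
      condition = rep(c("A", "B"), each = n_reps)
    )
    out <- tidyr::crossing(gene_id = genes$gene_id, samples) |>
      arrange(gene_id, sample_id)
    mu <- base[match(out$gene_id, genes$gene_id)] *
      2^(ifelse(out$condition == "A",
                shift[match(out$gene_id, genes$gene_id)], 0))
    out$value <- mu * 2^rnorm(nrow(out), 0, noise_sd)
    out
  })
}

#' Default qPCR gene panel
#'
#' The panel used by [gen_embryo_ct()] and [gen_single_cells()]: the
#' endogenous control (Actb), the knocked-out TF (Cdx2), the Neo cassette
#' reporting mutant-allele dosage, TE genes positively regulated by the TF
#' (Eomes, Elf5, Id2, Krt8), TE genes running in parallel to it (Gata3,
#' Tfap2c, Krt18, Cldn4), and ICM pluripotency genes it represses (Pou5f1,
#' Nanog, Sox2). `base_ct` is the expected threshold cycle at wild-type
#' dosage after preamplification.
#'
#' @return A tibble `gene`, `class`, `base_ct`.
#' @export
default_qpcr_panel <- function() {
  tibble(
    gene = c("Actb", "Cdx2", "Neo", "Eomes", "Elf5", "Id2", "Krt8",
             "Gata3", "Tfap2c", "Krt18", "Cldn4", "Pou5f1", "Nanog", "Sox2"),
    class = c("reference", "anchor", "cassette",
              rep("positive", 4), rep("parallel", 4), rep("negative", 3)),
    base_ct = c(14, 20, 22, 21, 21.5, 22, 20.5,
                21, 21.5, 20.8, 22.2, 19.5, 21, 21)
  )
}

#' Generate a single-embryo qPCR Ct table with planted genotypes
#'
#' Emulates microfluidic qPCR of blastocysts from a heterozygous
#' intercross of a TF knockout in which the Neo cassette replaces the TF
#' allele. Per embryo and gene, Ct = base_ct - log2(dosage effect) +
#' biological noise + technical noise, in technical triplicate; Ct values
#' above `detection_limit` are recorded as undetected (`NA`).
#' Genotype effects: nulls have no TF transcript (undetected in all
#' replicates), Neo at two-copy level, and ICM genes elevated ~2-fold;
#' hets have the TF at half dosage and Neo at one-copy level; wild types
#' have no Neo. Genes of class "positive" scale with TF dosage; "parallel"
#' genes are unperturbed. The reference gene has near-zero biological
#' noise, so it is always detected and has the lowest Ct variance in the
#' panel.
#'
#' @param n_embryos Cohort size (default 27).
#' @param n_null,n_wt Planted homozygous-null and wild-type counts
#'   (defaults 6 and 4); the remainder are heterozygous.
#' @param panel Panel tibble as in [default_qpcr_panel()]; must contain
#'   Cdx2, Neo and Actb.
#' @param n_replicates Technical replicates (default 3).
#' @param detection_limit Ct above which a reaction reads undetected
#'   (default 28 on the preamplified scale).
#' @param tech_sd Technical replicate noise, cycles (default 0.15).
#' @param bio_sd Biological embryo-to-embryo noise, log2 units
#'   (default 0.2; the reference gene uses 0.02).
#' @param icm_up_null Fold elevation of ICM genes in nulls (default 2).
#' @param seed Integer RNG seed.
#' @return A list with `ct` (long tibble `embryo_id`, `gene`, `replicate`,
#'   `ct`; `NA` = undetected) and `truth` (`embryo_genotypes` tibble).
#' @export
gen_embryo_ct <- function(n_embryos = 27, n_null = 6, n_wt = 4,
                          panel = default_qpcr_panel(), n_replicates = 3,
                          detection_limit = 28, tech_sd = 0.15,
                          bio_sd = 0.2, icm_up_null = 2, seed = 1) {
  if (n_null + n_wt > n_embryos) abort("n_null + n_wt exceeds n_embryos")
  if (!all(c("Cdx2", "Neo", "Actb") %in% panel$gene)) {
    abort("panel must contain Cdx2, Neo and Actb")
  }
  with_seed(seed, {
    geno <- sample(c(rep("null", n_null), rep("wt", n_wt),
                     rep("het", n_embryos - n_null - n_wt)))
    embryos <- sprintf("E%02d", seq_len(n_embryos))
    dosage <- c(wt = 1, het = 0.5, null = 0)[geno]
    grid <- tidyr::crossing(embryo_id = embryos, gene = panel$gene) |>
      left_join(panel, by = "gene") |>
      left_join(tibble(embryo_id = embryos, genotype = geno,
                       dosage = unname(dosage)),
                by = "embryo_id")
    # dosage-effect multiplier on the expression scale, per gene class
    grid <- grid |>
      mutate(mult = dplyr::case_when(
        class == "reference" ~ 1,
        class == "anchor" ~ dosage,
        class == "cassette" ~ 1 - dosage,       # 2-copy in null, 1 in het, 0 in wt
        class == "positive" ~ 0.25 + 0.75 * dosage,
        class == "parallel" ~ 1,
        class == "negative" ~ 1 + (icm_up_null - 1) * (1 - dosage)^2,
        TRUE ~ 1
      ))
    grid$bio <- rnorm(nrow(grid), 0,
                      ifelse(grid$class == "reference", 0.02, bio_sd))
    out <- grid |>
      tidyr::crossing(replicate = seq_len(n_replicates)) |>
      arrange(embryo_id, gene, replicate)
    true_ct <- out$base_ct - log2(out$mult) - out$bio
    ct_val <- true_ct + rnorm(nrow(out), 0, tech_sd)
    ct_val[!is.finite(ct_val) | ct_val > detection_limit] <- NA_real_
    ct <- out |> select(embryo_id, gene, replicate) |>
      mutate(ct = ct_val)
    truth <- new_truth(seed, embryo_genotypes = tibble(
      embryo_id = embryos, genotype = geno) |> arrange(embryo_id))
    list(ct = ct, truth = truth)
  })
}

#' Generate single-cell expression of wild-type blastocyst cells
#'
#' Emulates a panel-restricted single-cell profile of ~64-cell-stage
#' wild-type embryos: half the cells are trophectoderm (anchor TF high,
#' positive and parallel TE genes high, ICM genes low), half inner cell
#' mass (the reverse). Lognormal noise on every value; the cassette gene
#' is absent (0) in wild types.
#'
#' @param n_cells Number of cells (default 60).
#' @param panel Panel tibble as in [default_qpcr_panel()].
#' @param noise_sd Per-value noise, log2 units (default 0.3).
#' @param seed Integer RNG seed.
#' @return A list with `expr` (tibble `cell_id`, `gene`, `expression`)
#'   and `truth` (tibble `cell_id`, `lineage`).
#' @export
gen_single_cells <- function(n_cells = 60, panel = default_qpcr_panel(),
                             noise_sd = 0.3, seed = 1) {
  with_seed(seed, {
    lineage <- sample(rep(c("TE", "ICM"), length.out = n_cells))
    cells <- sprintf("C%03d", seq_len(n_cells))
    grid <- tidyr::crossing(cell_id = cells, gene = panel$gene) |>
      left_join(panel, by = "gene") |>
      left_join(tibble(cell_id = cells, lineage = lineage), by = "cell_id")
    grid <- grid |>
      mutate(level = dplyr::case_when(
        class == "reference" ~ 1,
        class == "cassette" ~ 0,
        class %in% c("anchor", "positive", "parallel") ~
          ifelse(lineage == "TE", 1, 0.08),
        class == "negative" ~ ifelse(lineage == "ICM", 1, 0.12),
        TRUE ~ 1
      ))
    expr <- grid |>
      mutate(expression = level * 2^rnorm(nrow(grid), 0, noise_sd)) |>
      mutate(expression = ifelse(level == 0, 0, expression)) |>
      select(cell_id, gene, expression) |>
      arrange(cell_id, gene)
    list(expr = expr,
         truth = tibble(cell_id = cells, lineage = lineage) |>
           arrange(cell_id))
  })
}
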