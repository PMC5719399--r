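#' Pipeline configuration
#'
#' Collects every tunable parameter of the pipeline with the study's
#' defaults: association decay length `d0 = 10000` bp, peak-to-TSS cutoff
#' `max_dist = 1e6` bp, `top_n = 3000` targets, sliding `window = 500`
#' genes with `step = 1`, co-occupancy border gap 200 bp, silencer triple
#' overlap gap 0 bp, DE rule `fc_cutoff = 2` with `alpha = 0.05`, and
#' correlation-map threshold `tau = 0.3`. Simulation-scale parameters
#' (`n_genes`, `n_targets`, ...) size the synthetic inputs.
#'
#' @param seed Integer seed driving every simulated input.
#' @param d0,max_dist,top_n,window,step,max_gap_cooccupancy,
#'   max_gap_silencer,fc_cutoff,alpha,tau Analysis parameters (see above).
#' @param n_chromosomes,chrom_length,n_genes,n_targets,prop_negative,
#'   background_rate,n_silencers,n_decoys,n_reps,effect_log2fc,noise_sd,
#'   n_embryos,n_null,n_wt,n_cells Synthetic-data dimensions.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, d0 = 10000, max_dist = 1e6,
                            top_n = 3000, window = 500, step = 1,
                            max_gap_cooccupancy = 200, max_gap_silencer = 0,
                            fc_cutoff = 2, alpha = 0.05, tau = 0.3,
                            n_chromosomes = 2, chrom_length = 2e7,
                            n_genes = 1000, n_targets = 300,
                            prop_negative = 1 / 3, background_rate = 5,
                            n_silencers = 20, n_decoys = 40, n_reps = 3,
                            effect_log2fc = 2, noise_sd = 0.25,
                            n_embryos = 27, n_null = 6, n_wt = 4,
                            n_cells = 60) {
  cfg <- as.list(environment())
  stopifnot(cfg$d0 > 0, cfg$max_dist > 0, cfg$top_n >= 1, cfg$window >= 1,
            cfg$step >= 1, cfg$max_gap_cooccupancy >= 0,
            cfg$max_gap_silencer >= 0, cfg$fc_cutoff >= 1,
            cfg$alpha > 0, cfg$alpha < 1, cfg$tau >= 0, cfg$tau < 1)
  structure(cfg, class = "pipeline_config")
}

#' Simulate every pipeline input
#'
#' Runs all generators of the synthetic-data module under one
#' configuration, deriving a distinct sub-seed per generator from
#' `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @return A list: `genes`, `peaks`, `dhs`, `k27`, `expr`, `ct`,
#'   `sc_expr`, and the merged `truth`.
#' @export
simulate_inputs <- function(config = pipeline_config()) {
  s <- config$seed
  genes <- gen_genome(config$n_chromosomes, config$chrom_length,
                      config$n_genes, seed = s)
  pk <- gen_peaks(genes, n_targets = config$n_targets,
                  prop_negative = config$prop_negative,
                  background_rate = config$background_rate,
                  max_dist = config$max_dist, seed = s + 1)
  ep <- gen_epigenome(pk$peaks, n_silencers = config$n_silencers,
                      n_decoys = config$n_decoys, seed = s + 2)
  expr <- gen_expression(genes, pk$truth, n_reps = config$n_reps,
                         effect_log2fc = config$effect_log2fc,
                         noise_sd = config$noise_sd, seed = s + 3)
  ec <- gen_embryo_ct(n_embryos = config$n_embryos, n_null = config$n_null,
                      n_wt = config$n_wt, seed = s + 4)
  sc <- gen_single_cells(n_cells = config$n_cells, seed = s + 5)
  truth <- new_truth(s,
                     planted_targets = pk$truth$planted_targets,
                     planted_silencers = ep$truth$planted_silencers,
                     decoy_loci = ep$truth$decoy_loci,
                     embryo_genotypes = ec$truth$embryo_genotypes)
  list(genes = genes, peaks = pk$peaks, dhs = ep$dhs, k27 = ep$k27,
       expr = expr, ct = ec$ct, sc_expr = sc$expr, truth = truth)
}

#' Run the full analysis pipeline on synthetic inputs
#'
#' Executes every stage end-to-end: simulation, genome-wide TF association
#' scoring with top-N target calling, differential expression and genome
#' ranking, the sliding-window association profile, TF/DHS co-occupancy,
#' silencer calling with nearest-gene assignment, and the single-embryo
#' qPCR analysis (relative expression, genotype calls, hierarchical
#' clustering, anchor-gene correlation map). When `outdir` is given, all
#' stage outputs are written as TSV/BED plus a JSON run manifest recording
#' the configuration, effective parameters and per-file MD5 checksums;
#' reruns with an identical configuration are bit-identical. `top_n` is
#' capped at the simulated genome size (the effective value is recorded in
#' the manifest).
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory, or `NULL` to skip writing.
#' @param inputs Optional pre-built input list as returned by
#'   [simulate_inputs()] (e.g. read from files); when `NULL`, inputs are
#'   simulated from `config`. A missing element aborts with the name of
#'   the stage that needs it.
#' @return A list of stage results: `inputs`, `assoc`, `targets`, `de`,
#'   `ranked`, `profile`, `cooccupancy`, `silencers`, `silencer_summary`,
#'   `embryo_expr`, `genotypes`, `clustering`, `cor_map`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         inputs = NULL) {
  stage <- function(name, code) {
    tryCatch(force(code), error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  need <- function(name, stage_name) {
    if (is.null(inputs[[name]])) {
      abort(paste0("pipeline stage '", stage_name,
                   "' failed: missing input '", name, "'"))
    }
    inputs[[name]]
  }
  if (is.null(inputs)) {
    inputs <- stage("simulate", simulate_inputs(config))
  } else {
    for (nm in c("genes", "peaks")) need(nm, "associate")
    need("dhs", "cooccupy")
    need("k27", "silencers")
    need("expr", "de")
    need("ct", "embryos")
    need("sc_expr", "embryos")
  }
  assoc <- stage("associate",
                 association_table(inputs$genes, inputs$peaks,
                                   d0 = config$d0, max_dist = config$max_dist))
  top_n_eff <- min(config$top_n, nrow(assoc))
  targets <- stage("targets", top_targets(assoc, n = top_n_eff))
  fc <- stage("de", fold_change_test(inputs$expr, "A", "B"))
  de <- stage("de", de_genes(fc, fc_cutoff = config$fc_cutoff,
                             alpha = config$alpha))
  ranked <- stage("rank", rank_genome(fc))
  window_eff <- min(config$window, nrow(ranked))
  profile <- stage("profile",
                   sliding_window_profile(ranked, assoc, window = window_eff,
                                          step = config$step))
  cooc <- stage("cooccupy",
                co_occupied_loci(inputs$peaks, inputs$dhs,
                                 max_gap = config$max_gap_cooccupancy))
  sil <- stage("silencers",
               call_silencers(inputs$peaks, inputs$dhs, inputs$k27,
                              max_gap = config$max_gap_silencer) |>
                 assign_genes(inputs$genes))
  sil_sum <- stage("silencers", silencer_gene_summary(sil))
  eexpr <- stage("embryos", relative_expression(inputs$ct))
  geno <- stage("embryos", classify_genotypes(eexpr, inputs$ct))
  clust <- stage("embryos", cluster_embryos(eexpr, k = 2))
  cmap <- stage("embryos",
                cdx2_correlation_map(inputs$sc_expr, eexpr, tau = config$tau))
  res <- list(inputs = inputs, assoc = assoc, targets = targets, de = de,
              ranked = ranked, profile = profile, cooccupancy = cooc,
              silencers = sil, silencer_summary = sil_sum,
              embryo_expr = eexpr, genotypes = geno, clustering = clust,
              cor_map = cmap, manifest = NULL)
  if (!is.null(outdir)) {
    res$manifest <- write_pipeline_outputs(res, config, outdir)
  }
  res
}

write_pipeline_outputs <- function(res, config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_gene_tsv(res$inputs$genes, p("genes.tsv"))
  write_bed(res$inputs$peaks, p("tf_peaks.bed"))
  write_bed(res$inputs$dhs, p("dhs.bed"))
  write_bed(res$inputs$k27, p("k27.bed"))
  write_expression_tsv(res$inputs$expr, p("expression.tsv"))
  write_ct_tsv(res$inputs$ct, p("embryo_ct.tsv"))
  readr::write_tsv(as_tibble(res$assoc), p("association.tsv"))
  readr::write_tsv(tibble(gene_id = res$targets), p("targets.tsv"))
  readr::write_tsv(res$de$up, p("de_up.tsv"))
  readr::write_tsv(res$de$down, p("de_down.tsv"))
  readr::write_tsv(as_tibble(res$profile), p("window_profile.tsv"))
  readr::write_tsv(res$cooccupancy, p("cooccupied.tsv"))
  readr::write_tsv(res$silencers, p("silencers.tsv"))
  readr::write_tsv(res$silencer_summary, p("silencer_genes.tsv"))
  readr::write_tsv(res$embryo_expr, p("embryo_expression.tsv"))
  readr::write_tsv(as_tibble(res$genotypes), p("genotypes.tsv"))
  readr::write_tsv(res$clustering$labels, p("embryo_clusters.tsv"))
  readr::write_tsv(as_tibble(res$cor_map), p("correlation_map.tsv"))
  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(
    config = unclass(config),
    effective = list(top_n = length(res$targets),
                     window = attr(res$profile, "window")),
    files = as.list(setNames(
      unname(tools::md5sum(file.path(outdir, files))), files))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}
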