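# Independent brute-force oracles for the geometric and scoring primitives.
# These deliberately use the plainest possible formulations (per-element
# loops / full scans) so they share no code path with the implementation.

oracle_gap <- function(a_start, a_end, b_start, b_end) {
  if (a_end <= b_start) return(b_start - a_end)
  if (b_end <= a_start) return(a_start - b_end)
  0
}

oracle_assoc_score <- function(tss, chrom, peaks, d0 = 10000, max_dist = 1e6) {
  s <- 0
  for (k in seq_len(nrow(peaks))) {
    if (peaks$chrom[k] != chrom) next
    d <- abs(floor((peaks$start[k] + peaks$end[k]) / 2) - tss)
    if (d > max_dist) next
    s <- s + peaks$intensity[k] * exp(-d / d0)
  }
  s
}

oracle_pairs <- function(a, b, max_gap) {
  hits <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          oracle_gap(a$start[i], a$end[i], b$start[j], b$end[j]) <= max_gap) {
        hits[[length(hits) + 1]] <- c(a$name[i], b$name[j])
      }
    }
  }
  if (length(hits) == 0) return(character(0))
  sort(vapply(hits, paste, character(1), collapse = "|"))
}

oracle_triple_members <- function(a, b, c, max_gap) {
  keep <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    hit_b <- FALSE
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          oracle_gap(a$start[i], a$end[i], b$start[j], b$end[j]) <= max_gap) {
        hit_b <- TRUE
        break
      }
    }
    if (!hit_b) next
    for (j in seq_len(nrow(c))) {
      if (a$chrom[i] == c$chrom[j] &&
          oracle_gap(a$start[i], a$end[i], c$start[j], c$end[j]) <= max_gap) {
        keep[i] <- TRUE
        break
      }
    }
  }
  sort(a$name[keep])
}

oracle_nearest <- function(mid, chrom, genes) {
  gi <- which(genes$chrom == chrom)
  if (length(gi) == 0) return(list(gene = NA_character_, dist = NA_real_))
  best <- NULL
  best_d <- Inf
  for (i in gi) {
    d <- abs(mid - genes$tss[i])
    if (d < best_d || (d == best_d && genes$gene_id[i] < genes$gene_id[best])) {
      best <- i
      best_d <- d
    }
  }
  off <- mid - genes$tss[best]
  list(gene = genes$gene_id[best],
       dist = if (genes$strand[best] == "+") off else -off)
}

random_intervals <- function(n, n_chrom = 3, span = 10000, width_max = 500) {
  start <- sample.int(span, n, replace = TRUE)
  tibble::tibble(
    chrom = paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
    start = start,
    end = start + sample.int(width_max, n, replace = TRUE),
    name = sprintf("r%04d", seq_len(n)),
    intensity = stats::runif(n, 0, 10)
  )
}

random_genes <- function(n, n_chrom = 3, span = 10000) {
  tibble::tibble(
    gene_id = sprintf("g%04d", sample.int(n * 10, n)),
    chrom = paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
    tss = sample.int(span, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE)
  )
}

# Vectorised brute-force variants for the larger acceptance-scale scans.
# Still independent of the implementation: full n x m comparison matrices,
# no sorting or sweeping.

oracle_assoc_vec <- function(genes, peaks, d0 = 10000, max_dist = 1e6) {
  mid <- floor((peaks$start + peaks$end) / 2)
  vapply(seq_len(nrow(genes)), function(i) {
    d <- abs(mid - genes$tss[i])
    ok <- peaks$chrom == genes$chrom[i] & d <= max_dist
    sum(peaks$intensity[ok] * exp(-d[ok] / d0))
  }, numeric(1))
}

oracle_gap_matrix <- function(a, b) {
  ae <- outer(a$end, b$start, function(x, y) y - x)
  be <- outer(a$start, b$end, function(x, y) x - y)
  g <- pmax(ae, be, 0)
  g[outer(a$chrom, b$chrom, `!=`)] <- Inf
  g
}

oracle_pairs_mat <- function(a, b, max_gap) {
  hit <- which(oracle_gap_matrix(a, b) <= max_gap, arr.ind = TRUE)
  sort(paste(a$name[hit[, 1]], b$name[hit[, 2]], sep = "|"))
}

oracle_triple_mat <- function(a, b, c, max_gap) {
  hb <- rowSums(oracle_gap_matrix(a, b) <= max_gap) > 0
  hc <- rowSums(oracle_gap_matrix(a, c) <= max_gap) > 0
  sort(a$name[hb & hc])
}

oracle_nearest_mat <- function(loci, genes) {
  mid <- floor((loci$start + loci$end) / 2)
  d <- abs(outer(mid, genes$tss, `-`))
  d[outer(loci$chrom, genes$chrom, `!=`)] <- Inf
  ord <- order(genes$gene_id)
  vapply(seq_len(nrow(loci)), function(i) {
    if (all(is.infinite(d[i, ]))) return(NA_character_)
    cand <- ord[d[i, ord] == min(d[i, ])]
    genes$gene_id[cand[1]]
  }, character(1))
}

# drop generator bookkeeping attributes before round-trip comparisons
as_plain_df <- function(x) {
  attr(x, "chrom_lengths") <- NULL
  as.data.frame(x)
}
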