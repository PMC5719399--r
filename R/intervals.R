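#' Genomic intervals and gene models as tibbles
#'
#' The package represents genomic intervals as tibbles with columns
#' `chrom` (character), `start`, `end` (0-based half-open, `start < end`),
#' `name` (character identifier) and `intensity` (non-negative peak height;
#' 0 for marks without an intensity). Gene models are tibbles with columns
#' `gene_id`, `chrom`, `tss` (0-based) and `strand` (`"+"` or `"-"`).
#' `as_intervals()` coerces and validates a data frame into the interval
#' shape; `as_gene_models()` does the same for annotations.
#'
#' @param x A data frame with at least `chrom`, `start`, `end`.
#' @return A validated, `(chrom, start)`-sorted tibble.
#' @examples
#' as_intervals(data.frame(chrom = "chr1", start = 100, end = 200))
#' @export
as_intervals <- function(x) {
  x <- as_tibble(x)
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("interval table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!("name" %in% names(x))) x$name <- paste0("iv", seq_len(nrow(x)))
  if (!("intensity" %in% names(x))) x$intensity <- 0
  x <- x |>
    mutate(
      chrom = as.character(chrom),
      start = as.numeric(start),
      end = as.numeric(end),
      name = as.character(name),
      intensity = as.numeric(intensity)
    ) |>
    select(chrom, start, end, name, intensity)
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0) {
    abort(paste0("invalid interval (need 0 <= start < end) at row ", bad[1],
                 ": ", x$chrom[bad[1]], ":", x$start[bad[1]], "-", x$end[bad[1]]))
  }
  if (any(x$intensity < 0)) abort("interval intensities must be >= 0")
  arrange(x, chrom, start, end, name)
}

#' @rdname as_intervals
#' @export
as_gene_models <- function(x) {
  x <- as_tibble(x)
  req <- c("gene_id", "chrom", "tss", "strand")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("gene annotation lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- x |>
    mutate(gene_id = as.character(gene_id), chrom = as.character(chrom),
           tss = as.numeric(tss), strand = as.character(strand)) |>
    select(gene_id, chrom, tss, strand)
  if (anyDuplicated(x$gene_id)) abort("gene_id values must be unique")
  if (!all(x$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  if (any(x$tss < 0)) abort("tss must be >= 0")
  arrange(x, chrom, tss, gene_id)
}

#' Read and write BED interval files
#'
#' `read_bed()` parses BED3+ files into the interval tibble shape; when a
#' 5th (score) column is present it is read as the peak intensity divided
#' by 10 (the inverse of the `write_bed()` scaling). `write_bed()` emits
#' BED6 with `score = round(intensity * 10)` and strand `"."`.
#' Round-tripping a valid interval set through `write_bed()`/`read_bed()`
#' is the identity up to that score rounding (exact for intensities in
#' tenths).
#'
#' @param path File path.
#' @param intervals An interval tibble (see [as_intervals()]).
#' @return `read_bed()` returns a sorted interval tibble; `write_bed()`
#'   returns `path` invisibly.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(as_intervals(tibble(chrom = character(), start = numeric(),
                               end = numeric(), name = character(),
                               intensity = numeric())))
  }
  fields <- stringr::str_split(lines, "\t")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(paste0("malformed BED line ", which(nf < 3)[1],
                 " in ", path, ": fewer than 3 fields"))
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    abort(paste0("malformed BED line ", bad[1], " in ", path,
                 ": non-numeric coordinates"))
  }
  bad <- which(!(start >= 0 & start < end))
  if (length(bad) > 0) {
    abort(paste0("malformed BED line ", bad[1], " in ", path,
                 ": need 0 <= start < end"))
  }
  nm <- ifelse(nf >= 4, vapply(fields, function(f) if (length(f) >= 4) f[[4]] else "", character(1)), "")
  nm[nm == ""] <- paste0("iv", which(nm == ""))
  sc <- rep(0, length(lines))
  has5 <- nf >= 5
  if (any(has5)) {
    raw <- vapply(fields[has5], `[[`, character(1), 5)
    val <- suppressWarnings(as.numeric(raw))
    if (anyNA(val)) {
      abort(paste0("malformed BED line ", which(has5)[which(is.na(val))[1]],
                   " in ", path, ": non-numeric score"))
    }
    sc[has5] <- val / 10
  }
  as_intervals(tibble(chrom = chrom, start = start, end = end,
                      name = nm, intensity = sc))
}

#' @rdname read_bed
#' @export
write_bed <- function(intervals, path) {
  intervals <- as_intervals(intervals)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.",
                   intervals$chrom, as.integer(intervals$start),
                   as.integer(intervals$end), intervals$name,
                   as.integer(round(intervals$intensity * 10)))
  readr::write_lines(lines, path)
  invisible(path)
}

# gap between the nearer borders of two half-open intervals on one chromosome;
# 0 when they touch or overlap
interval_gap <- function(a_start, a_end, b_start, b_end) {
  pmax(b_start - a_end, a_start - b_end, 0)
}

#' Do two intervals overlap within a border gap?
#'
#' Two intervals co-occupy a locus when they are on the same chromosome and
#' the gap between their nearer borders is at most `max_gap` bp. Touching or
#' overlapping intervals have gap 0, so `max_gap = 0` admits touching
#' intervals and otherwise reduces to standard half-open overlap.
#'
#' @param a,b Single-row interval tibbles (or one-interval lists with
#'   `chrom`, `start`, `end`).
#' @param max_gap Maximum tolerated distance between the nearer borders, bp.
#' @return Logical scalar; symmetric in `a` and `b`.
#' @examples
#' a <- data.frame(chrom = "chr1", start = 100, end = 200)
#' b <- data.frame(chrom = "chr1", start = 350, end = 450)
#' intervals_overlap(a, b, max_gap = 200)  # gap 150 -> TRUE
#' @export
intervals_overlap <- function(a, b, max_gap = 0) {
  stopifnot(max_gap >= 0)
  if (a$chrom[1] != b$chrom[1]) return(FALSE)
  interval_gap(a$start[1], a$end[1], b$start[1], b$end[1]) <= max_gap
}

# all (ia, ib) index pairs of rows of a that gap-overlap rows of b.
# sort/sweep over per-chromosome blocks keeps it near-linear for the sizes
# this pipeline sees while matching the quadratic definition exactly.
overlap_pairs_idx <- function(a, b, max_gap) {
  out_a <- integer(0); out_b <- integer(0)
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    bi <- b[ib, ]
    ord <- order(bi$start, bi$end)
    bs <- bi$start[ord]; be <- bi$end[ord]
    for (i in ia) {
      lo <- a$start[i] - max_gap
      hi <- a$end[i] + max_gap
      cand <- which(bs < hi + 1e-9 & be > lo - 1e-9)
      hit <- cand[interval_gap(a$start[i], a$end[i], bs[cand], be[cand]) <= max_gap]
      if (length(hit) > 0) {
        out_a <- c(out_a, rep(i, length(hit)))
        out_b <- c(out_b, ib[ord][hit])
      }
    }
  }
  ord <- order(a$chrom[out_a], a$start[out_a], a$end[out_a], a$name[out_a],
               b$chrom[out_b], b$start[out_b], b$end[out_b], b$name[out_b])
  list(a = out_a[ord], b = out_b[ord])
}

#' Co-occupied loci between two peak sets
#'
#' Returns every pair of intervals (one from `a`, one from `b`) whose
#' borders lie within `max_gap` bp of each other — the rule used to call
#' loci co-occupied by two transcription factors, with a default tolerance
#' of 200 bp between peak borders.
#'
#' @param a,b Interval tibbles.
#' @param max_gap Border gap tolerance in bp (default 200).
#' @return A tibble with the `a` interval columns (prefixed `a_`), the `b`
#'   columns (prefixed `b_`), and the border `gap`, ordered by `a` then `b`
#'   coordinates.
#' @export
co_occupied_loci <- function(a, b, max_gap = 200) {
  a <- as_intervals(a); b <- as_intervals(b)
  idx <- overlap_pairs_idx(a, b, max_gap)
  tibble(
    a_chrom = a$chrom[idx$a], a_start = a$start[idx$a], a_end = a$end[idx$a],
    a_name = a$name[idx$a], a_intensity = a$intensity[idx$a],
    b_chrom = b$chrom[idx$b], b_start = b$start[idx$b], b_end = b$end[idx$b],
    b_name = b$name[idx$b], b_intensity = b$intensity[idx$b],
    gap = interval_gap(a$start[idx$a], a$end[idx$a],
                       b$start[idx$b], b$end[idx$b])
  )
}

# nearest gap-qualifying row of pool for one query interval; ties broken by
# (start, end, name) order. Returns a row index into pool or NA.
nearest_witness_idx <- function(q_start, q_end, q_chrom, pool, max_gap) {
  same <- which(pool$chrom == q_chrom)
  if (length(same) == 0) return(NA_integer_)
  g <- interval_gap(q_start, q_end, pool$start[same], pool$end[same])
  ok <- same[g <= max_gap]
  if (length(ok) == 0) return(NA_integer_)
  gg <- g[g <= max_gap]
  ord <- order(gg, pool$start[ok], pool$end[ok], pool$name[ok])
  ok[ord[1]]
}

#' Triple intersection of interval sets
#'
#' Returns every interval of `a` that gap-overlaps at least one interval of
#' `b` and at least one interval of `c` — the geometric rule behind calling
#' candidate silencers from TF peaks, DNase-hypersensitive sites and
#' H3K27me3 domains. Each returned locus keeps the `a` footprint and records
#' the nearest qualifying witness from each of `b` and `c`.
#'
#' @param a,b,c Interval tibbles.
#' @param max_gap Border gap tolerance in bp (default 0, i.e. >= 1 bp
#'   overlap or touching).
#' @return A tibble of `a` rows with witness columns `b_*` and `c_*`.
#' @export
triple_intersect <- function(a, b, c, max_gap = 0) {
  a <- as_intervals(a); b <- as_intervals(b); c <- as_intervals(c)
  empty <- tibble(
    chrom = character(), start = numeric(), end = numeric(),
    name = character(), intensity = numeric(),
    b_chrom = character(), b_start = numeric(), b_end = numeric(), b_name = character(),
    c_chrom = character(), c_start = numeric(), c_end = numeric(), c_name = character()
  )
  if (nrow(a) == 0 || nrow(b) == 0 || nrow(c) == 0) return(empty)
  wb <- vapply(seq_len(nrow(a)), function(i)
    nearest_witness_idx(a$start[i], a$end[i], a$chrom[i], b, max_gap), integer(1))
  wc <- vapply(seq_len(nrow(a)), function(i)
    nearest_witness_idx(a$start[i], a$end[i], a$chrom[i], c, max_gap), integer(1))
  keep <- which(!is.na(wb) & !is.na(wc))
  if (length(keep) == 0) return(empty)
  tibble(
    chrom = a$chrom[keep], start = a$start[keep], end = a$end[keep],
    name = a$name[keep], intensity = a$intensity[keep],
    b_chrom = b$chrom[wb[keep]], b_start = b$start[wb[keep]],
    b_end = b$end[wb[keep]], b_name = b$name[wb[keep]],
    c_chrom = c$chrom[wc[keep]], c_start = c$start[wc[keep]],
    c_end = c$end[wc[keep]], c_name = c$name[wc[keep]]
  )
}

#' Nearest transcription start site for each locus
#'
#' Assigns each locus to the gene whose TSS is closest to the locus
#' midpoint `floor((start + end) / 2)`, the rule used to annotate candidate
#' silencers. Distance is the minimal absolute midpoint-to-TSS distance;
#' ties go to the lexicographically smaller `gene_id`. The reported
#' `signed_distance` is negative when the midpoint lies 5' of the TSS in
#' the gene's orientation (upstream) and positive downstream; strand never
#' changes the magnitude. Loci on chromosomes with no gene are returned
#' with `assigned_gene = NA` rather than dropped.
#'
#' @param loci Interval tibble.
#' @param genes Gene-model tibble (see [as_gene_models()]).
#' @return `loci` with added columns `midpoint`, `assigned_gene`,
#'   `signed_distance`.
#' @examples
#' loci <- data.frame(chrom = "chr1", start = 4900, end = 5100)
#' genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
#'                     tss = c(4000, 7500), strand = "+")
#' nearest_tss(loci, genes)  # gA at +1000
#' @export
nearest_tss <- function(loci, genes) {
  loci <- as_intervals(loci)
  genes <- as_gene_models(genes)
  n <- nrow(loci)
  mid <- floor((loci$start + loci$end) / 2)
  gid <- rep(NA_character_, n)
  sdist <- rep(NA_real_, n)
  for (ch in unique(loci$chrom)) {
    gi <- which(genes$chrom == ch)
    li <- which(loci$chrom == ch)
    if (length(gi) == 0) next
    for (i in li) {
      d <- abs(mid[i] - genes$tss[gi])
      best <- gi[order(d, genes$gene_id[gi])[1]]
      gid[i] <- genes$gene_id[best]
      offset <- mid[i] - genes$tss[best]
      sdist[i] <- if (genes$strand[best] == "+") offset else -offset
    }
  }
  loci |> mutate(midpoint = mid, assigned_gene = gid, signed_distance = sdist)
}
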