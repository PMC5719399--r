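test_that("BED round-trips and rejects malformed records", {
  iv <- as_intervals(tibble::tibble(
    chrom = c("chr2", "chr1", "chr1"),
    start = c(500, 100, 4000),
    end = c(900, 200, 4100),
    name = c("a", "b", "c"),
    intensity = c(2.5, 0, 7.1)
  ))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(iv, path)
  expect_equal(as.data.frame(read_bed(path)), as.data.frame(iv))

  # minimal BED3: intensity defaults to 0
  p3 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", p3)
  got <- read_bed(p3)
  expect_equal(got$start, 100)
  expect_equal(got$intensity, 0)

  # inverted coordinates are an error with the line number
  pbad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t300\t200"), pbad)
  expect_error(read_bed(pbad), "line 2")
  expect_error(as_intervals(data.frame(chrom = "chr1", start = 5, end = 5)),
               "start < end")
})

test_that("random valid interval sets survive a write/read round trip", {
  set.seed(41)
  for (i in 1:5) {
    iv <- random_intervals(80)
    iv$intensity <- round(iv$intensity, 1)  # representable in the BED score
    iv <- as_intervals(iv)
    path <- withr::local_tempfile(fileext = ".bed")
    write_bed(iv, path)
    expect_equal(as.data.frame(read_bed(path)), as.data.frame(iv))
  }
})

test_that("border-gap overlap follows the 200 bp rule and is symmetric", {
  a <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
  b <- tibble::tibble(chrom = "chr1", start = 350, end = 450)
  expect_true(intervals_overlap(a, b, max_gap = 200))   # gap 150
  expect_true(intervals_overlap(b, a, max_gap = 200))
  b2 <- tibble::tibble(chrom = "chr1", start = 401, end = 500)
  expect_false(intervals_overlap(a, b2, max_gap = 200)) # gap 201
  b3 <- tibble::tibble(chrom = "chr2", start = 100, end = 200)
  expect_false(intervals_overlap(a, b3, max_gap = 1e9))
  # touching half-open intervals have gap 0
  b4 <- tibble::tibble(chrom = "chr1", start = 200, end = 300)
  expect_true(intervals_overlap(a, b4, max_gap = 0))
})

test_that("max_gap = 0 overlap agrees with standard half-open intersection", {
  set.seed(7)
  a <- random_intervals(120)
  b <- random_intervals(120)
  for (i in sample.int(120, 30)) {
    for (j in sample.int(120, 30)) {
      std <- a$chrom[i] == b$chrom[j] &&
        a$start[i] <= b$end[j] && b$start[j] <= a$end[i]
      expect_identical(intervals_overlap(a[i, ], b[j, ], 0), std)
    }
  }
})

test_that("co-occupancy matches the brute-force pair scan", {
  set.seed(11)
  for (rep in 1:8) {
    a <- as_intervals(random_intervals(150))
    b <- as_intervals(random_intervals(150))
    got <- co_occupied_loci(a, b, max_gap = 200)
    expect_identical(sort(paste(got$a_name, got$b_name, sep = "|")),
                     oracle_pairs(a, b, 200))
    # output ordered by a's coordinates then b's
    expect_false(is.unsorted(order(got$a_chrom, got$a_start, got$a_end,
                                   got$b_chrom, got$b_start)))
  }
  # identical non-self-overlapping set pairs only with itself at gap 0
  iv <- as_intervals(tibble::tibble(chrom = "chr1",
                                    start = c(0, 1000, 2000),
                                    end = c(10, 1010, 2010)))
  self <- co_occupied_loci(iv, iv, max_gap = 0)
  expect_equal(nrow(self), 3)
  # disjoint chromosomes never pair
  c1 <- as_intervals(tibble::tibble(chrom = "chr1", start = 1, end = 100))
  c2 <- as_intervals(tibble::tibble(chrom = "chr2", start = 1, end = 100))
  expect_equal(nrow(co_occupied_loci(c1, c2, max_gap = 1e6)), 0)
})

test_that("triple intersection matches the brute-force scan and nests in pairs", {
  one <- as_intervals(tibble::tibble(chrom = "chr1", start = 10, end = 50))
  expect_equal(nrow(triple_intersect(one, one, one, 0)), 1)
  none <- one[0, ]
  expect_equal(nrow(triple_intersect(one, one, none, 0)), 0)
  set.seed(13)
  for (rep in 1:8) {
    a <- as_intervals(random_intervals(100))
    b <- as_intervals(random_intervals(100))
    c <- as_intervals(random_intervals(100))
    got <- triple_intersect(a, b, c, max_gap = 50)
    expect_identical(sort(got$name), oracle_triple_members(a, b, c, 50))
    # members must pair with both B and C
    ab <- unique(co_occupied_loci(a, b, 50)$a_name)
    ac <- unique(co_occupied_loci(a, c, 50)$a_name)
    expect_true(all(got$name %in% ab))
    expect_true(all(got$name %in% ac))
  }
})

test_that("nearest TSS uses the midpoint, signed by strand, ties by gene id", {
  genes <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "chr1",
                          tss = c(4000, 7500), strand = "+")
  locus <- tibble::tibble(chrom = "chr1", start = 4900, end = 5100)
  got <- nearest_tss(locus, genes)
  expect_equal(got$assigned_gene, "gA")
  expect_equal(got$signed_distance, 1000)
  # minus-strand gene flips the sign, not the magnitude
  genes_m <- dplyr::mutate(genes, strand = "-")
  expect_equal(nearest_tss(locus, genes_m)$signed_distance, -1000)
  # equidistant TSSs resolve to the lexicographically smaller id
  tie_genes <- tibble::tibble(gene_id = c("gZ", "gB"), chrom = "chr1",
                              tss = c(4000, 6000), strand = "+")
  got_tie <- nearest_tss(locus, tie_genes)
  expect_equal(got_tie$assigned_gene, "gB")
  # gene-free chromosome reports unassigned rather than erroring
  off <- tibble::tibble(chrom = "chrX", start = 0, end = 10)
  expect_true(is.na(nearest_tss(off, genes)$assigned_gene))
})

test_that("nearest TSS matches the brute-force per-gene scan", {
  set.seed(17)
  loci <- as_intervals(random_intervals(200, n_chrom = 4))
  genes <- as_gene_models(random_genes(80, n_chrom = 4))
  got <- nearest_tss(loci, genes)
  for (i in seq_len(nrow(got))) {
    ref <- oracle_nearest(got$midpoint[i], got$chrom[i], genes)
    expect_identical(got$assigned_gene[i], ref$gene)
    expect_identical(got$signed_distance[i], as.numeric(ref$dist))
  }
})
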