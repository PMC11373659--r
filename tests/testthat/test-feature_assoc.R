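# A small hand-built annotation: one "+" gene and one "-" gene on a 100-kb
# chromosome, with explicit exon/intron/UTR/CDS structure.
toy_annotation <- function() {
  genes <- data.frame(
    chrom = "c1", start = c(10000, 60000), end = c(19999, 69999),
    strand = c("+", "-"), gene_id = c("gA", "gB"), stringsAsFactors = FALSE)
  feats <- rbind(
    # gA (+): exon1 10000-10999 (UTR5 10000-10199, CDS 10200-10999),
    # intron 11000-14999, exon2 15000-19999 (CDS ...-19499, UTR3 19500-19999)
    data.frame(chrom = "c1", start = c(10000, 15000), end = c(10999, 19999),
               type = "exon", strand = "+", gene_id = "gA"),
    data.frame(chrom = "c1", start = 11000, end = 14999, type = "intron",
               strand = "+", gene_id = "gA"),
    data.frame(chrom = "c1", start = c(10200, 15000), end = c(10999, 19499),
               type = "CDS", strand = "+", gene_id = "gA"),
    data.frame(chrom = "c1", start = 10000, end = 10199,
               type = "five_prime_UTR", strand = "+", gene_id = "gA"),
    data.frame(chrom = "c1", start = 19500, end = 19999,
               type = "three_prime_UTR", strand = "+", gene_id = "gA"),
    # gB (-): single exon gene body with CDS 60500-69499, UTRs at the ends
    data.frame(chrom = "c1", start = 60000, end = 69999, type = "exon",
               strand = "-", gene_id = "gB"),
    data.frame(chrom = "c1", start = 60500, end = 69499, type = "CDS",
               strand = "-", gene_id = "gB"),
    data.frame(chrom = "c1", start = 69500, end = 69999,
               type = "five_prime_UTR", strand = "-", gene_id = "gB"),
    data.frame(chrom = "c1", start = 60000, end = 60499,
               type = "three_prime_UTR", strand = "-", gene_id = "gB"))
  annotation_set(genes, feats)
}

toy_calls <- function(points) data.frame(
  offspring = "O1", side = "paternal", chrom = "c1", arm = "q",
  left = points - 10, right = points + 10, point = points, precision = 20,
  transition = "GF>GM", spans_centromere = FALSE, artifact = FALSE,
  stringsAsFactors = FALSE)

test_that("points are classified hierarchically against the annotation", {
  ann <- toy_annotation()
  cls <- classify_co(toy_calls(c(10500, 12000, 5000, 10100, 19700, 65000)),
                     ann)
  expect_equal(cls$feat_gene,
               c("genic", "genic", "intergenic", "genic", "genic", "genic"))
  expect_equal(cls$feat_exon, c("exon", "intron", NA, "exon", "exon", "exon"))
  expect_equal(cls$feat_cds, c("CDS", NA, NA, "UTR", "UTR", "CDS"))
})

test_that("classification matches a brute-force interval scan", {
  lay <- telo_layout(2e6)
  set.seed(71)
  ann <- simulate_annotation(lay)
  pts <- sort(sample.int(2e6, 200))
  cls <- classify_co(toy_calls(pts), ann)
  f <- ann$features
  for (i in seq_along(pts)) {
    p <- pts[i]
    in_g <- any(p >= ann$genes$start & p <= ann$genes$end)
    expect_equal(cls$feat_gene[i] == "genic", in_g)
    if (in_g) {
      in_e <- any(p >= f$start[f$type == "exon"] & p <= f$end[f$type == "exon"])
      expect_equal(cls$feat_exon[i] == "exon", in_e)
      if (in_e) {
        in_c <- any(p >= f$start[f$type == "CDS"] & p <= f$end[f$type == "CDS"])
        expect_equal(cls$feat_cds[i] == "CDS", in_c)
      }
    }
  }
  # partition property: every point gets exactly one label per level
  expect_true(all(cls$feat_gene %in% c("intergenic", "genic")))
  expect_true(all(is.na(cls$feat_exon[cls$feat_gene == "intergenic"])))
  genic <- cls$feat_gene == "genic"
  expect_true(all(cls$feat_exon[genic] %in% c("exon", "intron")))
  ex <- genic & cls$feat_exon == "exon"
  expect_true(all(cls$feat_cds[ex] %in% c("UTR", "CDS")))
})

test_that("goodness of fit reproduces hand-computed chi-square values", {
  g <- gof_test(c(a = 30, b = 70), c(50, 50))
  expect_equal(g$statistic, (30 - 50)^2 / 50 + (70 - 50)^2 / 50)
  expect_equal(g$df, 1)
  expect_equal(sum(g$expected), 100)
  g0 <- gof_test(c(25, 75), c(1e6, 3e6))
  expect_equal(g0$statistic, 0)
  expect_equal(g0$p, 1)
  expect_error(gof_test(c(1, 2), c(0, 10)), "zero")
})

test_that("sub-telomeric filtering keeps calls within the window", {
  lay <- genome_layout(data.frame(chrom = "c1", length = 60e6,
                                  centromere = 20e6))
  pts <- c(1e5, 5e6, 54e6 + 1, 53.9e6, 30e6, 59.9e6, 6.1e6, 20e6 - 1e5)
  calls <- toy_calls(pts)
  at <- arm_table(lay)
  calls$arm <- at$arm[pedcross:::.arm_index(at, calls$chrom, calls$point)]
  kept <- subtelomeric_filter(calls, lay, window = 6e6)
  d <- arm_distance_metrics(calls, lay)$telo_dist
  expect_equal(kept$point, pts[d <= 6e6])
  # distance 0 kept, distance just over the window dropped
  expect_true(1e5 %in% kept$point)
  expect_false(6.1e6 %in% kept$point)   # 6.1 Mb from the left telomere
  wins <- subtelomeric_windows(lay, 6e6)
  expect_equal(nrow(wins), 2)
  expect_equal(wins$end[wins$start == 1] - wins$start[wins$start == 1] + 1,
               6e6)
})

test_that("nearest-gene distances are signed by strand-relative side", {
  ann <- toy_annotation()
  ng <- nearest_gene(toy_calls(c(15000,          # inside gA
                                 20499,          # 500 bp past gA's 3' end
                                 9500,           # 500 bp before gA's 5' end
                                 70499,          # 500 bp "before" gB (minus)
                                 59500)),        # 500 bp past gB's 3' end
                     ann)
  expect_equal(ng$distance, c(0, 500, -500, -500, 500))
  expect_equal(ng$gene_id, c("gA", "gA", "gA", "gB", "gB"))
  ng2 <- suppressWarnings(nearest_gene(
    data.frame(chrom = "c9", point = 1), ann))
  expect_true(is.na(ng2$distance))
})

test_that("permutation test is seed-deterministic and matches a re-implementation", {
  lay <- telo_layout(1e5)
  ann <- toy_annotation()
  calls <- classify_co(toy_calls(c(5000, 30000, 42000, 85000)), ann)
  r1 <- permutation_gene_proximity(calls, ann, lay, reps = 400, seed = 99)
  r2 <- permutation_gene_proximity(calls, ann, lay, reps = 400, seed = 99)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$null_median, r2$null_median)

  # independent re-implementation consuming the same uniform stream
  ig <- calls[calls$feat_gene == "intergenic", ]
  iv <- intergenic_intervals(ann, lay)
  hit <- function(p) which(iv$start <= p & iv$end >= p)
  home <- vapply(ig$point, hit, integer(1))
  obs <- median(abs(nearest_gene(ig, ann)$distance))
  set.seed(99)
  nm <- replicate(400, {
    x <- iv$start[home] + floor(runif(nrow(ig)) *
                                (iv$end[home] - iv$start[home] + 1))
    d <- vapply(seq_along(x), function(i) {
      g <- ann$genes
      min(abs(c(x[i] - g$end, g$start - x[i])[c(x[i] > g$end, g$start > x[i])]))
    }, numeric(1))
    median(d)
  })
  expect_equal(r1$p, mean(nm <= obs))
  expect_equal(r1$null_median, nm)
})

test_that("calls hugging genes give an extreme permutation P", {
  lay <- telo_layout(1e5)
  ann <- toy_annotation()
  # both intergenic calls 1 bp away from a gene edge
  calls <- classify_co(toy_calls(c(20000, 59999)), ann)
  res <- permutation_gene_proximity(calls, ann, lay, reps = 500, seed = 7)
  expect_lte(res$p, 0.01)
  expect_equal(res$observed_median, 1)
})
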