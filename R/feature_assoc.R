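#' Classify crossover point estimates against gene features
#'
#' Point-in-interval classification of each call's midpoint estimate using
#' 1-based inclusive annotation coordinates. Every point is either
#' `intergenic` or `genic`; genic points are `exon` or `intron`; exonic
#' points are `CDS` or `UTR`. Overlapping genes (e.g. on opposite strands)
#' resolve to `genic`; a point in any exon of any overlapping gene counts as
#' exonic.
#'
#' @param calls A `crossover_calls` data frame (or any data frame with
#'   `chrom` and `point` columns).
#' @param ann An [annotation_set()].
#' @return `calls` with added columns `feat_gene` (`"intergenic"`/`"genic"`),
#'   `feat_exon` (`"exon"`/`"intron"`/`NA`), `feat_cds`
#'   (`"CDS"`/`"UTR"`/`NA`).
#' @export
classify_co <- function(calls, ann) {
  stopifnot(inherits(ann, "annotation_set"))
  n <- nrow(calls)
  if (n == 0) {
    calls$feat_gene <- character(0); calls$feat_exon <- character(0)
    calls$feat_cds <- character(0)
    return(calls)
  }
  pts <- GenomicRanges::GRanges(calls$chrom,
                                IRanges::IRanges(calls$point, calls$point))
  hit <- function(df) {
    if (nrow(df) == 0) return(rep(FALSE, n))
    IRanges::overlapsAny(pts, .granges(df), ignore.strand = TRUE)
  }
  in_gene <- hit(ann$genes)
  in_exon <- hit(ann$features[ann$features$type == "exon", , drop = FALSE])
  in_cds <- hit(ann$features[ann$features$type == "CDS", , drop = FALSE])
  in_utr <- hit(.utr_rows(ann))
  calls$feat_gene <- ifelse(in_gene, "genic", "intergenic")
  calls$feat_exon <- ifelse(!in_gene, NA_character_,
                            ifelse(in_exon, "exon", "intron"))
  calls$feat_cds <- ifelse(!in_gene | !in_exon, NA_character_,
                           ifelse(in_cds, "CDS",
                                  ifelse(in_utr, "UTR", NA_character_)))
  calls
}

#' Chi-square goodness of fit against length-proportional expectations
#'
#' Tests whether observed crossover counts across annotation classes differ
#' from the counts expected if crossovers fell uniformly per bp: the
#' expected count of class i is `N * L_i / sum(L)`. Pearson chi-square
#' without continuity correction, df = classes - 1.
#'
#' @param observed Named (or ordered) integer vector of observed counts per
#'   class.
#' @param lengths Numeric vector of total class lengths in bp (or any
#'   weights proportional to them, e.g. precomputed expected counts).
#' @param scope Optional label (e.g. `"genome-wide"`, `"subtelomeric-6Mb"`).
#' @return A list of class `gof_result`: `observed`, `expected`,
#'   `statistic`, `df`, `p`, `scope`.
#' @examples
#' gof_test(c(intergenic = 109, genic = 115), c(138.5, 85.5))
#' @export
gof_test <- function(observed, lengths, scope = "genome-wide") {
  stopifnot(length(observed) == length(lengths), length(observed) >= 2,
            sum(observed) >= 1)
  if (any(lengths <= 0)) stop("zero or negative class length (expected count)")
  p <- lengths / sum(lengths)
  ct <- stats::chisq.test(observed, p = p, correct = FALSE)
  structure(list(observed = observed,
                 expected = sum(observed) * p,
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value, scope = scope),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat("chi-square goodness of fit (", x$scope, ")\n", sep = "")
  print(rbind(observed = x$observed, expected = round(x$expected, 1)))
  cat("  X2 =", format(x$statistic, digits = 4), " df =", x$df,
      " P =", format(x$p, digits = 3), "\n")
  invisible(x)
}

#' Sub-telomeric windows of every arm
#'
#' @param layout A [genome_layout()].
#' @param window Window size in bp from each arm's telomeric end
#'   (default 6 Mb).
#' @param autosomes_only Restrict to autosomal arms (default `TRUE`).
#' @return `data.frame` with columns `chrom`, `start`, `end`.
#' @export
subtelomeric_windows <- function(layout, window = 6e6, autosomes_only = TRUE) {
  arms <- arm_table(layout)
  if (autosomes_only) arms <- arms[arms$zclass == "autosome", , drop = FALSE]
  w <- pmin(window, arms$length)
  data.frame(chrom = arms$chrom,
             start = ifelse(arms$telomere == "left", arms$start,
                            arms$end - w + 1),
             end = ifelse(arms$telomere == "left", arms$start + w - 1,
                          arms$end),
             stringsAsFactors = FALSE)
}

#' Keep crossover calls within the sub-telomeric window of their arm
#'
#' @param calls A `crossover_calls` data frame.
#' @param layout A [genome_layout()].
#' @param window Distance threshold from the arm's telomeric end in bp
#'   (default 6 Mb).
#' @return The subset of `calls` whose physical telomere distance is at most
#'   `window`.
#' @export
subtelomeric_filter <- function(calls, layout, window = 6e6) {
  cm <- arm_distance_metrics(calls, layout)
  calls[cm$telo_dist <= window, , drop = FALSE]
}

#' Signed distance from each crossover to its nearest gene
#'
#' Minimal absolute distance from the call's point estimate to any gene on
#' its chromosome; 0 when inside a gene. The sign is strand-relative:
#' negative when the point lies upstream of the nearest gene (before its 5'
#' end in the gene's reading direction), positive when downstream.
#'
#' @param calls A data frame with `chrom` and `point` columns.
#' @param ann An [annotation_set()].
#' @return `data.frame` with columns `chrom`, `point`, `gene_id`,
#'   `distance` (bp, signed; `NA` with a warning for chromosomes without
#'   genes).
#' @export
nearest_gene <- function(calls, ann) {
  stopifnot(inherits(ann, "annotation_set"))
  n <- nrow(calls)
  out <- data.frame(chrom = calls$chrom, point = calls$point,
                    gene_id = NA_character_, distance = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    g <- ann$genes[ann$genes$chrom == calls$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) next
    p <- calls$point[i]
    gap <- ifelse(p < g$start, g$start - p, ifelse(p > g$end, p - g$end, 0))
    j <- which.min(gap)
    d <- gap[j]
    if (d > 0) {
      before <- p < g$start[j]  # left of the gene in genome coordinates
      upstream <- (before & g$strand[j] == "+") | (!before & g$strand[j] == "-")
      d <- if (upstream) -d else d
    }
    out$gene_id[i] <- g$gene_id[j]
    out$distance[i] <- d
  }
  if (anyNA(out$distance))
    warning("call(s) on chromosome(s) without genes: distance undefined")
  out
}

#' Permutation test: are intergenic crossovers closer to genes than chance?
#'
#' For the set of intergenic crossover calls, each replicate draws one
#' uniform position inside each call's own containing intergenic interval
#' and records the median absolute nearest-gene distance across calls; the
#' one-sided P value is the fraction of replicates whose null median is at
#' most the observed median ("closer than expected"). Reproducible for a
#' fixed seed.
#'
#' @param calls A `crossover_calls` data frame; only rows classified
#'   `intergenic` (via [classify_co()]) are used. If the classification
#'   columns are absent it is computed internally.
#' @param ann An [annotation_set()].
#' @param layout A [genome_layout()].
#' @param reps Number of permutation replicates (default 1000).
#' @param seed Optional integer seed.
#' @return A list of class `perm_result`: `p`, `observed_median`,
#'   `null_median` (vector of length `reps`), `n_calls`, `reps`.
#' @export
permutation_gene_proximity <- function(calls, ann, layout, reps = 1000,
                                       seed = NULL) {
  stopifnot(reps >= 1)
  if (!"feat_gene" %in% names(calls)) calls <- classify_co(calls, ann)
  ig <- calls[calls$feat_gene == "intergenic", , drop = FALSE]
  if (nrow(ig) == 0) stop("no intergenic crossover calls")
  if (!is.null(seed)) set.seed(seed)
  iv <- intergenic_intervals(ann, layout)
  ivgr <- GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start, iv$end))
  pts <- GenomicRanges::GRanges(ig$chrom, IRanges::IRanges(ig$point, ig$point))
  home <- GenomicRanges::findOverlaps(pts, ivgr, select = "first")
  if (anyNA(home)) stop("intergenic call without a containing interval")
  obs <- stats::median(abs(nearest_gene(ig, ann)$distance))
  ivs <- iv$start[home]; ive <- iv$end[home]; ivc <- iv$chrom[home]
  n <- nrow(ig)
  # inside an intergenic interval the nearest gene is a flanking one, so
  # distances follow from the interval edges (Inf when the interval abuts a
  # chromosome end rather than a gene)
  chlen <- layout$chromosomes$length[match(ivc, layout$chromosomes$chrom)]
  has_left <- ivs > 1
  has_right <- ive < chlen
  if (any(!has_left & !has_right))
    stop("intergenic call on a chromosome without genes")
  null_med <- vapply(seq_len(reps), function(r) {
    x <- ivs + floor(stats::runif(n) * (ive - ivs + 1))
    dl <- ifelse(has_left, x - (ivs - 1), Inf)
    dr <- ifelse(has_right, (ive + 1) - x, Inf)
    stats::median(pmin(dl, dr))
  }, numeric(1))
  structure(list(p = mean(null_med <= obs), observed_median = obs,
                 null_median = null_med, n_calls = n, reps = reps),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat("interval-constrained permutation test (", x$reps, " reps, ",
      x$n_calls, " intergenic calls)\n", sep = "")
  cat("  observed median |distance| =", format(x$observed_median),
      "bp;  P(closer) =", format(x$p, digits = 3), "\n")
  invisible(x)
}
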