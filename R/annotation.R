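#' Gene annotation set
#'
#' Holds gene spans and their child features (exon, intron, CDS, UTR) in
#' 1-based inclusive coordinates. Within each gene, exons and introns tile
#' the gene span and CDS plus UTR segments tile the exons; the intergenic
#' space is the complement of the gene spans.
#'
#' @param genes `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `gene_id`.
#' @param features `data.frame` with columns `chrom`, `start`, `end`,
#'   `type` (`exon`, `intron`, `CDS`, `five_prime_UTR`, `three_prime_UTR`
#'   or `UTR`), `strand`, `gene_id`.
#' @return Object of class `annotation_set`.
#' @export
annotation_set <- function(genes, features) {
  need_g <- c("chrom", "start", "end", "strand", "gene_id")
  need_f <- c("chrom", "start", "end", "type", "strand", "gene_id")
  stopifnot(is.data.frame(genes), all(need_g %in% names(genes)),
            is.data.frame(features), all(need_f %in% names(features)))
  ok_types <- c("exon", "intron", "CDS", "five_prime_UTR", "three_prime_UTR",
                "UTR")
  if (!all(features$type %in% ok_types))
    stop("unknown feature type(s): ",
         paste(setdiff(unique(features$type), ok_types), collapse = ", "))
  genes <- genes[order(genes$chrom, genes$start), need_g]
  features <- features[order(features$chrom, features$start), need_f]
  rownames(genes) <- rownames(features) <- NULL
  structure(list(genes = genes, features = features),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", nrow(x$genes), "genes,",
      nrow(x$features), "child features\n")
  invisible(x)
}

.granges <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                         strand = if (!is.null(df$strand)) df$strand else "*")
}

# UTR feature rows (either split 5'/3' types or a collapsed "UTR" type)
.utr_rows <- function(ann) {
  ann$features[ann$features$type %in%
               c("five_prime_UTR", "three_prime_UTR", "UTR"), , drop = FALSE]
}

#' Read a GFF3 gene annotation
#'
#' Imports gene/exon/intron/CDS/UTR features from a GFF3 file. Features are
#' linked to their gene by the `Parent`/`ID` attributes when present (one
#' transcript level is tolerated), otherwise by containment within the gene
#' span.
#'
#' @param path Path to a GFF3 file.
#' @return An [annotation_set()].
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(gr$type),
                   stringsAsFactors = FALSE)
  df$id <- if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
  par <- if (!is.null(gr$Parent)) {
    vapply(gr$Parent, function(p) if (length(p)) as.character(p[1])
           else NA_character_, character(1))
  } else rep(NA_character_, nrow(df))
  df$parent <- par
  genes <- df[df$type == "gene", , drop = FALSE]
  genes$gene_id <- ifelse(is.na(genes$id),
                          sprintf("gene%05d", seq_len(nrow(genes))), genes$id)
  feats <- df[df$type %in% c("exon", "intron", "CDS", "five_prime_UTR",
                             "three_prime_UTR", "UTR"), , drop = FALSE]
  # resolve Parent chains (feature -> mRNA -> gene) or fall back to overlap
  id2gene <- stats::setNames(genes$gene_id, genes$id)
  up <- stats::setNames(df$parent, df$id)
  resolve <- function(p) {
    for (i in 1:3) {
      if (is.na(p)) return(NA_character_)
      if (p %in% names(id2gene)) return(unname(id2gene[p]))
      p <- if (p %in% names(up)) unname(up[p]) else NA_character_
    }
    NA_character_
  }
  feats$gene_id <- vapply(feats$parent, resolve, character(1))
  if (anyNA(feats$gene_id)) {
    ggr <- .granges(genes)
    fgr <- .granges(feats)
    ov <- GenomicRanges::findOverlaps(fgr, ggr, type = "within", select = "first")
    feats$gene_id[is.na(feats$gene_id)] <- genes$gene_id[ov[is.na(feats$gene_id)]]
  }
  annotation_set(genes[, c("chrom", "start", "end", "strand", "gene_id")],
                 feats[, c("chrom", "start", "end", "type", "strand", "gene_id")])
}

#' Write an annotation set as GFF3
#'
#' @param ann An [annotation_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  g <- ann$genes
  f <- ann$features
  ggr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                                strand = g$strand, type = "gene",
                                ID = g$gene_id)
  # reading frame of each CDS segment, in transcription order per gene
  f$phase <- NA_integer_
  is_cds <- f$type == "CDS"
  for (gid in unique(f$gene_id[is_cds])) {
    i <- which(is_cds & f$gene_id == gid)
    i <- i[order(f$start[i], decreasing = f$strand[i][1] == "-")]
    before <- cumsum(c(0, (f$end[i] - f$start[i] + 1)))[seq_along(i)]
    f$phase[i] <- (3L - before %% 3L) %% 3L
  }
  fgr <- GenomicRanges::GRanges(f$chrom, IRanges::IRanges(f$start, f$end),
                                strand = f$strand, type = f$type,
                                phase = f$phase, Parent = f$gene_id)
  rtracklayer::export(c(ggr, fgr), path, format = "gff3")
  invisible(path)
}

#' Intergenic intervals of an annotated genome
#'
#' The complement of the (merged) gene spans within each chromosome's
#' bounds.
#'
#' @param ann An [annotation_set()].
#' @param layout A [genome_layout()] providing chromosome lengths.
#' @return `data.frame` with columns `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @export
intergenic_intervals <- function(ann, layout) {
  ch <- layout$chromosomes
  out <- lapply(seq_len(nrow(ch)), function(i) {
    cc <- ch$chrom[i]
    g <- ann$genes[ann$genes$chrom == cc, , drop = FALSE]
    full <- IRanges::IRanges(1, ch$length[i])
    gaps <- if (nrow(g)) {
      IRanges::setdiff(full, IRanges::reduce(IRanges::IRanges(g$start, g$end)))
    } else full
    if (length(gaps) == 0) return(NULL)
    data.frame(chrom = cc, start = IRanges::start(gaps),
               end = IRanges::end(gaps), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(chrom = character(), start = numeric(),
                               end = numeric()) else out
}

#' Total feature lengths for length-proportional expectations
#'
#' Computes the total bp covered by each annotation class, optionally
#' restricted to a set of windows (e.g. the 6-Mb sub-telomeric ends), for
#' use as length weights in [gof_test()]. Classes are merged before
#' measuring: `genic` is the union of gene spans, `intergenic` its
#' complement, `exon` the union of exons, `intron` genic minus exon, `UTR`
#' the union of UTR segments and `CDS` the union of CDS segments.
#'
#' @param ann An [annotation_set()].
#' @param layout A [genome_layout()].
#' @param windows Optional `GRanges` (or `data.frame` with `chrom`, `start`,
#'   `end`, 1-based inclusive) restricting the measured space.
#' @param chroms Optional character vector restricting to chromosomes (e.g.
#'   autosomes only).
#' @return Named numeric vector with elements `intergenic`, `genic`, `exon`,
#'   `intron`, `UTR`, `CDS`.
#' @export
feature_lengths <- function(ann, layout, windows = NULL, chroms = NULL) {
  ch <- layout$chromosomes
  if (!is.null(chroms)) ch <- ch[ch$chrom %in% chroms, , drop = FALSE]
  full <- GenomicRanges::GRanges(ch$chrom, IRanges::IRanges(1, ch$length))
  if (!is.null(windows)) {
    if (is.data.frame(windows)) windows <- .granges(windows)
    space <- GenomicRanges::intersect(full, GenomicRanges::reduce(
      windows, ignore.strand = TRUE), ignore.strand = TRUE)
  } else space <- full
  clip <- function(df) {
    df <- df[df$chrom %in% ch$chrom, , drop = FALSE]
    if (nrow(df) == 0)
      return(GenomicRanges::GRanges())
    gr <- GenomicRanges::reduce(.granges(df), ignore.strand = TRUE)
    GenomicRanges::intersect(space, gr, ignore.strand = TRUE)
  }
  genic <- clip(ann$genes)
  exon <- clip(ann$features[ann$features$type == "exon", , drop = FALSE])
  utr <- clip(.utr_rows(ann))
  cds <- clip(ann$features[ann$features$type == "CDS", , drop = FALSE])
  w <- function(gr) sum(as.numeric(GenomicRanges::width(gr)))
  c(intergenic = w(space) - w(genic), genic = w(genic),
    exon = w(exon), intron = w(genic) - w(exon),
    UTR = w(utr), CDS = w(cds))
}
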