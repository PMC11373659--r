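#' Genotype matrix of allele dosages
#'
#' Container for biallelic SNP genotypes coded as alternative-allele dosages
#' (0, 1, 2; `NA` = missing), at ordered sites (1-based bp) across the
#' pedigree individuals.
#'
#' @param sites `data.frame` with columns `chrom`, `pos` (1-based bp).
#' @param geno Integer matrix, one row per site, one named column per
#'   individual; values in `{0, 1, 2, NA}`.
#' @return Object of class `genotype_matrix` (a list with `sites`, `geno`).
#' @export
genotype_matrix <- function(sites, geno) {
  stopifnot(is.data.frame(sites), all(c("chrom", "pos") %in% names(sites)),
            is.matrix(geno), nrow(geno) == nrow(sites))
  if (is.null(colnames(geno))) stop("geno must have individual ids as colnames")
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% 0:2))
    stop("dosages must be 0, 1, 2 or NA (biallelic coding)")
  sites <- data.frame(chrom = as.character(sites$chrom),
                      pos = as.numeric(sites$pos), stringsAsFactors = FALSE)
  o <- order(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  geno <- geno[o, , drop = FALSE]
  rownames(sites) <- NULL
  key <- paste(sites$chrom, sites$pos)
  if (anyDuplicated(key)) stop("duplicate positions within a chromosome")
  structure(list(sites = sites, geno = geno), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$sites), "sites x", ncol(x$geno),
      "individuals on", length(unique(x$sites$chrom)), "sequence(s)\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Read a pedigree genotype table
#'
#' Reads either a VCF-derived GT-FORMAT table (columns `CHROM`, `POS`, then
#' one GT string per individual, e.g. `0/1`, `1|1`, `./.`) or a pre-recoded
#' 012 dosage TSV (same columns with values 0/1/2 and -1 or NA for missing),
#' and recodes to allele dosages. Phased separators are accepted and treated
#' as unphased; phase is re-derived from the pedigree. Non-biallelic GT
#' strings are an error.
#'
#' @param path Path to a tab-separated file with a header line.
#' @param pedigree Optional [pedigree_spec()]; every pedigree individual must
#'   appear in the header.
#' @return A [genotype_matrix()].
#' @export
read_gt_table <- function(path, pedigree = NULL) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 3) stop("genotype table needs CHROM, POS and >=1 individual")
  names(tab)[1:2] <- toupper(names(tab)[1:2])
  if (!all(c("CHROM", "POS") %in% names(tab)[1:2]))
    stop("first two columns must be CHROM and POS")
  ids <- names(tab)[-(1:2)]
  if (!is.null(pedigree)) {
    missing_ids <- setdiff(pedigree$id, ids)
    if (length(missing_ids))
      stop("pedigree individual(s) absent from header: ",
           paste(missing_ids, collapse = ", "))
    ids <- pedigree$id
  }
  raw <- as.matrix(tab[, ids, drop = FALSE])
  geno <- if (any(grepl("[/|]", raw))) .recode_gt(raw) else .recode_012(raw)
  genotype_matrix(data.frame(chrom = tab$CHROM, pos = as.numeric(tab$POS)),
                  geno)
}

# "0/0"->0, "0/1"->1, "1/1"->2, "./."->NA; error on other alleles
.recode_gt <- function(raw) {
  u <- unique(as.vector(raw))
  lut <- vapply(u, function(g) {
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) != 2) stop("malformed GT string: ", g)
    if (all(al == ".")) return(NA_integer_)
    if (!all(al %in% c("0", "1")))
      stop("non-biallelic or malformed GT string: ", g)
    sum(as.integer(al))
  }, integer(1))
  out <- matrix(lut[match(as.vector(raw), u)], nrow = nrow(raw))
  colnames(out) <- colnames(raw)
  out
}

.recode_012 <- function(raw) {
  v <- suppressWarnings(as.integer(as.vector(raw)))
  bad <- !is.na(v) & !(v %in% c(-1L, 0L, 1L, 2L))
  if (any(bad)) stop("012 table values must be -1/0/1/2/NA")
  v[!is.na(v) & v == -1L] <- NA_integer_
  out <- matrix(v, nrow = nrow(raw))
  colnames(out) <- colnames(raw)
  out
}

#' Write a genotype matrix as a 012 dosage TSV
#'
#' Missing dosages are written as -1 (vcftools 012 convention); the file
#' round-trips through [read_gt_table()].
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gt_table <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  g <- gm$geno
  g[is.na(g)] <- -1L
  out <- data.frame(CHROM = gm$sites$chrom, POS = gm$sites$pos, g,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Lift scaffold coordinates onto chromosome coordinates
#'
#' Applies a scaffold order/orientation table: sites on each scaffold are
#' offset by the summed lengths of the scaffolds preceding it on its
#' chromosome (zero-gap concatenation); sites on "-" scaffolds are
#' coordinate-reversed first (`new pos = scaffold_length - old_pos + 1`).
#' Sites are re-sorted by chromosome position.
#'
#' @param gm A [genotype_matrix()] whose `chrom` column holds scaffold names.
#' @param layout A [genome_layout()] whose scaffold table covers all scaffolds
#'   present in `gm`.
#' @return A [genotype_matrix()] in chromosome coordinates.
#' @export
apply_layout <- function(gm, layout) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(layout, "genome_layout"))
  sc <- layout$scaffolds
  m <- match(gm$sites$chrom, sc$scaffold)
  if (anyNA(m))
    stop("scaffold(s) missing from layout: ",
         paste(unique(gm$sites$chrom[is.na(m)]), collapse = ", "))
  pos <- gm$sites$pos
  rev <- sc$orient[m] == "-"
  pos[rev] <- sc$length[m][rev] - pos[rev] + 1
  newpos <- sc$offset[m] + pos
  genotype_matrix(data.frame(chrom = sc$chrom[m], pos = newpos), gm$geno)
}

#' Drop sites falling in repeat intervals
#'
#' @param gm A [genotype_matrix()].
#' @param repeat_bed Either a path to a BED file (0-based half-open) or a
#'   `data.frame` with columns `chrom`, `start`, `end` in BED convention.
#' @return The filtered [genotype_matrix()].
#' @export
mask_repeats <- function(gm, repeat_bed) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.character(repeat_bed)) {
    bed <- rtracklayer::import(repeat_bed, format = "BED")
  } else {
    stopifnot(all(c("chrom", "start", "end") %in% names(repeat_bed)))
    if (nrow(repeat_bed) == 0) return(gm)
    if (any(repeat_bed$end < repeat_bed$start)) stop("malformed BED interval")
    bed <- GenomicRanges::GRanges(
      repeat_bed$chrom,
      IRanges::IRanges(start = repeat_bed$start + 1, end = repeat_bed$end))
  }
  if (length(bed) == 0) return(gm)
  pts <- GenomicRanges::GRanges(gm$sites$chrom,
                                IRanges::IRanges(gm$sites$pos, gm$sites$pos))
  hit <- IRanges::overlapsAny(pts, bed)
  genotype_matrix(gm$sites[!hit, , drop = FALSE],
                  gm$geno[!hit, , drop = FALSE])
}
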