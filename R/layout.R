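#' Genome layout: chromosomes, scaffold order/orientation, arms, Z/PAR
#'
#' Holds the chromosome-level organisation needed to place SNPs and crossover
#' calls: per-chromosome length, an approximate centromere position (or
#' `NA` for telocentric chromosomes, whose centromere sits at the left end),
#' the Z flag with its pseudoautosomal region (PAR), and optionally the
#' order/orientation of the assembly scaffolds making up each chromosome
#' (zero-gap concatenation).
#'
#' @param chromosomes `data.frame` with columns `chrom`, `length` (bp) and
#'   optionally `centromere` (bp or `NA`), `is_z` (logical), `par_start`,
#'   `par_end` (1-based inclusive bp, `NA` when not Z).
#' @param scaffolds Optional `data.frame` with columns `chrom`, `scaffold`,
#'   `length` (bp), `orient` (`"+"` or `"-"`), listed in chromosome order.
#'   When omitted each chromosome is assumed to be a single scaffold named
#'   after itself.
#'
#' @return An object of class `genome_layout`.
#' @examples
#' gl <- genome_layout(data.frame(chrom = "chr1", length = 2e7,
#'                                centromere = 1.2e7))
#' arm_table(gl)
#' @export
genome_layout <- function(chromosomes, scaffolds = NULL) {
  stopifnot(is.data.frame(chromosomes),
            all(c("chrom", "length") %in% names(chromosomes)))
  ch <- chromosomes
  ch$chrom <- as.character(ch$chrom)
  if (anyDuplicated(ch$chrom)) stop("duplicated chromosome names")
  if (any(ch$length <= 0)) stop("chromosome lengths must be positive")
  if (is.null(ch$centromere)) ch$centromere <- NA_real_
  if (is.null(ch$is_z)) ch$is_z <- FALSE
  if (is.null(ch$par_start)) ch$par_start <- NA_real_
  if (is.null(ch$par_end)) ch$par_end <- NA_real_
  ok <- is.na(ch$centromere) | (ch$centromere > 0 & ch$centromere < ch$length)
  if (!all(ok)) stop("centromere positions must lie strictly inside the chromosome")
  if (any(ch$is_z & !is.na(ch$par_start))) {
    z <- ch[ch$is_z & !is.na(ch$par_start), ]
    if (any(z$par_start < 1 | z$par_end > z$length | z$par_start >= z$par_end))
      stop("PAR interval must lie within the Z chromosome")
  }
  if (is.null(scaffolds)) {
    scaffolds <- data.frame(chrom = ch$chrom, scaffold = ch$chrom,
                            length = ch$length, orient = "+",
                            stringsAsFactors = FALSE)
  }
  sc <- scaffolds
  sc$chrom <- as.character(sc$chrom)
  sc$scaffold <- as.character(sc$scaffold)
  if (!all(sc$orient %in% c("+", "-"))) stop("scaffold orient must be '+' or '-'")
  if (anyDuplicated(sc$scaffold)) stop("duplicated scaffold names")
  # zero-gap concatenation offsets, in listed order per chromosome
  sc$offset <- NA_real_
  for (cc in unique(sc$chrom)) {
    i <- which(sc$chrom == cc)
    sc$offset[i] <- cumsum(c(0, sc$length[i][-length(i)]))
    tot <- sum(sc$length[i])
    if (cc %in% ch$chrom && tot != ch$length[ch$chrom == cc])
      stop("scaffold lengths of ", cc, " do not sum to the chromosome length")
  }
  structure(list(chromosomes = ch, scaffolds = sc), class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", nrow(x$chromosomes), "chromosome(s),",
      nrow(x$scaffolds), "scaffold(s)\n")
  print(x$chromosomes)
  invisible(x)
}

#' Chromosome-arm table of a genome layout
#'
#' Splits each chromosome into arms. A chromosome with a centromere yields two
#' arms; the longer is labelled `q`, the shorter `p` (left arm wins ties). A
#' telocentric chromosome is one `q` arm whose centromere sits at the left
#' end, i.e. its telomeric end is the right end. The Z chromosome is split
#' into `PAR` and `nonPAR` segments instead: the PAR is telomeric at the left
#' end and the non-PAR at the right end.
#'
#' The `telomere` column records which physical end of the arm is telomeric
#' (`"left"` = chromosome start side, `"right"` = chromosome end side);
#' telomere distances of crossovers are measured from that end.
#'
#' @param layout A [genome_layout()].
#' @return `data.frame` with columns `chrom`, `arm`, `start`, `end`,
#'   `length`, `telomere`, `is_z`, `zclass` (`"autosome"`, `"PAR"`,
#'   `"nonPAR"`).
#' @export
arm_table <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  ch <- layout$chromosomes
  rows <- lapply(seq_len(nrow(ch)), function(i) {
    L <- ch$length[i]; cen <- ch$centromere[i]
    if (isTRUE(ch$is_z[i]) && !is.na(ch$par_start[i])) {
      ps <- ch$par_start[i]; pe <- ch$par_end[i]
      if (ps != 1) stop("PAR is assumed to occupy the left end of Z")
      return(data.frame(
        chrom = ch$chrom[i], arm = c("PAR", "nonPAR"),
        start = c(ps, pe + 1), end = c(pe, L),
        telomere = c("left", "right"), is_z = TRUE,
        zclass = c("PAR", "nonPAR"), stringsAsFactors = FALSE))
    }
    if (is.na(cen)) {
      return(data.frame(chrom = ch$chrom[i], arm = "q", start = 1, end = L,
                        telomere = "right", is_z = isTRUE(ch$is_z[i]),
                        zclass = if (isTRUE(ch$is_z[i])) "nonPAR" else "autosome",
                        stringsAsFactors = FALSE))
    }
    left_len <- cen; right_len <- L - cen
    labs <- if (left_len >= right_len) c("q", "p") else c("p", "q")
    data.frame(chrom = ch$chrom[i], arm = labs,
               start = c(1, cen + 1), end = c(cen, L),
               telomere = c("left", "right"), is_z = isTRUE(ch$is_z[i]),
               zclass = "autosome", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$length <- out$end - out$start + 1
  out[, c("chrom", "arm", "start", "end", "length", "telomere", "is_z", "zclass")]
}

#' Interior scaffold boundaries in chromosome coordinates
#'
#' @param layout A [genome_layout()].
#' @return `data.frame` with columns `chrom`, `pos`: the junction position
#'   (last bp of the left scaffold) of every interior scaffold join.
#' @export
scaffold_boundaries <- function(layout) {
  sc <- layout$scaffolds
  out <- do.call(rbind, lapply(unique(sc$chrom), function(cc) {
    i <- which(sc$chrom == cc)
    if (length(i) < 2) return(NULL)
    data.frame(chrom = cc, pos = cumsum(sc$length[i])[-length(i)],
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) data.frame(chrom = character(), pos = numeric()) else out
}

# Which arm contains each position (vectorised). Returns arm-table row index.
.arm_index <- function(arms, chrom, pos) {
  idx <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(arms))) {
    hit <- chrom == arms$chrom[i] & pos >= arms$start[i] & pos <= arms$end[i]
    idx[hit] <- i
  }
  idx
}
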