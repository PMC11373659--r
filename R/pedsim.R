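#' Simulation configuration for the pedigree meiosis simulator
#'
#' Defines the study conditions emulated by [simulate_pedigree()]: a small
#' genome of chromosome arms, biallelic SNPs segregating in a 12-individual
#' three-generation pedigree, and sex-specific telomere-biased crossover
#' placement with an obligate chiasma per arm transmitted to each gamete
#' with probability 1/2.
#'
#' Crossover placement law: the distance of a crossover from the telomeric
#' end of its arm, as a fraction of arm length, is drawn from Beta(1, b)
#' with shape `b >= 1`; larger `b` concentrates crossovers nearer the
#' telomere (mean fraction `1/(1+b)`). The default shapes are calibrated so
#' the median proportional telomere distances are 9.29% (paternal,
#' `b = 7.11`) and 13.14% (maternal, `b = 4.92`), reproducing the observed
#' male-biased sub-telomeric crossover placement.
#'
#' @param chromosomes `data.frame` describing the simulated genome, columns
#'   as in [genome_layout()] (`chrom`, `length`, `centromere`, `is_z`,
#'   `par_start`, `par_end`). The default genome has a two-armed 20-Mb
#'   chromosome, a telocentric 15-Mb chromosome and a 10-Mb Z with a 1.1-Mb
#'   PAR at its left end.
#' @param snp_density Expected SNPs per Mb (default 2000).
#' @param shape_paternal,shape_maternal Beta(1, b) telomere-bias shapes for
#'   paternal and maternal meioses (`b >= 1`).
#' @param obligate_co Logical; if `TRUE` (default) every arm receives exactly
#'   one chiasma per meiosis; if `FALSE` the chiasma count per arm is
#'   Poisson(1) (no interference model).
#' @param transmission_prob Probability a chiasma is seen as a crossover in
#'   the transmitted gamete (default 0.5: two of four chromatids carry the
#'   crossover product).
#' @param genotyping_error_rate Per-genotype probability of being flipped to
#'   one of the two other dosage values.
#' @param missing_rate Per-genotype probability of being set missing.
#' @param n_offspring Number of F2 offspring (default 6).
#' @param offspring_sex Optional character vector of offspring sexes
#'   (default five males, one ZW female).
#' @param maf_range Range of the per-site minor-allele fraction among
#'   founder haplotypes, uniform on this interval (default `c(0.1, 0.5)`:
#'   common variants, so a usable fraction of sites is informative).
#' @param gene_fraction Target fraction of sequence covered by genes in the
#'   toy annotation (default 0.4, i.e. ~60% intergenic).
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chromosomes = NULL,
                       snp_density = 2000,
                       shape_paternal = 7.11,
                       shape_maternal = 4.92,
                       obligate_co = TRUE,
                       transmission_prob = 0.5,
                       genotyping_error_rate = 0,
                       missing_rate = 0,
                       n_offspring = 6,
                       offspring_sex = NULL,
                       maf_range = c(0.1, 0.5),
                       gene_fraction = 0.4,
                       seed = NULL) {
  if (is.null(chromosomes)) {
    chromosomes <- data.frame(
      chrom = c("chr1", "chr2", "chrZ"),
      length = c(20e6, 15e6, 10e6),
      centromere = c(12e6, NA, NA),
      is_z = c(FALSE, FALSE, TRUE),
      par_start = c(NA, NA, 1),
      par_end = c(NA, NA, 1.1e6))
  }
  cfg <- list(chromosomes = chromosomes, snp_density = snp_density,
              shape_paternal = shape_paternal, shape_maternal = shape_maternal,
              obligate_co = obligate_co, transmission_prob = transmission_prob,
              genotyping_error_rate = genotyping_error_rate,
              missing_rate = missing_rate, n_offspring = n_offspring,
              offspring_sex = offspring_sex, maf_range = maf_range,
              gene_fraction = gene_fraction, seed = seed)
  rates <- c(transmission_prob, genotyping_error_rate, missing_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  if (shape_paternal < 1 || shape_maternal < 1)
    stop("telomere-bias shapes must be >= 1 (monotone non-increasing density)")
  if (snp_density <= 0) stop("snp_density must be positive")
  if (any(chromosomes$length <= 0)) stop("zero-length chromosome")
  layout <- genome_layout(chromosomes)
  arms <- arm_table(layout)
  n_per_arm <- round(snp_density * arms$length / 1e6)
  if (any(n_per_arm < 2))
    stop("snp_density too low: every arm needs >= 2 SNPs (worst arm would get ",
         min(n_per_arm), ")")
  if (gene_fraction <= 0 || gene_fraction >= 1)
    stop("gene_fraction must be in (0, 1)")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an increasing interval within (0, 0.5]")
  structure(cfg, class = "sim_config")
}

#' Sample crossover distances from the telomeric end of an arm
#'
#' Draws the telomere-distance law used by the simulator: distance from the
#' telomeric end = `arm_length * Beta(1, shape)`.
#'
#' @param n Number of draws.
#' @param shape Beta(1, b) shape, `b >= 1`.
#' @param arm_length Arm length in bp (default 1: return fractions).
#' @return Numeric vector of distances.
#' @export
sample_co_distances <- function(n, shape, arm_length = 1) {
  stopifnot(shape >= 1, arm_length > 0)
  arm_length * stats::rbeta(n, 1, shape)
}

# One meiosis over a set of arms: returns transmitted crossover positions.
# Chiasmata are placed per arm; each appears in the gamete with probability
# transmission_prob at a telomere-biased position.
.draw_cos <- function(armdf, shape, obligate, tp) {
  out <- numeric(0)
  for (i in seq_len(nrow(armdf))) {
    n_chi <- if (obligate) 1L else stats::rpois(1, 1)
    if (n_chi == 0L) next
    keep <- stats::runif(n_chi) < tp
    if (!any(keep)) next
    d <- sample_co_distances(sum(keep), shape, armdf$length[i])
    pos <- if (armdf$telomere[i] == "left") armdf$start[i] + d
           else armdf$end[i] - d
    # keep strictly inside the arm so flanking markers exist on both sides
    pos <- pmin(pmax(round(pos), armdf$start[i] + 1), armdf$end[i] - 1)
    out <- c(out, pos)
  }
  sort(out)
}

# Assemble a gamete haplotype from two parental haplotypes and CO positions:
# sites at pos >= co switch haplotype at each crossover.
.gamete <- function(h1, h2, pos, cos, start = sample.int(2L, 1L)) {
  k <- if (length(cos)) findInterval(pos, cos) else integer(length(pos))
  idx <- ifelse(k %% 2L == 0L, start, 3L - start)
  ifelse(idx == 1L, h1, h2)
}

.dosage <- function(a, b) {
  ifelse(is.na(a), 2L * b, ifelse(is.na(b), 2L * a, a + b))
}

#' Simulate a genotyped three-generation pedigree with known crossovers
#'
#' Simulates founder haplotypes (independent sites, minor-allele fraction
#' uniform on \[0.1, 0.5\]), transmits them through the pedigree with
#' sex-specific telomere-biased meioses, and returns 012 dosage genotypes for
#' the 12 (or `6 + n_offspring`) individuals together with the ground-truth
#' crossovers of every F1 meiosis and a toy gene annotation.
#'
#' Z-chromosome handling: females carry one Z and one W; the W carries
#' alleles only inside the PAR. Hemizygous (non-PAR) female genotypes are
#' coded homozygous for the single Z allele, as a diploid variant caller
#' would report them. Maternal meioses recombine only inside the PAR (Z-W
#' pairing); paternal meioses treat Z as a single arm whose telomeric end is
#' the non-PAR (right) end, keeping paternal crossovers out of the short PAR.
#'
#' F0 to F1 transmission passes one founder haplotype per chromosome without
#' recombination; grandparent-of-origin labels downstream are unaffected by
#' recombination in the grandparental germ line, so this loses no generality
#' for crossover detection in the F1 meioses.
#'
#' @param config A [sim_config()].
#' @return A list of class `pedcross_sim` with elements `genotypes`
#'   ([genotype_matrix()]), `truth` (`data.frame`: `offspring`, `side`,
#'   `chrom`, `arm`, `pos`), `annotation` ([annotation_set()]), `layout`
#'   ([genome_layout()]), `pedigree` ([pedigree_spec()]) and `config`.
#' @examples
#' sim <- simulate_pedigree(sim_config(
#'   chromosomes = data.frame(chrom = "a1", length = 2e6),
#'   snp_density = 300, seed = 1))
#' dim(sim$genotypes)
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  layout <- genome_layout(config$chromosomes)
  arms <- arm_table(layout)
  ped <- default_pedigree(config$n_offspring, config$offspring_sex)
  offs <- ped_offspring(ped)
  n_off <- length(offs)
  ids <- ped$id

  truth <- list()
  site_list <- list()
  geno_list <- list()

  for (ci in seq_len(nrow(layout$chromosomes))) {
    cc <- layout$chromosomes$chrom[ci]
    L <- layout$chromosomes$length[ci]
    is_z <- isTRUE(layout$chromosomes$is_z[ci])
    carms <- arms[arms$chrom == cc, , drop = FALSE]
    par_end <- if (is_z) layout$chromosomes$par_end[ci] else NA_real_

    # sites: fixed expected count per arm, positions uniform without ties
    pos <- sort(unlist(lapply(seq_len(nrow(carms)), function(i) {
      n_i <- round(config$snp_density * carms$length[i] / 1e6)
      carms$start[i] - 1 + sample.int(carms$length[i], n_i)
    })))
    pos <- unique(pos)
    n <- length(pos)
    maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])

    # founder haplotypes: columns PGF1 PGF2 PGM1 PGM2 MGF1 MGF2 MGM1 MGM2
    H <- matrix(stats::rbinom(n * 8L, 1L, maf), nrow = n, ncol = 8L)
    if (is_z) {
      w <- pos > par_end            # W chromosome carries no non-PAR alleles
      H[w, 4L] <- NA_integer_       # PGM hap2 = W
      H[w, 8L] <- NA_integer_       # MGM hap2 = W
    }

    # F1 haplotypes (no F0 recombination; labels are by grandparent anyway).
    # Father is male: receives Z (never W) from his mother -> PGM hap1.
    fa_p <- H[, sample.int(2L, 1L)]                      # from PGF
    fa_m <- if (is_z) H[, 3L] else H[, 2L + sample.int(2L, 1L)]  # from PGM
    mo_p <- H[, 4L + sample.int(2L, 1L)]                 # from MGF (Z in ZW)
    mo_m <- if (is_z) H[, 8L] else H[, 6L + sample.int(2L, 1L)]  # from MGM (W)

    G <- matrix(NA_integer_, nrow = n, ncol = length(ids),
                dimnames = list(NULL, ids))
    G[, "PGF"] <- .dosage(H[, 1L], H[, 2L])
    G[, "PGM"] <- .dosage(H[, 3L], H[, 4L])
    G[, "MGF"] <- .dosage(H[, 5L], H[, 6L])
    G[, "MGM"] <- .dosage(H[, 7L], H[, 8L])
    G[, "FA"]  <- .dosage(fa_p, fa_m)
    G[, "MO"]  <- .dosage(mo_p, mo_m)

    # arm sets for crossover placement
    pat_arms <- if (is_z) {
      data.frame(start = 1, end = L, length = L, telomere = "right",
                 stringsAsFactors = FALSE)
    } else carms
    mat_arms <- if (is_z) {
      data.frame(start = 1, end = par_end, length = par_end,
                 telomere = "left", stringsAsFactors = FALSE)
    } else carms

    for (oi in seq_along(offs)) {
      osx <- ped_sex(ped, offs[oi])

      cos_p <- .draw_cos(pat_arms, config$shape_paternal,
                         config$obligate_co, config$transmission_prob)
      gam_p <- .gamete(fa_p, fa_m, pos, cos_p)
      if (length(cos_p))
        truth[[length(truth) + 1L]] <- data.frame(
          offspring = offs[oi], side = "paternal", chrom = cc, pos = cos_p,
          stringsAsFactors = FALSE)

      cos_m <- .draw_cos(mat_arms, config$shape_maternal,
                         config$obligate_co, config$transmission_prob)
      if (is_z) {
        # son receives the Z (mo_p), daughter the W (mo_m); a PAR crossover
        # swaps the telomere-side PAR segment with the other sex chromosome
        base  <- if (osx == "M") mo_p else mo_m
        other <- if (osx == "M") mo_m else mo_p
        gam_m <- base
        if (length(cos_m)) {
          # centromere side must stay on the transmitted sex chromosome, so
          # segment parity is counted from the right (non-PAR) end
          k2 <- length(cos_m) - findInterval(pos, cos_m)
          swap <- k2 %% 2L == 1L
          gam_m[swap] <- other[swap]
        }
      } else {
        gam_m <- .gamete(mo_p, mo_m, pos, cos_m)
      }
      if (length(cos_m))
        truth[[length(truth) + 1L]] <- data.frame(
          offspring = offs[oi], side = "maternal", chrom = cc, pos = cos_m,
          stringsAsFactors = FALSE)

      G[, offs[oi]] <- .dosage(gam_p, gam_m)
    }

    site_list[[ci]] <- data.frame(chrom = cc, pos = pos,
                                  stringsAsFactors = FALSE)
    geno_list[[ci]] <- G
  }

  sites <- do.call(rbind, site_list)
  geno <- do.call(rbind, geno_list)

  # genotyping error: flip to one of the two other dosages
  if (config$genotyping_error_rate > 0) {
    flip <- which(stats::runif(length(geno)) < config$genotyping_error_rate &
                  !is.na(geno))
    if (length(flip))
      geno[flip] <- (geno[flip] +
                     sample(c(1L, 2L), length(flip), replace = TRUE)) %% 3L
  }
  if (config$missing_rate > 0) {
    geno[stats::runif(length(geno)) < config$missing_rate] <- NA_integer_
  }

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(offspring = character(), side = character(),
               chrom = character(), pos = numeric(), stringsAsFactors = FALSE)
  truth$arm <- if (nrow(truth)) arms$arm[.arm_index(arms, truth$chrom, truth$pos)]
               else character(0)
  truth <- truth[, c("offspring", "side", "chrom", "arm", "pos")]
  rownames(truth) <- NULL

  ann <- simulate_annotation(layout, gene_fraction = config$gene_fraction)

  structure(list(genotypes = genotype_matrix(sites, geno),
                 truth = truth, annotation = ann, layout = layout,
                 pedigree = ped, config = config),
            class = "pedcross_sim")
}

#' @export
print.pedcross_sim <- function(x, ...) {
  cat("pedcross_sim:", nrow(x$genotypes$sites), "sites,",
      nrow(x$truth), "truth crossovers,",
      nrow(x$annotation$genes), "genes\n")
  invisible(x)
}

#' Simulate a toy gene annotation over a genome layout
#'
#' Tiles each chromosome with non-overlapping multi-exon genes of random
#' strand until the target genic fraction is reached. Every gene has 3-7
#' exons separated by introns; the first and last exons carry 5' and 3' UTR
#' segments (strand-aware) with the remainder CDS, so exons+introns tile the
#' gene and UTR+CDS tile the exons.
#'
#' @param layout A [genome_layout()].
#' @param gene_fraction Target genic fraction of the sequence (default 0.4).
#' @return An [annotation_set()].
#' @export
simulate_annotation <- function(layout, gene_fraction = 0.4) {
  stopifnot(inherits(layout, "genome_layout"),
            gene_fraction > 0, gene_fraction < 1)
  genes <- list(); feats <- list()
  for (ci in seq_len(nrow(layout$chromosomes))) {
    cc <- layout$chromosomes$chrom[ci]
    L <- layout$chromosomes$length[ci]
    mean_gene <- 8250   # 5 exons of ~250 bp + 4 introns of ~1750 bp
    mean_gap <- mean_gene * (1 - gene_fraction) / gene_fraction
    x <- 0; k <- 0
    repeat {
      gap <- 200 + round(stats::rexp(1, 1 / mean_gap))
      n_ex <- sample(3:7, 1)
      ex_len <- round(stats::runif(n_ex, 100, 400))
      in_len <- round(stats::runif(n_ex - 1, 500, 3000))
      glen <- sum(ex_len) + sum(in_len)
      gstart <- x + gap + 1
      gend <- gstart + glen - 1
      if (gend > L - 200) break
      k <- k + 1
      gid <- sprintf("%s_g%04d", cc, k)
      strand <- sample(c("+", "-"), 1)
      # exon/intron tiling left to right
      seg_len <- as.vector(rbind(ex_len, c(in_len, 0)))[seq_len(2 * n_ex - 1)]
      starts <- gstart + cumsum(c(0, seg_len[-length(seg_len)]))
      ex_start <- starts[seq(1, 2 * n_ex - 1, by = 2)]
      ex_end <- ex_start + ex_len - 1
      in_start <- ex_end[-n_ex] + 1
      in_end <- ex_start[-1] - 1
      # 5' UTR sits in the transcription-start exon, 3' UTR in the last one
      ex5 <- if (strand == "+") 1 else n_ex
      ex3 <- if (strand == "+") n_ex else 1
      u5 <- min(150, ex_len[ex5] - 50)
      u3 <- min(250, ex_len[ex3] - 50)
      cds <- data.frame(start = ex_start, end = ex_end)
      if (strand == "+") {
        utr5 <- c(ex_start[1], ex_start[1] + u5 - 1)
        utr3 <- c(ex_end[n_ex] - u3 + 1, ex_end[n_ex])
        cds$start[1] <- cds$start[1] + u5
        cds$end[n_ex] <- cds$end[n_ex] - u3
      } else {  # transcription right-to-left
        utr5 <- c(ex_end[n_ex] - u5 + 1, ex_end[n_ex])
        utr3 <- c(ex_start[1], ex_start[1] + u3 - 1)
        cds$end[n_ex] <- cds$end[n_ex] - u5
        cds$start[1] <- cds$start[1] + u3
      }
      genes[[length(genes) + 1L]] <- data.frame(
        chrom = cc, start = gstart, end = gend, strand = strand, gene_id = gid,
        stringsAsFactors = FALSE)
      f <- rbind(
        data.frame(chrom = cc, start = ex_start, end = ex_end, type = "exon",
                   stringsAsFactors = FALSE),
        if (n_ex > 1) data.frame(chrom = cc, start = in_start, end = in_end,
                                 type = "intron", stringsAsFactors = FALSE),
        data.frame(chrom = cc, start = cds$start, end = cds$end, type = "CDS",
                   stringsAsFactors = FALSE),
        data.frame(chrom = cc, start = utr5[1], end = utr5[2],
                   type = "five_prime_UTR", stringsAsFactors = FALSE),
        data.frame(chrom = cc, start = utr3[1], end = utr3[2],
                   type = "three_prime_UTR", stringsAsFactors = FALSE))
      f$strand <- strand; f$gene_id <- gid
      feats[[length(feats) + 1L]] <- f
      x <- gend
    }
  }
  annotation_set(do.call(rbind, genes), do.call(rbind, feats))
}

#' Write ground-truth crossovers to TSV
#' @param truth Truth `data.frame` from [simulate_pedigree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ground-truth crossover TSV written by [write_truth()]
#' @param path Input path.
#' @return Truth `data.frame`.
#' @export
read_truth <- function(path) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(offspring = "character", side = "character",
                                   chrom = "character", arm = "character",
                                   pos = "numeric"))
}
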