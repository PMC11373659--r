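#' Per-arm sex-specific recombination map
#'
#' Aggregates crossover calls into per-arm counts and recombination
#' distances/rates. The recombination distance of an arm is
#' `cM = 100 * crossovers / meioses`; rates divide by arm length in Mb
#' (1 Mb = 1e6 bp exactly). Autosomal arms (and the PAR, where both sexes
#' recombine) count `n` paternal and `n` maternal meioses for `n` offspring
#' (`2n` sex-averaged); the Z non-PAR recombines only through the father and
#' counts `n` paternal meioses.
#'
#' Artifact-flagged calls are excluded by default, mirroring the manual
#' curation of scaffold-border artifacts.
#'
#' @param calls A `crossover_calls` data frame with arms assigned.
#' @param layout A [genome_layout()].
#' @param pedigree A [pedigree_spec()] (supplies the offspring count).
#' @param exclude_flagged Drop artifact-flagged calls (default `TRUE`).
#' @return `data.frame` of class `arm_recmap`: one row per arm with columns
#'   `chrom`, `arm`, `zclass`, `length_mb`, `meioses_total`,
#'   `meioses_paternal`, `meioses_maternal`, `n_co`, `n_co_paternal`,
#'   `n_co_maternal`, `cm_avg`, `cm_paternal`, `cm_maternal`, `rate_avg`,
#'   `rate_paternal`, `rate_maternal`.
#' @export
build_recmap <- function(calls, layout, pedigree, exclude_flagged = TRUE) {
  stopifnot(inherits(layout, "genome_layout"),
            inherits(pedigree, "pedigree_spec"))
  if (exclude_flagged && nrow(calls)) calls <- calls[!calls$artifact, ]
  arms <- arm_table(layout)
  n_off <- length(ped_offspring(pedigree))
  if (nrow(calls)) {
    akey <- paste(calls$chrom, calls$arm)
    bad <- !(akey %in% paste(arms$chrom, arms$arm))
    if (any(bad))
      stop("call(s) on arm absent from layout: ",
           paste(unique(akey[bad]), collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(arms)), function(i) {
    sel <- if (nrow(calls)) calls$chrom == arms$chrom[i] &
             calls$arm == arms$arm[i] else logical(0)
    n_pat <- sum(sel & calls$side == "paternal")
    n_mat <- sum(sel & calls$side == "maternal")
    m_pat <- n_off
    m_mat <- if (arms$zclass[i] == "nonPAR") 0L else n_off
    len_mb <- arms$length[i] / 1e6
    cm_p <- 100 * n_pat / m_pat
    cm_m <- if (m_mat > 0) 100 * n_mat / m_mat else NA_real_
    cm_a <- 100 * (n_pat + n_mat) / (m_pat + m_mat)
    data.frame(chrom = arms$chrom[i], arm = arms$arm[i],
               zclass = arms$zclass[i], length_mb = len_mb,
               meioses_total = m_pat + m_mat, meioses_paternal = m_pat,
               meioses_maternal = m_mat,
               n_co = n_pat + n_mat, n_co_paternal = n_pat,
               n_co_maternal = n_mat,
               cm_avg = cm_a, cm_paternal = cm_p, cm_maternal = cm_m,
               rate_avg = cm_a / len_mb, rate_paternal = cm_p / len_mb,
               rate_maternal = if (is.na(cm_m)) NA_real_ else cm_m / len_mb,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("arm_recmap", "data.frame")
  out
}

#' Telomere distances of crossover calls
#'
#' For every call, the physical distance (bp) of its point estimate from the
#' telomeric end of its arm and the proportional distance (fraction of arm
#' length, in \[0, 1\]). The telomeric end of a left arm is the chromosome
#' start; of a right arm (and of a telocentric chromosome) the chromosome
#' end.
#'
#' @param calls A `crossover_calls` data frame.
#' @param layout A [genome_layout()].
#' @return `calls` with added columns `telo_dist` (bp) and `telo_prop`.
#' @export
arm_distance_metrics <- function(calls, layout) {
  arms <- arm_table(layout)
  if (nrow(calls) == 0) {
    calls$telo_dist <- numeric(0); calls$telo_prop <- numeric(0)
    return(calls)
  }
  i <- match(paste(calls$chrom, calls$arm), paste(arms$chrom, arms$arm))
  if (anyNA(i)) stop("call(s) without a valid arm assignment")
  d <- ifelse(arms$telomere[i] == "left",
              calls$point - arms$start[i],
              arms$end[i] - calls$point)
  calls$telo_dist <- d
  calls$telo_prop <- d / arms$length[i]
  calls
}

#' Locate candidate centromeres from nucleotide-diversity deserts
#'
#' Centromeric regions are expected to show extremely low nucleotide
#' diversity. This computes windowed mean pairwise diversity from the
#' pedigree dosages (per-site unbiased heterozygosity summed per window and
#' divided by window bp) and reports, per chromosome, the longest contiguous
#' run of windows below the given quantile of that chromosome's window
#' diversities. Confidence is assessed by permuting window order: if the
#' observed run is no longer than the 95th percentile of maximal runs in
#' permuted orders the candidate is flagged `"low"`; a monomorphic (or
#' constant-diversity) chromosome is flagged `"degenerate"` and returns the
#' whole chromosome.
#'
#' @param gm A [genotype_matrix()].
#' @param layout A [genome_layout()].
#' @param window Window size in bp (default 500 kb).
#' @param quantile Diversity quantile defining "low" windows (default 0.1).
#' @param n_perm Permutations for the run-length null (default 199).
#' @return `data.frame` with columns `chrom`, `start`, `end`, `n_windows`,
#'   `confidence` (`"ok"`, `"low"`, `"degenerate"`).
#' @export
locate_centromere <- function(gm, layout, window = 5e5, quantile = 0.1,
                              n_perm = 199) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(layout, "genome_layout"))
  ch <- layout$chromosomes
  out <- lapply(seq_len(nrow(ch)), function(ci) {
    cc <- ch$chrom[ci]; L <- ch$length[ci]
    if (L < window) stop("chromosome ", cc, " is shorter than one window")
    sel <- gm$sites$chrom == cc
    pos <- gm$sites$pos[sel]
    g <- gm$geno[sel, , drop = FALSE]
    # per-site pairwise diversity: 2c(2n-c)/(2n(2n-1)) with c = alt count
    n_al <- 2 * rowSums(!is.na(g))
    c_al <- rowSums(g, na.rm = TRUE)
    pi_site <- ifelse(n_al > 1, 2 * c_al * (n_al - c_al) / (n_al * (n_al - 1)),
                      0)
    brk <- seq(0, ceiling(L / window) * window, by = window)
    wi <- findInterval(pos, brk, left.open = TRUE)
    n_win <- length(brk) - 1
    div <- as.numeric(tapply(pi_site, factor(wi, levels = seq_len(n_win)),
                             sum))
    div[is.na(div)] <- 0
    div <- div / window
    if (length(unique(div)) == 1) {
      return(data.frame(chrom = cc, start = 1, end = L, n_windows = n_win,
                        confidence = "degenerate", stringsAsFactors = FALSE))
    }
    thr <- stats::quantile(div, quantile, names = FALSE)
    low <- div <= thr
    run <- function(x) {
      r <- rle(x)
      if (!any(r$values)) return(c(0L, 0L))
      j <- which.max(r$lengths * r$values)
      to <- cumsum(r$lengths)[j]
      c(r$lengths[j], to)
    }
    obs <- run(low)
    null_max <- vapply(seq_len(n_perm), function(k)
      run(sample(low))[1], numeric(1))
    conf <- if (obs[1] > stats::quantile(null_max, 0.95, names = FALSE))
      "ok" else "low"
    w_to <- obs[2]; w_from <- w_to - obs[1] + 1
    data.frame(chrom = cc, start = brk[w_from] + 1,
               end = min(brk[w_to + 1], L), n_windows = n_win,
               confidence = conf, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fraction of segregating arms carrying at least one crossover
#'
#' Each autosomal arm segregates once per parental meiosis per offspring
#' (`2 * n_arms * n_offspring` segregating arm copies in total); under one
#' obligate chiasma per arm and 50% chromatid transmission about half of
#' them are expected to carry a crossover.
#'
#' @param calls A `crossover_calls` data frame (artifact-flagged calls are
#'   excluded).
#' @param layout A [genome_layout()].
#' @param pedigree A [pedigree_spec()].
#' @return A list with `n_with_co`, `n_segregating`, `fraction`.
#' @export
arms_with_co_fraction <- function(calls, layout, pedigree) {
  arms <- arm_table(layout)
  aut <- arms[arms$zclass == "autosome", , drop = FALSE]
  n_off <- length(ped_offspring(pedigree))
  n_seg <- 2L * nrow(aut) * n_off
  used <- calls[!calls$artifact & paste(calls$chrom, calls$arm) %in%
                paste(aut$chrom, aut$arm), , drop = FALSE]
  n_with <- length(unique(paste(used$offspring, used$side, used$chrom,
                                used$arm)))
  list(n_with_co = n_with, n_segregating = n_seg,
       fraction = n_with / n_seg)
}
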