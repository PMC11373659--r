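# Feasible allele set of a diploid genotype dosage: 0 -> {0}, 1 -> {0,1},
# 2 -> {1}. Hemizygous females on the Z are coded homozygous, so their set
# is the single allele they actually carry.
.allele_set <- function(g) switch(g + 1L, 0L, c(0L, 1L), 1L)

#' Decompose an offspring genotype into parental alleles
#'
#' For a trio of dosages (offspring, father, mother) at a biallelic site,
#' finds the decomposition `g_off = a_pat + a_mat` with the paternal allele
#' consistent with the father's genotype and the maternal allele with the
#' mother's. When both parents and the offspring are heterozygous two
#' decompositions fit and the site is `ambiguous`; when none fits the site
#' is a Mendelian `inconsistent`.
#'
#' @param g_off,g_fa,g_mo Dosages in `{0, 1, 2}` (scalars).
#' @return A list with `status` (`"ok"`, `"ambiguous"`, `"inconsistent"`)
#'   and, when `"ok"`, integer `paternal` and `maternal` alleles.
#' @examples
#' split_trio_alleles(2, 2, 2)  # forced (1, 1)
#' split_trio_alleles(1, 1, 1)  # ambiguous
#' @export
split_trio_alleles <- function(g_off, g_fa, g_mo) {
  stopifnot(g_off %in% 0:2, g_fa %in% 0:2, g_mo %in% 0:2)
  pairs <- expand.grid(p = .allele_set(g_fa), m = .allele_set(g_mo))
  pairs <- pairs[pairs$p + pairs$m == g_off, , drop = FALSE]
  pairs <- unique(pairs)
  if (nrow(pairs) == 0) return(list(status = "inconsistent"))
  if (nrow(pairs) > 1) return(list(status = "ambiguous"))
  list(status = "ok", paternal = pairs$p[1], maternal = pairs$m[1])
}

#' Assign a transmitted parental allele to its grandparent of origin
#'
#' A site is informative for one parental side when that parent is
#' heterozygous and the decomposition of the parent's two alleles onto its
#' own parents (the grandparents) is unique; the grandparental source of the
#' transmitted allele then follows. Homozygous parents, and grandparental
#' configurations admitting both decompositions (e.g. both grandparents
#' heterozygous), are uninformative.
#'
#' @param allele The allele (0 or 1) the parent transmitted, as resolved by
#'   [split_trio_alleles()].
#' @param g_parent Parent dosage.
#' @param g_gf,g_gm Dosages of the parent's father and mother.
#' @return One of `"grandfather"`, `"grandmother"`, `"uninformative"`,
#'   `"inconsistent"`.
#' @export
assign_grandparent <- function(allele, g_parent, g_gf, g_gm) {
  stopifnot(allele %in% 0:1, g_parent %in% 0:2, g_gf %in% 0:2, g_gm %in% 0:2)
  if (g_parent != 1L) return("uninformative")
  # parent carries alleles {0, 1}: either 0 from grandfather and 1 from
  # grandmother, or the reverse
  gf_set <- .allele_set(g_gf); gm_set <- .allele_set(g_gm)
  p01 <- (0L %in% gf_set) && (1L %in% gm_set)
  p10 <- (1L %in% gf_set) && (0L %in% gm_set)
  if (p01 && p10) return("uninformative")
  if (!p01 && !p10) return("inconsistent")
  from_gf <- if (p01) 0L else 1L
  if (allele == from_gf) "grandfather" else "grandmother"
}

# Composite per-site origin call for one parental side, over dosage tuples
# (g_off, g_parent, g_other_parent, g_gf, g_gm). Precomputed as a lookup
# table over all 3^5 dosage combinations.
.origin_code <- function(g_off, g_par, g_oth, g_gf, g_gm, side) {
  tr <- split_trio_alleles(g_off,
                           if (side == "paternal") g_par else g_oth,
                           if (side == "paternal") g_oth else g_par)
  if (tr$status == "inconsistent") return("mendel_inconsistent")
  if (tr$status == "ambiguous") return("ambiguous")
  a <- if (side == "paternal") tr$paternal else tr$maternal
  res <- assign_grandparent(a, g_par, g_gf, g_gm)
  switch(res, grandfather = "GF", grandmother = "GM",
         uninformative = "uninformative", inconsistent = "gp_inconsistent")
}

.origin_lut_cache <- new.env(parent = emptyenv())

.origin_lut <- function(side) {
  key <- side
  if (!is.null(.origin_lut_cache[[key]])) return(.origin_lut_cache[[key]])
  lut <- array(NA_character_, dim = rep(3L, 5L))
  for (go in 0:2) for (gp in 0:2) for (gq in 0:2) for (gf in 0:2)
    for (gm in 0:2)
      lut[go + 1L, gp + 1L, gq + 1L, gf + 1L, gm + 1L] <-
        .origin_code(go, gp, gq, gf, gm, side)
  .origin_lut_cache[[key]] <- lut
  lut
}

# Hemizygous-offspring paternal lookup (female offspring, Z outside PAR):
# the single Z allele comes from the father; dosage is coded 0 or 2.
.origin_lut_hemi <- function() {
  key <- "hemi"
  if (!is.null(.origin_lut_cache[[key]])) return(.origin_lut_cache[[key]])
  lut <- array(NA_character_, dim = rep(3L, 4L))
  for (go in 0:2) for (gp in 0:2) for (gf in 0:2) for (gm in 0:2) {
    lut[go + 1L, gp + 1L, gf + 1L, gm + 1L] <-
      if (go == 1L) "mendel_inconsistent" else {
        a <- go %/% 2L
        if (!(a %in% .allele_set(gp))) "mendel_inconsistent" else
          switch(assign_grandparent(a, gp, gf, gm),
                 grandfather = "GF", grandmother = "GM",
                 uninformative = "uninformative",
                 inconsistent = "gp_inconsistent")
      }
  }
  .origin_lut_cache[[key]] <- lut
  lut
}

#' Build grandparent-of-origin series for every offspring
#'
#' For each offspring, parental side and chromosome, labels every
#' informative site with the grandparent that contributed the transmitted
#' allele. Sites that are missing in any pedigree member involved,
#' ambiguous (all-heterozygous trio), uninformative, or Mendelian
#' inconsistent are excluded; exclusion counts are tallied per offspring and
#' side in the `exclusions` attribute.
#'
#' Z-chromosome handling (when `layout` marks a Z with a PAR): maternal
#' series are built only inside the PAR, where the Z and W recombine; the
#' non-PAR maternal Z is transmitted clonally and carries no crossover
#' signal. Paternal series span the whole Z; for hemizygously coded (ZW)
#' female offspring the single non-PAR allele is taken as paternal directly.
#'
#' @param gm A [genotype_matrix()] in chromosome coordinates.
#' @param pedigree A [pedigree_spec()] whose ids are columns of `gm`.
#' @param layout Optional [genome_layout()]; required for Z-aware handling.
#' @return `data.frame` of class `origin_series` with columns `offspring`,
#'   `side`, `chrom`, `pos`, `origin` (`"GF"`/`"GM"`), sorted by position
#'   within series, plus attribute `exclusions`.
#' @export
build_origin_series <- function(gm, pedigree, layout = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(pedigree, "pedigree_spec"))
  if (!all(pedigree$id %in% colnames(gm$geno)))
    stop("pedigree individual(s) missing from the genotype matrix")
  g <- gm$geno
  fa <- g[, ped_role(pedigree, "father")]
  mo <- g[, ped_role(pedigree, "mother")]
  pgf <- g[, ped_role(pedigree, "paternal_grandfather")]
  pgm <- g[, ped_role(pedigree, "paternal_grandmother")]
  mgf <- g[, ped_role(pedigree, "maternal_grandfather")]
  mgm <- g[, ped_role(pedigree, "maternal_grandmother")]
  chrom <- gm$sites$chrom
  pos <- gm$sites$pos

  z_nonpar <- rep(FALSE, length(pos))
  if (!is.null(layout)) {
    ch <- layout$chromosomes
    for (i in which(ch$is_z)) {
      on_z <- chrom == ch$chrom[i]
      inside_par <- !is.na(ch$par_start[i]) & pos >= ch$par_start[i] &
        pos <= ch$par_end[i]
      z_nonpar <- z_nonpar | (on_z & !inside_par)
    }
  }

  lut_p <- .origin_lut("paternal")
  lut_m <- .origin_lut("maternal")
  lut_h <- .origin_lut_hemi()
  excl_classes <- c("missing", "ambiguous", "uninformative",
                    "mendel_inconsistent", "gp_inconsistent")

  series <- list()
  excl <- list()
  for (off in ped_offspring(pedigree)) {
    go <- g[, off]
    osx <- ped_sex(pedigree, off)
    for (side in c("paternal", "maternal")) {
      use <- rep(TRUE, length(pos))
      if (side == "maternal") use <- use & !z_nonpar
      par_gp <- if (side == "paternal") cbind(pgf, pgm) else cbind(mgf, mgm)
      gpar <- if (side == "paternal") fa else mo
      code <- rep("missing", length(pos))
      cmpl <- use & !is.na(go) & !is.na(fa) & !is.na(mo) &
        !is.na(par_gp[, 1]) & !is.na(par_gp[, 2])
      hemi <- side == "paternal" & osx == "F" & z_nonpar
      norm <- cmpl & !hemi
      if (any(norm)) {
        lut <- if (side == "paternal") lut_p else lut_m
        oth <- if (side == "paternal") mo else fa
        code[norm] <- lut[cbind(go[norm] + 1L, gpar[norm] + 1L,
                                oth[norm] + 1L, par_gp[norm, 1] + 1L,
                                par_gp[norm, 2] + 1L)]
      }
      # hemizygous coding: mother's genotype is irrelevant on the non-PAR Z
      hm <- (use & hemi & !is.na(go) & !is.na(fa) &
             !is.na(par_gp[, 1]) & !is.na(par_gp[, 2]))
      if (any(hm)) {
        code[hm] <- lut_h[cbind(go[hm] + 1L, fa[hm] + 1L,
                                par_gp[hm, 1] + 1L, par_gp[hm, 2] + 1L)]
      }
      keep <- use & code %in% c("GF", "GM")
      if (any(keep)) {
        series[[length(series) + 1L]] <- data.frame(
          offspring = off, side = side, chrom = chrom[keep], pos = pos[keep],
          origin = code[keep], stringsAsFactors = FALSE)
      }
      cnt <- table(factor(code[use & !(code %in% c("GF", "GM"))],
                          levels = excl_classes))
      excl[[length(excl) + 1L]] <- data.frame(
        offspring = off, side = side, class = excl_classes,
        n = as.integer(cnt), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(series)) do.call(rbind, series) else
    data.frame(offspring = character(), side = character(),
               chrom = character(), pos = numeric(), origin = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$offspring, out$side, out$chrom, out$pos), ]
  rownames(out) <- NULL
  attr(out, "exclusions") <- do.call(rbind, excl)
  class(out) <- c("origin_series", "data.frame")
  out
}

#' Write origin series to TSV
#' @param series An `origin_series` from [build_origin_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_origin_series <- function(series, path) {
  utils::write.table(series, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
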