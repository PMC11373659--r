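mk_call <- function(off, side, chrom, arm, point) data.frame(
  offspring = off, side = side, chrom = chrom, arm = arm,
  left = point - 500, right = point + 500, point = point, precision = 1000,
  transition = "GF>GM", spans_centromere = FALSE, artifact = FALSE,
  stringsAsFactors = FALSE)

test_that("recombination distances and rates follow the cM arithmetic", {
  lay <- genome_layout(data.frame(chrom = "c1", length = 2e6))
  ped <- default_pedigree(6)
  calls <- rbind(mk_call("O1", "paternal", "c1", "q", 1e5),
                 mk_call("O2", "paternal", "c1", "q", 2e5),
                 mk_call("O3", "paternal", "c1", "q", 3e5),
                 mk_call("O1", "maternal", "c1", "q", 4e5),
                 mk_call("O4", "maternal", "c1", "q", 5e5))
  rm <- build_recmap(calls, lay, ped)
  expect_equal(rm$n_co, 5)
  expect_equal(rm$cm_paternal, 100 * 3 / 6)
  expect_equal(rm$cm_maternal, 100 * 2 / 6)
  expect_equal(rm$cm_avg, 100 * 5 / 12)
  expect_equal(rm$rate_avg, rm$cm_avg / 2)
  # artifact-flagged calls are excluded by default
  calls$artifact[1] <- TRUE
  expect_equal(build_recmap(calls, lay, ped)$n_co_paternal, 2)
  expect_equal(build_recmap(calls, lay, ped, exclude_flagged = FALSE)$n_co, 5)
})

test_that("arms without crossovers map to zero, and counts are conserved", {
  lay <- genome_layout(data.frame(chrom = c("c1", "c2"),
                                  length = c(2e6, 1e6)))
  ped <- default_pedigree(6)
  calls <- mk_call("O1", "paternal", "c1", "q", 1e5)
  rm <- build_recmap(calls, lay, ped)
  c2 <- rm[rm$chrom == "c2", ]
  expect_equal(c2$cm_avg, 0)
  expect_equal(c2$rate_avg, 0)
  expect_equal(sum(rm$n_co), nrow(calls))
  expect_error(build_recmap(mk_call("O1", "paternal", "cX", "q", 1),
                            lay, ped), "absent")
})

test_that("Z PAR counts both sexes, non-PAR only paternal meioses", {
  lay <- genome_layout(data.frame(chrom = "chrZ", length = 87.5e6,
                                  is_z = TRUE, par_start = 1, par_end = 1.1e6))
  ped <- default_pedigree(6)
  calls <- rbind(mk_call("O1", "maternal", "chrZ", "PAR", 5e5),
                 do.call(rbind, lapply(1:6, function(i)
                   mk_call(paste0("O", i), "paternal", "chrZ", "nonPAR", 5e7))))
  rm <- build_recmap(calls, lay, ped)
  par <- rm[rm$arm == "PAR", ]; np <- rm[rm$arm == "nonPAR", ]
  expect_equal(par$meioses_total, 12)
  expect_equal(par$cm_avg, 100 * 1 / 12)
  expect_equal(np$meioses_total, 6)
  expect_equal(np$cm_paternal, 100)
  expect_true(is.na(np$cm_maternal))
})

test_that("telomere distances use the arm's telomeric end", {
  # right arm of 10 Mb ending the 60-Mb chromosome; telomere at 60 Mb
  lay <- genome_layout(data.frame(chrom = "c1", length = 60e6,
                                  centromere = 50e6))
  at <- arm_table(lay)
  right_arm <- at$arm[at$telomere == "right"]   # the shorter arm here: "p"
  co <- mk_call("O1", "paternal", "c1", right_arm, 57e6)
  d <- arm_distance_metrics(co, lay)
  expect_equal(d$telo_dist, 3e6)
  expect_equal(d$telo_prop, 0.30)
  # outermost base of the arm: distance 0; arm middle: proportion 0.5
  expect_equal(arm_distance_metrics(
    mk_call("O1", "paternal", "c1", right_arm, 60e6), lay)$telo_dist, 0)
  expect_equal(arm_distance_metrics(
    mk_call("O1", "paternal", "c1", right_arm, 55e6), lay)$telo_prop, 0.5)
  # the left (q) arm of the same chromosome is telomeric at position 1
  expect_equal(arm_distance_metrics(
    mk_call("O1", "paternal", "c1", "q", 2e6), lay)$telo_dist, 2e6 - 1)
})

test_that("segregating-arm crossover fraction counts arm copies once", {
  lay <- genome_layout(data.frame(chrom = c("c1", "c2"),
                                  length = c(2e6, 2e6)))
  ped <- default_pedigree(6)
  calls <- rbind(mk_call("O1", "paternal", "c1", "q", 1e5),
                 mk_call("O1", "paternal", "c1", "q", 1.5e6),  # same arm copy
                 mk_call("O2", "maternal", "c2", "q", 1e5))
  awc <- arms_with_co_fraction(calls, lay, ped)
  expect_equal(awc$n_segregating, 2 * 2 * 6)
  expect_equal(awc$n_with_co, 2)
  expect_equal(awc$fraction, 2 / 24)
})

test_that("a planted diversity desert is recovered as the centromere", {
  set.seed(51)
  n_ind <- 12
  pos <- sort(sample.int(15e6, 12000))
  geno <- matrix(rbinom(length(pos) * n_ind, 2, 0.3), ncol = n_ind,
                 dimnames = list(NULL, paste0("i", 1:n_ind)))
  desert <- pos >= 6e6 & pos < 11e6
  geno[desert, ] <- 0L
  gm <- genotype_matrix(data.frame(chrom = "c1", pos = pos), geno)
  lay <- telo_layout(15e6)
  cen <- locate_centromere(gm, lay, window = 5e5)
  expect_equal(cen$confidence, "ok")
  expect_lt(cen$start, 11e6)
  expect_gt(cen$end, 6e6)
  # monomorphic chromosome: degenerate, whole chromosome returned
  gm0 <- genotype_matrix(data.frame(chrom = "c1", pos = pos),
                         matrix(0L, length(pos), n_ind,
                                dimnames = list(NULL, paste0("i", 1:n_ind))))
  cen0 <- locate_centromere(gm0, lay, window = 5e5)
  expect_equal(cen0$confidence, "degenerate")
  expect_equal(c(cen0$start, cen0$end), c(1, 15e6))
  expect_error(locate_centromere(gm, lay, window = 2e7), "shorter")
})

test_that("uniform diversity yields a low-confidence candidate", {
  set.seed(52)
  pos <- sort(sample.int(10e6, 8000))
  geno <- matrix(rbinom(length(pos) * 12, 2, 0.3), ncol = 12,
                 dimnames = list(NULL, paste0("i", 1:12)))
  gm <- genotype_matrix(data.frame(chrom = "c1", pos = pos), geno)
  cen <- locate_centromere(gm, telo_layout(10e6), window = 5e5)
  expect_equal(cen$confidence, "low")
})

test_that("recombination rate falls with arm length under obligate chiasma", {
  cfg <- sim_config(chromosomes = data.frame(chrom = paste0("a", 1:4),
                                             length = c(5e6, 10e6, 20e6, 40e6)),
                    snp_density = 400, n_offspring = 12,
                    offspring_sex = rep(c("M", "F"), 6), seed = 53)
  sim <- simulate_pedigree(cfg)
  ser <- build_origin_series(sim$genotypes, sim$pedigree, sim$layout)
  calls <- suppressWarnings(call_crossovers(ser, 50, sim$layout))
  rm <- build_recmap(calls, sim$layout, sim$pedigree)
  rho <- suppressWarnings(
    cor.test(rm$rate_avg, rm$length_mb, method = "spearman"))
  expect_lt(rho$estimate, 0)
})
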