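# Shared fixtures: tiny layouts, series builders, and small simulation
# configurations used across the test files.

telo_layout <- function(len = 1e6, chrom = "c1") {
  genome_layout(data.frame(chrom = chrom, length = len))
}

make_series <- function(labels, pos = seq_along(labels) * 1000,
                        offspring = "O1", side = "paternal", chrom = "c1") {
  data.frame(offspring = offspring, side = side, chrom = chrom,
             pos = pos, origin = labels, stringsAsFactors = FALSE)
}

small_sim_cfg <- function(len = 2e6, density = 1000, seed = 1, ...) {
  sim_config(chromosomes = data.frame(chrom = "c1", length = len),
             snp_density = density, seed = seed, ...)
}

# Mendelian rule for one biallelic trio of dosages: is there a decomposition
# of the offspring genotype into one allele from each parent?
mendel_ok <- function(go, gf, gm) {
  fa <- if (gf == 1) 0:1 else gf / 2
  mo <- if (gm == 1) 0:1 else gm / 2
  any(outer(fa, mo, "+") == go)
}
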