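test_that("continuity scores equal run lengths", {
  expect_equal(ccs(c("A", "A", "A")),
               data.frame(forward = 1:3, backward = 3:1))
  expect_equal(ccs(c("A", "B")),
               data.frame(forward = c(1L, 1L), backward = c(1L, 1L)))
  set.seed(41)
  labs <- sample(c("GF", "GM"), 200, replace = TRUE, prob = c(0.7, 0.3))
  got <- ccs(labs)
  # brute force: count identical neighbours outward from each site
  fwd <- vapply(seq_along(labs), function(i) {
    k <- 0; while (i - k >= 1 && labs[i - k] == labs[i]) k <- k + 1; k
  }, numeric(1))
  bwd <- vapply(seq_along(labs), function(i) {
    k <- 0; while (i + k <= 200 && labs[i + k] == labs[i]) k <- k + 1; k
  }, numeric(1))
  expect_equal(got$forward, fwd)
  expect_equal(got$backward, bwd)
  expect_true(all(got$forward >= 1 & got$backward >= 1))
  expect_error(ccs(character(0)), "informative")
})

test_that("a clean transition is called at the flanking-marker midpoint", {
  s <- make_series(rep(c("GF", "GM"), each = 100))
  calls <- call_crossovers(s, threshold = 50)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$left, 100 * 1000)
  expect_equal(calls$right, 101 * 1000)
  expect_equal(calls$point, 100500)
  expect_equal(calls$precision, 1000)
  expect_equal(calls$transition, "GF>GM")
  expect_gt(calls$point, calls$left)
  expect_lt(calls$point, calls$right)
})

test_that("sub-threshold noise blocks are ignored", {
  s <- make_series(c(rep("GF", 100), rep("GM", 5), rep("GF", 100)))
  expect_equal(nrow(call_crossovers(s, threshold = 50)), 0L)
  # ...but a genuine double crossover is two calls
  s2 <- make_series(c(rep("GF", 100), rep("GM", 60), rep("GF", 100)))
  expect_equal(nrow(call_crossovers(s2, threshold = 50)), 2L)
})

test_that("caller matches the brute-force block oracle on random series", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(60:500, 1)
    thr <- sample(c(10, 25, 50), 1)
    labs <- sample(c("GF", "GM"), n, replace = TRUE,
                   prob = c(runif(1, 0.2, 0.8), 1))
    # inject longer blocks so calls actually occur sometimes
    if (runif(1) < 0.7) {
      cut <- sample(n - 1, 1)
      labs[1:cut] <- sample(c("GF", "GM"), 1)
    }
    pos <- sort(sample.int(1e6, n))
    s <- make_series(labs, pos = pos)
    got <- call_crossovers(s, threshold = thr)
    want <- brute_calls(labs, pos, thr)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$left, want$left)
      expect_equal(got$right, want$right)
    }
  }
})

test_that("raising the threshold never increases the number of calls", {
  set.seed(43)
  for (rep in 1:30) {
    labs <- sample(c("GF", "GM"), 400, replace = TRUE, prob = c(0.85, 0.15))
    labs[1:200] <- "GM"
    s <- make_series(labs)
    counts <- vapply(c(5, 20, 50, 100),
                     function(t) nrow(call_crossovers(s, t)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("series shorter than the threshold warn and yield nothing", {
  s <- make_series(rep("GF", 10))
  expect_warning(calls <- call_crossovers(s, threshold = 50), "shorter")
  expect_equal(nrow(calls), 0L)
})

test_that("calls are assigned to arms and centromere-spanning ones flagged", {
  lay <- genome_layout(data.frame(chrom = "c1", length = 4e5,
                                  centromere = 2e5))
  s <- make_series(rep(c("GF", "GM"), each = 100),
                   pos = seq(1000, 400000, length.out = 200))
  calls <- call_crossovers(s, threshold = 50, layout = lay)
  # equal-length arms: the left arm wins the q label, so the midpoint just
  # right of the centromere falls on p
  expect_equal(calls$arm, "p")
  expect_true(calls$spans_centromere)
})

test_that("scaffold-border artifact groups are flagged, interior calls not", {
  lay <- genome_layout(
    chromosomes = data.frame(chrom = "c1", length = 1e6),
    scaffolds = data.frame(chrom = "c1", scaffold = c("s1", "s2"),
                           length = c(5e5, 5e5), orient = "+"))
  mk <- function(off, point) data.frame(
    offspring = off, side = "paternal", chrom = "c1", arm = "q",
    left = point - 500, right = point + 500, point = point, precision = 1000,
    transition = "GF>GM", spans_centromere = FALSE, artifact = FALSE,
    stringsAsFactors = FALSE)
  calls <- rbind(mk("O1", 500100), mk("O2", 500050), mk("O3", 499900),
                 mk("O4", 250000), mk("O5", 700000))
  flagged <- flag_scaffold_artifacts(calls, lay, tol = 1000)
  expect_equal(flagged$artifact, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  # the same shared point far from any boundary is left alone
  calls2 <- rbind(mk("O1", 250000), mk("O2", 250000))
  expect_false(any(flag_scaffold_artifacts(calls2, lay, tol = 1000)$artifact))
  # single-scaffold layouts have no interior boundaries
  expect_false(any(flag_scaffold_artifacts(calls, telo_layout(1e6),
                                           tol = 1000)$artifact))
})

test_that("detectability predicate matches flanking informative counts", {
  sim <- simulate_pedigree(small_sim_cfg(len = 3e6, density = 600, seed = 44))
  ser <- build_origin_series(sim$genotypes, sim$pedigree, sim$layout)
  tr <- co_detectable(sim$truth, ser, threshold = 50)
  calls <- suppressWarnings(call_crossovers(ser, 50, sim$layout))
  # every detectable truth CO is recovered with truth inside the interval
  for (i in which(tr$detectable)) {
    hit <- calls$offspring == tr$offspring[i] & calls$side == tr$side[i] &
      calls$chrom == tr$chrom[i] & calls$left < tr$pos[i] &
      calls$right >= tr$pos[i]
    expect_equal(sum(hit), 1L)
  }
  expect_equal(nrow(calls), sum(tr$detectable))
})
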