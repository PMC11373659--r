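#' Pipeline configuration
#'
#' Bundles the tunables of the full analysis: the continuity-score
#' threshold, the scaffold-artifact tolerance, the sub-telomeric window,
#' the permutation replicate count, a seed, and either a simulation
#' configuration or paths to input files (012/GT genotype table, scaffold
#' layout not yet applied, GFF3 annotation).
#'
#' @param sim A [sim_config()] to run in simulate mode, or `NULL` to read
#'   inputs from files.
#' @param genotypes,annotation Paths to a genotype table and GFF3 annotation
#'   (file mode only).
#' @param layout A [genome_layout()] (file mode only).
#' @param pedigree A [pedigree_spec()] (file mode; defaults to
#'   [default_pedigree()]).
#' @param threshold Continuity-score threshold (default 50, must be >= 2).
#' @param artifact_tol Scaffold-artifact matching tolerance in bp.
#' @param subtel_window Sub-telomeric window in bp (default 6 Mb).
#' @param perm_reps Permutation replicates (default 1000, must be >= 1).
#' @param seed Integer seed used for the simulation and permutation stages.
#' @param out_dir Optional output directory for stage TSVs and the metrics
#'   JSON.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = NULL, genotypes = NULL, annotation = NULL,
                       layout = NULL, pedigree = NULL, threshold = 50,
                       artifact_tol = 1000, subtel_window = 6e6,
                       perm_reps = 1000, seed = NULL, out_dir = NULL) {
  if (threshold < 2) stop("threshold must be >= 2")
  if (subtel_window <= 0) stop("subtelomeric window must be positive")
  if (perm_reps < 1) stop("perm_reps must be >= 1")
  if (is.null(sim) && (is.null(genotypes) || is.null(layout)))
    stop("either a sim_config or genotype + layout inputs are required")
  structure(list(sim = sim, genotypes = genotypes, annotation = annotation,
                 layout = layout, pedigree = pedigree, threshold = threshold,
                 artifact_tol = artifact_tol, subtel_window = subtel_window,
                 perm_reps = perm_reps, seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [run_config()] and
#' [sim_config()]; a `sim:` block switches to simulate mode.
#'
#' @param path Path to a YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$sim)) {
    sim_args <- y$sim
    if (!is.null(sim_args$chromosomes))
      sim_args$chromosomes <- as.data.frame(
        lapply(sim_args$chromosomes, unlist), stringsAsFactors = FALSE)
    sim <- do.call(sim_config, sim_args)
  }
  lay <- NULL
  if (!is.null(y$layout)) {
    lay <- genome_layout(
      chromosomes = as.data.frame(lapply(y$layout$chromosomes, unlist),
                                  stringsAsFactors = FALSE),
      scaffolds = if (!is.null(y$layout$scaffolds))
        as.data.frame(lapply(y$layout$scaffolds, unlist),
                      stringsAsFactors = FALSE))
  }
  run_config(sim = sim, genotypes = y$genotypes, annotation = y$annotation,
             layout = lay,
             threshold = y$threshold %||% 50,
             artifact_tol = y$artifact_tol %||% 1000,
             subtel_window = y$subtel_window %||% 6e6,
             perm_reps = y$perm_reps %||% 1000,
             seed = y$seed, out_dir = y$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full crossover-mapping analysis
#'
#' Orchestrates simulate/load, grandparent-of-origin phasing, crossover
#' calling with artifact flagging, the sex-specific recombination map,
#' sex-difference tests, and the gene-feature association analyses, and
#' collects a machine-readable metrics list. With identical seed and inputs
#' the bundle is identical. Every excluded class of sites and calls is
#' counted and reported; nothing is dropped silently.
#'
#' @param config A [run_config()].
#' @return A list of class `pedcross_run` with elements `sim` (in simulate
#'   mode), `series`, `calls`, `recmap`, `centromeres`, `sexdiff`
#'   (paired cM/rate tests and the two rank tests), `features`
#'   (classification, goodness-of-fit results, nearest-gene distances,
#'   permutation test), `summary` and `metrics` (flat named list). When
#'   `config$out_dir` is set, stage TSVs and `metrics.json` are written
#'   there.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  bundle <- list()
  if (!is.null(config$sim)) {
    sim_cfg <- config$sim
    if (!is.null(config$seed)) sim_cfg$seed <- config$seed
    sim <- simulate_pedigree(sim_cfg)
    gm <- sim$genotypes; layout <- sim$layout; ped <- sim$pedigree
    ann <- sim$annotation
    bundle$sim <- sim
  } else {
    ped <- config$pedigree %||% default_pedigree()
    layout <- config$layout
    gm <- read_gt_table(config$genotypes, ped)
    if (!all(gm$sites$chrom %in% layout$chromosomes$chrom))
      gm <- apply_layout(gm, layout)
    ann <- if (!is.null(config$annotation)) read_annotation(config$annotation)
  }

  series <- build_origin_series(gm, ped, layout)
  calls <- call_crossovers(series, threshold = config$threshold,
                           layout = layout)
  calls <- flag_scaffold_artifacts(calls, layout, tol = config$artifact_tol)
  rm_map <- build_recmap(calls, layout, ped)
  cen <- locate_centromere(gm, layout)

  used <- calls[!calls$artifact, , drop = FALSE]
  sexdiff <- list(
    cm = tryCatch(paired_sex_test(rm_map, "cM"), error = function(e) NULL),
    rate = tryCatch(paired_sex_test(rm_map, "cM_per_Mb"),
                    error = function(e) NULL),
    physical = tryCatch(position_rank_test(used, layout, "physical"),
                        error = function(e) NULL),
    proportional = tryCatch(position_rank_test(used, layout, "proportional"),
                            error = function(e) NULL))

  aut_chroms <- layout$chromosomes$chrom[!layout$chromosomes$is_z]
  aut <- used[used$chrom %in% aut_chroms, , drop = FALSE]
  features <- NULL
  if (!is.null(ann) && nrow(aut) > 0) {
    cls <- classify_co(aut, ann)
    len_gw <- feature_lengths(ann, layout, chroms = aut_chroms)
    wins <- subtelomeric_windows(layout, config$subtel_window)
    len_st <- feature_lengths(ann, layout, windows = wins,
                              chroms = aut_chroms)
    st <- subtelomeric_filter(cls, layout, config$subtel_window)
    gof <- function(cls_df, lens, scope) {
      res <- list()
      o_g <- c(intergenic = sum(cls_df$feat_gene == "intergenic"),
               genic = sum(cls_df$feat_gene == "genic"))
      if (sum(o_g) > 0)
        res$intergenic_genic <- gof_test(o_g, lens[c("intergenic", "genic")],
                                         scope)
      o_e <- c(exon = sum(cls_df$feat_exon == "exon", na.rm = TRUE),
               intron = sum(cls_df$feat_exon == "intron", na.rm = TRUE))
      if (sum(o_e) > 0)
        res$exon_intron <- gof_test(o_e, lens[c("exon", "intron")], scope)
      o_c <- c(UTR = sum(cls_df$feat_cds == "UTR", na.rm = TRUE),
               CDS = sum(cls_df$feat_cds == "CDS", na.rm = TRUE))
      if (sum(o_c) > 0)
        res$utr_cds <- gof_test(o_c, lens[c("UTR", "CDS")], scope)
      res
    }
    ng <- nearest_gene(cls, ann)
    perm <- if (any(cls$feat_gene == "intergenic"))
      permutation_gene_proximity(cls, ann, layout, reps = config$perm_reps,
                                 seed = config$seed)
    features <- list(classification = cls,
                     gof_genome = gof(cls, len_gw, "genome-wide"),
                     gof_subtel = gof(st, len_st,
                                      sprintf("subtelomeric-%gMb",
                                              config$subtel_window / 1e6)),
                     nearest_gene = ng, permutation = perm)
  }

  arm_aut <- rm_map[rm_map$zclass == "autosome", , drop = FALSE]
  summary <- list(
    n_sites = nrow(gm$sites),
    n_series = length(unique(interaction(series$offspring, series$side,
                                         series$chrom, drop = TRUE))),
    n_calls = nrow(calls),
    n_calls_flagged = sum(calls$artifact),
    n_calls_paternal = sum(used$side == "paternal"),
    n_calls_maternal = sum(used$side == "maternal"),
    exclusions = attr(series, "exclusions"))
  awc <- arms_with_co_fraction(calls, layout, ped)
  summary$arms_segregating <- awc$n_segregating
  summary$arms_with_co <- awc$n_with_co
  summary$frac_arms_with_co <- awc$fraction

  metrics <- list(
    n_calls = nrow(calls), n_flagged = sum(calls$artifact),
    n_paternal = sum(used$side == "paternal"),
    n_maternal = sum(used$side == "maternal"),
    mean_cm_avg = mean(arm_aut$cm_avg),
    mean_cm_paternal = mean(arm_aut$cm_paternal),
    mean_cm_maternal = mean(arm_aut$cm_maternal),
    mean_precision_bp = if (nrow(used)) mean(used$precision) else NA,
    frac_arms_with_co = summary$frac_arms_with_co,
    paired_t_cm_p = if (!is.null(sexdiff$cm)) sexdiff$cm$p,
    paired_t_rate_p = if (!is.null(sexdiff$rate)) sexdiff$rate$p,
    u_physical = if (!is.null(sexdiff$physical)) sexdiff$physical$statistic,
    u_physical_p = if (!is.null(sexdiff$physical)) sexdiff$physical$p,
    u_proportional_p = if (!is.null(sexdiff$proportional))
      sexdiff$proportional$p,
    perm_gene_proximity_p = if (!is.null(features$permutation))
      features$permutation$p)
  if (!is.null(bundle$sim)) metrics$n_truth <- nrow(bundle$sim$truth)

  bundle <- c(bundle, list(series = series, calls = calls, recmap = rm_map,
                           centromeres = cen, sexdiff = sexdiff,
                           features = features, summary = summary,
                           metrics = metrics, layout = layout,
                           pedigree = ped, config = config))
  class(bundle) <- "pedcross_run"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, f) utils::write.table(
      df, file.path(config$out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    write_origin_series(series, file.path(config$out_dir, "origin_series.tsv"))
    wt(calls, "crossovers.tsv")
    wt(rm_map, "recmap.tsv")
    wt(cen, "centromeres.tsv")
    wt(attr(series, "exclusions"), "site_exclusions.tsv")
    if (!is.null(features)) {
      wt(features$classification, "co_classification.tsv")
      wt(features$nearest_gene, "nearest_gene.tsv")
    }
    if (!is.null(bundle$sim)) write_truth(bundle$sim$truth,
                                          file.path(config$out_dir,
                                                    "truth_crossovers.tsv"))
    jsonlite::write_json(metrics, file.path(config$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  bundle
}

#' @export
print.pedcross_run <- function(x, ...) {
  cat("pedcross_run:", x$summary$n_calls, "crossover calls (",
      x$summary$n_calls_flagged, "flagged ) over",
      nrow(x$recmap), "arms;",
      sprintf("%.1f%%", 100 * x$summary$frac_arms_with_co),
      "of segregating autosomal arms carry a crossover\n")
  invisible(x)
}
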