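#' Paired sex-difference test on arm-level recombination
#'
#' Two-sided paired t-test of paternal versus maternal per-arm recombination
#' distance (cM) or rate (cM/Mb) across autosomal arms (Z rows are
#' excluded: its meioses are not paired between the sexes).
#'
#' @param recmap An `arm_recmap` from [build_recmap()].
#' @param metric `"cM"` or `"cM_per_Mb"`.
#' @return A list of class `sexdiff_result`: `test`, `metric`, `statistic`
#'   (t), `df`, `p`, `n` (arms), `mean_paternal`, `mean_maternal`,
#'   `degenerate` (TRUE when the paired differences have zero variance, in
#'   which case `statistic`/`p` are `NA`).
#' @export
paired_sex_test <- function(recmap, metric = c("cM", "cM_per_Mb")) {
  metric <- match.arg(metric)
  aut <- recmap[recmap$zclass == "autosome", , drop = FALSE]
  if (nrow(aut) < 2) stop("need at least two autosomal arms")
  pat <- if (metric == "cM") aut$cm_paternal else aut$rate_paternal
  mat <- if (metric == "cM") aut$cm_maternal else aut$rate_maternal
  d <- pat - mat
  res <- list(test = "paired t", metric = metric, n = nrow(aut),
              mean_paternal = mean(pat), mean_maternal = mean(mat),
              degenerate = FALSE)
  if (stats::sd(d) == 0) {
    # zero-variance differences: identical vectors give t = 0, P = 1; a
    # constant non-zero shift is reported as infinitely significant
    res$degenerate <- TRUE
    res$df <- nrow(aut) - 1
    res$statistic <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    res$p <- if (mean(d) == 0) 1 else 0
    warning("zero variance of paired differences; test degenerate")
  } else {
    tt <- stats::t.test(pat, mat, paired = TRUE, alternative = "two.sided")
    res$statistic <- unname(tt$statistic)
    res$df <- unname(tt$parameter)
    res$p <- tt$p.value
  }
  class(res) <- "sexdiff_result"
  res
}

#' Mann-Whitney U test of crossover telomere distances between sexes
#'
#' Two-sided rank test comparing paternal versus maternal crossover
#' positions measured from the telomeric end of their arms, either as
#' physical distances (bp) or as proportions of arm length. The U statistic
#' is reported for the paternal sample. The exact null distribution is used
#' for samples of at most 20 per sex without ties; otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param calls A `crossover_calls` data frame (artifact-flagged calls are
#'   excluded).
#' @param layout A [genome_layout()].
#' @param mode `"physical"` or `"proportional"`.
#' @return A list of class `sexdiff_result`: `test`, `mode`, `statistic`
#'   (U for the paternal group), `p`, `n_paternal`, `n_maternal`,
#'   `median_paternal`, `median_maternal`.
#' @export
position_rank_test <- function(calls, layout, mode = c("physical",
                                                       "proportional")) {
  mode <- match.arg(mode)
  calls <- calls[!calls$artifact, , drop = FALSE]
  cm <- arm_distance_metrics(calls, layout)
  v <- if (mode == "physical") cm$telo_dist else cm$telo_prop
  pat <- v[cm$side == "paternal"]
  mat <- v[cm$side == "maternal"]
  if (length(pat) == 0 || length(mat) == 0)
    stop("need at least one crossover per sex")
  exact <- length(pat) <= 20 && length(mat) <= 20
  wt <- suppressWarnings(stats::wilcox.test(pat, mat, exact = exact,
                                            correct = TRUE,
                                            alternative = "two.sided"))
  structure(list(test = "Mann-Whitney U", mode = mode,
                 statistic = unname(wt$statistic), p = wt$p.value,
                 n_paternal = length(pat), n_maternal = length(mat),
                 median_paternal = stats::median(pat),
                 median_maternal = stats::median(mat)),
            class = "sexdiff_result")
}

#' @export
print.sexdiff_result <- function(x, ...) {
  cat(x$test, if (!is.null(x$metric)) paste0("on ", x$metric)
      else paste0("(", x$mode, " telomere distance)"), "\n")
  cat("  statistic =", format(x$statistic, digits = 4),
      if (!is.null(x$df)) paste0("(df = ", format(x$df), ")") else "",
      " P =", format(x$p, digits = 3), "\n")
  invisible(x)
}
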