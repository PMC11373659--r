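#' Cumulative continuity scores of an origin series
#'
#' For an ordered series of grandparent-of-origin labels, the forward score
#' at site i is the number of consecutive same-label sites ending at i
#' (resetting to 1 at each label change); the backward score is the mirror
#' (consecutive same-label sites starting at i). A site deep inside a
#' genuine origin block has a high score in at least one direction; isolated
#' genotyping errors score 1.
#'
#' @param labels Character vector of origin labels (e.g. `"GF"`/`"GM"`), in
#'   positional order.
#' @return `data.frame` with columns `forward`, `backward` (both `>= 1`).
#' @examples
#' ccs(c("GF", "GF", "GM"))
#' @export
ccs <- function(labels) {
  n <- length(labels)
  if (n == 0) stop("at least one informative site is required")
  r <- rle(labels)
  fwd <- unlist(lapply(r$lengths, seq_len), use.names = FALSE)
  bwd <- unlist(lapply(r$lengths, function(l) rev(seq_len(l))),
                use.names = FALSE)
  data.frame(forward = fwd, backward = bwd)
}

# Maximal same-label blocks of a label vector:
# data.frame(label, len, from, to) with from/to site indices.
.blocks <- function(labels) {
  r <- rle(labels)
  to <- cumsum(r$lengths)
  data.frame(label = r$values, len = r$lengths,
             from = to - r$lengths + 1L, to = to, stringsAsFactors = FALSE)
}

#' Call crossovers in origin series with a continuity-score threshold
#'
#' Crossovers are called between adjacent maximal same-origin blocks whose
#' lengths (in informative sites) both reach the threshold; interior blocks
#' shorter than the threshold are treated as genotyping noise and ignored
#' (adjacent qualifying blocks with equal labels therefore yield no call).
#' Each call is reported with its flanking informative markers (last site of
#' the left block, first site of the right block), the midpoint point
#' estimate, and the flanking interval length as the positional precision.
#'
#' Two genuine crossovers closer together than the threshold span cannot be
#' separated by construction; this is a stated detection limit of the
#' method.
#'
#' @param series An `origin_series` (or any `data.frame` with columns
#'   `offspring`, `side`, `chrom`, `pos`, `origin`).
#' @param threshold Minimum block length in informative sites (default 50).
#' @param layout Optional [genome_layout()]; when given, calls are assigned
#'   to chromosome arms (a call whose flanking interval spans the centromere
#'   is assigned by its midpoint and flagged in `spans_centromere`).
#' @return `data.frame` of class `crossover_calls` with columns `offspring`,
#'   `side`, `chrom`, `arm`, `left`, `right`, `point`, `precision`,
#'   `transition`, `spans_centromere`, `artifact`.
#' @export
call_crossovers <- function(series, threshold = 50, layout = NULL) {
  stopifnot(threshold >= 2)
  need <- c("offspring", "side", "chrom", "pos", "origin")
  stopifnot(all(need %in% names(series)))
  key <- interaction(series$offspring, series$side, series$chrom, drop = TRUE)
  out <- list()
  short_series <- 0L
  for (k in levels(key)) {
    s <- series[key == k, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    if (nrow(s) < threshold) {
      short_series <- short_series + 1L
      next
    }
    b <- .blocks(s$origin)
    q <- b[b$len >= threshold, , drop = FALSE]
    if (nrow(q) < 2) next
    for (i in seq_len(nrow(q) - 1)) {
      if (q$label[i] == q$label[i + 1]) next
      left <- s$pos[q$to[i]]
      right <- s$pos[q$from[i + 1]]
      out[[length(out) + 1L]] <- data.frame(
        offspring = s$offspring[1], side = s$side[1], chrom = s$chrom[1],
        left = left, right = right, point = (left + right) / 2,
        precision = right - left,
        transition = paste0(q$label[i], ">", q$label[i + 1]),
        stringsAsFactors = FALSE)
    }
  }
  if (short_series > 0)
    warning(short_series, " series shorter than the threshold produced no calls")
  calls <- if (length(out)) do.call(rbind, out) else
    data.frame(offspring = character(), side = character(),
               chrom = character(), left = numeric(), right = numeric(),
               point = numeric(), precision = numeric(),
               transition = character(), stringsAsFactors = FALSE)
  calls$arm <- rep(NA_character_, nrow(calls))
  calls$spans_centromere <- rep(FALSE, nrow(calls))
  if (!is.null(layout) && nrow(calls)) {
    arms <- arm_table(layout)
    mid_arm <- .arm_index(arms, calls$chrom, calls$point)
    l_arm <- .arm_index(arms, calls$chrom, calls$left)
    r_arm <- .arm_index(arms, calls$chrom, calls$right)
    calls$arm <- arms$arm[mid_arm]
    calls$spans_centromere <- !is.na(l_arm) & !is.na(r_arm) & l_arm != r_arm
  }
  calls$artifact <- rep(FALSE, nrow(calls))
  calls <- calls[, c("offspring", "side", "chrom", "arm", "left", "right",
                     "point", "precision", "transition", "spans_centromere",
                     "artifact")]
  rownames(calls) <- NULL
  class(calls) <- c("crossover_calls", "data.frame")
  calls
}

#' Flag crossover calls coinciding with scaffold borders
#'
#' Identically positioned crossovers recurring in more than one offspring
#' that also sit at a scaffold junction are the signature of a wrongly
#' ordered or oriented scaffold, not of recombination. This flags (never
#' deletes) every group of calls from at least two different offspring whose
#' point estimates agree within `tol` and lie within `tol` of an interior
#' scaffold boundary.
#'
#' @param calls A `crossover_calls` data frame.
#' @param layout A [genome_layout()] with scaffold information.
#' @param tol Matching tolerance in bp (default 1000).
#' @return `calls` with the `artifact` column updated.
#' @export
flag_scaffold_artifacts <- function(calls, layout, tol = 1000) {
  stopifnot(inherits(layout, "genome_layout"))
  if (nrow(calls) < 2) return(calls)
  bnd <- scaffold_boundaries(layout)
  if (nrow(bnd) == 0) return(calls)
  for (i in seq_len(nrow(bnd))) {
    near <- which(calls$chrom == bnd$chrom[i] &
                  abs(calls$point - bnd$pos[i]) <= tol)
    if (length(near) < 2) next
    # require point agreement across >= 2 distinct offspring
    pts <- calls$point[near]
    grp <- near[abs(pts - stats::median(pts)) <= tol]
    if (length(unique(calls$offspring[grp])) >= 2)
      calls$artifact[grp] <- TRUE
  }
  calls
}

#' Detectability of ground-truth crossovers under the continuity threshold
#'
#' A crossover is detectable by the threshold rule only if at least
#' `threshold` informative markers of consistent origin flank it on both
#' sides within its series, with no other crossover interrupting them.
#' Crossovers falling telomere-ward of the first `threshold` informative
#' markers, or pairs closer together than the threshold span, are censored
#' by construction: this predicate states the method's detection limit
#' independently of the caller.
#'
#' @param truth Truth `data.frame` from [simulate_pedigree()] (`offspring`,
#'   `side`, `chrom`, `pos`).
#' @param series An `origin_series` from [build_origin_series()].
#' @param threshold Continuity-score threshold (default 50).
#' @return `truth` with an added logical column `detectable`.
#' @export
co_detectable <- function(truth, series, threshold = 50) {
  det <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    s <- series[series$offspring == truth$offspring[i] &
                series$side == truth$side[i] &
                series$chrom == truth$chrom[i], , drop = FALSE]
    pos <- sort(s$pos)
    x <- truth$pos[i]
    sib <- truth$pos[truth$offspring == truth$offspring[i] &
                     truth$side == truth$side[i] &
                     truth$chrom == truth$chrom[i]]
    lo <- max(c(-Inf, sib[sib < x]))
    hi <- min(c(Inf, sib[sib > x]))
    # markers between this crossover and the nearest series end or
    # neighbouring crossover, on each side (sites at pos >= x switch)
    det[i] <- sum(pos < x & pos > lo) >= threshold &&
              sum(pos >= x & pos < hi) >= threshold
  }
  truth$detectable <- det
  truth
}
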