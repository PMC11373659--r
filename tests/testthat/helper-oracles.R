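# Independent oracles shared by the unit and acceptance tests.

# Brute-force caller: scan the label vector with an explicit loop, build
# maximal runs, keep runs of at least `thr` sites, and pair neighbouring
# kept runs with different labels. Written independently of the rle-based
# implementation.
brute_calls <- function(labels, pos, thr) {
  runs <- list(); cur <- labels[1]; from <- 1
  for (i in seq_along(labels)[-1]) {
    if (labels[i] != cur) {
      runs[[length(runs) + 1]] <- list(lab = cur, from = from, to = i - 1)
      cur <- labels[i]; from <- i
    }
  }
  runs[[length(runs) + 1]] <- list(lab = cur, from = from, to = length(labels))
  keep <- Filter(function(r) r$to - r$from + 1 >= thr, runs)
  out <- NULL
  if (length(keep) >= 2) {
    for (i in seq_len(length(keep) - 1)) {
      a <- keep[[i]]; b <- keep[[i + 1]]
      if (a$lab != b$lab)
        out <- rbind(out, data.frame(left = pos[a$to], right = pos[b$from]))
    }
  }
  out
}

# Trio-decomposition oracle: enumerate explicit parental haplotype pairs and
# count which transmitted-allele decompositions are compatible.
trio_oracle <- function(go, gf, gm) {
  hp <- list(c(0, 0), c(0, 1), c(1, 1))[[gf + 1]]
  hm <- list(c(0, 0), c(0, 1), c(1, 1))[[gm + 1]]
  found <- unique(do.call(rbind, lapply(hp, function(a)
    do.call(rbind, lapply(hm, function(b)
      if (a + b == go) c(a, b))))))
  if (is.null(found)) return(list(status = "inconsistent"))
  if (nrow(found) > 1) return(list(status = "ambiguous"))
  list(status = "ok", paternal = found[1, 1], maternal = found[1, 2])
}

# Grandparent-assignment oracle: enumerate grandparental haplotypes and
# collect the set of feasible origins of the transmitted allele.
gp_oracle <- function(allele, gp, ggf, ggm) {
  if (gp != 1) return("uninformative")
  haps <- list(c(0, 0), c(0, 1), c(1, 1))
  origins <- character(0)
  for (x in haps[[ggf + 1]]) for (y in haps[[ggm + 1]]) {
    if (sort(c(x, y))[1] == 0 && sort(c(x, y))[2] == 1) {
      origins <- c(origins, if (allele == x) "grandfather" else "grandmother")
    }
  }
  origins <- unique(origins)
  if (length(origins) == 0) return("inconsistent")
  if (length(origins) > 1) return("uninformative")
  origins
}

# Mann-Whitney U for the first sample by direct pairwise enumeration.
u_oracle <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}
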