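#' Pedigree specification for a three-generation crossover-mapping design
#'
#' Describes the 12-individual design used for grandparent-of-origin phasing:
#' four grandparents (F0), two parents (F1) and one or more offspring (F2).
#' Crossovers are detected in the two F1 meioses behind each offspring, so a
#' pedigree with `n` offspring contributes `2 * n` informative meioses per
#' autosomal arm (`n` paternal, `n` maternal).
#'
#' @param id Character vector of individual identifiers (must match genotype
#'   table column names).
#' @param role Character vector, one of `"paternal_grandfather"`,
#'   `"paternal_grandmother"`, `"maternal_grandfather"`,
#'   `"maternal_grandmother"`, `"father"`, `"mother"`, `"offspring"`.
#' @param sex Character vector, `"M"` or `"F"`. In a ZW system males are the
#'   homogametic (ZZ) sex; offspring sex controls Z-chromosome phasing.
#'
#' @return A `data.frame` of class `pedigree_spec` with columns `id`, `role`,
#'   `sex`.
#' @examples
#' ped <- default_pedigree(n_offspring = 2)
#' ped_offspring(ped)
#' @export
pedigree_spec <- function(id, role, sex) {
  roles <- c("paternal_grandfather", "paternal_grandmother",
             "maternal_grandfather", "maternal_grandmother",
             "father", "mother", "offspring")
  stopifnot(length(id) == length(role), length(id) == length(sex))
  if (anyDuplicated(id)) stop("duplicated individual ids")
  if (!all(role %in% roles)) stop("unknown pedigree role")
  if (!all(sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  for (r in setdiff(roles, "offspring")) {
    if (sum(role == r) != 1L) stop("exactly one individual must have role ", r)
  }
  if (sum(role == "offspring") < 1L) stop("at least one offspring required")
  if (sex[role == "father"] != "M") stop("father must be male")
  if (sex[role == "mother"] != "F") stop("mother must be female")
  if (sex[role == "paternal_grandfather"] != "M" ||
      sex[role == "maternal_grandfather"] != "M" ||
      sex[role == "paternal_grandmother"] != "F" ||
      sex[role == "maternal_grandmother"] != "F") {
    stop("grandparent sexes must match their roles")
  }
  structure(data.frame(id = as.character(id), role = role, sex = sex,
                       stringsAsFactors = FALSE),
            class = c("pedigree_spec", "data.frame"))
}

#' Default 12-individual pedigree
#'
#' The standard design: 4 grandparents, 2 parents and 6 offspring (5 males,
#' 1 female, mirroring a typical songbird brood with one ZW female).
#'
#' @param n_offspring Number of F2 offspring (default 6).
#' @param offspring_sex Character vector of offspring sexes; defaults to five
#'   males and one female when `n_offspring == 6`, otherwise alternating.
#' @return A [pedigree_spec()] object.
#' @export
default_pedigree <- function(n_offspring = 6,
                             offspring_sex = NULL) {
  if (is.null(offspring_sex)) {
    offspring_sex <- if (n_offspring == 6) c(rep("M", 5), "F")
                     else rep(c("M", "F"), length.out = n_offspring)
  }
  stopifnot(length(offspring_sex) == n_offspring)
  pedigree_spec(
    id = c("PGF", "PGM", "MGF", "MGM", "FA", "MO",
           paste0("O", seq_len(n_offspring))),
    role = c("paternal_grandfather", "paternal_grandmother",
             "maternal_grandfather", "maternal_grandmother",
             "father", "mother", rep("offspring", n_offspring)),
    sex = c("M", "F", "M", "F", "M", "F", offspring_sex)
  )
}

#' Look up the id of a pedigree role
#' @param ped A [pedigree_spec()].
#' @param role A single role name.
#' @return Individual id(s) holding that role.
#' @export
ped_role <- function(ped, role) ped$id[ped$role == role]

#' Offspring ids of a pedigree
#' @param ped A [pedigree_spec()].
#' @return Character vector of offspring ids.
#' @export
ped_offspring <- function(ped) ped$id[ped$role == "offspring"]

#' Sex of an individual
#' @param ped A [pedigree_spec()].
#' @param id Individual id.
#' @return `"M"` or `"F"`.
#' @export
ped_sex <- function(ped, id) ped$sex[match(id, ped$id)]
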