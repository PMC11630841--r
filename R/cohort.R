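#' Cohort stratum of a domain plDDT
#'
#' Strata used when sampling proteins for remodelling: `low` below 70,
#' `medium` in `[70, 90)`, `high` at or above 90. Note these cut-points
#' differ deliberately from the peak classes of [classify_peak]: peak
#' classes describe where a family's modes sit, strata describe which
#' members to remodel (low), and which serve as mid/positive controls.
#'
#' @param domain_plddt plDDT in `[0, 100]`.
#' @return `"low"`, `"medium"` or `"high"`.
#' @export
assign_stratum <- function(domain_plddt) {
  if (is.na(domain_plddt) || domain_plddt < 0 || domain_plddt > 100)
    stopf("plDDT value must lie in [0, 100]")
  if (domain_plddt < 70) "low" else if (domain_plddt < 90) "medium" else "high"
}

#' Select a stratified cohort from one family
#'
#' Draws up to `per_stratum` proteins from each stratum, preferring
#' complete proteins: fragments are only drawn once a stratum's
#' non-fragments are exhausted. Within a priority class selection is a
#' seeded uniform draw. A deficit in one stratum is not transferred to
#' the others, so the cohort size is at most `3 * per_stratum`.
#'
#' @param members Data frame with columns `protein_id`, `domain_plddt`,
#'   `is_fragment` (extra columns are carried through).
#' @param family_id Family accession recorded on each entry.
#' @param per_stratum Target count per stratum (default 10, i.e. a
#'   maximum of 30 per family).
#' @param seed Integer seed for the within-class draws.
#' @return Data frame of cohort entries with columns `protein_id`,
#'   `family_id`, `stratum`, `domain_plddt`, `is_fragment` plus any
#'   extra input columns.
#' @export
select_cohort <- function(members, family_id, per_stratum = 10L, seed = 1L) {
  if (per_stratum < 1L) stopf("per_stratum must be >= 1")
  if (!nrow(members)) {
    warnf("family %s has no members; empty cohort", family_id)
    return(empty_cohort(members, family_id))
  }
  stopifnot(all(c("protein_id", "domain_plddt", "is_fragment") %in% names(members)))
  members$stratum <- vapply(members$domain_plddt, assign_stratum, "")
  picked <- lapply(c("low", "medium", "high"), function(s) {
    pool <- members[members$stratum == s, , drop = FALSE]
    if (!nrow(pool)) return(pool)
    take <- function(pool_part, n_want, sub) {
      if (n_want <= 0L || !nrow(pool_part)) return(pool_part[0, , drop = FALSE])
      if (nrow(pool_part) <= n_want) return(pool_part)
      i <- with_seed(derive_seed(seed, family_id, s, sub),
                     sample.int(nrow(pool_part), n_want))
      pool_part[sort(i), , drop = FALSE]
    }
    full <- take(pool[!pool$is_fragment, , drop = FALSE], per_stratum, "complete")
    frag <- take(pool[pool$is_fragment, , drop = FALSE],
                 per_stratum - nrow(full), "fragment")
    rbind(full, frag)
  })
  out <- do.call(rbind, picked)
  out$family_id <- family_id
  rownames(out) <- NULL
  front <- c("protein_id", "family_id", "stratum", "domain_plddt", "is_fragment")
  out[c(front, setdiff(names(out), front))]
}

empty_cohort <- function(members, family_id) {
  out <- members[0, , drop = FALSE]
  out$stratum <- character(0)
  out$family_id <- character(0)
  out
}
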