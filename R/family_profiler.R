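#' Peak-detection parameters
#'
#' Defaults follow the standard settings for scanning a 0-1 normalized
#' 100-bin plDDT histogram: peaks lower than 3% of the tallest bin are
#' noise, and two modes closer than 19 bins (~19 plDDT units) are treated
#' as one.
#'
#' @param min_height Minimum normalized bin height for a retained peak.
#' @param min_distance Minimum separation, in bins, between retained peaks.
#' @param n_bins Number of histogram bins over `[0, 100]`.
#' @return A `peak_params` list.
#' @export
peak_params <- function(min_height = 0.03, min_distance = 19L, n_bins = 100L) {
  if (!(min_height > 0 && min_height <= 1)) stopf("min_height must be in (0, 1]")
  if (min_distance < 1L) stopf("min_distance must be >= 1")
  structure(list(min_height = min_height, min_distance = as.integer(min_distance),
                 n_bins = as.integer(n_bins)), class = "peak_params")
}

#' Max-normalized histogram of plDDT values
#'
#' Counts over `n_bins` equal-width bins on `[0, 100]` (bin k covers
#' `[(k-1)*100/n, k*100/n)`, the last bin right-closed), divided by the
#' maximum count so the tallest bin reads 1.0. Heights are therefore
#' relative, which is what a fractional peak-height threshold acts on.
#'
#' @param values plDDT values in `[0, 100]`.
#' @param n_bins Number of bins (default 100).
#' @return Numeric vector of length `n_bins` with max 1.
#' @export
build_histogram <- function(values, n_bins = 100L) {
  values <- as.numeric(values)
  if (!length(values)) stopf("cannot build a histogram from zero values")
  if (anyNA(values) || any(values < 0 | values > 100))
    stopf("plDDT values must lie in [0, 100]")
  n_bins <- as.integer(n_bins)
  bin <- pmin(floor(values / 100 * n_bins) + 1L, n_bins)  # 100.0 -> last bin
  counts <- tabulate(bin, nbins = n_bins)
  counts / max(counts)
}

#' Detect peaks in a normalized histogram
#'
#' A candidate peak is a bin (or flat plateau, resolved to its midpoint,
#' left bin on even-width plateaus) strictly greater than its nearest
#' unequal neighbour on both sides; plateaus touching the histogram edge
#' have no lower neighbour there and are not peaks. Candidates below
#' `min_height` are dropped, then the minimum-distance constraint is
#' enforced greedily: candidates are visited in order of descending
#' height (ties: lower bin first) and discarded when within
#' `min_distance` bins (exclusive) of an already-accepted peak.
#'
#' @param histogram Numeric vector of values in `[0, 1]`.
#' @param params A [peak_params] object.
#' @return Data frame with columns `bin_index`, `height`, `plddt_value`
#'   (bin center) and `peak_class`, sorted by `bin_index`; zero rows when
#'   no peak survives.
#' @export
detect_peaks <- function(histogram, params = peak_params()) {
  h <- as.numeric(histogram)
  if (anyNA(h) || any(h < 0 | h > 1)) stopf("histogram values must lie in [0, 1]")
  n <- length(h)
  cand_bin <- integer(0); cand_height <- numeric(0)
  i <- 2L
  while (i <= n - 1L) {
    if (h[i] > h[i - 1L]) {
      j <- i                                     # extend over a flat plateau
      while (j < n && h[j + 1L] == h[i]) j <- j + 1L
      if (j < n && h[j + 1L] < h[i]) {
        cand_bin <- c(cand_bin, (i + j) %/% 2L)
        cand_height <- c(cand_height, h[i])
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  keep <- cand_height >= params$min_height
  cand_bin <- cand_bin[keep]; cand_height <- cand_height[keep]
  ord <- order(-cand_height, cand_bin)
  accepted <- integer(0)
  for (k in ord) {
    if (!length(accepted) ||
        all(abs(cand_bin[k] - accepted) >= params$min_distance))
      accepted <- c(accepted, cand_bin[k])
  }
  accepted <- sort(accepted)
  height <- cand_height[match(accepted, cand_bin)]
  center <- (accepted - 0.5) * 100 / params$n_bins
  data.frame(bin_index = accepted, height = height, plddt_value = center,
             peak_class = if (length(accepted))
               vapply(center, classify_peak, "") else character(0),
             stringsAsFactors = FALSE)
}

#' Confidence class of a plDDT value
#'
#' `low` below 50, `medium` in `[50, 70)`, `high` at or above 70 -- the
#' class boundaries used for histogram peaks when screening families.
#'
#' @param plddt_value plDDT in `[0, 100]`.
#' @return `"low"`, `"medium"` or `"high"`.
#' @export
classify_peak <- function(plddt_value) {
  if (is.na(plddt_value) || plddt_value < 0 || plddt_value > 100)
    stopf("plDDT value must lie in [0, 100]")
  if (plddt_value < 50) "low" else if (plddt_value < 70) "medium" else "high"
}

#' Build a family plDDT profile
#'
#' @param family_id Family accession.
#' @param member_plddts Named numeric vector: protein id -> domain mean
#'   plDDT.
#' @param params [peak_params] for histogram binning and peak detection.
#' @return A `family_profile` with the normalized histogram and detected,
#'   classified peaks.
#' @export
family_profile <- function(family_id, member_plddts, params = peak_params()) {
  if (is.null(names(member_plddts)) || any(!nzchar(names(member_plddts))))
    stopf("member_plddts must be named by protein id")
  hist <- build_histogram(member_plddts, params$n_bins)
  structure(list(family_id = family_id,
                 member_plddts = member_plddts,
                 histogram = hist,
                 peaks = detect_peaks(hist, params),
                 params = params),
            class = "family_profile")
}

#' @export
print.family_profile <- function(x, ...) {
  cat(sprintf("<family_profile> %s: %d members, %d peak(s)%s\n",
              x$family_id, length(x$member_plddts), nrow(x$peaks),
              if (nrow(x$peaks))
                paste0(" [", paste(sprintf("%s@%.1f", x$peaks$peak_class,
                                           x$peaks$plddt_value), collapse = ", "),
                       "]") else ""))
  invisible(x)
}

#' Is a family a rescue candidate?
#'
#' A family qualifies when it is large enough and its domain-plDDT
#' distribution is bimodal in the useful sense: one confident mode (high,
#' >= 70) that can supply templates, plus one medium or low mode that
#' could benefit from them.
#'
#' @param profile A [family_profile] with peaks detected.
#' @param min_members Minimum family size (default 100).
#' @return `TRUE` or `FALSE`.
#' @export
is_rescuable_bimodal <- function(profile, min_members = 100L) {
  stopifnot(inherits(profile, "family_profile"))
  classes <- profile$peaks$peak_class
  length(profile$member_plddts) >= min_members &&
    "high" %in% classes && any(c("low", "medium") %in% classes)
}

#' Rank families by low/high balance
#'
#' Balance score is `|n_below70 - n_at_or_above70| / n_total` over the
#' member domain plDDTs: 0 for a perfectly even split. Families are
#' sorted ascending by score; ties go to the larger family, then to
#' lexicographic family id.
#'
#' @param profiles List of [family_profile] objects (all rescue candidates).
#' @param k Number of families to return.
#' @return Character vector of up to `k` family ids, best-balanced first.
#' @export
rank_families <- function(profiles, k) {
  if (!length(profiles)) return(character(0))
  fam <- vapply(profiles, `[[`, "", "family_id")
  n_total <- vapply(profiles, function(p) length(p$member_plddts), integer(1))
  score <- vapply(profiles, function(p) {
    lo <- sum(p$member_plddts < 70)
    abs(lo - (length(p$member_plddts) - lo)) / length(p$member_plddts)
  }, numeric(1))
  ord <- order(score, -n_total, fam)
  if (k > length(profiles)) {
    warnf("requested %d families but only %d are available; returning all",
          k, length(profiles))
    k <- length(profiles)
  }
  fam[ord][seq_len(k)]
}

#' Serialize family profiles to JSON
#' @param profiles List of [family_profile] objects.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  payload <- lapply(profiles, function(p)
    list(family_id = p$family_id,
         member_plddts = as.list(p$member_plddts),
         histogram = p$histogram,
         peaks = p$peaks))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
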