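# Independent oracles used to check the package's implementations.
# Deliberately naive code: clarity and independence over speed.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_seq <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# Brute-force histogram: place every value by linear scan over bin edges.
oracle_histogram <- function(values, n_bins = 100) {
  edges <- seq(0, 100, length.out = n_bins + 1)
  counts <- integer(n_bins)
  for (v in values) {
    placed <- FALSE
    for (k in seq_len(n_bins)) {
      hi_ok <- if (k == n_bins) v <= edges[k + 1] else v < edges[k + 1]
      if (v >= edges[k] && hi_ok) { counts[k] <- counts[k] + 1L; placed <- TRUE; break }
    }
    stopifnot(placed)
  }
  counts / max(counts)
}

# Enumerate all local maxima (plateau midpoint, left bin on even widths,
# plateaus touching an edge excluded), then greedily filter: by
# descending height (ties: lower bin), drop anything closer than
# min_distance to an accepted peak.
oracle_peaks <- function(h, min_height = 0.03, min_distance = 19) {
  n <- length(h)
  runs <- rle(h)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  cand <- data.frame(bin = integer(0), height = numeric(0))
  for (k in seq_along(runs$values)) {
    l <- starts[k]; r <- ends[k]
    if (l == 1 || r == n) next
    if (h[l - 1] < h[l] && h[r + 1] < h[l])
      cand <- rbind(cand, data.frame(bin = (l + r) %/% 2, height = h[l]))
  }
  cand <- cand[cand$height >= min_height, , drop = FALSE]
  cand <- cand[order(-cand$height, cand$bin), , drop = FALSE]
  accepted <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (all(abs(cand$bin[i] - accepted) >= min_distance))
      accepted <- c(accepted, cand$bin[i])
  }
  as.integer(sort(accepted))
}

# Exhaustive global-alignment optimum under affine gaps: recursively
# enumerate every alignment path; a gap run of length L costs
# open + (L - 1) * extend (both negative).
oracle_align_score <- function(a, b, mat, open = -11, extend = -1) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, last, sc) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, sc); return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      rec(i + 1, j + 1, "M", sc + mat[ca[i], cb[j]])
    if (i <= length(ca))            # ca[i] against a gap in b
      rec(i + 1, j, "A", sc + if (last == "A") extend else open)
    if (j <= length(cb))            # cb[j] against a gap in a
      rec(i, j + 1, "B", sc + if (last == "B") extend else open)
  }
  rec(1, 1, "start", 0)
  best
}

# Exact one-sided signed-rank p by enumerating all 2^n sign vectors.
oracle_wilcoxon_p <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  hits <- 0
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1) == 1
    w <- sum(r[signs])
    if (alternative == "greater") {
      if (w >= w_obs) hits <- hits + 1
    } else if (w <= w_obs) hits <- hits + 1
  }
  hits / 2^n
}

# Small ready-made structure model.
toy_model <- function(id = "P1", n = 8, plddt = NULL, seed = 1) {
  withr::with_seed(seed, {
    seq1 <- random_seq(n)
    structure_model(id, seq1, plddt %||% runif(n, 20, 95),
                    ca_coords = cbind(seq_len(n), 0, 0))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
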