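#' Specification of a synthetic protein family
#'
#' Describes one simulated family of homologous single-domain proteins.
#' Member domain plDDTs are drawn from a two-component truncated-Gaussian
#' mixture on `[0, 100]` (the bimodal shape the pipeline screens for),
#' and each member's sequence is the family consensus mutated at a rate
#' tied to its mixture component, so low-confidence members are also the
#' more diverged ones.
#'
#' @param family_id Family accession.
#' @param n_members Number of members (default 150).
#' @param length Protein length in residues (default 120).
#' @param domain_start,domain_end Domain span, 1-based inclusive
#'   (default 11..110).
#' @param consensus Optional consensus sequence; randomly drawn when
#'   `NULL`.
#' @param mixture_means,mixture_sds,mixture_weights Two-component
#'   mixture of the domain mean plDDT; weights must sum to 1.
#' @param identity_decay Upper bound on the per-site mutation rate of
#'   low-confidence members (high-confidence members mutate at up to a
#'   sixth of it), in `[0, 1]`.
#' @param fragment_fraction Probability that a member is flagged as a
#'   fragment entry.
#' @param seed Integer seed; the whole family is a deterministic
#'   function of the spec.
#' @return A `family_spec`.
#' @export
family_spec <- function(family_id, n_members = 150L, length = 120L,
                        domain_start = 11L, domain_end = 110L,
                        consensus = NULL,
                        mixture_means = c(40, 85), mixture_sds = c(2, 2),
                        mixture_weights = c(0.5, 0.5),
                        identity_decay = 0.6, fragment_fraction = 0.1,
                        seed = 1L) {
  if (abs(sum(mixture_weights) - 1) > 1e-9) stopf("mixture weights must sum to 1")
  if (any(mixture_means < 0 | mixture_means > 100))
    stopf("mixture means must lie in [0, 100]")
  if (identity_decay < 0 || identity_decay > 1)
    stopf("identity_decay must lie in [0, 1]")
  if (fragment_fraction < 0 || fragment_fraction > 1)
    stopf("fragment_fraction must lie in [0, 1]")
  if (!(domain_start >= 1 && domain_start <= domain_end && domain_end <= length))
    stopf("domain span must satisfy 1 <= start <= end <= length")
  if (!is.null(consensus)) check_sequence(consensus)
  structure(list(family_id = family_id, n_members = as.integer(n_members),
                 length = as.integer(length),
                 domain_start = as.integer(domain_start),
                 domain_end = as.integer(domain_end),
                 consensus = consensus,
                 mixture_means = mixture_means, mixture_sds = mixture_sds,
                 mixture_weights = mixture_weights,
                 identity_decay = identity_decay,
                 fragment_fraction = fragment_fraction,
                 seed = as.integer(seed)),
            class = "family_spec")
}

rtrunc_norm <- function(n, mean, sd, lo = 0, hi = 100) {
  u <- runif(n, pnorm((lo - mean) / sd), pnorm((hi - mean) / sd))
  qnorm(u) * sd + mean
}

# Idealized alpha-helical Calpha trace: 100 degrees and 1.5 A rise per
# residue on a 2.3 A radius. Geometry is a placeholder; confidence is
# decoupled from coordinates throughout the pipeline.
helix_trace <- function(n) {
  t <- (seq_len(n) - 1) * 100 * pi / 180
  cbind(x = 2.3 * cos(t), y = 2.3 * sin(t), z = 1.5 * (seq_len(n) - 1))
}

mutate_sequence <- function(consensus, rate) {
  letters1 <- strsplit(consensus, "")[[1L]]
  hit <- runif(length(letters1)) < rate
  if (any(hit)) {
    letters1[hit] <- vapply(letters1[hit], function(a)
      sample(setdiff(AA1, a), 1L), "")
  }
  list(sequence = paste(letters1, collapse = ""),
       identity_pct = 100 * (1 - mean(hit)))
}

#' Generate a synthetic protein family
#'
#' Draws every member of the family described by `spec`: its mixture
#' component, domain mean plDDT (truncated normal), a smooth per-residue
#' plDDT profile whose domain mean equals the drawn value exactly (with
#' noisier, lower-confidence termini outside the domain), a mutated copy
#' of the consensus sequence, a helix-like Calpha trace, and a fragment
#' flag. Deterministic given the spec (including its seed).
#'
#' @param spec A [family_spec].
#' @return List with `models` (named list of [structure_model]),
#'   `annotations` (domain-annotation data frame) and `truth` (the
#'   generator's bookkeeping: component, drawn domain mean, realized
#'   identity to the consensus, mutation rate, fragment flag).
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(spec$seed, {
    L <- spec$length
    consensus <- spec$consensus %||%
      paste(sample(AA1, L, replace = TRUE), collapse = "")
    if (nchar(consensus) != L) stopf("consensus length != spec length")
    dom <- spec$domain_start:spec$domain_end
    n <- spec$n_members
    component <- sample.int(2L, n, replace = TRUE, prob = spec$mixture_weights)
    ids <- sprintf("%s_%04d", spec$family_id, seq_len(n))
    models <- vector("list", n)
    truth <- data.frame(protein_id = ids, component = component,
                        domain_plddt = NA_real_, mean_plddt = NA_real_,
                        mutation_rate = NA_real_, planted_identity = NA_real_,
                        is_fragment = runif(n) < spec$fragment_fraction,
                        stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      ci <- component[i]
      m <- rtrunc_norm(1L, spec$mixture_means[ci], spec$mixture_sds[ci])
      # low-confidence members are the diverged ones; confident members
      # stay close to the consensus so they make informative templates
      rate <- if (spec$mixture_means[ci] < 70)
        runif(1L, min(0.05, spec$identity_decay), spec$identity_decay)
      else runif(1L, 0, spec$identity_decay / 6)
      mut <- mutate_sequence(consensus, rate)
      noise <- as.numeric(stats::filter(rnorm(L, 0, 6), rep(1 / 4, 4),
                                        circular = TRUE))
      noise <- noise - mean(noise[dom])          # domain mean == drawn mean
      shrink <- min(1,
                    if (max(noise) > 0) (100 - m) / max(noise) else 1,
                    if (min(noise) < 0) -m / min(noise) else 1)
      plddt <- m + noise * shrink
      taper <- rep(0, L)                         # termini outside the domain
      if (spec$domain_start > 1)
        taper[1:(spec$domain_start - 1)] <- seq(8, 2, length.out = spec$domain_start - 1)
      if (spec$domain_end < L)
        taper[(spec$domain_end + 1):L] <- seq(2, 8, length.out = L - spec$domain_end)
      plddt <- plddt - taper
      plddt[-dom] <- pmin(pmax(plddt[-dom], 0), 100)
      models[[i]] <- structure_model(ids[i], mut$sequence, plddt,
                                     ca_coords = helix_trace(L))
      truth$domain_plddt[i] <- m
      truth$mean_plddt[i] <- mean(plddt)
      truth$mutation_rate[i] <- rate
      truth$planted_identity[i] <- mut$identity_pct
    }
    names(models) <- ids
    annotations <- data.frame(protein_id = ids, family_id = spec$family_id,
                              start = spec$domain_start, end = spec$domain_end,
                              is_fragment = truth$is_fragment,
                              sequence = vapply(models, `[[`, "", "sequence"),
                              stringsAsFactors = FALSE, row.names = NULL)
    list(models = models, annotations = annotations, truth = truth,
         spec = spec, consensus = consensus)
  })
}

#' Response model of the mock prediction backend
#'
#' A piecewise-linear-in-identity plDDT response used for testing the
#' pipeline without a neural network: re-predicting with templates
#' changes the mean plDDT by
#' `gain * (identity - floor) / (100 - floor) + noise`. In
#' single-sequence mode the response follows that line everywhere, so
#' templates more diverged than `identity_floor` actively hurt; in MSA
#' mode the MSA dominates and templates are partially ignored -- the
#' gain is attenuated by `msa_attenuation` and floored at zero below
#' `identity_floor` -- with smaller run-to-run noise. This is a test
#' harness emulating the qualitative behaviour of template-based
#' re-prediction, not a scientific model.
#'
#' @param gain_at_full_identity Expected plDDT gain at 100% identity in
#'   single-sequence mode (default 25).
#' @param identity_floor Percent identity below which templates stop
#'   helping (default 30).
#' @param sd_single,sd_msa Run-to-run noise SDs; single-sequence mode
#'   must be at least as variable as MSA mode.
#' @param msa_attenuation Fraction of the gain retained in MSA mode
#'   (default 0.4).
#' @param seed Base seed mixed into each request's noise draw.
#' @return A `mock_response_spec`.
#' @export
mock_response_spec <- function(gain_at_full_identity = 25,
                               identity_floor = 30,
                               sd_single = 8, sd_msa = 5,
                               msa_attenuation = 0.35, seed = 0L) {
  if (sd_single < sd_msa)
    stopf("single-sequence mode must be at least as variable as MSA mode")
  if (identity_floor < 0 || identity_floor >= 100)
    stopf("identity_floor must lie in [0, 100)")
  structure(list(gain_at_full_identity = gain_at_full_identity,
                 identity_floor = identity_floor,
                 sd_single = sd_single, sd_msa = sd_msa,
                 msa_attenuation = msa_attenuation, seed = as.integer(seed)),
            class = "mock_response_spec")
}

#' Mock prediction backend
#'
#' Serves the generated first-round model as the no-template baseline
#' and applies the [mock_response_spec] plDDT response in the template
#' modes, using the alignment identity of the closest supplied template.
#' Deterministic per `(request seed, protein id, mode)`.
#'
#' @param models Named list of baseline [structure_model]s (as produced
#'   by [generate_family]), keyed by protein id.
#' @param response A [mock_response_spec].
#' @return A `mock_backend`.
#' @export
mock_backend <- function(models, response = mock_response_spec()) {
  stopifnot(inherits(response, "mock_response_spec"))
  if (is.null(names(models))) stopf("baseline models must be named by protein id")
  structure(list(models = models, response = response),
            class = c("mock_backend", "prediction_backend"))
}

#' @rdname predict_structure
#' @export
predict_structure.mock_backend <- function(backend, request,
                                           domain_span = NULL, ...) {
  stopifnot(inherits(request, "prediction_request"))
  base <- backend$models[[request$protein_id]]
  if (is.null(base))
    stopf("mock backend has no baseline model for %s", request$protein_id)
  if (request$mode == "no_template_msa")
    return(prediction_result(request$protein_id, request$mode, base, domain_span))
  if (!length(request$templates))
    stopf("template mode request without templates violates the backend contract")
  resp <- backend$response
  identity <- closest_template_identity(request$sequence,
                                        request$templates)$identity_pct
  s <- (identity - resp$identity_floor) / (100 - resp$identity_floor)
  gain <- if (request$mode == "template_single") {
    resp$gain_at_full_identity * s
  } else {
    resp$gain_at_full_identity * resp$msa_attenuation * max(s, 0)
  }
  sd <- if (request$mode == "template_single") resp$sd_single else resp$sd_msa
  noise <- with_seed(derive_seed(request$seed + resp$seed, request$protein_id,
                                 request$mode),
                     if (sd > 0) rnorm(1L, 0, sd) else 0)
  delta <- gain + noise
  new_mean <- min(max(mean(base$plddt) + delta, 0), 100)
  plddt <- pmin(pmax(base$plddt + (new_mean - mean(base$plddt)), 0), 100)
  model <- structure_model(base$protein_id, base$sequence, plddt,
                           ca_coords = base$ca_coords)
  prediction_result(request$protein_id, request$mode, model, domain_span)
}

#' Write a synthetic family to disk
#'
#' Materializes a generated family as model files plus the domain TSV
#' and truth CSV, in the layout the file-based pipeline entry points
#' consume.
#'
#' @param family Output of [generate_family].
#' @param dir Output directory (created if needed).
#' @param format Model file format (default `"pdb"`).
#' @return `dir`, invisibly.
#' @export
write_family <- function(family, dir, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  ext <- if (format == "pdb") "pdb" else "cif"
  dir.create(file.path(dir, "models"), recursive = TRUE, showWarnings = FALSE)
  for (m in family$models)
    write_model(m, file.path(dir, "models", paste0(m$protein_id, ".", ext)),
                format)
  write_domain_table(family$annotations, file.path(dir, "domains.tsv"))
  write.csv(family$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
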