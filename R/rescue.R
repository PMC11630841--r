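PREDICTION_MODES <- c("no_template_msa", "template_msa", "template_single")

#' Construct a prediction request
#'
#' The unit of work handed to a prediction backend: one sequence, the
#' mode to run it in, and the structural templates to supply. The MSA
#' flag is derived from the mode -- templates plus a single sequence is
#' the only MSA-free mode.
#'
#' @param protein_id Accession.
#' @param sequence Query sequence.
#' @param mode One of `"no_template_msa"`, `"template_msa"`,
#'   `"template_single"`.
#' @param templates List of [structure_model] templates; must be empty
#'   for `no_template_msa`.
#' @param seed Integer seed forwarded to stochastic backends.
#' @return A `prediction_request`.
#' @export
prediction_request <- function(protein_id, sequence, mode, templates = list(),
                               seed = 1L) {
  mode <- match.arg(mode, PREDICTION_MODES)
  if (mode == "no_template_msa" && length(templates))
    stopf("no_template_msa requests must not carry templates")
  if (mode != "no_template_msa" && !length(templates))
    stopf("%s requests need at least one template", mode)
  structure(list(protein_id = protein_id, sequence = sequence, mode = mode,
                 templates = templates,
                 msa_enabled = mode != "template_single",
                 seed = as.integer(seed)),
            class = "prediction_request")
}

#' Construct a prediction result
#'
#' @param protein_id Accession.
#' @param mode Prediction mode of the run.
#' @param model The predicted [structure_model].
#' @param domain_span Optional 1-based inclusive `(start, end)` over
#'   which the domain plDDT is computed.
#' @return A `prediction_result` with `mean_plddt` and `domain_plddt`.
#' @export
prediction_result <- function(protein_id, mode, model, domain_span = NULL) {
  mode <- match.arg(mode, PREDICTION_MODES)
  stopifnot(inherits(model, "structure_model"))
  structure(list(protein_id = protein_id, mode = mode, model = model,
                 mean_plddt = mean(model$plddt),
                 domain_plddt = if (is.null(domain_span)) NA_real_
                                else mean_plddt(model, domain_span)),
            class = "prediction_result")
}

#' Run one prediction through a backend
#'
#' Generic dispatched on the backend object; implementations must return
#' a `prediction_result` for the request's protein and mode.
#'
#' @param backend A backend object (e.g. [mock_backend] or
#'   [command_backend]).
#' @param request A [prediction_request].
#' @param ... Implementation-specific arguments (e.g. `domain_span`).
#' @return A [prediction_result].
#' @export
predict_structure <- function(backend, request, ...) UseMethod("predict_structure")

#' Build the family template bank
#'
#' Collects the confident first-round models -- mean plDDT at or above
#' `min_plddt` (70 by convention, the boundary value included) -- to be
#' reused as structural templates, sorted by descending confidence.
#'
#' @param results List of [prediction_result]s from the no-template MSA
#'   run of one family.
#' @param family_id Family accession.
#' @param min_plddt Confidence cutoff (default 70).
#' @return A `template_bank`; empty (with a warning) when no model
#'   qualifies, in which case the family is skipped downstream.
#' @export
build_template_bank <- function(results, family_id, min_plddt = 70) {
  if (length(results)) {
    ok <- vapply(results, inherits, logical(1), "prediction_result")
    if (!all(ok)) stopf("all bank inputs must be prediction_results")
    modes <- vapply(results, `[[`, "", "mode")
    if (any(modes != "no_template_msa"))
      stopf("template banks are built from no_template_msa runs only")
  }
  plddts <- vapply(results, `[[`, numeric(1), "mean_plddt")
  keep <- which(plddts >= min_plddt)
  keep <- keep[order(-plddts[keep])]
  if (!length(keep))
    warnf("family %s: no model reaches plDDT %.0f; empty template bank",
          family_id, min_plddt)
  structure(list(family_id = family_id,
                 templates = lapply(results[keep], `[[`, "model"),
                 template_plddts = plddts[keep],
                 min_plddt = min_plddt),
            class = "template_bank")
}

#' @export
print.template_bank <- function(x, ...) {
  cat(sprintf("<template_bank> %s: %d template(s) with plDDT >= %.0f\n",
              x$family_id, length(x$templates), x$min_plddt))
  invisible(x)
}

#' Best pick between the two template modes
#'
#' The model with the higher mean plDDT wins; on a tie the template+MSA
#' model is preferred as the lower-variance mode.
#'
#' @param template_msa_plddt,template_single_plddt Mean plDDTs.
#' @return List with `mode` and `plddt`.
#' @export
best_pick <- function(template_msa_plddt, template_single_plddt) {
  if (template_single_plddt > template_msa_plddt)
    list(mode = "template_single", plddt = template_single_plddt)
  else list(mode = "template_msa", plddt = template_msa_plddt)
}

#' Rescue one cohort protein
#'
#' Runs the protein through the backend in the three modes (the baseline
#' no-template run is reused when supplied), selects the best-pick
#' template model, and classifies the protein as rescued when its
#' baseline mean plDDT was below the confidence threshold and the best
#' pick reaches it. A protein's own first-round model may sit in the
#' bank (that is the design of the positive control, where the template
#' coincides with the protein to be modelled); set `exclude_self = TRUE`
#' to remove it from the protein's own template set.
#'
#' @param protein_id,sequence Query protein.
#' @param family_id Family accession.
#' @param bank A [template_bank] (non-empty).
#' @param backend Prediction backend.
#' @param seed Integer seed forwarded to the backend.
#' @param baseline Optional cached no-template [prediction_result].
#' @param domain_span Optional domain `(start, end)` for domain-level
#'   plDDT columns.
#' @param max_templates Maximum templates per request (default 4, the
#'   highest-plDDT ones).
#' @param exclude_self Drop the protein's own model from its template
#'   set (default `FALSE`).
#' @param threshold Rescue confidence threshold (default 70; "reaches
#'   the threshold" is inclusive).
#' @return One-row data frame (the rescue record).
#' @export
run_rescue <- function(protein_id, sequence, family_id, bank, backend,
                       seed = 1L, baseline = NULL, domain_span = NULL,
                       max_templates = 4L, exclude_self = FALSE,
                       threshold = 70) {
  stopifnot(inherits(bank, "template_bank"))
  templates <- bank$templates
  if (exclude_self) {
    templates <- templates[vapply(templates, `[[`, "", "protein_id") != protein_id]
  }
  if (!length(templates))
    stopf("template bank for family %s is empty%s", family_id,
          if (exclude_self) " after self-exclusion" else "")
  templates <- templates[seq_len(min(length(templates), max_templates))]

  run <- function(mode, tmpl) {
    req <- prediction_request(protein_id, sequence, mode, tmpl, seed)
    tryCatch(predict_structure(backend, req, domain_span = domain_span),
             error = function(e) {
               warnf("backend failed for %s in mode %s: %s", protein_id, mode,
                     conditionMessage(e))
               NULL
             })
  }
  if (is.null(baseline)) baseline <- run("no_template_msa", list())
  res_msa <- run("template_msa", templates)
  res_sgl <- run("template_single", templates)

  pl <- function(r) if (is.null(r)) NA_real_ else r$mean_plddt
  dpl <- function(r) if (is.null(r)) NA_real_ else r$domain_plddt
  base_pl <- pl(baseline); msa_pl <- pl(res_msa); sgl_pl <- pl(res_sgl)

  if (!is.na(msa_pl) && !is.na(sgl_pl)) {
    bp <- best_pick(msa_pl, sgl_pl)
  } else if (!is.na(msa_pl)) {
    bp <- list(mode = "template_msa", plddt = msa_pl)
  } else if (!is.na(sgl_pl)) {
    bp <- list(mode = "template_single", plddt = sgl_pl)
  } else bp <- list(mode = NA_character_, plddt = NA_real_)

  rescued <- if (is.na(base_pl)) NA
  else if (base_pl >= threshold) FALSE         # already confident: a control
  else if (!is.na(bp$plddt)) bp$plddt >= threshold
  else NA

  closest <- closest_template_identity(sequence, templates)
  data.frame(protein_id = protein_id, family_id = family_id,
             baseline_plddt = base_pl,
             template_msa_plddt = msa_pl,
             template_single_plddt = sgl_pl,
             best_pick_plddt = bp$plddt, best_pick_mode = bp$mode,
             rescued = rescued,
             closest_template_id = closest$template_id,
             closest_template_identity_pct = closest$identity_pct,
             baseline_domain_plddt = dpl(baseline),
             template_msa_domain_plddt = dpl(res_msa),
             template_single_domain_plddt = dpl(res_sgl),
             stringsAsFactors = FALSE)
}

#' Command-template prediction backend
#'
#' Adapter for an external structure predictor invoked from the shell
#' (e.g. a ColabFold wrapper). For each request it writes the query
#' FASTA and a directory of Calpha template PDBs, substitutes them into
#' the command template, runs it, and reads the predicted model back.
#' The command template may use the placeholders `{fasta}`,
#' `{templates}`, `{out}` and `{msa}` (`1`/`0`).
#'
#' @param command Shell command template.
#' @param workdir Scratch directory for the exchanged files.
#' @return A `command_backend`.
#' @export
command_backend <- function(command, workdir = tempdir()) {
  stopifnot(is.character(command), length(command) == 1L)
  structure(list(command = command, workdir = workdir),
            class = c("command_backend", "prediction_backend"))
}

#' @rdname predict_structure
#' @param domain_span Optional domain `(start, end)` for the result's
#'   domain plDDT.
#' @export
predict_structure.command_backend <- function(backend, request,
                                              domain_span = NULL, ...) {
  stopifnot(inherits(request, "prediction_request"))
  dir <- file.path(backend$workdir,
                   paste0(request$protein_id, "_", request$mode))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "query.fasta")
  seqs <- Biostrings::AAStringSet(request$sequence)
  names(seqs) <- request$protein_id
  Biostrings::writeXStringSet(seqs, fasta)
  tmpl_dir <- file.path(dir, "templates")
  dir.create(tmpl_dir, showWarnings = FALSE)
  for (t in request$templates)
    write_model(t, file.path(tmpl_dir, paste0(t$protein_id, ".pdb")), "pdb")
  out <- file.path(dir, "model.pdb")
  cmd <- backend$command
  for (sub in list(c("{fasta}", fasta), c("{templates}", tmpl_dir),
                   c("{out}", out),
                   c("{msa}", if (request$msa_enabled) "1" else "0")))
    cmd <- gsub(sub[1], sub[2], cmd, fixed = TRUE)
  status <- system(cmd)
  if (status != 0L) stopf("predictor command failed (exit %d): %s", status, cmd)
  if (!file.exists(out)) stopf("predictor command produced no model at %s", out)
  model <- read_model(out, protein_id = request$protein_id)
  prediction_result(request$protein_id, request$mode, model, domain_span)
}
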