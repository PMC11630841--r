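#' Construct a structure model
#'
#' A `structure_model` holds one protein's predicted structure at the level
#' this pipeline needs: its sequence, the per-residue plDDT confidence
#' (0-100, conventionally stored in the B-factor field of AlphaFold-style
#' coordinate files) and, optionally, a Calpha trace.
#'
#' @param protein_id Accession string.
#' @param sequence One-letter amino-acid string (20 standard letters plus
#'   `X` for nonstandard residues).
#' @param plddt Numeric vector, one value per residue, each in `[0, 100]`.
#' @param ca_coords Optional numeric matrix with one row per residue and
#'   columns x, y, z (Angstrom).
#' @param source_path Optional path the model was read from.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(protein_id, sequence, plddt, ca_coords = NULL,
                            source_path = NULL) {
  if (!is.character(protein_id) || length(protein_id) != 1L || !nzchar(protein_id))
    stopf("`protein_id` must be a non-empty string")
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stopf("`sequence` must be a non-empty string")
  check_sequence(sequence)
  plddt <- as.numeric(plddt)
  if (length(plddt) != nchar(sequence))
    stopf("length(plddt) [%d] != number of residues [%d] for %s",
          length(plddt), nchar(sequence), protein_id)
  if (anyNA(plddt) || any(plddt < 0 | plddt > 100))
    stopf("plDDT values must lie in [0, 100] (protein %s)", protein_id)
  if (!is.null(ca_coords)) {
    ca_coords <- as.matrix(ca_coords)
    if (nrow(ca_coords) != nchar(sequence) || ncol(ca_coords) != 3L)
      stopf("ca_coords must be an L x 3 matrix matching the sequence length")
    storage.mode(ca_coords) <- "double"
    dimnames(ca_coords) <- list(NULL, c("x", "y", "z"))
  }
  structure(list(protein_id = protein_id, sequence = sequence, plddt = plddt,
                 ca_coords = ca_coords, source_path = source_path),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s: %d residues, mean plDDT %.2f%s\n",
              x$protein_id, nchar(x$sequence), mean(x$plddt),
              if (is.null(x$ca_coords)) ", no coordinates" else ""))
  invisible(x)
}

AA1 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y")

check_sequence <- function(sequence) {
  letters1 <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(letters1), c(AA1, "X"))
  if (length(bad))
    stopf("sequence contains characters outside the 20 amino acids + X: %s",
          paste(bad, collapse = ", "))
  invisible(letters1)
}

aa_three_to_one <- function(resid) {
  one <- suppressWarnings(bio3d::aa321(resid))
  one[is.na(one) | !(one %in% AA1)] <- "X"   # nonstandard residues kept as X
  one
}

aa_one_to_three <- function(letters1) {
  three <- suppressWarnings(bio3d::aa123(letters1))
  three[is.na(three) | letters1 == "X"] <- "UNK"
  three
}

#' Read an AlphaFold-style structure model
#'
#' Parses a single-chain PDB or mmCIF file and extracts per-residue plDDT
#' from the temperature-factor (B-factor) field of each residue's
#' representative atom: the Calpha where present, otherwise the residue's
#' first atom. Residues are ordered by residue number and the sequence is
#' derived from the residue names (nonstandard residues become `X`).
#'
#' @param path Path to a `.pdb`, `.cif`/`.mmcif` file.
#' @param format `"auto"` (default, by extension), `"pdb"` or `"mmcif"`.
#' @param protein_id Accession to assign; defaults to the file stem.
#' @return A [structure_model].
#' @export
read_model <- function(path, format = c("auto", "pdb", "mmcif"),
                       protein_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (format == "auto") format <- guess_format(path)
  atoms <- switch(format,
    pdb = read_pdb_atoms(path),
    mmcif = read_mmcif_atoms(path))
  if (nrow(atoms) == 0L) stopf("no ATOM records parsed from %s", path)
  chains <- unique(atoms$chain)
  if (length(chains) > 1L)
    stopf("multi-chain models are not supported: %s has chains %s",
          path, paste(chains, collapse = ", "))
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  resnos <- unique(atoms$resno)
  idx <- split(seq_len(nrow(atoms)), factor(atoms$resno, levels = resnos))
  rep_row <- vapply(idx, function(i) {
    ca <- i[atoms$elety[i] == "CA"]
    if (length(ca)) ca[1L] else i[1L]
  }, integer(1))
  plddt <- atoms$b[rep_row]
  seq1 <- paste(aa_three_to_one(atoms$resid[rep_row]), collapse = "")
  has_ca <- vapply(idx, function(i) any(atoms$elety[i] == "CA"), logical(1))
  coords <- NULL
  if (all(has_ca)) {
    ca_row <- vapply(idx, function(i) i[atoms$elety[i] == "CA"][1L], integer(1))
    coords <- cbind(x = atoms$x[ca_row], y = atoms$y[ca_row], z = atoms$z[ca_row])
  }
  structure_model(protein_id = protein_id %||% strip_ext(path),
                  sequence = seq1, plddt = plddt, ca_coords = coords,
                  source_path = path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdb") "pdb"
  else if (ext %in% c("cif", "mmcif")) "mmcif"
  else stopf("cannot guess model format from extension '.%s' (%s)", ext, path)
}

strip_ext <- function(path) sub("\\.[^.]+$", "", basename(path))

read_pdb_atoms <- function(path) {
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
                  error = function(e) stopf("failed to parse %s as PDB: %s",
                                            path, conditionMessage(e)))
  a <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  data.frame(resid = a$resid, resno = a$resno,
             chain = ifelse(is.na(a$chain), "A", a$chain),
             elety = a$elety, x = a$x, y = a$y, z = a$z, b = a$b,
             stringsAsFactors = FALSE)
}

# Minimal PDBx/mmCIF reader for the atom_site loop: the category is a
# whitespace-separated table whose column order is declared by its
# _atom_site.* tags, so the parse is driven by the declared header.
read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  start <- grep("^_atom_site\\.", lines)
  if (!length(start)) stopf("failed to parse %s as mmCIF: no _atom_site loop", path)
  tag_lines <- lines[start]
  tags <- sub("^_atom_site\\.", "", trimws(tag_lines))
  body_from <- max(start) + 1L
  rows <- character(0)
  for (i in body_from:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" ) next
    if (startsWith(ln, "#") || startsWith(ln, "_") || startsWith(ln, "loop_") ||
        startsWith(ln, "data_")) break
    rows <- c(rows, ln)
  }
  if (!length(rows)) stopf("failed to parse %s as mmCIF: empty atom_site loop", path)
  fields <- strsplit(rows, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != length(tags)))
    stopf("failed to parse %s as mmCIF: row %d has %d fields, expected %d",
          path, which(nf != length(tags))[1L], nf[nf != length(tags)][1L],
          length(tags))
  tab <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(tab) <- tags
  col <- function(main, alt = NULL) {
    if (main %in% names(tab)) tab[[main]]
    else if (!is.null(alt) && alt %in% names(tab)) tab[[alt]]
    else stopf("failed to parse %s as mmCIF: missing _atom_site.%s", path, main)
  }
  keep <- col("group_PDB") == "ATOM"
  out <- data.frame(
    resid = col("label_comp_id"),
    resno = as.integer(col("auth_seq_id", "label_seq_id")),
    chain = col("auth_asym_id", "label_asym_id"),
    elety = col("label_atom_id"),
    x = as.numeric(col("Cartn_x")), y = as.numeric(col("Cartn_y")),
    z = as.numeric(col("Cartn_z")),
    b = as.numeric(col("B_iso_or_equiv")),
    stringsAsFactors = FALSE)
  out[keep, , drop = FALSE]
}

#' Write a structure model as a Calpha-only PDB or mmCIF file
#'
#' Emits one Calpha ATOM record per residue with occupancy 1.00 and the
#' plDDT in the temperature-factor column, formatted to two decimals --
#' the convention used by AlphaFold model files and sufficient for
#' feeding templates to a prediction backend.
#'
#' @param model A [structure_model] with `ca_coords`.
#' @param path Output file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "pdb", "mmcif")) {
  stopifnot(inherits(model, "structure_model"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (is.null(model$ca_coords))
    stopf("cannot write %s: model has no Calpha coordinates", model$protein_id)
  if (any(model$plddt < 0 | model$plddt > 100))
    stopf("plDDT outside [0, 100]")
  letters1 <- strsplit(model$sequence, "")[[1]]
  res3 <- aa_one_to_three(letters1)
  n <- length(letters1)
  xyz <- model$ca_coords
  lines <- if (format == "pdb") {
    c(sprintf("ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
              seq_len(n), res3, seq_len(n), xyz[, 1], xyz[, 2], xyz[, 3],
              1.00, model$plddt),
      "TER", "END")
  } else {
    c(sprintf("data_%s", model$protein_id), "#", "loop_",
      paste0("_atom_site.",
             c("group_PDB", "id", "type_symbol", "label_atom_id",
               "label_alt_id", "label_comp_id", "label_asym_id",
               "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
               "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
               "B_iso_or_equiv", "auth_seq_id", "auth_asym_id",
               "pdbx_PDB_model_num")),
      sprintf("ATOM %d C CA . %s A 1 %d ? %.3f %.3f %.3f 1.00 %.2f %d A 1",
              seq_len(n), res3, seq_len(n), xyz[, 1], xyz[, 2], xyz[, 3],
              model$plddt, seq_len(n)),
      "#")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Mean plDDT of a model, optionally over a residue span
#'
#' @param model A [structure_model].
#' @param span Optional integer pair `(start, end)`, 1-based inclusive
#'   (Pfam/PDB convention); whole protein when absent.
#' @return Arithmetic mean plDDT.
#' @export
mean_plddt <- function(model, span = NULL) {
  stopifnot(inherits(model, "structure_model"))
  L <- length(model$plddt)
  if (is.null(span)) return(mean(model$plddt))
  span <- as.integer(span)
  if (length(span) != 2L || anyNA(span) || span[1] < 1L || span[2] > L ||
      span[1] > span[2])
    stopf("span (%s) out of bounds for a %d-residue protein",
          paste(span, collapse = ","), L)
  mean(model$plddt[span[1]:span[2]])
}

#' Read all models in a directory
#'
#' @param dir Directory containing `*.pdb` / `*.cif` files (a single file
#'   path is also accepted).
#' @return Named list of [structure_model] objects, keyed by protein id.
#' @export
read_models <- function(dir) {
  paths <- if (dir.exists(dir)) {
    list.files(dir, pattern = "\\.(pdb|cif|mmcif)$", full.names = TRUE)
  } else dir
  models <- lapply(paths, read_model)
  names(models) <- vapply(models, `[[`, "", "protein_id")
  models
}

#' Read a domain-annotation table
#'
#' Tab-separated table with header columns `protein_id`, `family_id`,
#' `start`, `end`, `is_fragment` and optionally `sequence`. Spans are
#' 1-based inclusive residue coordinates of the annotated domain.
#'
#' @param path TSV file path.
#' @return A data frame with one row per domain annotation.
#' @export
read_domain_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("protein_id", "family_id", "start", "end", "is_fragment")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stopf("domain table %s is missing required column(s): %s",
          path, paste(missing, collapse = ", "))
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) | v != round(v))
    if (length(bad))
      stopf("non-integer '%s' in domain table row %d", col, bad[1L])
    tab[[col]] <- as.integer(v)
  }
  bad <- which(tab$start < 1L | tab$start > tab$end)
  if (length(bad))
    stopf("invalid span (start %d, end %d) in domain table row %d",
          tab$start[bad[1L]], tab$end[bad[1L]], bad[1L])
  tab$is_fragment <- parse_logical(tab$is_fragment)
  if (!"sequence" %in% names(tab)) tab$sequence <- NA_character_
  if (any(!is.na(tab$sequence))) {
    too_long <- which(!is.na(tab$sequence) & tab$end > nchar(tab$sequence))
    if (length(too_long))
      stopf("domain end exceeds protein length in domain table row %d",
            too_long[1L])
  }
  tab[c("protein_id", "family_id", "start", "end", "is_fragment", "sequence")]
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  v <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[v %in% c("FALSE", "F", "0", "NO")] <- FALSE
  if (anyNA(out))
    stopf("cannot interpret is_fragment value '%s' as logical", v[is.na(out)][1L])
  out
}

#' Write a domain-annotation table
#' @param annotations Data frame as returned by [read_domain_table].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
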