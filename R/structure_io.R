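# Multi-model PDB input/output for single-chain coarse structures.
#
# The rest of the package consumes two coordinate views per residue: the
# C-alpha position and an "interaction center" (side-chain heavy-atom
# centroid, falling back to C-alpha for glycine or side-chain-less input).
# Author residue numbering is deliberately discarded: the free-energy model
# is positional, and numbering gaps would corrupt internal-loop lengths.

AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
AA_123 <- setNames(names(AA_321), AA_321)

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Construct a structure model
#'
#' A `structure_model` holds one conformation of a single chain: one-letter
#' amino-acid codes plus two n-by-3 coordinate matrices (angstroms), the
#' C-alpha trace and the per-residue interaction centers. Residues are
#' implicitly numbered `1..n` in chain order.
#'
#' @param aa Character vector of one-letter amino-acid codes.
#' @param ca Numeric n-by-3 matrix of C-alpha coordinates.
#' @param center Numeric n-by-3 matrix of interaction-center coordinates;
#'   defaults to `ca`.
#' @param model_id Identifier string.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(aa, ca, center = ca, model_id = "1") {
  aa <- as.character(aa)
  ca <- as.matrix(ca)
  center <- as.matrix(center)
  n <- length(aa)
  if (n < 1L) abort("structure_model needs at least one residue")
  if (!all(dim(ca) == c(n, 3L)) || !all(dim(center) == c(n, 3L))) {
    abort("coordinate matrices must be n-by-3 and match the sequence length")
  }
  if (!all(is.finite(ca)) || !all(is.finite(center))) {
    abort("coordinates must be finite")
  }
  bad <- !aa %in% names(AA_123)
  if (any(bad)) {
    abort(paste0("unknown one-letter amino-acid code(s): ",
                 paste(unique(aa[bad]), collapse = ", ")))
  }
  structure(
    list(model_id = as.character(model_id), aa = aa,
         ca = unname(ca), center = unname(center)),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model> ", n_residues(x), " residues, id ", x$model_id, "\n",
      sep = "")
  invisible(x)
}

#' Number of residues in a model or ensemble
#' @param x A `structure_model` or `ensemble`.
#' @return Integer residue count.
#' @export
n_residues <- function(x) {
  if (inherits(x, "ensemble")) nchar(x$sequence) else length(x$aa)
}

#' Construct an ensemble of conformations of one sequence
#'
#' @param models List of [structure_model()] objects, all of the same length
#'   and amino-acid sequence.
#' @param sequence Optional one-letter sequence string; defaults to the
#'   sequence of the first model.
#' @return An object of class `ensemble`.
#' @export
ensemble <- function(models, sequence = NULL) {
  if (length(models) < 1L) abort("ensemble needs at least one model")
  seqs <- vapply(models, function(m) paste(m$aa, collapse = ""), character(1))
  if (is.null(sequence)) sequence <- seqs[[1]]
  if (length(unique(nchar(seqs))) > 1L) {
    abort("shape error: models have differing residue counts")
  }
  if (!all(seqs == sequence)) {
    abort("models disagree with the ensemble sequence")
  }
  structure(list(sequence = sequence, models = models), class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat("<ensemble> ", length(x$models), " model(s) of ", nchar(x$sequence),
      " residues\n", sep = "")
  invisible(x)
}

parse_atom_line <- function(line, lineno) {
  pad <- function(s, k) formatC(s, width = k, flag = "-")
  line <- pad(line, 80)
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(line, from, to)))
    if (is.na(v)) {
      abort(sprintf("malformed ATOM record at line %d: bad %s field",
                    lineno, what))
    }
    v
  }
  list(
    name = trimws(substr(line, 13, 16)),
    altloc = substr(line, 17, 17),
    resname = trimws(substr(line, 18, 20)),
    chain = substr(line, 22, 22),
    resseq = trimws(substr(line, 23, 27)),  # includes insertion code
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    element = trimws(substr(line, 77, 78))
  )
}

model_from_atoms <- function(atoms, model_id) {
  chains <- unique(vapply(atoms, `[[`, character(1), "chain"))
  if (length(chains) > 1L) {
    abort(sprintf(
      "model %s has %d chains (%s); only single-chain input is supported",
      model_id, length(chains), paste(chains, collapse = ", ")))
  }
  keys <- vapply(atoms, function(a) paste(a$resname, a$resseq), character(1))
  split_idx <- split(seq_along(atoms), factor(keys, levels = unique(keys)))
  n <- length(split_idx)
  aa <- character(n); ca <- matrix(NA_real_, n, 3); center <- matrix(NA_real_, n, 3)
  for (r in seq_len(n)) {
    res_atoms <- atoms[split_idx[[r]]]
    resname <- res_atoms[[1]]$resname
    one <- AA_321[resname]
    if (is.na(one)) abort(paste0("unknown residue name: ", resname))
    aa[r] <- one
    coords <- t(vapply(res_atoms, function(a) c(a$x, a$y, a$z), numeric(3)))
    names_ <- vapply(res_atoms, `[[`, character(1), "name")
    elems <- vapply(res_atoms, `[[`, character(1), "element")
    ica <- which(names_ == "CA")
    if (length(ica) == 0L) {
      abort(sprintf("model %s: residue %d (%s) has no CA atom", model_id, r, resname))
    }
    ca[r, ] <- coords[ica[1L], ]
    sc <- which(!(names_ %in% BACKBONE_ATOMS) & elems != "H" &
                  !grepl("^H", names_))
    center[r, ] <- if (length(sc) > 0L) colMeans(coords[sc, , drop = FALSE]) else ca[r, ]
  }
  structure_model(aa, ca, center, model_id = model_id)
}

#' Read a (multi-model) PDB file as an ensemble
#'
#' Models are delimited by `MODEL`/`ENDMDL` records; a file with no `MODEL`
#' record is read as a single model. Only `ATOM` records are used (`HETATM`
#' skipped); alternate locations other than blank or `'A'` are dropped.
#' Input residue numbering is discarded and residues renumbered `1..n` in
#' chain order. Multi-chain models are rejected. The interaction center of
#' each residue is the centroid of its side-chain heavy atoms, or the
#' C-alpha when no side-chain atom is present.
#'
#' @param path Path to a PDB file.
#' @return An [ensemble()].
#' @export
read_ensemble <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  models <- list()
  cur <- list(); cur_n <- 0L; in_model <- FALSE; model_ids <- character()
  flush_model <- function() {
    if (cur_n > 0L) {
      id <- if (length(model_ids) >= length(models) + 1L) {
        model_ids[[length(models) + 1L]]
      } else as.character(length(models) + 1L)
      models[[length(models) + 1L]] <<- model_from_atoms(cur[seq_len(cur_n)], id)
    }
    cur <<- list(); cur_n <<- 0L
  }
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (r == "MODEL ") {
      flush_model()
      in_model <- TRUE
      model_ids <- c(model_ids, trimws(substr(lines[i], 7, 80)))
    } else if (r == "ENDMDL") {
      flush_model()
      in_model <- FALSE
    } else if (r == "ATOM  ") {
      a <- parse_atom_line(lines[i], i)
      if (!a$altloc %in% c(" ", "A", "")) next
      cur_n <- cur_n + 1L
      cur[[cur_n]] <- a
    }
  }
  flush_model()
  if (length(models) == 0L) abort(paste0("no ATOM records found in ", path))
  counts <- vapply(models, n_residues, integer(1))
  if (length(unique(counts)) > 1L) {
    abort(sprintf("shape error: models have differing residue counts (%s)",
                  paste(unique(counts), collapse = ", ")))
  }
  e <- ensemble(models)
  check_ca_geometry(e)
  e
}

check_ca_geometry <- function(e) {
  for (m in e$models) {
    if (n_residues(m) < 2L) next
    d <- sqrt(rowSums((m$ca[-1, , drop = FALSE] -
                         m$ca[-nrow(m$ca), , drop = FALSE])^2))
    if (any(d <= 2.0 | d >= 5.0)) {
      warn(sprintf(
        "model %s: %d consecutive C-alpha distance(s) outside (2, 5) angstrom",
        m$model_id, sum(d <= 2.0 | d >= 5.0)))
    }
  }
  invisible(e)
}

format_atom <- function(serial, name, resname, resseq, xyz) {
  sprintf("ATOM  %5d  %-4s%3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, name, resname, resseq, xyz[1], xyz[2], xyz[3])
}

#' Write an ensemble as a multi-model PDB file
#'
#' `MODEL`/`ENDMDL` records are always emitted, also for a single model, so
#' that round-trips are unambiguous. Each residue is written as its C-alpha
#' atom; when the interaction center differs from the C-alpha a `CB`
#' pseudo-atom is written at the center, so
#' `read_ensemble(write_ensemble(e))` reproduces both coordinate views to
#' PDB precision (3 decimals).
#'
#' @param e An [ensemble()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(e, path) {
  stopifnot(inherits(e, "ensemble"))
  out <- character()
  for (k in seq_along(e$models)) {
    m <- e$models[[k]]
    out <- c(out, sprintf("MODEL %8d", k))
    serial <- 0L
    for (r in seq_len(n_residues(m))) {
      resname <- AA_123[m$aa[r]]
      serial <- serial + 1L
      out <- c(out, format_atom(serial, "CA", resname, r, m$ca[r, ]))
      if (any(abs(m$center[r, ] - m$ca[r, ]) > 5e-4)) {
        serial <- serial + 1L
        out <- c(out, format_atom(serial, "CB", resname, r, m$center[r, ]))
      }
    }
    out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(paste0("cannot open for writing: ", path))
  })
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Tabulate a structure model
#'
#' @param x A `structure_model`.
#' @param ... Unused.
#' @return A tibble with one row per residue: index, one-letter code and the
#'   two coordinate views.
#' @method tidy structure_model
#' @export
tidy.structure_model <- function(x, ...) {
  tibble::tibble(
    residue = seq_along(x$aa), aa = x$aa,
    ca_x = x$ca[, 1], ca_y = x$ca[, 2], ca_z = x$ca[, 3],
    center_x = x$center[, 1], center_y = x$center[, 2], center_z = x$center[, 3]
  )
}
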