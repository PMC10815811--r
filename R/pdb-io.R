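#' Parse a PDB file into a residue table
#'
#' Reads the fixed-column ATOM records of a legacy-format PDB file and
#' returns one row per residue, in file order, with the C-alpha coordinate
#' where one is present. Only the first model of a multi-model file is read;
#' for alternate locations only altloc `' '` or `'A'` is kept; HETATM
#' records are ignored.
#'
#' @param file Path to a PDB file. Exactly one of `file`/`text` must be given.
#' @param text PDB-format text (single string or character vector of lines).
#' @param id Protein identifier. Defaults to the file name without extension.
#' @return A tibble with columns `id`, `chain`, `resno`, `resname`,
#'   `has_ca`, and the C-alpha coordinates `x`, `y`, `z` in Angstrom
#'   (`NA` when the residue has no C-alpha atom).
#' @examples
#' pdb <- synthetic_pdb(length = 10, geometry = "helix", seed = 1)
#' read_pdb(text = pdb$text, id = "demo")
#' @export
read_pdb <- function(file = NULL, text = NULL, id = NULL) {
  if (is.null(file) == is.null(text)) {
    abort("supply exactly one of `file` or `text`")
  }
  if (!is.null(file)) {
    id <- id %||% sub("\\.(pdb|ent)$", "", basename(file), ignore.case = TRUE)
    lines <- readLines(file, warn = FALSE)
  } else {
    id <- id %||% "protein"
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  }

  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "ATOM ")
  if (!any(is_atom)) {
    abort(sprintf("no ATOM records in structure '%s'", id))
  }
  # coordinate columns 31-54 must parse as three reals; report the line
  atom_idx <- which(is_atom)
  for (ln in atom_idx) {
    flds <- substring(lines[ln], c(31, 39, 47), c(38, 46, 54))
    if (anyNA(suppressWarnings(as.numeric(flds)))) {
      abort(sprintf("malformed coordinates in structure '%s' at line %d", id, ln))
    }
  }
  # first model only: truncate at the first ENDMDL when MODEL records exist
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (any(startsWith(lines, "MODEL")) && length(endmdl)) {
    lines <- lines[seq_len(endmdl[1])]
  }

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(tf, multi = FALSE, rm.alt = TRUE, verbose = FALSE)),
    error = function(e) abort(sprintf("failed to parse structure '%s': %s", id, conditionMessage(e)))
  )
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) abort(sprintf("no ATOM records in structure '%s'", id))

  res_key <- paste(atoms$chain, atoms$resno, atoms$insert %||% "", sep = "\r")
  first <- !duplicated(res_key)
  res <- atoms[first, c("chain", "resno", "resid"), drop = FALSE]
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(paste(ca$chain, ca$resno, ca$insert %||% "", sep = "\r")), , drop = FALSE]
  ca_key <- paste(ca$chain, ca$resno, ca$insert %||% "", sep = "\r")
  pos <- match(res_key[first], ca_key)

  tibble(
    id = id,
    chain = as.character(res$chain),
    resno = as.integer(res$resno),
    resname = as.character(res$resid),
    has_ca = !is.na(pos),
    x = ca$x[pos], y = ca$y[pos], z = ca$z[pos]
  )
}

#' Map three-letter residue names to one-letter codes
#'
#' Standard 20-amino-acid mapping; any unrecognized or modified residue name
#' (e.g. `"MSE"`) maps to `"X"`. Vectorized and total: never errors.
#'
#' @param resname Character vector of three-letter residue names.
#' @return Character vector of single letters over `{A..Y, X}`.
#' @examples
#' residue_one_letter(c("ALA", "TRP", "MSE"))
#' @export
residue_one_letter <- function(resname) {
  std <- c(
    ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
    GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
    LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
    SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
  )
  out <- unname(std[toupper(trimws(resname))])
  out[is.na(out)] <- "X"
  out
}

#' Extract the C-alpha trace of a parsed structure
#'
#' Concatenates residues across chains in file order, keeping only residues
#' that carry a C-alpha atom (skipped residues are counted in a warning),
#' and builds the one-letter sequence in lockstep with the coordinates.
#'
#' @param structure A residue table from [read_pdb()] (a single protein).
#' @return A tibble with one row per retained residue: `id`, `chain`,
#'   `resno`, `resname`, `aa` (one-letter code), `x`, `y`, `z`.
#' @examples
#' pdb <- synthetic_pdb(length = 10, geometry = "extended", seed = 1)
#' tr <- ca_trace(read_pdb(text = pdb$text, id = "demo"))
#' nrow(tr)
#' @export
ca_trace <- function(structure) {
  stopifnot(is.data.frame(structure), all(c("id", "has_ca") %in% names(structure)))
  n_skip <- sum(!structure$has_ca)
  if (n_skip > 0) {
    warn(sprintf("structure '%s': skipped %d residue(s) without a C-alpha atom",
                 structure$id[1], n_skip))
  }
  tr <- structure[structure$has_ca, , drop = FALSE]
  if (nrow(tr) == 0L) abort(sprintf("empty trace: structure '%s' has no C-alpha atoms", structure$id[1]))
  if (!all(is.finite(tr$x) & is.finite(tr$y) & is.finite(tr$z))) {
    abort(sprintf("non-finite C-alpha coordinates in structure '%s'", tr$id[1]))
  }
  out <- tr[c("id", "chain", "resno", "resname", "x", "y", "z")]
  out$aa <- residue_one_letter(out$resname)
  as_tibble(out[c("id", "chain", "resno", "resname", "aa", "x", "y", "z")])
}

#' Read C-alpha traces for a set of PDB files
#'
#' Convenience wrapper: parses each file with [read_pdb()], extracts the
#' trace with [ca_trace()], and stacks the results into one long tibble
#' keyed by `id`.
#'
#' @param files Character vector of PDB file paths, or a single directory,
#'   in which case all `*.pdb` files in it are read (alphabetical order).
#' @return A tibble of traces, multiple proteins distinguished by `id`.
#' @export
read_ca_traces <- function(files) {
  if (length(files) == 1L && dir.exists(files)) {
    files <- list.files(files, pattern = "\\.pdb$", full.names = TRUE)
  }
  if (length(files) == 0L) abort("no PDB files to read")
  purrr::map(files, function(f) ca_trace(read_pdb(file = f))) |>
    dplyr::bind_rows()
}

#' Collapse traces to one sequence per protein
#'
#' @param traces A trace tibble from [ca_trace()] or [read_ca_traces()].
#' @return A tibble with columns `id` and `sequence`, one row per protein,
#'   preserving first-appearance order of ids.
#' @export
trace_sequences <- function(traces) {
  stopifnot(is.data.frame(traces), all(c("id", "aa") %in% names(traces)))
  ids <- unique(traces$id)
  tibble(
    id = ids,
    sequence = vapply(ids, function(i) paste(traces$aa[traces$id == i], collapse = ""),
                      "", USE.NAMES = FALSE)
  )
}

#' Write protein sequences to a FASTA file
#'
#' One record per protein, header equal to the identifier, wrapped at 60
#' columns.
#'
#' @param sequences A tibble with columns `id` and `sequence`
#'   (as from [trace_sequences()]).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(sequences, file) {
  stopifnot(is.data.frame(sequences), all(c("id", "sequence") %in% names(sequences)))
  dup <- unique(sequences$id[duplicated(sequences$id)])
  if (length(dup)) abort(paste0("duplicate identifiers: ", paste(dup, collapse = ", ")))
  if (any(!nzchar(sequences$sequence))) abort("empty sequence(s) cannot be written")
  seqinr::write.fasta(
    sequences = lapply(sequences$sequence, function(s) strsplit(s, "")[[1]]),
    names = sequences$id, file.out = file, nbchar = 60
  )
  invisible(file)
}
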