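# idealized C-alpha geometries (Angstrom): alpha helix rise/turn/radius and
# extended-chain CA-CA spacing
HELIX_RISE <- 1.5
HELIX_TURN_DEG <- 100
HELIX_RADIUS <- 2.3
EXTENDED_STEP <- 3.8

STANDARD_RESIDUES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

one_to_three <- function(aa) {
  idx <- match(aa, residue_one_letter(STANDARD_RESIDUES))
  STANDARD_RESIDUES[idx]
}

geometry_coords <- function(n, geometry) {
  helix <- function(m, offset = c(0, 0, 0)) {
    th <- (seq_len(m) - 1) * HELIX_TURN_DEG * pi / 180
    cbind(HELIX_RADIUS * cos(th) + offset[1],
          HELIX_RADIUS * sin(th) + offset[2],
          HELIX_RISE * (seq_len(m) - 1) + offset[3])
  }
  extended <- function(m, offset = c(0, 0, 0)) {
    cbind(EXTENDED_STEP * (seq_len(m) - 1) + offset[1],
          rep(offset[2], m), rep(offset[3], m))
  }
  switch(geometry,
    helix = helix(n),
    extended = extended(n),
    mixed = {
      n1 <- ceiling(n / 2)
      a <- helix(n1)
      b <- extended(n - n1, offset = a[n1, ] + c(EXTENDED_STEP, 0, 0))
      rbind(a, b)
    },
    abort(sprintf("unknown geometry '%s' (use helix, extended or mixed)", geometry))
  )
}

format_atom_line <- function(serial, resname, chain, resno, xyz) {
  sprintf("ATOM  %5d  CA  %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, resname, chain, resno, xyz[1], xyz[2], xyz[3])
}

implant_motif <- function(sequence, motif, rate) {
  chars <- strsplit(sequence, "")[[1]]
  m <- strsplit(motif, "")[[1]]
  L <- length(chars)
  if (L < length(m)) return(sequence)
  n_windows <- L - length(m) + 1
  n_copies <- max(1L, round(rate * n_windows))
  starts <- sample(n_windows, min(n_copies, n_windows))
  for (s in starts) chars[s:(s + length(m) - 1)] <- m
  paste(chars, collapse = "")
}

#' Generate a synthetic single-chain PDB structure
#'
#' Builds an idealized C-alpha-only structure: `"helix"` uses ideal
#' alpha-helix parameters (rise 1.5 A per residue, 100 degree turn, radius
#' 2.3 A), `"extended"` places consecutive C-alphas 3.8 A apart on a line,
#' and `"mixed"` is a helix followed by an extended tail. Gaussian jitter
#' with standard deviation `noise_sd` is added per coordinate. Residues are
#' drawn uniformly from the 20 standard amino acids unless `sequence` is
#' supplied. The ground-truth coordinates are returned alongside the text
#' for round-trip tests.
#'
#' @param length Number of residues (at least 4).
#' @param geometry `"helix"`, `"extended"` or `"mixed"`.
#' @param noise_sd Coordinate jitter standard deviation in Angstrom
#'   (default 0).
#' @param seed Optional seed; the same seed reproduces the file exactly.
#' @param id Protein identifier (used in the HEADER line).
#' @param sequence Optional one-letter sequence of length `length` over the
#'   20 standard amino acids; `X` is not placeable as an ATOM residue.
#' @return A list with `id`, `text` (PDB-format string), `coords`
#'   (`length x 3` matrix, jitter included) and `sequence`.
#' @examples
#' p <- synthetic_pdb(length = 5, geometry = "extended", seed = 1)
#' cat(substr(p$text, 1, 80), "\n")
#' @export
synthetic_pdb <- function(length, geometry = c("helix", "extended", "mixed"),
                          noise_sd = 0, seed = NULL, id = "synthetic",
                          sequence = NULL) {
  if (length < 4) abort("`length` must be at least 4")
  geometry <- match.arg(geometry)
  stopifnot(noise_sd >= 0)
  with_seed_if(if (is.null(seed)) NULL else as.integer(seed), {
    coords <- geometry_coords(length, geometry)
    if (noise_sd > 0) coords <- coords + matrix(rnorm(3 * length, 0, noise_sd), ncol = 3)
    if (is.null(sequence)) {
      aa <- sample(residue_one_letter(STANDARD_RESIDUES), length, replace = TRUE)
    } else {
      aa <- strsplit(sequence, "")[[1]]
      stopifnot(base::length(aa) == length)
    }
    resnames <- one_to_three(aa)
    if (anyNA(resnames)) abort("`sequence` must use the 20 standard amino acids")
    lines <- c(
      sprintf("HEADER    SYNTHETIC STRUCTURE                     01-JAN-26   %s", id),
      vapply(seq_len(length), function(i) {
        format_atom_line(i, resnames[i], "A", i, coords[i, ])
      }, ""),
      "TER", "END"
    )
    list(id = id, text = paste(lines, collapse = "\n"), coords = coords,
         sequence = paste(aa, collapse = ""))
  })
}

#' Generate a labeled synthetic corpus of PDB files
#'
#' Writes one synthetic PDB file per protein plus a labels table, with
#' class structure controlled by a components table: each row contributes
#' `n` proteins of one `label` with a given backbone `geometry` and an
#' optional sequence `motif` implanted at `motif_rate` (fraction of sliding
#' windows overwritten). A class may span several rows, giving mixture
#' classes whose identity depends jointly on geometry and sequence.
#' Optionally a random external-embedding table (`external_dim` columns)
#' keyed to the same ids is written, standing in for precomputed
#' language-model vectors.
#'
#' @param components A data frame with columns `label`, `geometry`, `n`,
#'   and optionally `motif` (character, `NA` for none) and `motif_rate`.
#' @param length_range Integer range of protein lengths, drawn uniformly.
#' @param noise_sd Coordinate jitter in Angstrom (default 0.2).
#' @param seed Integer seed; the whole corpus is reproducible from it.
#' @param dir Output directory (created if needed); default a fresh
#'   directory under `tempdir()`.
#' @param motif_rate Default implant rate for rows without their own.
#' @param external_dim If positive, also write `external.csv` with random
#'   standard-normal vectors of this dimension.
#' @return A tibble manifest: `id`, `label`, `geometry`, `motif`, `file`;
#'   attributes `"dir"`, `"labels_file"` and (if requested)
#'   `"external_file"`.
#' @export
synthetic_corpus <- function(components, length_range = c(30, 60),
                             noise_sd = 0.2, seed = 0L, dir = NULL,
                             motif_rate = 0.05, external_dim = 0) {
  stopifnot(is.data.frame(components),
            all(c("label", "geometry", "n") %in% names(components)),
            length_range[1] >= 4, length_range[2] >= length_range[1])
  if (!"motif" %in% names(components)) components$motif <- NA_character_
  if (!"motif_rate" %in% names(components)) components$motif_rate <- motif_rate
  dir <- dir %||% tempfile("corpus")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) abort(sprintf("cannot create output directory '%s'", dir))

  with_seed_if(as.integer(seed), {
    rows <- list()
    counter <- 0L
    for (ci in seq_len(nrow(components))) {
      comp <- components[ci, ]
      for (j in seq_len(comp$n)) {
        counter <- counter + 1L
        pid <- sprintf("prot%04d", counter)
        len <- if (length_range[1] == length_range[2]) length_range[1] else
          sample(seq(length_range[1], length_range[2]), 1L)
        p <- synthetic_pdb(len, comp$geometry, noise_sd = noise_sd, id = pid)
        if (!is.na(comp$motif)) {
          seq2 <- implant_motif(p$sequence, comp$motif, comp$motif_rate)
          # rebuild with the motif-bearing sequence, same coordinates
          resnames <- one_to_three(strsplit(seq2, "")[[1]])
          lines <- c(
            sprintf("HEADER    SYNTHETIC STRUCTURE                     01-JAN-26   %s", pid),
            vapply(seq_len(len), function(i) {
              format_atom_line(i, resnames[i], "A", i, p$coords[i, ])
            }, ""),
            "TER", "END"
          )
          p$text <- paste(lines, collapse = "\n")
          p$sequence <- seq2
        }
        path <- file.path(dir, paste0(pid, ".pdb"))
        writeLines(p$text, path)
        rows[[counter]] <- tibble(id = pid, label = comp$label,
                                  geometry = comp$geometry, motif = comp$motif,
                                  file = path)
      }
    }
    manifest <- dplyr::bind_rows(rows)
    labels_file <- file.path(dir, "labels.csv")
    readr::write_csv(manifest[c("id", "label")], labels_file)
    attr(manifest, "dir") <- dir
    attr(manifest, "labels_file") <- labels_file
    if (external_dim > 0) {
      ext <- as_embedding_tbl(
        manifest$id,
        matrix(rnorm(nrow(manifest) * external_dim), nrow = nrow(manifest)),
        "external"
      )
      external_file <- file.path(dir, "external.csv")
      write_embedding_table(ext, external_file)
      attr(manifest, "external_file") <- external_file
    }
    manifest
  })
}
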