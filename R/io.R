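#' Read protein sequences from FASTA
#'
#' Reads a FASTA file into a named character vector. Lowercase residues are
#' normalised to uppercase, duplicate ids are an error, and non-standard
#' residues are rejected with a position-specific message.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences (order preserved).
#' @export
read_fasta_sequences <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids) > 0L)
    stop("duplicate FASTA ids: ", ids[duplicated(ids)][1L])
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  for (i in seq_along(seqs)) {
    tryCatch(validate_sequence(seqs[[i]]),
             error = function(e) stop("in record '", ids[i], "': ",
                                      conditionMessage(e), call. = FALSE))
  }
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_sequences <- function(sequences, path) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a conformational ensemble from xyz or PDB
#'
#' One conformation per frame/model, one representative point per residue,
#' coordinates in Angstrom. In the xyz format each frame is an atom count,
#' a comment line, then one `<residue letter> x y z` line per residue; the
#' sequence is recovered from the residue letters. Multi-model PDB files
#' are read through bio3d, taking CA atoms as the per-residue points.
#'
#' @param path file path.
#' @param format `"xyz"`, `"pdb"` or `"auto"` (by extension).
#' @param label ensemble label (`"target"` or `"reference"`).
#' @return A `conform_ensemble`.
#' @export
read_ensemble <- function(path, format = c("auto", "xyz", "pdb"),
                          label = "target") {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  if (format == "xyz") read_ensemble_xyz(path, label)
  else read_ensemble_pdb(path, label)
}

read_ensemble_xyz <- function(path, label) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  confs <- list(); seqs <- list(); i <- 1L; model <- 0L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    model <- model + 1L
    if (is.na(n) || n < 1L)
      stop("malformed xyz: bad atom count at model ", model)
    if (i + 1L + n > length(lines))
      stop("malformed xyz: truncated model ", model,
           " (coordinate count not matching the declared atoms)")
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    if (any(lengths(parts) < 4L))
      stop("malformed xyz: short coordinate line in model ", model)
    el <- vapply(parts, `[[`, character(1), 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(xyz)) stop("malformed xyz: non-numeric coordinate in model ", model)
    confs[[model]] <- xyz
    seqs[[model]] <- paste(toupper(el), collapse = "")
    i <- i + 2L + n
  }
  if (length(confs) == 0L) stop("no models in ", path)
  if (length(unique(vapply(confs, nrow, integer(1)))) != 1L ||
      length(unique(unlist(seqs))) != 1L) {
    bad <- which(vapply(seqs, `!=`, logical(1), seqs[[1L]]) |
                   vapply(confs, nrow, integer(1)) != nrow(confs[[1L]]))[1L]
    stop("model ", bad, " differs in length or sequence from model 1")
  }
  structure(list(sequence = seqs[[1L]], conformations = confs,
                 label = label, sticker_positions = integer(0)),
            class = "conform_ensemble")
}

read_ensemble_pdb <- function(path, label) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  ca <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  if (length(ca$atom) == 0L) stop("no CA atoms found in ", path)
  seq1 <- paste(bio3d::aa321(pdb$atom$resid[ca$atom]), collapse = "")
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  confs <- lapply(seq_len(nrow(xyz)), function(f)
    matrix(xyz[f, ca$xyz], ncol = 3L, byrow = TRUE))
  structure(list(sequence = seq1, conformations = confs,
                 label = label, sticker_positions = integer(0)),
            class = "conform_ensemble")
}

#' Write a conformational ensemble to xyz
#'
#' One frame per conformation; residue one-letter codes serve as element
#' labels, so [read_ensemble()] round-trips sequence and coordinates.
#'
#' @param ensemble a `conform_ensemble`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble_xyz <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "conform_ensemble"))
  aa <- strsplit(ensemble$sequence, "")[[1L]]
  con <- file(path, "w"); on.exit(close(con))
  for (k in seq_along(ensemble$conformations)) {
    xyz <- ensemble$conformations[[k]]
    writeLines(c(as.character(nrow(xyz)), sprintf("model %d", k)), con)
    writeLines(sprintf("%s %.4f %.4f %.4f", aa, xyz[, 1], xyz[, 2], xyz[, 3]),
               con)
  }
  invisible(path)
}

#' Write a pixel table to CSV
#'
#' @param pixels pixel table from [gen_optodroplet_cells()].
#' @param path output path.
#' @return `path`, invisibly. A JSON sidecar `<path>.truth.json` records the
#'   ground truth when present.
#' @export
write_pixel_csv <- function(pixels, path) {
  utils::write.csv(pixels, path, row.names = FALSE)
  gt <- attr(pixels, "ground_truth")
  if (!is.null(gt))
    jsonlite::write_json(gt, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pixel table from CSV
#'
#' @param path CSV with columns `cell_id`, `pixel_id`, `intensity_before`,
#'   `intensity_after`.
#' @return Pixel table data frame (ground-truth sidecar re-attached when
#'   present).
#' @export
read_pixel_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "pixel_id", "intensity_before", "intensity_after")
  if (!all(need %in% names(out)))
    stop("pixel CSV must have columns: ", paste(need, collapse = ", "))
  sidecar <- paste0(path, ".truth.json")
  if (file.exists(sidecar))
    attr(out, "ground_truth") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  out
}

#' Write an abundance table to TSV
#'
#' Two header rows (group, replicate) above the proteins x samples matrix.
#'
#' @param tbl an [abundance_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(tbl, path) {
  stopifnot(inherits(tbl, "abundance_table"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c("group", tbl$groups), collapse = "\t"), con)
  writeLines(paste(c("replicate", tbl$replicate), collapse = "\t"), con)
  utils::write.table(tbl$abundance, con, sep = "\t", quote = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read an abundance table from TSV
#'
#' @param path TSV written by [write_abundance_tsv()].
#' @return An [abundance_table()].
#' @export
read_abundance_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("abundance TSV needs 2 header rows and data")
  hdr1 <- strsplit(lines[1L], "\t")[[1L]]
  hdr2 <- strsplit(lines[2L], "\t")[[1L]]
  if (hdr1[1L] != "group" || hdr2[1L] != "replicate")
    stop("abundance TSV must start with 'group' and 'replicate' header rows")
  body <- utils::read.table(text = lines[-(1:2)], sep = "\t",
                            row.names = 1L, header = FALSE)
  ab <- as.matrix(body)
  colnames(ab) <- paste0(hdr1[-1L], "_r", hdr2[-1L])
  abundance_table(ab, groups = hdr1[-1L], replicate = as.integer(hdr2[-1L]))
}
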