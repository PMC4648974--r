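#' Read molecules from a SMILES or SDF file
#'
#' SMILES files are whitespace-separated `SMILES id` per line; lines
#' starting with `#` are ignored, and a missing id column falls back to the
#' line number. SDF files are standard V2000 multi-record; the id is taken
#' from the title line unless `id_prop` names a data-block property. SDF
#' structures are converted to SMILES so that downstream code holds a
#' uniform molecule table. Records that fail to parse are skipped with a
#' warning reporting the count; an empty file yields an empty table with a
#' warning.
#'
#' Requires the ChemmineR/ChemmineOB toolkit for SDF input and for SMILES
#' validation.
#'
#' @param path input file.
#' @param format `"smiles"` or `"sdf"`.
#' @param id_prop for SDF input, the name of a data-block property holding
#'   the compound id (default: the title line).
#' @param validate for SMILES input, parse each structure with the
#'   chemistry toolkit and drop invalid records (default `TRUE`).
#' @return data.frame with columns `id` and `structure` (SMILES), in input
#'   order.
#' @export
read_molecules <- function(path, format = c("smiles", "sdf"), id_prop = NULL,
                           validate = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "smiles") {
    lines <- readLines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0L) {
      warning("no molecule records in ", path)
      return(data.frame(id = character(), structure = character(),
                        stringsAsFactors = FALSE))
    }
    parts <- strsplit(lines, "[[:space:]]+")
    smiles <- vapply(parts, `[[`, character(1), 1)
    ids <- vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) >= 2) parts[[i]][2] else as.character(i)
    }, character(1))
    mols <- data.frame(id = ids, structure = smiles, stringsAsFactors = FALSE)
    if (validate) {
      ok <- .validate_smiles(mols$structure, mols$id)
      if (any(!ok))
        warning(sum(!ok), " record(s) failed to parse and were skipped: ",
                paste(utils::head(mols$id[!ok], 5), collapse = ", "))
      mols <- mols[ok, , drop = FALSE]
      rownames(mols) <- NULL
    }
    mols
  } else {
    .require_chemistry()
    sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
    if (length(sdfs) == 0L) {
      warning("no molecule records in ", path)
      return(data.frame(id = character(), structure = character(),
                        stringsAsFactors = FALSE))
    }
    valid <- ChemmineR::validSDF(sdfs)
    if (any(!valid))
      warning(sum(!valid), " SDF record(s) failed to parse and were skipped")
    sdfs <- sdfs[valid]
    if (is.null(id_prop)) {
      ids <- as.character(ChemmineR::sdfid(sdfs))
    } else {
      blocks <- ChemmineR::datablock(sdfs)
      ids <- vapply(blocks, function(b) {
        if (id_prop %in% names(b)) as.character(b[[id_prop]]) else NA_character_
      }, character(1))
      if (anyNA(ids))
        stop("SDF property '", id_prop, "' missing for some records")
    }
    smiles <- as.character(ChemmineR::sdf2smiles(sdfs))
    data.frame(id = ids, structure = smiles, stringsAsFactors = FALSE)
  }
}

.require_chemistry <- function() {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE))
    stop("reading/parsing molecular structures requires the ChemmineR and ",
         "ChemmineOB packages; precomputed fingerprints can be loaded with ",
         "read_fingerprints() instead")
  invisible(TRUE)
}

.validate_smiles <- function(smiles, ids) {
  .require_chemistry()
  named <- stats::setNames(smiles, ids)
  sdfs <- suppressWarnings(ChemmineR::smiles2sdf(named))
  ChemmineR::validSDF(sdfs)
}

#' Compute hashed circular (ECFP/Morgan-type) fingerprints
#'
#' Encodes each molecule as a fixed-length binary vector of hashed circular
#' substructure features, the fingerprint family behind ECFP and Morgan
#' fingerprints. Atom environments up to the given radius are hashed by
#' OpenBabel's ECFP implementation (radius 2 = ECFP4, the community
#' standard) and folded by OR-ing hash positions modulo `length` down to
#' the requested width. The computation is a pure function of
#' (structure, length, radius): identical SMILES give bit-identical
#' fingerprints.
#'
#' @param molecules data.frame with columns `id` and `structure` (SMILES),
#'   as returned by [read_molecules()].
#' @param length fingerprint width in bits (default 1024).
#' @param radius circular neighborhood radius in bonds (default 2).
#' @return binary matrix with one row per molecule, rownames = ids.
#' @export
compute_fingerprints <- function(molecules, length = 1024L, radius = 2L) {
  .require_chemistry()
  stopifnot(is.data.frame(molecules),
            all(c("id", "structure") %in% names(molecules)))
  if (length <= 0) stop("fingerprint length must be positive")
  if (!radius %in% 0:5) stop("radius must be an integer in 0..5")
  if (anyDuplicated(molecules$id))
    stop("molecule ids must be unique within a database")
  smiles <- stats::setNames(molecules$structure, molecules$id)
  sdfs <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  valid <- ChemmineR::validSDF(sdfs)
  if (any(!valid))
    stop("unparseable structure(s): ",
         paste(molecules$id[!valid], collapse = ", "))
  fpset <- ChemmineR::fingerprintOB(sdfs, sprintf("ECFP%d", 2L * radius))
  raw <- fpset@fpma
  storage.mode(raw) <- "numeric"
  folded <- .fold_fingerprints(raw, length)
  rownames(folded) <- molecules$id
  folded
}

#' @rdname compute_fingerprints
#' @param structure a single SMILES string.
#' @param id compound id used in error messages and the result name.
#' @export
compute_fingerprint <- function(structure, id = "query", length = 1024L,
                                radius = 2L) {
  m <- compute_fingerprints(
    data.frame(id = id, structure = structure, stringsAsFactors = FALSE),
    length = length, radius = radius)
  m[1, ]
}

# OR-fold a wide bit matrix down to `length` columns (position i of the
# source maps to i mod length). A no-op when already at the target width.
.fold_fingerprints <- function(mat, length) {
  m <- ncol(mat)
  if (m == length) return(mat)
  if (m < length)
    stop("cannot fold a ", m, "-bit fingerprint up to ", length, " bits")
  out <- matrix(0, nrow = nrow(mat), ncol = length)
  for (start in seq(1L, m, by = length)) {
    chunk <- mat[, start:min(start + length - 1L, m), drop = FALSE]
    out[, seq_len(ncol(chunk))] <- pmax(out[, seq_len(ncol(chunk))], chunk)
  }
  out
}

#' Read / write precomputed fingerprints
#'
#' Plain-text exchange format: one record per line, `id<TAB>bitstring` of
#' 0/1 characters, with an optional `#length=M` header. All fingerprints in
#' a file must share one length; a mixed-length file is rejected before any
#' search can run on it.
#'
#' @param path input/output file.
#' @return `read_fingerprints`: binary matrix, one row per compound.
#' @export
read_fingerprints <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  declared <- NA_integer_
  hdr <- grepl("^#length=", lines)
  if (any(hdr)) declared <- as.integer(sub("^#length=", "", lines[hdr][1]))
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L)
    stop("no fingerprint records in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1)
  bits <- vapply(parts, `[[`, character(1), 2)
  lens <- nchar(bits)
  if (length(unique(lens)) != 1L)
    stop("mixed fingerprint lengths in ", path, ": ",
         paste(unique(lens), collapse = ", "))
  if (!is.na(declared) && lens[1] != declared)
    stop("fingerprint length ", lens[1], " does not match declared header ",
         "#length=", declared)
  if (anyDuplicated(ids))
    stop("duplicate compound ids in ", path)
  mat <- t(vapply(bits, function(b) {
    v <- as.integer(strsplit(b, "", fixed = TRUE)[[1]])
    if (anyNA(v) || !all(v %in% c(0L, 1L)))
      stop("non-binary character in fingerprint bitstring")
    v
  }, integer(lens[1])))
  dimnames(mat) <- list(ids, NULL)
  storage.mode(mat) <- "numeric"
  mat
}

#' @rdname read_fingerprints
#' @param fps binary fingerprint matrix with rownames (compound ids).
#' @export
write_fingerprints <- function(fps, path) {
  fps <- as_fingerprint_matrix(fps)
  lines <- c(sprintf("#length=%d", ncol(fps)),
             paste0(rownames(fps), "\t",
                    apply(fps, 1, function(r) paste0(as.integer(r),
                                                     collapse = ""))))
  writeLines(lines, path)
  invisible(path)
}

#' Validate a fingerprint matrix
#'
#' Coerces to a numeric matrix and checks the database invariants: binary
#' entries, a single shared length (columns), and unique non-missing row
#' ids.
#'
#' @param fps matrix-like object of 0/1 values with rownames.
#' @return validated numeric matrix.
#' @export
as_fingerprint_matrix <- function(fps) {
  if (is.null(dim(fps))) fps <- matrix(fps, nrow = 1)
  fps <- as.matrix(fps)
  storage.mode(fps) <- "numeric"
  if (ncol(fps) == 0L) stop("fingerprints must have positive length")
  if (!all(fps %in% c(0, 1)))
    stop("fingerprint matrix must be binary (0/1)")
  if (is.null(rownames(fps)))
    rownames(fps) <- as.character(seq_len(nrow(fps)))
  if (anyDuplicated(rownames(fps)))
    stop("compound ids (rownames) must be unique")
  fps
}
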