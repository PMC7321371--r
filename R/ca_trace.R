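#' Construct a C-alpha trace
#'
#' A `ca_trace` is the unit the pipeline operates on: the ordered list of
#' alpha-carbon coordinates of one structure, one row per residue, in
#' Angstrom. All templates of an ensemble must share the same residue count
#' and a one-to-one residue correspondence by index.
#'
#' @param coords numeric matrix with 3 columns (x, y, z) and one row per
#'   residue, in Angstrom.
#' @param label free-text identifier for the structure.
#' @return An object of class `ca_trace`: a list with elements `coords`
#'   (n x 3 matrix), `residue_count` and `label`.
#' @examples
#' tr <- ca_trace(matrix(rnorm(30), ncol = 3), label = "demo")
#' tr$residue_count
#' @export
ca_trace <- function(coords, label = "") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("`coords` must have exactly 3 columns (x, y, z)", call. = FALSE)
  if (nrow(coords) < 3L)
    stop("degenerate structure: a ca_trace needs at least 3 residues",
         call. = FALSE)
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords)))
    stop("all coordinates must be finite", call. = FALSE)
  dimnames(coords) <- NULL
  structure(
    list(coords = coords, residue_count = nrow(coords),
         label = as.character(label)[1]),
    class = "ca_trace"
  )
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("ca_trace '%s': %d residues\n", x$label, x$residue_count))
  invisible(x)
}

#' @export
all.equal.ca_trace <- function(target, current, ...) {
  all.equal(target$coords, current$coords, ...)
}

is_ca_trace <- function(x) inherits(x, "ca_trace")

stopifnot_same_length <- function(a, b) {
  if (a$residue_count != b$residue_count)
    stop(sprintf(
      "residue correspondence error: traces have %d and %d residues",
      a$residue_count, b$residue_count), call. = FALSE)
}

#' Read a C-alpha trace from a PDB file
#'
#' Extracts the alpha-carbon coordinates of one chain from a PDB file.
#' Only ATOM/HETATM records are interpreted; alternate locations collapse to
#' the first occurrence per residue, insertion codes are ignored with a
#' warning, and residues lacking a CA atom are skipped with a warning.
#'
#' @param path path to a PDB-format file.
#' @param chain optional single chain identifier; by default all chains are
#'   taken in file order.
#' @return A [ca_trace] labelled with the file's base name.
#' @seealso [write_ca_trace()]
#' @export
read_ca_trace <- function(path, chain = NULL) {
  if (!file.exists(path))
    stop(sprintf("cannot read PDB file '%s': no such file", path),
         call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e)
      stop(sprintf("cannot parse PDB file '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
  )
  atoms <- pdb$atom
  keep <- atoms$elety == "CA"
  if (!is.null(chain)) keep <- keep & atoms$chain %in% chain
  atoms <- atoms[keep, , drop = FALSE]
  if (any(nzchar(atoms$insert) & !is.na(atoms$insert)))
    warning("insertion codes present; they are ignored", call. = FALSE)
  # first occurrence wins for alt-loc duplicates of the same residue
  res_key <- paste(atoms$chain, atoms$resno)
  atoms <- atoms[!duplicated(res_key), , drop = FALSE]
  if (nrow(atoms) < 3L)
    stop(sprintf(
      "degenerate structure in '%s': found %d CA atoms, need at least 3",
      path, nrow(atoms)), call. = FALSE)
  ca_trace(cbind(atoms$x, atoms$y, atoms$z),
           label = sub("\\.(pdb|ent)$", "", basename(path)))
}

#' Write a C-alpha trace as a PDB file
#'
#' Emits one CA ATOM record per residue (residues numbered 1..n, chain A,
#' occupancy 1.00) at the PDB fixed-column 3-decimal precision, so that
#' [read_ca_trace()] round-trips the coordinates to within 5e-4 Angstrom.
#'
#' @param trace a [ca_trace].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_ca_trace <- function(trace, path) {
  stopifnot(is_ca_trace(trace))
  if (!nzchar(path))
    stop("cannot write PDB file: empty path", call. = FALSE)
  n <- trace$residue_count
  ok <- tryCatch({
    bio3d::write.pdb(
      file = path,
      xyz = as.vector(t(trace$coords)),
      resno = seq_len(n),
      resid = rep("ALA", n), elety = rep("CA", n), chain = rep("A", n),
      o = rep(1.00, n), b = rep(0.00, n)
    )
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop(sprintf("cannot write PDB file '%s': %s", path,
                 conditionMessage(ok)), call. = FALSE)
  invisible(path)
}

#' Flatten a trace to a coordinate vector
#'
#' Uses the package-wide atom-major convention
#' (x1, y1, z1, x2, y2, z2, ...): the flattened vector has length
#' 3 * residue_count and is the column a template contributes to the
#' ensemble matrix.
#'
#' @param trace a [ca_trace].
#' @return Numeric vector of length `3 * residue_count`.
#' @seealso [unflatten()]
#' @export
flatten <- function(trace) {
  stopifnot(is_ca_trace(trace))
  as.vector(t(trace$coords))
}

#' Rebuild a trace from a flattened coordinate vector
#'
#' Inverse of [flatten()]: `unflatten(flatten(t))` reproduces `t`.
#'
#' @param x numeric vector of length divisible by 3 (atom-major order).
#' @param label identifier for the rebuilt trace.
#' @return A [ca_trace].
#' @export
unflatten <- function(x, label = "") {
  if (length(x) %% 3L != 0L)
    stop("flattened coordinate vector length must be a multiple of 3",
         call. = FALSE)
  ca_trace(matrix(x, ncol = 3, byrow = TRUE), label = label)
}
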