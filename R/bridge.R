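#' @useDynLib cddap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Locate the Python interpreter used by the chemistry worker
#'
#' All molecular mechanics (SMILES parsing, descriptors, fingerprints,
#' reaction application, UMAP) run in a bundled batch-mode Python worker
#' backed by RDKit. The interpreter is resolved, in order, from the R option
#' `cddap.python`, the environment variable `CDDAP_PYTHON`, and finally
#' `"python"` on the `PATH`.
#'
#' @return Absolute path to the interpreter.
#' @export
cddap_python <- function() {
  cand <- getOption("cddap.python",
                    default = Sys.getenv("CDDAP_PYTHON", unset = "python"))
  path <- Sys.which(cand)
  if (!nzchar(path)) {
    stop("Python interpreter '", cand, "' not found; set options(cddap.python=)",
         call. = FALSE)
  }
  unname(path)
}

worker_script <- function() {
  p <- system.file("python", "worker.py", package = "cddap")
  if (!nzchar(p)) stop("bundled worker.py not found; reinstall cddap")
  p
}

#' Call the chemistry worker once, with a JSON request/response round trip.
#' @noRd
py_worker <- function(cmd, request) {
  req <- tempfile(fileext = ".json")
  res <- tempfile(fileext = ".json")
  on.exit(unlink(c(req, res)), add = TRUE)
  jsonlite::write_json(request, req, auto_unbox = TRUE, null = "null",
                       digits = NA)
  out <- suppressWarnings(system2(
    cddap_python(), c(worker_script(), cmd, req, res),
    stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("chemistry worker failed (", cmd, "):\n",
         paste(utils::tail(out, 12), collapse = "\n"), call. = FALSE)
  }
  jsonlite::read_json(res, simplifyVector = TRUE)
}

# NULL-preserving character extraction from a simplified JSON vector
chr_or_na <- function(x) {
  if (is.list(x)) x <- vapply(x, function(v) if (is.null(v)) NA_character_ else as.character(v), "")
  x[!nzchar(x) & is.na(x)] <- NA_character_
  as.character(x)
}

#' Canonicalise SMILES strings
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of RDKit canonical SMILES (`NA` where parsing
#'   fails).
#' @export
canonical_smiles <- function(smiles) {
  if (length(smiles) == 0) return(character())
  chr_or_na(py_worker("canon", list(smiles = as.list(smiles)))$smiles)
}

#' Count substructure matches against SMARTS patterns
#'
#' @param smiles Character vector of SMILES.
#' @param smarts Character vector of SMARTS patterns.
#' @return Integer matrix, one row per molecule and one column per pattern;
#'   rows for unparsable molecules are `NA`.
#' @export
smarts_count <- function(smiles, smarts) {
  if (length(smiles) == 0) {
    return(matrix(integer(), 0, length(smarts),
                  dimnames = list(NULL, names(smarts))))
  }
  res <- py_worker("match", list(smiles = as.list(smiles),
                                 smarts = as.list(unname(smarts))))
  counts <- matrix(as.integer(t(res$counts)), nrow = length(smiles),
                   byrow = TRUE)
  counts[counts < 0] <- NA_integer_
  colnames(counts) <- names(smarts)
  counts
}

#' Raw molecular descriptors from the chemistry worker
#'
#' Returns, per molecule: average molecular weight, monoisotopic mass,
#' Crippen clogP, Lipinski hydrogen-bond donor (N-H plus O-H hydrogens) and
#' acceptor (N plus O atoms) counts, and the eight raw QED descriptors
#' (MW, ALOGP, HBA, HBD, PSA, ROTB, AROM, ALERTS). The column `qed_rdkit`
#' carries the reference implementation's QED score and is used only as an
#' independent oracle by the test suite; [profile_molecules()] computes QED
#' in R from the raw descriptors.
#'
#' @param smiles Character vector of SMILES.
#' @return `data.frame`, one row per input; `ok = FALSE` rows are `NA`.
#' @export
raw_descriptors <- function(smiles) {
  if (length(smiles) == 0) {
    stop("raw_descriptors(): empty input")
  }
  res <- py_worker("descriptors", list(smiles = as.list(smiles)))
  num <- function(x) {
    if (is.list(x)) x <- vapply(x, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 0)
    as.numeric(x)
  }
  d <- data.frame(smiles = smiles,
                  ok = as.logical(res$ok),
                  stringsAsFactors = FALSE)
  for (col in setdiff(names(res), "ok")) d[[col]] <- num(res[[col]])
  d
}

#' Read a fingerprint sidecar file into a 0/1 integer matrix
#' @noRd
read_fp_file <- function(path, nbits) {
  lines <- readLines(path)
  mat <- matrix(0L, nrow = length(lines), ncol = nbits)
  ok <- nzchar(lines)
  if (any(ok)) {
    bits <- vapply(strsplit(lines[ok], "", fixed = TRUE),
                   function(x) as.integer(x), integer(nbits))
    mat[ok, ] <- t(bits)
  }
  mat[!ok, ] <- NA_integer_
  mat
}

#' Write a 0/1 matrix as a fingerprint sidecar file
#' @noRd
write_fp_file <- function(fps, path) {
  stopifnot(is.matrix(fps))
  lines <- apply(fps, 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

fingerprints_raw <- function(smiles, nbits, radius, kind) {
  out <- tempfile(fileext = ".fps")
  on.exit(unlink(out), add = TRUE)
  res <- py_worker("fingerprints",
                   list(smiles = as.list(smiles), nbits = nbits,
                        radius = radius, kind = kind, out = out))
  mat <- read_fp_file(out, nbits)
  rownames(mat) <- names(smiles)
  attr(mat, "failed") <- as.integer(res$failed)
  mat
}
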