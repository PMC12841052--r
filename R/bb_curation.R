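## Building-block curation: desalting, class filtering, rule-of-2 filtering,
## fingerprinting and k-means diversity selection.

# SMARTS defining the three building-block classes and their
# cross-reactivity guards. The active-methylene pattern requires a ketone
# flank (C-attached carbonyl) next to the CH2 -- that carbonyl is the one
# consumed by the enolate [3+2] cycloaddition -- plus a second activating
# group (carbonyl, sulfonyl, nitrile or aryl) on the other side, which
# admits benzyl phenyl ketone. Acids must carry exactly one COOH and no
# azide, terminal alkyne or free primary amine (self-reactive under
# amidation); alkynes exactly one terminal alkyne and no azide.
.cddap_smarts <- list(
  active_methylene = paste0(
    "[#6][CX3](=[OX1])[CH2X4]",
    "[$([CX3]=[OX1]),$([SX4](=[OX1])=[OX1]),$([CX2]#[NX1]),$(c)]"),
  terminal_alkyne = "[CX2H1]#[CX2]",
  carboxylic_acid = "[CX3](=[OX1])[OX2H1]",
  azide           = "[NX2]=[NX2+]=[NX1-]",
  primary_amine   = "[NX3H2;!$(NC=O)]"
)

#' Class-defining SMARTS patterns
#'
#' @param bb_class One of `"active_methylene"`, `"terminal_alkyne"`,
#'   `"carboxylic_acid"`; with no argument the full named list (including
#'   the cross-reactivity guard patterns) is returned.
#' @return A SMARTS string, or the named list of patterns.
#' @export
bb_class_smarts <- function(bb_class) {
  if (missing(bb_class)) return(.cddap_smarts)
  match.arg(bb_class, c("active_methylene", "terminal_alkyne",
                        "carboxylic_acid"))
  .cddap_smarts[[bb_class]]
}

#' Desalt candidate structures
#'
#' Keeps the largest covalent fragment by heavy-atom count (ties broken by
#' canonical-SMILES sort order, so the result is independent of fragment
#' order in the input) and neutralises simple protonation states. Unparsable
#' records are rejected, not fatal.
#'
#' @param smiles Character vector of raw SMILES.
#' @return `data.frame` with columns `input`, `smiles` (desalted canonical
#'   SMILES or `NA`), `ok`, `reason` (`"parse_error"` etc.).
#' @export
desalt <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) {
    return(data.frame(input = character(), smiles = character(),
                      ok = logical(), reason = character()))
  }
  res <- py_worker("desalt", list(smiles = as.list(smiles)))
  data.frame(input = smiles,
             smiles = chr_or_na(res$smiles),
             ok = as.logical(res$ok),
             reason = as.character(res$reason),
             stringsAsFactors = FALSE)
}

#' Rule-of-2 building-block profile
#'
#' A building block passes the rule of 2 iff MW < 200 g/mol, clogP < 2,
#' HBD <= 2 and HBA <= 4 (Lipinski-style counts: HBD = N-H plus O-H
#' hydrogens, HBA = N plus O atoms; clogP by the Crippen atomic-contribution
#' method).
#'
#' @param smiles Character vector of desalted SMILES.
#' @return `data.frame` with `smiles`, `mw`, `clogp`, `hbd`, `hba`,
#'   `passes`, and `reject_reasons` (comma-joined subset of
#'   `"mw","clogp","hbd","hba"`, empty iff `passes`).
#' @export
ro2_profile <- function(smiles) {
  d <- raw_descriptors(smiles)
  fail <- cbind(mw    = !(d$mw < 200),
                clogp = !(d$clogp < 2),
                hbd   = !(d$hbd <= 2),
                hba   = !(d$hba <= 4))
  reasons <- apply(fail, 1L, function(f) {
    paste(colnames(fail)[which(f)], collapse = ",")
  })
  reasons[!d$ok] <- "descriptor_error"
  data.frame(smiles = smiles,
             mw = d$mw, clogp = d$clogp, hbd = d$hbd, hba = d$hba,
             passes = d$ok & !apply(fail, 1L, any),
             reject_reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Morgan fingerprints
#'
#' Circular (ECFP-style) hashed bit fingerprints, 1024 bits and radius 2 by
#' default -- the representation used for building-block diversity
#' clustering.
#'
#' @param smiles Character vector of SMILES.
#' @param nbits,radius Fingerprint size and radius.
#' @return Integer 0/1 matrix, one row per molecule; rows for unparsable
#'   inputs are `NA` and listed in `attr(,"failed")`.
#' @export
morgan_fp <- function(smiles, nbits = 1024L, radius = 2L) {
  fingerprints_raw(smiles, nbits = nbits, radius = radius, kind = "morgan")
}

#' Functional-class (FCFP-style) circular fingerprints
#'
#' Feature-invariant Morgan fingerprints of diameter 4 (radius 2), hashed to
#' 1024 bits -- the representation used for chemical-space embedding.
#'
#' @inheritParams morgan_fp
#' @return Integer 0/1 matrix as for [morgan_fp()].
#' @export
fcfp_fp <- function(smiles, nbits = 1024L, radius = 2L) {
  fingerprints_raw(smiles, nbits = nbits, radius = radius, kind = "fcfp")
}

# squared Euclidean distances between rows of X (n x d) and C (k x d)
.sqdist <- function(X, C) {
  outer(rowSums(X^2), rowSums(C^2), "+") - 2 * tcrossprod(X, C)
}

# k-means++ seeding (Arthur & Vassilvitskii) with multiplicity weights,
# under the current RNG state
.kmeanspp <- function(X, k, w) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L, prob = w)
  d2 <- .sqdist(X, X[centers[1L], , drop = FALSE])[, 1L]
  for (i in seq_len(k - 1L)) {
    d2 <- pmax(d2, 0)
    p <- w * d2
    probs <- if (sum(p) > 0) p / sum(p) else w / sum(w)
    centers[i + 1L] <- sample.int(n, 1L, prob = probs)
    d2 <- pmin(d2, .sqdist(X, X[centers[i + 1L], , drop = FALSE])[, 1L])
  }
  centers
}

#' Diversity selection by k-means on fingerprint bits
#'
#' Lloyd k-means (k-means++ initialisation, at most 300 iterations, relative
#' centroid-shift tolerance 1e-4) on the 0/1 fingerprint coordinates under
#' Euclidean distance. The representative of each cluster is the member
#' nearest its centroid, ties broken by lower canonical-SMILES sort order.
#' Inputs are sorted by `ids` before clustering so the fixed-seed result is
#' invariant to input order.
#'
#' @param fps 0/1 fingerprint matrix (one row per molecule).
#' @param k Number of clusters (default 200).
#' @param seed Integer seed controlling initialisation.
#' @param ids Character vector of stable identifiers (canonical SMILES work
#'   well); defaults to row names.
#' @return A list of class `cddap_selection` with `k`, `seed`,
#'   `representative_ids` (ordered by cluster index) and
#'   `cluster_assignments` (named integer vector).
#' @export
kmeans_select <- function(fps, k = 200L, seed, ids = rownames(fps)) {
  stopifnot(is.matrix(fps), nrow(fps) >= 1L, !missing(seed))
  if (is.null(ids)) ids <- as.character(seq_len(nrow(fps)))
  stopifnot(length(ids) == nrow(fps), !anyDuplicated(ids))
  ord <- order(ids)
  X <- fps[ord, , drop = FALSE] * 1.0
  ids <- ids[ord]
  n <- nrow(X)
  if (n <= k) {
    if (n < k) warning("fewer inputs (", n, ") than clusters (", k,
                       "); every input is its own representative")
    assign <- seq_len(n)
    names(assign) <- ids
    out <- list(k = n, seed = as.integer(seed),
                representative_ids = ids, cluster_assignments = assign)
    class(out) <- "cddap_selection"
    return(out)
  }

  # cluster unique rows with multiplicity weights: mathematically
  # equivalent to Lloyd on the full data and exactly invariant under
  # duplication of the input vectors
  key <- apply(X, 1L, paste, collapse = "")
  first <- !duplicated(key)
  U <- X[first, , drop = FALSE]
  w <- as.vector(table(factor(key, levels = key[first])))
  m <- nrow(U)
  if (m < k) {
    # fewer distinct vectors than clusters: same degenerate path as n < k,
    # every distinct vector seeds its own cluster
    k <- m
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  C <- U[.kmeanspp(U, k, w), , drop = FALSE]
  assign_u <- integer(m)
  for (iter in seq_len(300L)) {
    D <- .sqdist(U, C)
    assign_u <- max.col(-D, ties.method = "first")
    Cnew <- C
    for (j in seq_len(k)) {
      mem <- which(assign_u == j)
      if (length(mem)) {
        Cnew[j, ] <- colSums(U[mem, , drop = FALSE] * w[mem]) / sum(w[mem])
      }
    }
    shift <- sqrt(sum((Cnew - C)^2)) / max(sqrt(sum(C^2)), .Machine$double.eps)
    C <- Cnew
    if (shift < 1e-4) break
  }
  D <- .sqdist(U, C)
  u_of_row <- match(key, key[first])
  assign <- assign_u[u_of_row]
  reps <- vapply(seq_len(k), function(j) {
    mem <- which(assign == j)
    if (!length(mem)) return(NA_character_)
    dj <- D[u_of_row[mem], j]
    best <- mem[dj <= min(dj) + 1e-12]
    sort(ids[best])[1L]          # tie-break: lower canonical sort order
  }, "")
  keep <- !is.na(reps)
  names(assign) <- ids
  out <- list(k = sum(keep), seed = as.integer(seed),
              representative_ids = reps[keep],
              cluster_assignments = assign)
  class(out) <- "cddap_selection"
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Curate a building-block candidate list
#'
#' Full curation pipeline for one building-block class:
#' desalt -> class-pattern filter (including cross-reactivity guards) ->
#' rule-of-2 filter -> Morgan fingerprint -> k-means diversity selection.
#' Mirrors the workflow that reduced a commercial catalogue to 200
#' representatives per class.
#'
#' @param candidates `data.frame` with columns `source_id` and `smiles`, or
#'   a character vector of SMILES.
#' @param bb_class `"active_methylene"`, `"terminal_alkyne"` or
#'   `"carboxylic_acid"`.
#' @param k Number of representatives to select (default 200).
#' @param seed Integer seed for the diversity selection.
#' @return `data.frame` of class `cddap_bb_set` with columns `bb_id`,
#'   `smiles`, `class`, `mw`, `clogp`, `hbd`, `hba`, `cluster`; the curation
#'   report (per-stage counts, parameters) is in `attr(, "report")`.
#' @export
curate <- function(candidates, bb_class, k = 200L, seed) {
  bb_class <- match.arg(bb_class, c("active_methylene", "terminal_alkyne",
                                    "carboxylic_acid"))
  stopifnot(!missing(seed))
  if (is.character(candidates)) {
    candidates <- data.frame(source_id = paste0("cand", seq_along(candidates)),
                             smiles = candidates, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("source_id", "smiles") %in% names(candidates)))
  n0 <- nrow(candidates)
  if (n0 == 0) stop("curate(): empty candidate set at stage 'input'")

  de <- desalt(candidates$smiles)
  keep <- de$ok
  report <- list(bb_class = bb_class, k = as.integer(k),
                 seed = as.integer(seed),
                 n_input = n0, n_desalted = sum(keep),
                 n_rejected_parse = sum(!keep))
  if (!any(keep)) stop("curate(): empty candidate set at stage 'desalt'")
  df <- data.frame(source_id = candidates$source_id[keep],
                   smiles = de$smiles[keep], stringsAsFactors = FALSE)
  # collapse desalting duplicates (same parent structure from several salts)
  df <- df[!duplicated(df$smiles), , drop = FALSE]

  ok_class <- class_filter(df$smiles, bb_class)
  report$n_class <- sum(ok_class)
  if (!any(ok_class)) stop("curate(): empty candidate set at stage 'class'")
  df <- df[ok_class, , drop = FALSE]

  prof <- ro2_profile(df$smiles)
  report$n_ro2 <- sum(prof$passes)
  if (!any(prof$passes)) stop("curate(): empty candidate set at stage 'ro2'")
  df <- df[prof$passes, , drop = FALSE]
  prof <- prof[prof$passes, , drop = FALSE]

  fps <- morgan_fp(df$smiles)
  sel <- kmeans_select(fps, k = k, seed = seed, ids = df$smiles)
  report$n_selected <- length(sel$representative_ids)

  idx <- match(sel$representative_ids, df$smiles)
  out <- data.frame(
    bb_id = sprintf("%s_%03d", substr(bb_class, 1L, 2L),
                    seq_along(idx)),
    source_id = df$source_id[idx],
    smiles = df$smiles[idx],
    class = bb_class,
    mw = prof$mw[idx], clogp = prof$clogp[idx],
    hbd = prof$hbd[idx], hba = prof$hba[idx],
    cluster = seq_along(idx),
    stringsAsFactors = FALSE)
  attr(out, "report") <- report
  class(out) <- c("cddap_bb_set", "data.frame")
  out
}

#' Class-pattern filter with cross-reactivity guards
#'
#' @param smiles Character vector of desalted SMILES.
#' @param bb_class Building-block class.
#' @return Logical vector: `TRUE` where the structure matches its class
#'   pattern and none of the class's exclusion patterns.
#' @export
class_filter <- function(smiles, bb_class) {
  bb_class <- match.arg(bb_class, c("active_methylene", "terminal_alkyne",
                                    "carboxylic_acid"))
  pat <- .cddap_smarts
  counts <- smarts_count(smiles, c(am = pat$active_methylene,
                                   alk = pat$terminal_alkyne,
                                   acid = pat$carboxylic_acid,
                                   azide = pat$azide,
                                   amine = pat$primary_amine))
  counts[is.na(counts)] <- -1L
  switch(bb_class,
    active_methylene =
      counts[, "am"] >= 1L & counts[, "azide"] == 0L &
      counts[, "alk"] == 0L & counts[, "acid"] == 0L,
    terminal_alkyne =
      counts[, "alk"] == 1L & counts[, "azide"] == 0L &
      counts[, "acid"] == 0L,
    carboxylic_acid =
      counts[, "acid"] == 1L & counts[, "azide"] == 0L &
      counts[, "alk"] == 0L & counts[, "amine"] == 0L)
}

#' Read a .smi file (one SMILES per line, optional whitespace-separated id)
#'
#' @param path File path.
#' @return `data.frame` with `source_id` and `smiles` columns.
#' @export
read_smi <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[[:space:]]+")
  smiles <- vapply(parts, `[[`, "", 1L)
  ids <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else NA_character_, "")
  ids[is.na(ids)] <- paste0("line", which(is.na(ids)))
  data.frame(source_id = ids, smiles = smiles, stringsAsFactors = FALSE)
}

#' Read building-block candidates from a delimited table
#'
#' @param path CSV/TSV path (delimiter inferred from the extension).
#' @param smiles_col Name of the SMILES column.
#' @param id_col Optional name of the identifier column.
#' @return `data.frame` with `source_id` and `smiles` columns.
#' @export
read_bb_table <- function(path, smiles_col = "smiles", id_col = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!smiles_col %in% names(tab)) {
    stop("column '", smiles_col, "' not found in ", path)
  }
  ids <- if (!is.null(id_col) && id_col %in% names(tab)) {
    as.character(tab[[id_col]])
  } else paste0("row", seq_len(nrow(tab)))
  data.frame(source_id = ids, smiles = as.character(tab[[smiles_col]]),
             stringsAsFactors = FALSE)
}

#' Write a curated building-block set (CSV + JSON report)
#'
#' @param bb_set Result of [curate()].
#' @param csv_path,report_path Output file paths (`NULL` to skip either).
#' @return Invisibly, the report list.
#' @export
write_bb_set <- function(bb_set, csv_path = NULL, report_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(bb_set), csv_path, row.names = FALSE)
  }
  rep <- attr(bb_set, "report")
  if (!is.null(report_path)) {
    jsonlite::write_json(rep, report_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(rep)
}
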