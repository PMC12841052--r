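## The compact diazide scaffold and the four stepwise reaction schemes.

# 3-azido-5-(azidomethyl)benzoic acid carrying the DNA-headpiece attachment
# as an N-methyl amide cap. The cap keeps the amide HBA that the headpiece
# linkage contributes to every warhead without adding a primary-amide HBD
# pair.
.cddap_scaffold_capped <- "CNC(=O)c1cc(CN=[N+]=[N-])cc(N=[N+]=[N-])c1"
.cddap_scaffold_acid   <- "OC(=O)c1cc(CN=[N+]=[N-])cc(N=[N+]=[N-])c1"

#' The compact diazide scaffold
#'
#' 3-azido-5-(azidomethyl)benzoic acid, the minimal diazide platform: one
#' aromatic azide (reacts first in every scheme), one benzylic azide
#' (elaborated second), and a carboxyl that anchors the DNA headpiece. For
#' property work the headpiece is represented as an N-methyl amide cap
#' (`cap = "methylamide"`); `cap = "acid"` returns the free acid
#' (molecular formula C8H6N6O2).
#'
#' @param cap `"methylamide"` (default) or `"acid"`.
#' @return SMILES string.
#' @export
cddap_scaffold <- function(cap = c("methylamide", "acid")) {
  cap <- match.arg(cap)
  if (cap == "acid") .cddap_scaffold_acid else .cddap_scaffold_capped
}

# scheme table: step1 always consumes the aromatic azide, step2 the
# benzylic site. Names A-D follow the library architectures.
.cddap_schemes <- list(
  A = list(name = "A", step1 = "enolate_cycloaddition", step2 = "cuaac",
           bb1_class = "active_methylene", bb2_class = "terminal_alkyne"),
  B = list(name = "B", step1 = "enolate_cycloaddition",
           step2 = "reduce_amidate_aliphatic",
           bb1_class = "active_methylene", bb2_class = "carboxylic_acid"),
  C = list(name = "C", step1 = "reduce_amidate_aromatic", step2 = "cuaac",
           bb1_class = "carboxylic_acid", bb2_class = "terminal_alkyne"),
  D = list(name = "D", step1 = "reduce_amidate_aromatic",
           step2 = "reduce_amidate_aliphatic",
           bb1_class = "carboxylic_acid", bb2_class = "carboxylic_acid")
)

# fixed monoisotopic mass deltas per scheme: product - (scaffold + bb1 + bb2)
.h2o <- 18.0105646863
.n2_minus_h2 <- 25.9904980536   # azide -> amine: lose N2, gain H2
.cddap_scheme_delta <- c(
  A = -.h2o,
  B = -.h2o - .n2_minus_h2 - .h2o,
  C = -.n2_minus_h2 - .h2o,
  D = 2 * (-.n2_minus_h2 - .h2o))

#' Library scheme definitions
#'
#' The four ordered transform sequences. In every scheme the aromatic azide
#' is consumed first (its higher reactivity is what makes the stepwise
#' chemistry selective), the benzylic azide second:
#' \describe{
#'   \item{A}{enolate \[3+2\] cycloaddition (active methylene), then CuAAC
#'     (terminal alkyne).}
#'   \item{B}{enolate \[3+2\] cycloaddition, then reduction + amidation
#'     (carboxylic acid).}
#'   \item{C}{reduction + amidation, then CuAAC.}
#'   \item{D}{reduction + amidation twice (two carboxylic acids).}
#' }
#'
#' @param name `"A"`, `"B"`, `"C"` or `"D"`; with no argument the full list.
#' @return A scheme definition list (`name`, `step1`, `step2`, `bb1_class`,
#'   `bb2_class`, `mass_delta`).
#' @export
library_scheme <- function(name) {
  if (missing(name)) {
    return(lapply(names(.cddap_schemes), library_scheme))
  }
  name <- match.arg(name, names(.cddap_schemes))
  sch <- .cddap_schemes[[name]]
  sch$mass_delta <- unname(.cddap_scheme_delta[name])
  sch
}

# shared single-transform driver
.apply_transform <- function(op, structures, bbs = NULL, strict = TRUE) {
  res <- py_worker("transform",
                   list(op = op, structures = as.list(structures),
                        bbs = if (is.null(bbs)) NULL else as.list(bbs)))
  smi <- chr_or_na(res$smiles)
  reason <- as.character(res$reason)
  if (strict && anyNA(smi)) {
    bad <- which(is.na(smi))[1L]
    stop(op, " failed for input ", bad, ": ", reason[bad], call. = FALSE)
  }
  attr(smi, "reason") <- reason
  smi
}

#' Enolate \[3+2\] cycloaddition at the aromatic azide
#'
#' Aromatic azide + active methylene (R2-CO-CH2-R3) gives the
#' 1-aryl-1,4,5-trisubstituted 1,2,3-triazole: the former methylene carbon
#' becomes C4 (bearing R3), the former ketone carbon becomes C5 (bearing
#' R2), and the ketone oxygen leaves as water. When an unsymmetrical
#' 1,3-diketone offers two competing ketone sites, the product with the
#' lowest canonical SMILES is chosen (deterministic) and flagged via
#' `attr(, "reason") == "ambiguous_site"`.
#'
#' @param structures SMILES of the azide-bearing component(s).
#' @param bbs SMILES of the active-methylene building block(s), recycled
#'   pairwise.
#' @param strict Stop on any failure (`TRUE`) or return `NA` with a reason
#'   attribute.
#' @return Character vector of product SMILES.
#' @export
enolate_cycloaddition <- function(structures, bbs, strict = TRUE) {
  n <- max(length(structures), length(bbs))
  .apply_transform("enolate_cycloaddition",
                   rep_len(structures, n), rep_len(bbs, n), strict)
}

#' Copper-catalysed azide-alkyne cycloaddition at the benzylic azide
#'
#' Benzylic azide + terminal alkyne gives the 1,4-disubstituted
#' 1,2,3-triazole (N1 from the azide-bearing carbon, C4 from the alkyne
#' substituent); atom-conserving. Refuses structures that still carry an
#' aromatic azide (the reactivity hierarchy demands the aromatic site react
#' first) and building blocks without exactly one terminal alkyne.
#'
#' @inheritParams enolate_cycloaddition
#' @return Character vector of product SMILES.
#' @export
cuaac <- function(structures, bbs, strict = TRUE) {
  n <- max(length(structures), length(bbs))
  .apply_transform("cuaac", rep_len(structures, n), rep_len(bbs, n), strict)
}

#' Reduce an azide to a primary amine
#'
#' Replaces -N3 by -NH2 (monoisotopic mass change -25.9905: lose N2, gain
#' 2 H). `site = "aromatic"` targets the aryl azide; `site = "aliphatic"`
#' targets the benzylic azide and refuses structures whose aromatic azide
#' is still intact.
#'
#' @param structures SMILES.
#' @param site `"aromatic"` or `"aliphatic"`.
#' @param strict Stop on failure or return `NA`.
#' @return Character vector of product SMILES.
#' @export
reduce_azide <- function(structures, site = c("aromatic", "aliphatic"),
                         strict = TRUE) {
  site <- match.arg(site)
  .apply_transform(paste0("reduce_azide_", site), structures, NULL, strict)
}

#' Amide coupling of a primary amine with a carboxylic acid
#'
#' Forms the amide with net loss of one water. Building blocks with other
#' than exactly one carboxylic acid are rejected (`"ambiguous_bb"`).
#'
#' @inheritParams enolate_cycloaddition
#' @return Character vector of product SMILES.
#' @export
amidate <- function(structures, bbs, strict = TRUE) {
  n <- max(length(structures), length(bbs))
  .apply_transform("amidate", rep_len(structures, n), rep_len(bbs, n), strict)
}

#' Enumerate a full warhead library for one scheme
#'
#' Applies the scheme's step 1 to the scaffold with every BB1 and step 2 to
#' every (intermediate, BB2) pair, in deterministic BB1-major order. Every
#' pair yields one row; per-pair transform failures are recorded with their
#' provenance and enumeration continues. Duplicate product structures
#' (distinct BB pairs giving the same warhead) are retained and flagged.
#'
#' @param scheme Scheme name (`"A"`--`"D"`) or a [library_scheme()] list.
#' @param bb1_set,bb2_set Curated building-block sets ([curate()] output) or
#'   data frames with `bb_id` and `smiles` columns.
#' @param scaffold Scaffold SMILES (default [cddap_scaffold()]).
#' @return `data.frame` of class `cddap_warheads` with columns `smiles`,
#'   `scheme`, `bb1_id`, `bb2_id`, `mw`, `exactmw`, `ok`, `reason`,
#'   `duplicate`; failures have `ok = FALSE`.
#' @export
enumerate_library <- function(scheme, bb1_set, bb2_set,
                              scaffold = cddap_scaffold()) {
  if (is.character(scheme)) scheme <- library_scheme(scheme)
  as_bb <- function(x, cls) {
    if (is.character(x)) x <- data.frame(bb_id = x, smiles = x,
                                         stringsAsFactors = FALSE)
    stopifnot(all(c("bb_id", "smiles") %in% names(x)))
    if ("class" %in% names(x) && !all(x$class == cls)) {
      stop("building-block class mismatch: scheme ", scheme$name,
           " expects ", cls)
    }
    x
  }
  bb1 <- as_bb(bb1_set, scheme$bb1_class)
  bb2 <- as_bb(bb2_set, scheme$bb2_class)
  out_csv <- tempfile(fileext = ".csv")
  on.exit(unlink(out_csv), add = TRUE)
  py_worker("enumerate",
            list(scaffold = scaffold,
                 steps = list(scheme$step1, scheme$step2),
                 bb1 = as.list(bb1$smiles), bb2 = as.list(bb2$smiles),
                 out = out_csv))
  tab <- utils::read.csv(out_csv, stringsAsFactors = FALSE,
                         colClasses = c("integer", "integer", "character",
                                        "numeric", "numeric", "character"))
  out <- data.frame(
    smiles = ifelse(nzchar(tab$smiles), tab$smiles, NA_character_),
    scheme = scheme$name,
    bb1_id = bb1$bb_id[tab$i],
    bb2_id = bb2$bb_id[tab$j],
    mw = tab$mw, exactmw = tab$exactmw,
    ok = nzchar(tab$smiles),
    reason = tab$reason,
    stringsAsFactors = FALSE)
  out$duplicate <- duplicated(out$smiles) & out$ok
  class(out) <- c("cddap_warheads", "data.frame")
  out
}

#' Write enumerated warheads to CSV and/or SDF
#'
#' @param warheads Result of [enumerate_library()].
#' @param csv_path,sdf_path Output paths (`NULL` to skip either). The SDF
#'   carries scheme and building-block provenance as record properties.
#' @return Invisibly, the number of successful products written.
#' @export
write_warheads <- function(warheads, csv_path = NULL, sdf_path = NULL) {
  ok <- warheads[warheads$ok, , drop = FALSE]
  if (!is.null(csv_path)) {
    utils::write.csv(
      ok[, c("smiles", "scheme", "bb1_id", "bb2_id", "mw")],
      csv_path, row.names = FALSE)
  }
  if (!is.null(sdf_path)) {
    py_worker("sdf_write",
              list(smiles = as.list(ok$smiles), out = sdf_path,
                   props = list(scheme = as.list(ok$scheme),
                                bb1_id = as.list(ok$bb1_id),
                                bb2_id = as.list(ok$bb2_id))))
  }
  invisible(nrow(ok))
}
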