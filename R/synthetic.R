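## Synthetic data generators: class-valid building-block sets straddling
## the rule-of-2 boundary, and a reference population emulating an
## approved-drug property mixture (drug-like small molecules plus a
## peptide-like heavy-MW, low-QED tail).

# Decoration fragments, written so that string concatenation after a class
# head ("C#C", "OC(=O)", "<activator>CC(=O)") yields valid SMILES with the
# fragment's first atom as the attachment point. The grid deliberately
# straddles the rule-of-2 boundary: small polar decorations mostly pass,
# the decor_fail set breaks MW, clogP, HBD or HBA by a wide margin, and
# borderline combinations land where the descriptors put them -- gen_bbs()
# classifies the whole grid with the package's own Ro2 filter and samples
# the pass/fail arms to the requested mixture.
.syn_frag <- local({
  benz_sub <- c("F", "C", "OC", "O", "C#N", "Cl")
  aryls <- c("c1ccccc1", sprintf("c1ccc(%s)cc1", benz_sub))
  two <- expand.grid(a = benz_sub, b = benz_sub, stringsAsFactors = FALSE)
  two <- two[as.integer(factor(two$a, benz_sub)) <=
               as.integer(factor(two$b, benz_sub)), ]
  aryls <- c(aryls, sprintf("c1cc(%s)cc(%s)c1", two$a, two$b),
             "c1ccncc1", "c1cccnc1", "c1ccoc1", "c1ccsc1", "c1cncnc1",
             "c1cc[nH]c1", "c1cnn(C)c1", "c1csc(C)n1", "c1ccc2occc2c1",
             "c1ccnnc1", "c1cc(C)on1", "c1conc1C", "c1cn(C)cn1",
             "c1ccn(C)c1")
  chains <- c("C", "CC", "CCC", "CCCC", "CC(C)", "C(C)C", "CC(C)C",
              "C1CC1", "C1CCC1", "C1CCCC1", "CC1CC1", "CO", "CCO", "CCCO",
              "COC", "CCOC", "COCC", "CC#N", "CCC#N", "CCF", "CCCF",
              "C(F)(F)F", "CCl", "C(C)O", "CC(C)O", "C(C)CO", "COCCO",
              "C1CCOCC1", "C1CCOC1", "C1COC1", "CN1CCOCC1", "CN1CCCC1",
              "CN(C)C", "CCN(C)C", "CC(=O)N(C)C", "CC(=O)OC", "CCC(=O)OC",
              "CC(=O)OCC", "CN(C)C(=O)C", "CS(=O)(=O)C", "CCS(=O)(=O)C")
  decor_fail <- c("CCCCCCCCCC", "CCCCCCCCCCCC", "c1ccc2ccccc2c1",
                  "c1ccc(-c2ccccc2)cc1", "CCCCc1ccccc1", "CCCCCCc1ccccc1",
                  "c1ccc(C(F)(F)F)cc1", "c1ccc(Cl)c(Cl)c1",
                  "C1CCCCCCCCCCC1", "CCCCCCCC(C)C", "c1ccc(OCCCCCCCC)cc1",
                  "C(O)C(O)C(O)CO", "COCCOCCOCCOC", "CCCCCCCCc1ccccc1",
                  "c1ccc(-c2ccccc2Cl)cc1", "C(F)(F)C(F)(F)C(F)(F)F")
  linkers <- c("", "C", "CC", "CCC", "C(C)")
  decors <- unique(c(
    as.vector(outer(linkers, c(aryls, chains), paste0)),
    as.vector(outer(linkers[1:2], decor_fail, paste0))))
  activators <- c("N#C", "COC(=O)", "CCOC(=O)", "CC(C)OC(=O)",
                  "CS(=O)(=O)", "CCS(=O)(=O)", "CN(C)C(=O)", "CNC(=O)",
                  "CC(=O)", "CCC(=O)", "C1CC1C(=O)", "c1ccccc1",
                  "c1ccncc1", "c1ccc(F)cc1")
  list(decors = decors, activators = activators)
})

# per-session cache for the classified grids (deterministic contents)
.cddap_cache <- new.env(parent = emptyenv())

# all template candidates of one class
.bb_universe <- function(bb_class) {
  f <- .syn_frag
  switch(bb_class,
    terminal_alkyne = paste0("C#C", f$decors),
    carboxylic_acid = paste0("OC(=O)", f$decors),
    active_methylene = as.vector(outer(f$activators, f$decors,
                                       function(a, d) paste0(a, "CC(=O)", d))))
}

# classify the template universe once per class: keep class-valid,
# canonically unique candidates, split into Ro2 pass/fail arms
.bb_arms <- function(bb_class) {
  key <- paste0("arms_", bb_class)
  if (!is.null(.cddap_cache[[key]])) return(.cddap_cache[[key]])
  uni <- .bb_universe(bb_class)
  can <- canonical_smiles(uni)
  keep <- !is.na(can) & !duplicated(can)
  uni <- uni[keep]
  uni <- uni[class_filter(uni, bb_class)]
  prof <- ro2_profile(uni)
  arms <- list(pass = uni[prof$passes], fail = uni[!prof$passes])
  .cddap_cache[[key]] <- arms
  arms
}

# reference-population samplers ------------------------------------------

.ref_smallmol <- list(
  heads = c("c1ccccc1", "c1ccc(F)cc1", "c1ccc(Cl)cc1", "c1ccc(C)cc1",
            "c1ccc(OC)cc1", "c1ccncc1", "c1cccnc1", "c1cncnc1",
            "c1ccc2ncccc2c1", "c1ccc2[nH]ccc2c1", "c1ccoc1", "c1ccsc1",
            "c1ccc(C#N)cc1", "c1ccc(O)cc1", "Cc1ccccc1", "c1cnn(C)c1",
            "c1ccc2ccccc2c1", "c1ccc(S(C)(=O)=O)cc1"),
  linkers = c("C(=O)N(C)", "C(=O)NC", "CC(=O)N(C)", "S(=O)(=O)N(C)",
              "OCC(=O)N(C)", "C(=O)N(CC)", "CNC(=O)C", "COC(=O)",
              "CN(C)C(=O)", "C(=O)NCC", "N(C)C(=O)", "CN(C)S(=O)(=O)",
              "OC(=O)", "C(=O)N(C)C"),
  tails = c("c1ccccc1", "c1ccc(F)cc1", "c1ccncc1", "c1ccc(OC)cc1",
            "C1CC1", "C1CCCC1", "C1CCCCC1", "C1CCOCC1",
            "CC1CCCCC1", "Cc1ccccc1", "CCO", "C(C)C", "c1ccc(Cl)cc1",
            "c1cccnc1", "C1CCNCC1", "CC(C)C", "c1ccco1", "CCN(C)C")
)

# amide residues for the peptide-like heavy tail, with average residue
# masses (used to steer chains above MW 1500)
.ref_residues <- c("NCC(=O)" = 57.05, "NC(C)C(=O)" = 71.08,
                   "NC(CO)C(=O)" = 87.08, "NC(C(C)C)C(=O)" = 99.13,
                   "NC(Cc1ccccc1)C(=O)" = 147.18)

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Generate synthetic building-block candidates
#'
#' Template-constructed candidates of one class, spanning the rule-of-2
#' pass/fail boundary. Each molecule is a class head (terminal alkyne,
#' carboxylic acid, or ketone-flanked active methylene) plus decorations
#' drawn from a fixed combinatorial grid; the grid is classified with the
#' package's own Ro2 filter and the pass/fail arms are sampled so the
#' realised Ro2-fail fraction is binomial around `fraction_ro2_fail`. The
#' class pattern holds for every molecule by construction, candidates are
#' canonically unique, and the output is deterministic under `seed`.
#'
#' @param bb_class Building-block class.
#' @param n Number of candidates.
#' @param seed Integer seed.
#' @param fraction_ro2_fail Target fraction drawn from the Ro2-fail arm
#'   (default 0.3, a realistic catalogue attrition at this stage).
#' @return `data.frame` with `source_id` and `smiles`, ready for
#'   [curate()].
#' @export
gen_bbs <- function(bb_class, n, seed, fraction_ro2_fail = 0.3) {
  bb_class <- match.arg(bb_class, c("active_methylene", "terminal_alkyne",
                                    "carboxylic_acid"))
  stopifnot(n >= 1, fraction_ro2_fail >= 0, fraction_ro2_fail <= 1)
  arms <- .bb_arms(bb_class)
  with_seed(seed, {
    n_fail <- stats::rbinom(1L, n, fraction_ro2_fail)
    n_pass <- n - n_fail
    if (n_fail > length(arms$fail) || n_pass > length(arms$pass)) {
      stop("gen_bbs(): requested ", n, " candidates (", n_pass, " pass / ",
           n_fail, " fail) exceeds template capacity (",
           length(arms$pass), " pass / ", length(arms$fail), " fail)")
    }
    smiles <- sample(c(sample(arms$pass, n_pass), sample(arms$fail, n_fail)))
    data.frame(source_id = sprintf("syn_%s_%04d", substr(bb_class, 1, 2),
                                   seq_len(n)),
               smiles = smiles, stringsAsFactors = FALSE)
  })
}

.gen_heavy <- function(n_heavy) {
  res <- names(.ref_residues)
  vapply(seq_len(n_heavy), function(i) {
    len <- sample(25:60, 1L)
    idx <- sample(length(res), len, replace = TRUE)
    # extend until the chain clears MW 1500 (cap at 60 residues)
    while (sum(.ref_residues[idx]) + 18 <= 1500 && length(idx) < 60L) {
      idx <- c(idx, sample(length(res), 1L))
    }
    paste0(paste(res[idx], collapse = ""), "O")
  }, "")
}

#' Generate a synthetic approved-drug-like reference population
#'
#' A mixture population: a majority component of drug-like small molecules
#' (aryl head + polar linker + ring/chain tail; MW roughly 200--450, QED
#' well above 0.2) plus a heavy tail of linear oligo-amide chains
#' (glycine/alanine-like repeats, 25--60 residues, MW > 1500) whose QED
#' falls below 0.2 -- emulating the peptide-drug tail of an approved-drug
#' set. Deterministic under `seed`.
#'
#' @param n Population size (>= 100).
#' @param seed Integer seed.
#' @param fraction_heavy_tail Fraction of peptide-like heavy members
#'   (default 0.152).
#' @return `data.frame` with `source_id`, `smiles`, and the construction
#'   label `component` (`"smallmol"` or `"heavy"`).
#' @export
gen_reference <- function(n, seed, fraction_heavy_tail = 0.152) {
  stopifnot(n >= 100, fraction_heavy_tail >= 0, fraction_heavy_tail <= 1)
  with_seed(seed, {
    n_heavy <- stats::rbinom(1L, n, fraction_heavy_tail)
    n_small <- n - n_heavy
    sm <- .ref_smallmol
    grid_cap <- length(sm$heads) * length(sm$linkers) * length(sm$tails)
    if (n_small > grid_cap) {
      stop("gen_reference(): small-molecule capacity ", grid_cap,
           " exceeded (need ", n_small, ")")
    }
    combo <- sample(grid_cap, n_small)
    i <- (combo - 1L) %% length(sm$heads) + 1L
    j <- ((combo - 1L) %/% length(sm$heads)) %% length(sm$linkers) + 1L
    k <- (combo - 1L) %/% (length(sm$heads) * length(sm$linkers)) + 1L
    small <- paste0(sm$heads[i], sm$linkers[j], sm$tails[k])

    heavy <- character(0)
    if (n_heavy > 0) {
      heavy <- unique(.gen_heavy(n_heavy))
      tries <- 0L
      while (length(heavy) < n_heavy && tries < 50L) {
        heavy <- unique(c(heavy, .gen_heavy(n_heavy - length(heavy))))
        tries <- tries + 1L
      }
      if (length(heavy) < n_heavy) {
        stop("gen_reference(): could not draw ", n_heavy,
             " unique heavy-tail members")
      }
    }
    df <- data.frame(
      smiles = c(small, heavy),
      component = rep(c("smallmol", "heavy"), c(n_small, n_heavy)),
      stringsAsFactors = FALSE)
    df <- df[sample(nrow(df)), , drop = FALSE]
    df$source_id <- sprintf("ref_%05d", seq_len(nrow(df)))
    rownames(df) <- NULL
    df[, c("source_id", "smiles", "component")]
  })
}
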