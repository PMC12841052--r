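## Pipeline driver: curate -> enumerate A-D -> profile -> embed ->
## occupancy -> report, under one config with full seed control.

#' Assemble a pipeline run configuration
#'
#' Defaults equal the published analysis parameters: 200 building blocks
#' per class, all four schemes, UMAP with n_neighbors = 50 and the Jaccard
#' metric, KDE on a 512 x 512 lattice with occupancy threshold 0.01. The
#' whole config is serialised into every report, so each number in a
#' result traces back to a config field or a seed.
#'
#' @param seed Global integer seed; stage seeds are derived from it.
#' @param bb_files Optional named list
#'   (`active_methylene`/`terminal_alkyne`/`carboxylic_acid` -> file path)
#'   of candidate lists (.smi or CSV). When `NULL`, candidates are
#'   generated synthetically.
#' @param n_candidates Synthetic candidates generated per class before
#'   curation (ignored when `bb_files` is given).
#' @param fraction_ro2_fail Synthetic rule-of-2 failure fraction.
#' @param k Representatives per class (default 200).
#' @param schemes Library schemes to enumerate (default A--D).
#' @param reference_file Optional SMILES file for the reference population;
#'   `NULL` generates a synthetic approved-drug-like mixture.
#' @param n_reference Synthetic reference size.
#' @param fraction_heavy_tail Heavy peptide-like fraction of the synthetic
#'   reference.
#' @param n_neighbors,metric,umap_seed UMAP parameters.
#' @param kde_resolution,kde_threshold,grid_pad KDE lattice parameters.
#' @return List of class `cddap_config`.
#' @export
run_config <- function(seed = 1L,
                       bb_files = NULL,
                       n_candidates = 420L,
                       fraction_ro2_fail = 0.3,
                       k = 200L,
                       schemes = c("A", "B", "C", "D"),
                       reference_file = NULL,
                       n_reference = 3594L,
                       fraction_heavy_tail = 0.152,
                       n_neighbors = 50L,
                       metric = "jaccard",
                       umap_seed = 42L,
                       kde_resolution = 512L,
                       kde_threshold = 0.01,
                       grid_pad = 0.05) {
  cfg <- list(seed = as.integer(seed), bb_files = bb_files,
              n_candidates = as.integer(n_candidates),
              fraction_ro2_fail = fraction_ro2_fail, k = as.integer(k),
              schemes = match.arg(schemes, c("A", "B", "C", "D"),
                                  several.ok = TRUE),
              reference_file = reference_file,
              n_reference = as.integer(n_reference),
              fraction_heavy_tail = fraction_heavy_tail,
              n_neighbors = as.integer(n_neighbors), metric = metric,
              umap_seed = as.integer(umap_seed),
              kde_resolution = as.integer(kde_resolution),
              kde_threshold = kde_threshold, grid_pad = grid_pad)
  class(cfg) <- "cddap_config"
  cfg
}

.stage_seed <- function(cfg, offset) (cfg$seed * 1000L + offset) %% 2147483647L

.load_candidates <- function(path) {
  if (grepl("\\.smi$", path, ignore.case = TRUE)) read_smi(path)
  else read_bb_table(path)
}

#' Run the full analysis pipeline
#'
#' Executes curation for the three building-block classes, enumerates the
#' configured schemes, profiles every library (rule-of-5 violation counts,
#' QED, molecular weight), embeds all sets into a shared 2-D chemical
#' space (UMAP fit on the reference only), computes KDE occupancy of the
#' reference region per library, and the two summary correlations
#' (Ro5-compliant fraction vs mean QED; occupancy vs mean QED). Idempotent
#' under a fixed config.
#'
#' @param config A [run_config()] list.
#' @param out_dir Output directory; created if missing. Per-library CSVs,
#'   summary JSONs and a top-level `manifest.json` are written there.
#' @return Invisibly, the manifest list.
#' @export
run_full <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "cddap_config"))
  if (missing(out_dir)) stop("run_full(): out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config), stages = list())

  ## stage 1: building blocks
  classes <- c("active_methylene", "terminal_alkyne", "carboxylic_acid")
  bbs <- list()
  for (i in seq_along(classes)) {
    cl <- classes[[i]]
    cand <- if (!is.null(config$bb_files)) {
      .load_candidates(config$bb_files[[cl]])
    } else {
      gen_bbs(cl, config$n_candidates, seed = .stage_seed(config, i),
              fraction_ro2_fail = config$fraction_ro2_fail)
    }
    set <- curate(cand, cl, k = config$k, seed = .stage_seed(config, 10L + i))
    write_bb_set(set, file.path(out_dir, paste0("bb_", cl, ".csv")),
                 file.path(out_dir, paste0("bb_", cl, "_report.json")))
    bbs[[cl]] <- set
    manifest$stages$curation[[cl]] <- attr(set, "report")
  }

  ## stage 2 + 3: enumeration and profiling
  libs <- list()
  profiles <- list()
  summaries <- list()
  for (sch in config$schemes) {
    scheme <- library_scheme(sch)
    wh <- enumerate_library(scheme, bbs[[scheme$bb1_class]],
                            bbs[[scheme$bb2_class]])
    write_warheads(wh, csv_path = file.path(out_dir,
                                            paste0("library_", sch, ".csv")))
    libs[[sch]] <- wh
    ok <- wh[wh$ok, , drop = FALSE]
    prof <- profile_molecules(ok$smiles)
    profiles[[sch]] <- prof
    s <- summarize_library(prof)
    summaries[[sch]] <- s
    utils::write.csv(prof, file.path(out_dir, paste0("profiles_", sch, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(unclass(s),
                         file.path(out_dir, paste0("summary_", sch, ".json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest$stages$enumeration[[sch]] <-
      list(n_pairs = nrow(wh), n_ok = sum(wh$ok),
           n_duplicates = sum(wh$duplicate))
  }

  ## drug-likeness trend across libraries: Ro5VC = 0 fraction vs mean QED
  if (length(summaries) >= 3) {
    ro5vc0 <- vapply(summaries, function(s) s$ro5vc_fractions[["0"]], 0)
    mqed <- vapply(summaries, function(s) s$mean_qed, 0)
    manifest$stages$ro5vc_qed_correlation <- pearson_r(ro5vc0, mqed)
  }

  ## stage 4: reference population and embedding
  ref <- if (!is.null(config$reference_file)) {
    .load_candidates(config$reference_file)
  } else {
    gen_reference(config$n_reference, seed = .stage_seed(config, 40L),
                  fraction_heavy_tail = config$fraction_heavy_tail)
  }
  ref_prof <- profile_molecules(ref$smiles)
  manifest$stages$reference <-
    list(n = nrow(ref), median_qed = stats::median(ref_prof$qed, na.rm = TRUE),
         frac_qed_lt_02 = mean(ref_prof$qed < 0.2, na.rm = TRUE))

  lib_smiles <- lapply(libs, function(wh) wh$smiles[wh$ok])
  emb <- embed_sets(ref$smiles, lib_smiles,
                    n_neighbors = config$n_neighbors, metric = config$metric,
                    seed = config$umap_seed)
  coords_out <- do.call(rbind, c(
    list(data.frame(set = "reference", emb$reference)),
    lapply(names(emb$queries),
           function(nm) data.frame(set = nm, emb$queries[[nm]]))))
  utils::write.csv(coords_out, file.path(out_dir, "umap_coords.csv"),
                   row.names = FALSE)

  ## stage 5: KDE occupancy on a shared lattice
  grid <- build_grid(c(list(emb$reference), emb$queries),
                     resolution = config$kde_resolution,
                     pad = config$grid_pad)
  ref_map <- kde_map(emb$reference, grid, threshold = config$kde_threshold)
  occ <- list()
  for (sch in names(emb$queries)) {
    lib_map <- kde_map(emb$queries[[sch]], grid,
                       threshold = config$kde_threshold)
    occ[[sch]] <- occupancy(lib_map, ref_map, name = sch,
                            mean_qed = summaries[[sch]]$mean_qed)
  }
  manifest$stages$occupancy <- lapply(occ, unclass)
  manifest$stages$reference_kde_area <- ref_map$area
  if (length(occ) >= 3) {
    manifest$stages$occupancy_qed_correlation <- pearson_r(
      vapply(occ, function(o) o$occupancy_rate, 0),
      vapply(occ, function(o) o$mean_qed, 0))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Regression statistics for a user-supplied approved-drug table
#'
#' Import adapter for users who download a reference release themselves
#' (e.g. a ChEMBL approved-drug export): computes the rule-of-5 violation
#' distribution, median QED, the QED < 0.2 count, and the MW < 500 subset
#' statistics, for comparison against published values. Requires no
#' network access; input is a local delimited table with a SMILES column
#' (and optionally a max-phase column used to keep approved compounds
#' only).
#'
#' @param path CSV/TSV path.
#' @param smiles_col Name of the SMILES column.
#' @param max_phase_col Optional max-phase column; rows with value >= 4 are
#'   kept.
#' @return List with `n`, `ro5vc_fractions`, `median_qed`,
#'   `n_qed_lt_02`, and `mw_lt_500` (subset `n`, `median_qed`,
#'   `ro5vc_fractions`, `frac_ro5vc_le_1`).
#' @export
chembl_regression <- function(path, smiles_col = "canonical_smiles",
                              max_phase_col = NULL) {
  tab <- read_bb_table(path, smiles_col = smiles_col)
  if (!is.null(max_phase_col)) {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    full <- utils::read.table(path, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE, check.names = FALSE)
    tab <- tab[!is.na(full[[max_phase_col]]) & full[[max_phase_col]] >= 4, ]
  }
  prof <- profile_molecules(tab$smiles)
  prof <- prof[prof$ok, , drop = FALSE]
  s <- summarize_library(prof)
  sub <- prof[prof$mw < 500, , drop = FALSE]
  ssub <- summarize_library(sub)
  list(n = s$n,
       ro5vc_fractions = s$ro5vc_fractions,
       median_qed = s$median_qed,
       n_qed_lt_02 = sum(prof$qed < 0.2),
       mw_lt_500 = list(n = ssub$n, median_qed = ssub$median_qed,
                        ro5vc_fractions = ssub$ro5vc_fractions,
                        frac_ro5vc_le_1 = sum(ssub$ro5vc_fractions[c("0", "1")])))
}
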