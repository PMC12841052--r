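test_that("desalt keeps the largest fragment and handles ties and errors", {
  res <- desalt(c("CC(=O)O.[Na+].[Cl-]", "C#Cc1ccccc1", "not-a-smiles"))
  expect_equal(res$smiles[1], canonical_smiles("CC(=O)O"))
  expect_equal(res$smiles[2], canonical_smiles("C#Cc1ccccc1"))
  expect_false(res$ok[3])
  expect_equal(res$reason[3], "parse_error")

  # equal-size fragments: lower canonical sort order wins, independent of
  # the order the fragments are written in
  a <- desalt("CCO.CCN")$smiles
  b <- desalt("CCN.CCO")$smiles
  expect_equal(a, b)
  expect_equal(a, canonical_smiles("CCN"))
})

test_that("desalt neutralises simple protonation states", {
  expect_equal(desalt("CC(=O)[O-]")$smiles, canonical_smiles("CC(=O)O"))
  expect_equal(desalt("CC[NH3+]")$smiles, canonical_smiles("CCN"))
})

test_that("ro2_profile applies the four thresholds conjunctively", {
  # MW 200.28 (just over), everything else compliant -> only "mw"
  over_mw <- "CC(=O)NCCCCCCNC(=O)C"
  # cyclopropane carboxylic acid: MW 86.09, HBD 1, HBA 2, clogP < 2
  # glycerol: HBD 3 -> fails regardless of the rest
  prof <- ro2_profile(c(over_mw, fix$cpca, "OCC(O)CO"))
  expect_equal(prof$passes, c(FALSE, TRUE, FALSE))
  expect_equal(prof$reject_reasons[1], "mw")
  expect_equal(prof$reject_reasons[2], "")
  expect_match(prof$reject_reasons[3], "hbd")
  # profile fields populated and consistent with the pass flag
  expect_true(all(is.finite(prof$mw)))
  recomputed <- prof$mw < 200 & prof$clogp < 2 & prof$hbd <= 2 & prof$hba <= 4
  expect_equal(prof$passes, recomputed)
})

test_that("morgan fingerprints are deterministic 1024-bit vectors", {
  fp <- morgan_fp(c("c1ccccc1", "c1ccccc1", "C", "CC"))
  expect_equal(ncol(fp), 1024L)
  expect_equal(fp[1, ], fp[2, ])          # identical structure -> identical fp
  expect_false(all(fp[3, ] == fp[4, ]))   # methane vs ethane differ
  # reference value: benzene sets exactly 3 bits at 1024/r2
  expect_equal(sum(fp[1, ]), 3L)
})

test_that("kmeans_select honours degenerate and duplicated inputs", {
  fp <- morgan_fp(fix$acids)
  sel <- kmeans_select(fp, k = 4L, seed = 1L, ids = fix$acids)
  expect_setequal(sel$representative_ids, fix$acids)  # n = k

  expect_warning(sel2 <- kmeans_select(fp, k = 10L, seed = 1L,
                                       ids = fix$acids),
                 "fewer inputs")
  expect_setequal(sel2$representative_ids, fix$acids)

  # duplicated vector set: brute-force expectation on <= 10 points is that
  # the representative set is unchanged by duplicating every row
  smi <- c(fix$acids, fix$alkynes)
  fp8 <- rbind(morgan_fp(smi))
  rownames(fp8) <- NULL
  sel_a <- kmeans_select(fp8, k = 2L, seed = 5L, ids = smi)
  dup_ids <- c(smi, paste0(smi, " dup"))  # distinct ids, same vectors
  sel_b <- kmeans_select(rbind(fp8, fp8), k = 2L, seed = 5L, ids = dup_ids)
  expect_setequal(gsub(" dup", "", sel_b$representative_ids),
                  gsub(" dup", "", sel_a$representative_ids))
})

test_that("kmeans_select is invariant to input order under a fixed seed", {
  smi <- c(fix$acids, fix$alkynes, fix$actmeths)
  fp <- morgan_fp(smi)
  sel1 <- kmeans_select(fp, k = 3L, seed = 11L, ids = smi)
  perm <- c(7, 2, 9, 4, 12, 6, 1, 8, 3, 10, 5, 11)
  sel2 <- kmeans_select(fp[perm, ], k = 3L, seed = 11L, ids = smi[perm])
  expect_setequal(sel1$representative_ids, sel2$representative_ids)
})

test_that("class_filter enforces patterns and cross-reactivity guards", {
  expect_true(class_filter("CC(=O)CC(=O)OCC", "active_methylene"))
  expect_true(class_filter("c1ccccc1C(=O)Cc1ccccc1", "active_methylene"))
  expect_false(class_filter("CCCC", "active_methylene"))
  expect_true(class_filter("C#CCCO", "terminal_alkyne"))
  expect_false(class_filter("CC#CC", "terminal_alkyne"))     # internal
  expect_false(class_filter("C#CCC#C", "terminal_alkyne"))   # two alkynes
  expect_true(class_filter(fix$cpca, "carboxylic_acid"))
  expect_false(class_filter("OC(=O)CC(=O)O", "carboxylic_acid"))  # di-acid
  expect_false(class_filter("OC(=O)CCN=[N+]=[N-]", "carboxylic_acid"))
  expect_false(class_filter("OC(=O)CC#C", "carboxylic_acid"))
})

test_that("curate runs the full pipeline deterministically", {
  cand <- gen_bbs("carboxylic_acid", 60, seed = 3L, fraction_ro2_fail = 0.3)
  set1 <- curate(cand, "carboxylic_acid", k = 10L, seed = 2L)
  set2 <- curate(cand, "carboxylic_acid", k = 10L, seed = 2L)
  expect_identical(as.data.frame(set1), as.data.frame(set2))
  expect_equal(nrow(set1), 10L)

  # representative validity: every representative passes Ro2 and its class
  expect_true(all(class_filter(set1$smiles, "carboxylic_acid")))
  expect_true(all(ro2_profile(set1$smiles)$passes))

  rep <- attr(set1, "report")
  expect_equal(rep$n_input, 60L)
  expect_true(rep$n_ro2 <= rep$n_class)
})

test_that("curate reports empty stages and k > survivors", {
  all_fail <- gen_bbs("terminal_alkyne", 30, seed = 4L,
                      fraction_ro2_fail = 1)
  expect_error(curate(all_fail, "terminal_alkyne", k = 5L, seed = 1L),
               "stage 'ro2'")
  wrong_class <- data.frame(source_id = "x", smiles = "CCCC")
  expect_error(curate(wrong_class, "terminal_alkyne", k = 5L, seed = 1L),
               "stage 'class'")
  few <- gen_bbs("terminal_alkyne", 12, seed = 5L, fraction_ro2_fail = 0)
  expect_warning(set <- curate(few, "terminal_alkyne", k = 50L, seed = 1L),
                 "fewer inputs")
  expect_lte(nrow(set), 12L)
})

test_that("class and Ro2 filters commute", {
  cand <- gen_bbs("active_methylene", 80, seed = 6L,
                  fraction_ro2_fail = 0.5)
  smi <- desalt(cand$smiles)$smiles
  cls <- class_filter(smi, "active_methylene")
  ro2 <- ro2_profile(smi)$passes
  surv_class_first <- smi[cls][ro2[cls]]
  surv_ro2_first <- smi[ro2][cls[ro2]]
  expect_setequal(surv_class_first, surv_ro2_first)
})

test_that("filter monotonicity: adding a candidate never evicts a passer", {
  base <- gen_bbs("carboxylic_acid", 40, seed = 9L, fraction_ro2_fail = 0.3)
  prof_base <- ro2_profile(base$smiles)
  extra <- rbind(base, data.frame(source_id = "new", smiles = "OC(=O)CCCO"))
  prof_ext <- ro2_profile(extra$smiles)
  pass_base <- base$smiles[prof_base$passes]
  pass_ext <- extra$smiles[prof_ext$passes]
  expect_true(all(pass_base %in% pass_ext))
})

test_that("smi and table readers produce curate-ready candidates", {
  smi_path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("C#Cc1ccccc1 alk1", "C#CCCO", "# comment", ""), smi_path)
  tab <- read_smi(smi_path)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$smiles, c("C#Cc1ccccc1", "C#CCCO"))
  expect_equal(tab$source_id[1], "alk1")

  csv_path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(id = "a", SMILES = "OC(=O)C1CC1"),
                   csv_path, row.names = FALSE)
  tab2 <- read_bb_table(csv_path, smiles_col = "SMILES", id_col = "id")
  expect_equal(tab2$smiles, "OC(=O)C1CC1")
  expect_error(read_bb_table(csv_path, smiles_col = "nope"), "not found")
})
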