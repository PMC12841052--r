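sc <- cddap_scaffold()

test_that("the scaffold carries one aromatic azide, one benzylic azide, one amide cap", {
  counts <- smarts_count(sc, c(ar = "c[NX2]=[NX2+]=[NX1-]",
                               al = "[CX4][NX2]=[NX2+]=[NX1-]",
                               amide = "[CX3](=[OX1])[NX3]"))
  expect_equal(unname(counts[1, ]), c(1L, 1L, 1L))
})

test_that("enolate cycloaddition builds the 1,4,5-triazole with correct regiochemistry", {
  # tert-butyl acetoacetate: methyl (ketone side) ends up at C5, the
  # tert-butyl ester survives at C4; hand-built product for comparison
  got <- enolate_cycloaddition(sc, fix$tbaa)
  want <- "Cc1c(C(=O)OC(C)(C)C)nnn1-c1cc(CN=[N+]=[N-])cc(C(=O)NC)c1"
  expect_canon_equal(got, want)

  # ethyl acetoacetate: ester at C4, ketone methyl at C5
  got2 <- enolate_cycloaddition(sc, fix$etaa)
  want2 <- "CCOC(=O)c1nnn(-c2cc(CN=[N+]=[N-])cc(C(=O)NC)c2)c1C"
  expect_canon_equal(got2, want2)

  # condensation stoichiometry: product mass = azide + bb - H2O
  d <- raw_descriptors(c(sc, fix$tbaa, got))
  expect_equal(d$exactmw[3], d$exactmw[1] + d$exactmw[2] - 18.0106,
               tolerance = 1e-3 / d$exactmw[3])

  expect_error(enolate_cycloaddition(sc, "CCCC"), "incompatible_bb")
})

test_that("unsymmetrical 1,3-diketones resolve to one flagged deterministic product", {
  got <- enolate_cycloaddition(sc, "CC(=O)CC(=O)c1ccccc1")
  expect_equal(attr(got, "reason"), "ambiguous_site")
  expect_identical(got[1], enolate_cycloaddition(sc, "CC(=O)CC(=O)c1ccccc1")[1])
})

test_that("cuaac forms the 1,4-triazole, conserves atoms, and enforces order", {
  inter <- reduce_azide(sc, "aromatic")               # clear the aromatic site
  inter <- amidate(inter, fix$cpca)
  got <- cuaac(inter, fix$phenylacetylene)
  want <- paste0("CNC(=O)c1cc(NC(=O)C2CC2)cc(Cn2cc(-c3ccccc3)nn2)c1")
  expect_canon_equal(got, want)

  # atom conservation
  d <- raw_descriptors(c(inter, fix$phenylacetylene, got))
  expect_equal(d$exactmw[3], d$exactmw[1] + d$exactmw[2],
               tolerance = 1e-3 / d$exactmw[3])

  # reactivity hierarchy: benzylic CuAAC refused while the aromatic azide
  # is intact
  expect_error(cuaac(sc, fix$phenylacetylene), "aromatic_azide_present")
  # bb preconditions
  expect_error(cuaac(inter, "CC#CC"), "incompatible_bb")   # internal alkyne
  expect_error(cuaac(inter, "C#CCC#C"), "incompatible_bb") # two alkynes
})

test_that("reduce_azide swaps N3 for NH2 with the exact mass delta", {
  red <- reduce_azide(sc, "aromatic")
  counts <- smarts_count(red, c(ar = "c[NX2]=[NX2+]=[NX1-]",
                                amine = "c[NX3H2]"))
  expect_equal(unname(counts[1, ]), c(0L, 1L))
  d <- raw_descriptors(c(sc, red))
  expect_equal(d$exactmw[2] - d$exactmw[1], -25.9905, tolerance = 1e-3)
  # applying twice to the same site violates the precondition
  expect_error(reduce_azide(red, "aromatic"), "no_aromatic_azide")
  # aliphatic reduction refuses while the aromatic azide is intact
  expect_error(reduce_azide(sc, "aliphatic"), "aromatic_azide_present")
})

test_that("amidate couples one acid and rejects ambiguous building blocks", {
  amine <- reduce_azide(sc, "aromatic")
  got <- amidate(amine, fix$cpca)
  want <- "CNC(=O)c1cc(CN=[N+]=[N-])cc(NC(=O)C2CC2)c1"
  expect_canon_equal(got, want)
  d <- raw_descriptors(c(amine, fix$cpca, got))
  expect_equal(d$exactmw[3], d$exactmw[1] + d$exactmw[2] - 18.0106,
               tolerance = 1e-3 / d$exactmw[3])
  expect_error(amidate(amine, "OC(=O)CC(=O)O"), "ambiguous_bb")
})

test_that("scheme definitions match the four architectures", {
  A <- library_scheme("A")
  expect_equal(A$step1, "enolate_cycloaddition")
  expect_equal(A$step2, "cuaac")
  expect_equal(A$bb1_class, "active_methylene")
  expect_equal(A$bb2_class, "terminal_alkyne")
  D <- library_scheme("D")
  expect_equal(D$bb1_class, "carboxylic_acid")
  expect_equal(D$bb2_class, "carboxylic_acid")
  expect_equal(length(library_scheme()), 4L)
  # fixed per-scheme mass deltas
  expect_equal(library_scheme("A")$mass_delta, -18.0106, tolerance = 1e-4)
  expect_equal(library_scheme("C")$mass_delta, -25.9905 - 18.0106,
               tolerance = 1e-4)
})

test_that("enumeration is exhaustive, ordered, composable, and azide-free", {
  wh <- enumerate_library("D", fix$acids[1:3], fix$acids)
  expect_s3_class(wh, "cddap_warheads")
  expect_equal(nrow(wh), 12L)
  expect_true(all(wh$ok))
  # bb1-major deterministic order
  expect_equal(wh$bb1_id, rep(fix$acids[1:3], each = 4L))

  # 1 x 1 equals the sequential application of step1 then step2
  one <- enumerate_library("D", fix$acids[1], fix$acids[2])
  manual <- amidate(reduce_azide(amidate(reduce_azide(sc, "aromatic"),
                                         fix$acids[1]), "aliphatic"),
                    fix$acids[2])
  expect_canon_equal(one$smiles, manual)

  # every product consumed both azide handles
  az <- smarts_count(wh$smiles, c(azide = "[NX2]=[NX2+]=[NX1-]"))
  expect_true(all(az[, 1] == 0L))

  # independently hand-built product for a specific scheme-D pair:
  # cyclopropanecarboxamide at the aniline, glycolamide at the benzylamine
  pair <- wh[wh$bb1_id == fix$acids[1] & wh$bb2_id == fix$acids[3], ]
  hand <- "CNC(=O)c1cc(NC(=O)C2CC2)cc(CNC(=O)CCO)c1"
  expect_canon_equal(pair$smiles, hand)
})

test_that("enumeration records per-pair failures and flags duplicates", {
  bad_mixed <- c(fix$alkynes[1], "CC#CC")   # second is internal: step2 fails
  wh <- enumerate_library("C", fix$acids[1:2], bad_mixed)
  expect_equal(nrow(wh), 4L)
  expect_equal(sum(wh$ok), 2L)
  expect_match(wh$reason[!wh$ok], "incompatible_bb")

  # duplicate products retained and flagged (same bb offered twice)
  dup_bb2 <- data.frame(bb_id = c("x", "y"),
                        smiles = rep(fix$alkynes[1], 2L))
  wh2 <- enumerate_library("C", data.frame(bb_id = "a", smiles = fix$acids[1]),
                           dup_bb2)
  expect_equal(nrow(wh2), 2L)
  expect_equal(wh2$duplicate, c(FALSE, TRUE))
  expect_equal(wh2$smiles[1], wh2$smiles[2])
})

test_that("scheme class mismatch is rejected", {
  acids <- gen_bbs("carboxylic_acid", 4, seed = 1, fraction_ro2_fail = 0)
  set <- curate(acids, "carboxylic_acid", k = 4L, seed = 1L)
  expect_error(enumerate_library("A", set, set), "class mismatch")
})

test_that("warheads round-trip through CSV and SDF", {
  wh <- enumerate_library("D", fix$acids[1:2], fix$acids[1:2])
  csv <- withr::local_tempfile(fileext = ".csv")
  sdf <- withr::local_tempfile(fileext = ".sdf")
  n <- write_warheads(wh, csv_path = csv, sdf_path = sdf)
  expect_equal(n, 4L)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), 4L)
  expect_true(any(grepl("\\$\\$\\$\\$", readLines(sdf))))
})
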