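# Descriptor engines: molecular properties, chi indices, E-state,
# circular fingerprints and subset algebra.

test_that("molprops has the fixed 19-column inventory with sane values", {
  mp <- compute_molprops("c1ccccc1")
  expect_length(mp, 19)
  expect_named(mp, c(
    "ALogP", "Molecular_Weight", "Num_RotatableBonds", "Num_Bonds",
    "Num_Atoms", "Num_H_Acceptors", "Num_H_Acceptors_Lipinski", "HBA_Count",
    "Num_H_Donors_Lipinski", "HBD_Count", "Num_H_Donors", "Num_Rings",
    "Num_StereoBonds", "Num_AromaticBonds", "Num_AromaticRings",
    "Num_StereoAtoms", "Num_BridgeBonds", "Num_BridgeHeadAtoms",
    "Num_SpiroAtoms"))
  expect_equal(unname(mp["Num_AromaticRings"]), 1)
  expect_equal(unname(mp["Num_RotatableBonds"]), 0)
  expect_equal(unname(mp["Num_SpiroAtoms"]), 0)
  # ethanol molecular weight from standard atomic masses
  expect_equal(unname(compute_molprops("CCO")["Molecular_Weight"]),
    2 * 12.011 + 6 * 1.008 + 15.999, tolerance = 1e-3)
})

test_that("ring topology counts identify bridged and spiro systems", {
  norb <- compute_molprops("C1CC2CCC1C2")  # bicyclo[2.2.1]heptane
  expect_equal(unname(norb["Num_BridgeHeadAtoms"]), 2)
  expect_equal(unname(norb["Num_BridgeBonds"]), 2)
  spiro <- compute_molprops("C1CC12CC2")   # spiro[2.2]pentane
  expect_equal(unname(spiro["Num_SpiroAtoms"]), 1)
  naph <- compute_molprops("c1ccc2ccccc2c1")  # ortho-fusion: no bridgeheads
  expect_equal(unname(naph["Num_BridgeHeadAtoms"]), 0)
  expect_equal(unname(naph["Num_AromaticRings"]), 2)
})

test_that("stereo counts find @ centres and directional double bonds", {
  expect_equal(unname(compute_molprops("C[C@H](N)C(=O)O")["Num_StereoAtoms"]), 1)
  expect_equal(unname(compute_molprops("F/C=C/F")["Num_StereoBonds"]), 1)
  expect_equal(unname(compute_molprops("FC=CF")["Num_StereoBonds"]), 0)
})

test_that("chi indices match hand evaluation and have 12 components", {
  ch <- compute_chi("CC")
  expect_length(ch, 12)
  expect_equal(unname(ch["Chi0"]), 2.0)  # two delta=1 atoms
  expect_equal(unname(ch["Chi1"]), 1.0)  # one bond, (1*1)^(-1/2)
  # propane by hand: deltas (1,2,1); chi0 = 2 + 1/sqrt(2); chi1 = 2/sqrt(2)
  chp <- compute_chi("CCC")
  expect_equal(unname(chp["Chi0"]), 2 + 1 / sqrt(2))
  expect_equal(unname(chp["Chi1"]), 2 / sqrt(2))
  expect_equal(unname(chp["Chi2"]), 1 / sqrt(1 * 2 * 1))
  # isobutane cluster term: centre delta 3, three delta-1 leaves
  chi3c <- compute_chi("CC(C)C")["Chi3_C"]
  expect_equal(unname(chi3c), 1 / sqrt(3))
})

test_that("valence chi differs from simple chi for heteroatoms only", {
  ethane <- compute_chi("CC")
  expect_equal(unname(ethane["Chi1"]), unname(ethane["Chi1_V"]))
  ethanol <- compute_chi("CCO")
  expect_false(isTRUE(all.equal(ethanol[["Chi1"]], ethanol[["Chi1_V"]])))
})

test_that("E-state values match the hand-computed ethanol oracle", {
  # graph C1-C2-O3; delta = (1,2,1); delta_v = (1,2,5);
  # I = (delta_v+1)/delta = (2, 1.5, 6); r^2 terms at distances 1,2
  I <- c(2, 1.5, 6)
  S1 <- I[1] + (I[1] - I[2]) / 4 + (I[1] - I[3]) / 9
  S2 <- I[2] + (I[2] - I[1]) / 4 + (I[2] - I[3]) / 4
  S3 <- I[3] + (I[3] - I[1]) / 9 + (I[3] - I[2]) / 4
  es <- compute_estate("CCO")
  expect_length(es, 161)
  expect_equal(unname(es["Estate_S_sCH3"]), S1)
  expect_equal(unname(es["Estate_S_ssCH2"]), S2)
  expect_equal(unname(es["Estate_S_sOH"]), S3)
  expect_equal(unname(es["Estate_S_total"]), sum(I))  # perturbations cancel
  expect_equal(unname(es["Estate_N_sCH3"]), 1)
})

test_that("E-state perturbation antisymmetry: sum S equals sum I", {
  for (smi in c("CC", "c1ccccc1O", "CC(=O)NC1CCC1", "O=S(=O)(N)c1ccc(Cl)cc1")) {
    es <- compute_estate(smi)
    g <- qsarmatrix:::mol_graph(smi)
    av <- qsarmatrix:::estate_atom_values(g)
    expect_equal(unname(es["Estate_S_total"]), sum(av$I), tolerance = 1e-10)
  }
  # symmetric ethane: both atoms keep S = I
  g2 <- qsarmatrix:::mol_graph("CC")
  av2 <- qsarmatrix:::estate_atom_values(g2)
  expect_equal(av2$S, av2$I)
})

test_that("fingerprints are deterministic, bounded, and see propane's two environments", {
  f1 <- compute_fingerprint("c1ccccc1CCO", "ECFP6", 1024)
  f2 <- compute_fingerprint("OCCc1ccccc1", "ECFP6", 1024)
  expect_identical(f1$ids, f2$ids)          # same molecule, same multiset
  expect_lte(sum(f1$folded), 1024)
  expect_lte(sum(f1$folded), length(f1$ids))
  # radius-0 invariants of propane: CH3 vs CH2 only
  g <- qsarmatrix:::mol_graph("CCC")
  expect_length(unique(qsarmatrix:::fp_initial_invariants(g)), 2)
  # FCFP functional classes: phenol and aniline N/O differ
  fc <- compute_fingerprint("c1ccccc1O", "FCFP4", 512)
  expect_lte(max(fc$folded), 1)
})

test_that("descriptor values are invariant to atom renumbering", {
  variants <- list(
    c("CCO", "OCC", "C(O)C"),
    c("c1ccccc1C(=O)O", "OC(=O)c1ccccc1"),
    c("CC(C)N", "NC(C)C")
  )
  for (v in variants) {
    chis <- lapply(v, compute_chi)
    ests <- lapply(v, compute_estate)
    fps <- lapply(v, function(s) compute_fingerprint(s, "ECFP6", 256)$ids)
    for (i in seq_along(v)[-1]) {
      expect_equal(chis[[i]], chis[[1]])
      expect_equal(ests[[i]], ests[[1]])
      expect_identical(fps[[i]], fps[[1]])
    }
  }
})

test_that("subset algebra reproduces the standard combination sizes", {
  s <- default_subsets()
  sizes <- setNames(s$size, s$label)
  expect_equal(unname(sizes[c("Chi", "ECFP6", "Estate", "FCFP4", "Molprops")]),
    c(12, 1, 161, 1, 19))
  expect_equal(unname(sizes["Chi_Molprops"]), 31)
  expect_equal(unname(sizes["ECFP6_Molprops"]), 20)
  expect_equal(unname(sizes["Estate_Molprops"]), 180)
  expect_equal(unname(sizes["FCFP4_Molprops"]), 20)
  expect_equal(unname(sizes["Chi_ECFP6_Estate_FCFP4_Molprops"]), 194)
})

test_that("make_subsets rejects unknown blocks and duplicate labels", {
  expect_error(make_subsets(list(a = "NotABlock")), "unknown block")
  expect_error(make_subsets(list(a = "Chi", a = "Molprops")), "duplicate")
})

test_that("descriptor matrices cover all records with no missing values", {
  desc <- cls_desc()
  expect_length(desc$record_ids, nrow(cls_ds()))
  for (b in names(desc$blocks)) {
    expect_false(anyNA(desc$blocks[[b]]))
    expect_equal(rownames(desc$blocks[[b]]), desc$record_ids)
  }
  # folding is a pure function of ids and width
  ids <- desc$fp_ids$ECFP6[[1]]
  refold <- numeric(256); refold[(ids %% 256) + 1] <- 1
  expect_equal(unname(desc$blocks$ECFP6[1, ]), refold)
})
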