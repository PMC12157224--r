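test_that("SMILES parsing assigns valences and implicit hydrogens", {
  eth <- parseSmiles("CCO")
  expect_equal(nAtoms(eth), 3L)
  expect_equal(eth@atoms$hcount, c(3L, 2L, 1L))
  expect_equal(molecularFormula(eth), "C2H6O")

  benzene <- parseSmiles("c1ccccc1")
  expect_true(all(benzene@atoms$aromatic))
  expect_equal(nBonds(benzene), 6L)
  pr <- perceiveRings(benzene)
  expect_equal(pr$ringCount, 1L)
  expect_equal(pr$aromaticRingCount, 1L)

  ## charges, multi-component input, stereo markers ignored
  salt <- parseSmiles("[Zn+2].CC(=O)[O-].CC(=O)[O-]")
  expect_equal(sum(salt@atoms$charge), 0L)
  expect_equal(max(connectedComponents(salt)), 3L)
  expect_equal(molecularFormula(parseSmiles("C/C=C/C")),
               molecularFormula(parseSmiles("CC=CC")))

  expect_error(parseSmiles("C1CC"), "unclosed ring")
  expect_error(parseSmiles("[Xx]"), "cannot parse|unknown element")
  expect_error(parseSmiles("C(C)(C)(C)(C)C"), "valence violation")
})

test_that("study fixtures reproduce the printed census row by row", {
  ref <- referenceCensus()
  mols <- fixtureMols()
  for (i in seq_len(nrow(ref))) {
    cid <- ref$cid[i]
    cs <- structuralCensus(mols[[cid]])
    expect_identical(cs$mf, ref$mf[i], label = paste("MF", cid))
    expect_lt(abs(cs$mw - ref$mw[i]), 0.015, label = paste("MW", cid))
    for (e in c("C", "H", "O", "P", "S", "Zn", "N", "Cl")) {
      got <- if (e %in% names(cs$atomCounts)) cs$atomCounts[[e]] else 0L
      expect_equal(got, ref[[e]][i], label = paste(e, cid))
    }
    for (g in c("R3N", "ROH", "RCOR", "RCOOH", "RCOOR", "ROR"))
      expect_equal(unname(cs$groupCounts[[g]]), ref[[g]][i],
                   label = paste(g, cid))
    expect_equal(cs$ringCount, ref$rings[i], label = paste("rings", cid))
    expect_equal(cs$aromaticRingCount, ref$aromatics[i],
                 label = paste("aromatics", cid))
  }
  ## groups absent from the whole set
  for (m in mols) {
    gc <- detectFunctionalGroups(m)
    expect_equal(sum(gc[c("RNH2", "R2NH", "ROPO3", "RCHO", "RCCH", "RCN")]), 0L)
  }
})

test_that("SDF V2000 round trip preserves the graph and the census", {
  mols <- fixtureMols()
  lines <- writeSDF(mols)
  back <- parseSDF(lines)
  expect_length(back, length(mols))
  for (i in seq_along(mols)) {
    expect_identical(back[[i]]@cid, mols[[i]]@cid)
    expect_identical(back[[i]]@atoms$element, mols[[i]]@atoms$element)
    expect_identical(back[[i]]@atoms$charge, mols[[i]]@atoms$charge)
    expect_identical(back[[i]]@atoms$hcount, mols[[i]]@atoms$hcount)
    expect_identical(back[[i]]@bonds, mols[[i]]@bonds)
  }
  expect_identical(writeSDF(list()), character(0))
  rec <- writeSDF(parseSmiles("c1ccccc1"))
  expect_match(rec[4], "^  6  6")
  expect_error(parseSDF(c("name", "", "", "bad counts line", "$$$$")),
               "record 1")
})

test_that("explicit-hydrogen and charged SDF records parse correctly", {
  ## methane with explicit hydrogens
  rec <- c("methane", "", "",
           "  5  4  0  0  0  0  0  0  0  0999 V2000",
           sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   0, 0, 0, c("C", "H", "H", "H", "H")),
           "  1  2  1  0", "  1  3  1  0", "  1  4  1  0", "  1  5  1  0",
           "M  END", "$$$$")
  m <- parseSDF(rec)[[1]]
  expect_equal(nAtoms(m), 1L)
  expect_equal(m@atoms$hcount, 4L)
  ## M CHG on a carboxylate oxygen
  rec2 <- writeSDF(parseSmiles("CC(=O)[O-]"))
  m2 <- parseSDF(rec2)[[1]]
  expect_equal(m2@atoms$charge[4], -1L)
  expect_equal(m2@atoms$hcount[4], 0L)
})

test_that("ring perception realizes the cycle-space dimension on random graphs", {
  for (s in 1:50) {
    m <- randomMolecule(s, nHeavy = 3L + (s %% 10L), ringProb = 0.25)
    pr <- perceiveRings(m)
    dimExpected <- nBonds(m) - nAtoms(m) + max(connectedComponents(m))
    expect_equal(pr$ringCount, dimExpected, label = paste("seed", s))
  }
  expect_equal(perceiveRings(parseSmiles("C1CCCCC1"))$aromaticRingCount, 0L)
  expect_equal(perceiveRings(fixtureMols()[["70355"]])[c(1, 2)],
               list(ringCount = 2L, aromaticRingCount = 1L))
})

test_that("Kekule and aromatic-form benzene normalize to the same graph", {
  kek <- normalizeAromaticity(parseSmiles("C1=CC=CC=C1"))
  expect_true(all(kek@atoms$aromatic))
  expect_true(all(kek@bonds$order == "aromatic"))
  r <- mcs(parseSmiles("C1=CC=CC=C1"), parseSmiles("c1ccccc1"))
  expect_equal(r@c, 6L)
})

test_that("functional-group precedence never double-counts oxygens", {
  mols <- c(fixtureMols(),
            lapply(1:30, function(s) randomMolecule(s, nHeavy = 8L)))
  for (m in mols) {
    gc <- detectFunctionalGroups(m)
    nO <- sum(m@atoms$element == "O")
    expect_gte(nO, gc[["ROH"]] + 2L * gc[["RCOOH"]] + 2L * gc[["RCOOR"]] +
                 gc[["RCOR"]] + gc[["ROR"]])
  }
})

test_that("molecular weight agrees with the ChemmineR oracle", {
  ## cross-check on the aliphatic fixtures (ChemmineR's implicit-H model
  ## does not handle the aromatic bond-type-4 records this package writes)
  suppressWarnings(suppressMessages(library(ChemmineR)))
  sub <- fixtureMols()[c("12738", "31250", "172473")]
  tmp <- tempfile(fileext = ".sdf")
  writeSDF(sub, tmp)
  sdfset <- suppressWarnings(read.SDFset(tmp))
  ours <- vapply(sub, molecularWeight, numeric(1))
  theirs <- suppressWarnings(MW(sdfset, addH = TRUE))
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-6)
})
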