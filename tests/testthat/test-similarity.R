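test_that("atom-pair fingerprints encode typed pairs at bond distances", {
  eth <- atomPairSet(parseSmiles("CCO"))
  expect_length(eth, 3L)
  expect_length(unique(eth), 3L)
  expect_length(atomPairSet(parseSmiles("C")), 0L)
  ## benzene: one atom type, three distinct distances (1, 2, 3)
  bz <- atomPairSet(parseSmiles("c1ccccc1"))
  expect_length(bz, 15L)
  expect_length(unique(bz), 3L)
  expect_setequal(as.integer(sub(".*\\|", "", unique(bz))), 1:3)
  ## pairs across disconnected components are omitted
  two <- atomPairSet(parseSmiles("CC.OO"))
  expect_length(two, 2L)
})

test_that("atom-pair Tanimoto: self-identity, disjoint sets, printed cells", {
  mols <- fixtureMols()
  for (cid in c("4632", "11178", "91601"))
    expect_equal(tanimotoAP(mols[[cid]], mols[[cid]]), 1)
  expect_equal(tanimotoAP(parseSmiles("CCCCCC"), parseSmiles("OCO")), 0)
  expect_warning(z <- tanimotoAP(parseSmiles("C"), parseSmiles("O")),
                 "empty")
  expect_equal(z, 0)
  ## printed study cells (counted-multiset convention)
  printed <- list(c("4632", "8569", 0.76), c("4632", "8572", 0.70),
                  c("4632", "8571", 0.42), c("8569", "8571", 0.55),
                  c("62531", "77470", 0.66), c("11178", "31250", 0.42),
                  c("12738", "31250", 0.52), c("17113", "62485", 0.44),
                  c("15797", "4992761", 0.34))
  for (p in printed)
    expect_equal(round(tanimotoAP(mols[[p[1]]], mols[[p[2]]]), 2),
                 as.numeric(p[3]), label = paste("AP", p[1], p[2]))
})

test_that("atom-pair similarity agrees with the ChemmineR implementation", {
  suppressWarnings(suppressMessages(library(ChemmineR)))
  mols <- fixtureMols()[c("4632", "8569", "8572", "17113", "31404")]
  tmp <- tempfile(fileext = ".sdf")
  writeSDF(mols, tmp)
  sdfset <- suppressWarnings(read.SDFset(tmp))
  apset <- suppressWarnings(sdf2ap(sdfset))
  for (i in 1:4) for (j in (i + 1):5) {
    ours <- tanimotoAP(mols[[i]], mols[[j]])
    theirs <- suppressWarnings(cmp.similarity(apset[i], apset[j]))
    expect_lt(abs(ours - theirs), 0.05,
              label = paste("AP vs ChemmineR", i, j))
  }
})

test_that("apMatrix is symmetric with unit diagonal and stores the cutoff", {
  one <- apMatrix(fixtureMols()["4632"])
  expect_equal(unname(simValues(one)), matrix(1, 1, 1))
  mols <- fixtureMols()[1:6]
  S <- apMatrix(mols, cutoff = 0)
  v <- simValues(S)
  expect_equal(v, t(v))
  expect_equal(unname(diag(v)), rep(1, 6))
  expect_equal(S@cutoff, 0)
})

test_that("MCS: identity, symmetry, and printed study values", {
  bz <- parseSmiles("c1ccccc1")
  r <- mcs(bz, bz)
  expect_equal(r@c, 6L)
  expect_equal(ocCoef(r), 1)
  expect_equal(tcCoef(r), 1)
  mols <- fixtureMols()
  ## Fig 6 values
  r1 <- mcs(mols[["4632"]], mols[["8572"]])
  expect_equal(r1@c, 16L)
  expect_equal(round(tcCoef(r1), 2), 0.94)
  r2 <- mcs(mols[["8571"]], mols[["8572"]])
  expect_equal(r2@c, 16L)
  expect_equal(ocCoef(r2), 1)
  expect_equal(round(tcCoef(r2), 2), 0.89)
  r3 <- mcs(mols[["11178"]], mols[["4992761"]])
  expect_equal(r3@c, 7L)
  expect_equal(round(ocCoef(r3), 2), 0.22)
  expect_equal(round(tcCoef(r3), 2), 0.11)
  ## order symmetry
  for (s in 1:15) {
    a <- randomMolecule(s, nHeavy = 4L + s %% 6L)
    b <- randomMolecule(100 + s, nHeavy = 4L + (s + 3L) %% 6L)
    expect_equal(mcs(a, b)@c, mcs(b, a)@c, label = paste("sym", s))
  }
})

test_that("MCS equals the exhaustive oracle and recovers planted cores", {
  for (s in 1:40) {
    a <- randomMolecule(300 + s, nHeavy = 3L + s %% 8L)
    b <- randomMolecule(400 + s, nHeavy = 3L + (s + 4L) %% 8L)
    expect_equal(mcs(a, b)@c, oracleMcs(a, b), label = paste("oracle", s))
  }
  for (s in 1:15) {
    p <- plantedMcsPair(s, coreSize = 5L + s %% 5L)
    expect_equal(mcs(p$molA, p$molB)@c, p$coreSize,
                 label = paste("planted", s))
  }
})

test_that("mismatch budgets only enlarge the common substructure", {
  for (s in 1:12) {
    a <- randomMolecule(500 + s, nHeavy = 7L)
    b <- randomMolecule(600 + s, nHeavy = 7L)
    c00 <- mcs(a, b)@c
    expect_gte(mcs(a, b, au = 1L)@c, c00)
    expect_gte(mcs(a, b, bu = 1L)@c, c00)
  }
  ## a single atom mismatch bridges pyridine and benzene
  expect_equal(mcs(parseSmiles("c1ccncc1"), parseSmiles("c1ccccc1"),
                   au = 1L)@c, 6L)
})

test_that("timeout truncates the search gracefully, never with an error", {
  mols <- fixtureMols()
  r <- mcs(mols[["12738"]], mols[["64819"]], timeout = 0.001)
  expect_s4_class(r, "MCSResult")
  expect_false(r@exhausted)
  expect_lte(r@c, min(r@a, r@b))
})

test_that("mcsMatrix computes all pairs once with TC <= OC elementwise", {
  bz <- parseSmiles("c1ccccc1")
  m2 <- mcsMatrix(list(bz, bz))
  expect_equal(unname(simValues(m2$oc)), matrix(1, 2, 2))
  expect_equal(unname(simValues(m2$tc)), matrix(1, 2, 2))
  mm <- fixtureMcs()
  oc <- simValues(mm$oc); tc <- simValues(mm$tc)
  expect_true(all(tc <= oc + 1e-12))
  expect_true(all(oc >= 0 & oc <= 1))
  expect_equal(oc, t(oc))
  ## spot row against the printed overlap-coefficient table
  expect_equal(unname(round(oc["4632", c("8569", "8571", "8572")], 2)),
               c(1, 0.94, 1))
})
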