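test_that("LogP and TPSA classes follow the documented boundaries", {
  expect_equal(classifyLogP(c(12.66, 5.0, 4.99, 3.0, 1.0, 0.99, -2)),
               c("high_bioaccumulation", "borderline", "borderline", "mild",
                 "mild", "low_lipophilicity", "low_lipophilicity"))
  expect_equal(classifyLogP(5.0001), "high_bioaccumulation")
  expect_equal(classifyTPSA(c(186.12, 140, 76, 75, 60, 59.99, 0)),
               c("reduced_systemic", "higher_safety", "higher_safety",
                 "borderline", "borderline", "concern", "concern"))
  expect_error(classifyLogP(NA_real_), "finite")
  expect_error(classifyTPSA(-1), "finite")
})

test_that("the joint flag encodes the hazard and follow-up bands", {
  expect_equal(jointFlag(12.66, 74.60), "hazard")
  expect_equal(jointFlag(2.63, 46.53), "low_risk")
  expect_equal(jointFlag(9.43, 77.90), "investigate")
  expect_equal(jointFlag(3.02, 35.53), "investigate")  # borderline LogP band
  expect_equal(jointFlag(15.88, 186.12), "low_risk")   # very polar override
  ## totality: every point gets exactly one flag per axis
  grid <- expand.grid(logp = c(-3, 0.99, 1, 3, 3.01, 5, 5.01, 12, 16),
                      tpsa = c(0, 59.99, 60, 74.99, 75, 77, 83, 83.01,
                               140, 140.01, 200))
  fl <- jointFlag(grid$logp, grid$tpsa)
  expect_true(all(fl %in% c("hazard", "investigate", "low_risk")))
  expect_true(all(classifyLogP(grid$logp) %in%
                    c("high_bioaccumulation", "borderline", "mild",
                      "low_lipophilicity")))
  expect_true(all(classifyTPSA(grid$tpsa) %in%
                    c("reduced_systemic", "higher_safety", "borderline",
                      "concern")))
  ## monotonicity: raising LogP at fixed TPSA < 75 never leaves hazard
  for (tp in c(0, 30, 60, 74.9)) {
    flags <- jointFlag(seq(5.01, 20, by = 0.5), tp)
    expect_true(all(flags == "hazard"), label = paste("tpsa", tp))
  }
})

test_that("the printed descriptor table reproduces the study's flag lists", {
  risk <- riskTable(referenceDescriptors())
  hazard <- c("11178", "15797", "16386", "24667", "77470", "91601",
              "112412", "4992761")
  lowRisk <- c("4632", "8569", "8571", "8572", "17113", "64819", "70355",
               "93481")
  investigate <- c("31250", "90571", "3601357", "31404", "62485", "62531")
  expect_setequal(risk$cid[risk$joint_flag == "hazard"], hazard)
  expect_true(all(lowRisk %in% risk$cid[risk$joint_flag == "low_risk"]))
  expect_true(all(investigate %in%
                    risk$cid[risk$joint_flag == "investigate"]))
  ## the two compounds the study's example lists omit fall out of the same
  ## rules: 12738 sits in the high-LogP follow-up band (TPSA 77.90), and
  ## the low-LogP HALS/succinate salt is unflagged
  expect_equal(risk$joint_flag[risk$cid == "12738"], "investigate")
  expect_equal(risk$joint_flag[risk$cid == "172473"], "low_risk")
})

test_that("flags computed from the package's own descriptors are total", {
  desc <- descriptorTable(fixtureMols(), attachReference = FALSE)
  risk <- riskTable(desc)
  expect_equal(nrow(risk), 24L)
  expect_true(all(risk$joint_flag %in% c("hazard", "investigate",
                                         "low_risk")))
  ## agreement with the printed lists holds for the compounds whose
  ## LogP/TPSA conventions match the study's engine
  ref <- riskTable(referenceDescriptors())
  both <- merge(risk[, c("cid", "joint_flag")],
                ref[, c("cid", "joint_flag")], by = "cid")
  agree <- mean(both$joint_flag.x == both$joint_flag.y)
  expect_gte(agree, 20 / 24)
})
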