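test_that("binding-rate conversion and round trip", {
  expect_equal(logFbToFb(1.628), 42.462, tolerance = 5e-4)
  expect_equal(logFbToFb(0), 1)
  expect_equal(logFbToFb(2), 100)
  x <- c(0.3, 1.1, 1.9)
  expect_equal(fbToLogFb(logFbToFb(x)), x, tolerance = 1e-12)
})

test_that("relative changes reproduce the endpoint tables", {
  # docking score change of the 1-ethyl-5-phosphino derivative
  expect_equal(round(relativeChange(56.5253, 74.7975), 2), -24.43)
  # bioconcentration change of the 1-nitro derivative
  expect_equal(round(relativeChange(0.940, 2.436), 2), -61.41)
  # photodegradation change of the 1-nitro derivative
  expect_equal(round(relativeChange(1.801, 2.267), 2), -20.56)
  expect_equal(relativeChange(5, 5), 0)
  expect_error(relativeChange(1, 0), "nonzero")

  # scale invariance
  set.seed(44)
  v <- runif(10, 1, 5); p <- runif(10, 1, 5)
  for (c in c(0.1, -3, 7)) {
    expect_equal(relativeChange(c * v, c * p), relativeChange(v, p),
                 tolerance = 1e-10)
  }

  # full relative-change columns recompute from the fixture tables
  t3 <- loadFixture("table3")
  parent <- t3[t3$compound == "Trovafloxacin", ]
  dv <- t3[t3$compound != "Trovafloxacin", ]
  expect_equal(round(relativeChange(dv$logkow, parent$logkow), 2),
               dv$relative_error_kow_pct, tolerance = 0.011)
  expect_equal(round(relativeChange(dv$logt12, parent$logt12), 2),
               dv$relative_error_t12_pct, tolerance = 0.011)
  t6 <- loadFixture("table6")
  p6 <- t6$libdock[t6$compound == "Trovafloxacin"]
  d6 <- t6[t6$compound != "Trovafloxacin", ]
  expect_equal(round(relativeChange(d6$libdock, p6), 2),
               d6$relative_error_pct, tolerance = 0.011)
})

test_that("fb relative changes support both parent conventions", {
  # strongest reduction: 10^1.748 = 55.976 unrounded, 56.0 rounded; the
  # published -24.18% implies the rounded-parent convention
  expect_equal(round(fbRelativeChange(1.628, 1.748, roundedParent = TRUE), 2),
               -24.18)
  expect_equal(round(fbRelativeChange(1.648, 1.748, roundedParent = TRUE), 2),
               -20.60)
  expect_equal(round(fbRelativeChange(1.628, 1.748), 2), -24.14)
  # the two conventions agree within the rounding of the parent
  t2 <- loadFixture("table2")
  expect_true(all(abs(
    fbRelativeChange(t2$logfb_pred, 1.748, roundedParent = TRUE) -
      t2$relative_error_fb_pct) <= 0.011))
})

test_that("the lower-binding screen returns the eleven derivatives", {
  t2 <- loadFixture("table2")
  scr <- screenLowerBinding(data.frame(name = t2$name,
                                       logfb = t2$logfb_pred), 1.748)
  expect_identical(length(scr), 11L)
  expect_identical(scr[1], "Derivative-10")
  expect_identical(scr[2], "Derivative-11")
  expect_true(all(paste0("Derivative-", 1:11) %in% scr))

  expect_identical(
    screenLowerBinding(data.frame(name = "a", logfb = 2), 1.748),
    character(0))
  # a compound exactly at the parent value is excluded
  expect_identical(
    screenLowerBinding(data.frame(name = c("p", "d"),
                                  logfb = c(1.748, 1.5)), 1.748), "d")
})

test_that("Gibbs energy conversion matches the reaction table", {
  expect_equal(deltaG(-1704.0287, -1720.0301), -10041.0544, tolerance = 0.05)
  expect_equal(deltaG(-1841.3928, -1858.0118), -10428.5490, tolerance = 0.05)
  expect_equal(deltaG(-3.2, -3.2), 0)
  # additivity over composed reactions
  expect_equal(deltaG(-1, -3), deltaG(-1, -2) + deltaG(-2, -3),
               tolerance = 1e-9)
  # all eleven shipped paths are exergonic and agree within rounding
  t5 <- loadFixture("table5")
  dg <- deltaG(t5$g_react, t5$g_prod)
  expect_true(all(dg < 0))
  expect_true(all(abs(dg - t5$dg_kcal) <= 0.05))
})

test_that("stability holds iff the minimum frequency is positive", {
  expect_true(stabilityCheck(9.69))
  expect_false(stabilityCheck(c(-12, 30)))
  expect_error(stabilityCheck(numeric(0)), "empty")
  t4 <- loadFixture("table4")
  expect_identical(nrow(t4), 11L)
  expect_true(all(vapply(t4$min_frequency, stabilityCheck, logical(1))))
})

test_that("contact residues classify as in the docking analysis", {
  t7 <- loadFixture("table7")
  trova <- classifyContacts(data.frame(code = t7$residue,
                                       count = t7$n_trovafloxacin))
  expect_equal(unname(trova), c(9, 3))
  d10 <- classifyContacts(data.frame(code = t7$residue,
                                     count = t7$n_derivative10))
  expect_equal(unname(d10), c(6, 5))
  expect_equal(unname(classifyContacts(character(0))), c(0, 0))
  expect_error(classifyContacts("XXX"), "XXX")
  # class table consistency with the contact tables
  lut <- residueHydropathy()
  expect_identical(length(lut), 20L)
  expect_true(all(lut[c("LEU", "VAL", "PHE", "MET", "ALA", "TYR", "PRO")] ==
                    "hydrophobic"))
  expect_true(all(lut[c("GLN", "ARG", "LYS")] == "hydrophilic"))
})

test_that("mean contact distances match the measured tables", {
  expect_equal(meanContactDistance(c(5.9, 7.6, 8.2)), 7.2)
  expect_equal(meanContactDistance(c(6.2, 9.0, 12.1, 17.5, 6.1)), 10.2)
  expect_equal(meanContactDistance(4), 4)
  expect_error(meanContactDistance(numeric(0)), "empty")
  expect_error(meanContactDistance(c(3, -1)), "positive")
  t8 <- loadFixture("table8")
  for (cmp in unique(t8$compound)) {
    d <- t8$distance[t8$compound == cmp]
    expect_equal(meanContactDistance(d),
                 if (cmp == "Trovafloxacin") 7.2 else 10.2)
  }
})

test_that("RMSD series follows its closed forms", {
  base <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1, 1, 1, 1), ncol = 3,
                 byrow = TRUE)
  arr <- array(NA_real_, c(2, 5, 3))
  arr[1, , ] <- base
  arr[2, , ] <- base
  tr <- trajectory(arr)
  expect_equal(rmsdSeries(tr), c(0, 0))

  # pure translation: removed by superposition, 1 A without
  arr[2, , ] <- base + matrix(c(1, 0, 0), 5, 3, byrow = TRUE)
  tr2 <- trajectory(arr)
  expect_equal(rmsdSeries(tr2, superpose = FALSE), c(0, 1))
  expect_equal(rmsdSeries(tr2, superpose = TRUE), c(0, 0),
               tolerance = 1e-9)
})

test_that("RMSD matches an explicit per-atom loop on random frames", {
  set.seed(7)
  arr <- array(rnorm(3 * 5 * 3), c(3, 5, 3))
  tr <- trajectory(arr)
  got <- rmsdSeries(tr)
  for (f in 1:3) {
    acc <- 0
    for (i in 1:5) {
      acc <- acc + sum((arr[f, i, ] - arr[1, i, ])^2)
    }
    expect_equal(got[f], sqrt(acc / 5), tolerance = 1e-9)
  }
})

test_that("superposed RMSD is invariant under rigid motion of a frame", {
  set.seed(10)
  arr <- array(rnorm(2 * 6 * 3), c(2, 6, 3))
  tr <- trajectory(arr)
  r0 <- rmsdSeries(tr, superpose = TRUE)
  th <- 0.8
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  arr2 <- arr
  arr2[2, , ] <- arr[2, , ] %*% R + matrix(c(4, -2, 1), 6, 3, byrow = TRUE)
  expect_equal(rmsdSeries(trajectory(arr2), superpose = TRUE), r0,
               tolerance = 1e-9)
})

test_that("RMSF follows its closed form and an explicit loop", {
  # one atom oscillating +/- d along x over two frames: RMSF = d
  d <- 0.7
  arr <- array(0, c(2, 2, 3))
  arr[1, 1, 1] <- d
  arr[2, 1, 1] <- -d
  tr <- trajectory(arr, residueIds = c("A1", "A2"))
  rf <- rmsfPerResidue(tr)
  expect_equal(unname(rf["A1"]), d, tolerance = 1e-12)
  expect_equal(unname(rf["A2"]), 0)

  expect_error(rmsfPerResidue(trajectory(array(0, c(1, 2, 3)))), "two frames")

  set.seed(12)
  arr <- array(rnorm(4 * 6 * 3), c(4, 6, 3))
  rid <- c("R1", "R1", "R2", "R2", "R2", "R3")
  got <- rmsfPerResidue(trajectory(arr, rid))
  atomR <- numeric(6)
  for (i in 1:6) {
    mu <- colMeans(arr[, i, ])
    atomR[i] <- sqrt(mean(rowSums(sweep(arr[, i, ], 2, mu)^2)))
  }
  expect_equal(unname(got),
               c(mean(atomR[1:2]), mean(atomR[3:5]), atomR[6]),
               tolerance = 1e-9)
})

test_that("multi-model PDB files round-trip into trajectories", {
  pdb <- c(
    "MODEL        1",
    "ATOM      1  N   GLN A 149       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLN A 149       1.500   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  ARG A 153       0.000   2.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   GLN A 149       1.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLN A 149       2.500   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  ARG A 153       1.000   2.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "END"
  )
  f <- tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  tr <- readTrajectoryPDB(f)
  expect_identical(nFrames(tr), 2L)
  expect_identical(dim(tr@coords)[2], 3L)
  expect_identical(unique(tr@residueIds), c("GLN149", "ARG153"))
  # the second frame is the first shifted by 1 A in x
  expect_equal(rmsdSeries(tr), c(0, 1), tolerance = 1e-9)
  expect_equal(unname(rmsdSeries(tr, superpose = TRUE)[2]), 0,
               tolerance = 1e-9)
})
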