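test_that("stdev*coeff values match direct arithmetic", {
  s <- makeToySet(nMol = 10, nAtoms = 5, sigma = 0, seed = 23)
  dm <- s@descriptors
  fit <- fitPLS(dm, s@y, 2)
  map <- stdevCoeffMap(fit, dm)
  cols <- fit@columns
  sc <- cols$sdRaw * cols$blockScale
  for (k in unique(cols$field)) {
    sel <- cols$field == k
    expect_equal(map@values[[k]][cols$point[sel]],
                 unname(sc[sel] * fit@coefficients[sel]), tolerance = 1e-12)
    # masked columns carry zero
    expect_true(all(map@values[[k]][!map@kept[[k]]] == 0))
  }

  # doubling y doubles every contour value
  fit2 <- fitPLS(dm, 2 * s@y, 2)
  map2 <- stdevCoeffMap(fit2, dm)
  for (k in names(map@values)) {
    expect_equal(map2@values[[k]], 2 * map@values[[k]], tolerance = 1e-9)
  }
})

test_that("contour values are invariant to molecule order", {
  s <- makeToySet(nMol = 8, nAtoms = 5, sigma = 0, seed = 29)
  dm <- s@descriptors
  fit <- fitPLS(dm, s@y, 2)
  map <- stdevCoeffMap(fit, dm)

  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  dmP <- dm
  for (k in names(dmP@blocks)) {
    dmP@blocks[[k]] <- dmP@blocks[[k]][perm, , drop = FALSE]
  }
  fitP <- fitPLS(dmP, s@y[perm], 2)
  mapP <- stdevCoeffMap(fitP, dmP)
  for (k in names(map@values)) {
    expect_equal(mapP@values[[k]], map@values[[k]], tolerance = 1e-9)
    expect_identical(mapP@favored[[k]], map@favored[[k]])
  }
})

makeBareMap <- function(values, kept = rep(TRUE, length(values))) {
  n <- length(values)
  grid <- new("GridSpec", origin = c(0, 0, 0), spacing = 1,
              dims = c(n, 1L, 1L))
  pad <- function(v) stats::setNames(
    lapply(c("S", "E", "H", "D", "A"), function(k) v),
    c("S", "E", "H", "D", "A"))
  new("ContourMap", values = pad(values), kept = pad(kept),
      favored = pad(rep(FALSE, n)), disfavored = pad(rep(FALSE, n)),
      percentiles = c(favored = 80, disfavored = 20), grid = grid)
}

test_that("percentile thresholds pick the expected tails", {
  map <- makeBareMap(as.numeric(1:10))
  map <- thresholdContours(map, 80, 20)
  expect_identical(which(map@favored$S), c(9L, 10L))
  expect_identical(which(map@disfavored$S), c(1L, 2L))

  # all-equal values: both masks empty
  flat <- thresholdContours(makeBareMap(rep(1, 6)), 80, 20)
  expect_false(any(flat@favored$S))
  expect_false(any(flat@disfavored$S))

  expect_error(thresholdContours(map, 20, 80), "percentile")

  # masks never overlap (random maps)
  set.seed(31)
  for (rep in 1:5) {
    m <- thresholdContours(makeBareMap(rnorm(12)), 70, 30)
    expect_false(any(m@favored$S & m@disfavored$S))
  }
})

test_that("a planted positive coefficient lands in the favored mask", {
  s <- makeToySet(nMol = 10, nAtoms = 5, sigma = 0, seed = 23)
  dm <- s@descriptors
  fit <- fitPLS(dm, s@y, 3)
  map <- stdevCoeffMap(fit, dm, favPct = 80, disfavPct = 20)
  # the top-valued kept point of each field must be favored at any
  # percentile at or below its rank
  for (k in names(map@values)) {
    kept <- which(map@kept[[k]])
    if (length(kept) < 2) next
    top <- kept[which.max(map@values[[k]][kept])]
    expect_true(map@favored[[k]][top])
  }
})

test_that("site summaries match a brute-force point-in-sphere tally", {
  map <- makeBareMap(as.numeric(1:10))
  map <- thresholdContours(map, 80, 20)
  pts <- gridPoints(map@grid)
  sites <- rbind(high = c(9, 0, 0), low = c(1, 0, 0))
  sm <- summarizeSites(map, sites, radius = 1.5)
  for (s in rownames(sites)) {
    near <- which(sqrt(rowSums(sweep(pts, 2, sites[s, ])^2)) <= 1.5)
    for (k in c("S", "E")) {
      row <- sm[sm$site == s & sm$field == k, ]
      expect_identical(row$favoredPoints, sum(map@favored[[k]][near]))
      expect_identical(row$disfavoredPoints, sum(map@disfavored[[k]][near]))
    }
  }
  expect_identical(sm$flag[sm$site == "high" & sm$field == "S"], "favored")
  expect_identical(sm$flag[sm$site == "low" & sm$field == "S"], "disfavored")

  # radius too small to reach any lattice point: neutral with warning
  expect_warning(
    sm0 <- summarizeSites(map, rbind(off = c(0.5, 0.5, 0.5)), radius = 0.1),
    "no grid points")
  expect_true(all(sm0$flag == "neutral"))
})

test_that("the registry enumerates the sixteen derivatives", {
  d <- enumerateDerivatives()
  expect_identical(nrow(d), 16L)
  expect_true(all(d$valid))
  expect_identical(d$name, paste0("Derivative-", 1:16))
  # composition: eight site-1 mono-substitutions, two site-5
  # mono-substitutions, six bis-substitutions
  mono1 <- d$site1 != "NH2" & d$site5 == ""
  mono5 <- d$site1 == "NH2" & d$site5 != ""
  bis <- d$site1 != "NH2" & d$site5 != ""
  expect_identical(sum(mono1), 8L)
  expect_identical(sum(mono5), 2L)
  expect_identical(sum(bis), 6L)
  # spot-check a product formula: the 1-ethyl-5-phosphino derivative
  expect_identical(d$formula[d$name == "Derivative-10"], "C22H19F3N3O3P")
  # enumeration agrees with the shipped fixture structures
  fx <- loadFixture("derivatives")
  expect_identical(d$smiles, fx$smiles)
})

test_that("registry edge cases and the cross-product enumerator", {
  empty <- enumerateDerivatives(data.frame(name = character(0),
                                           site1 = character(0),
                                           site5 = character(0)))
  expect_identical(nrow(empty), 0L)

  reg <- crossProductRegistry(c("CH3", "SH"))
  expect_identical(nrow(reg), 2L)
  d <- enumerateDerivatives(reg)
  expect_identical(nrow(d), 2L)
  expect_true(all(d$valid))

  reg2 <- crossProductRegistry(c("CH3", "SH"), c("", "PH2"))
  expect_identical(nrow(reg2), 4L)

  expect_error(enumerateDerivatives(
    data.frame(name = "x", site1 = "XYZ", site5 = "")), "XYZ")
})
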