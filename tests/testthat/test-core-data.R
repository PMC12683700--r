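test_that("complete surface tables round-trip through read/write", {
  s <- tinySurfaces()
  path <- withr::local_tempfile(fileext = ".csv")
  writeSurfaces(s, path)
  s2 <- readSurfaces(path, tinyFrame())
  for (a in c("G", "entScalar", "AIS", "prey", "DSM"))
    expect_equal(assay(s2, a), assay(s, a), tolerance = 1e-12)
  expect_equal(S4Vectors::metadata(s2)$nFilled, 0L)
})

test_that("missing cells are filled with the region-season climatology", {
  s <- tinySurfaces()
  fr <- tinyFrame()
  path <- withr::local_tempfile(fileext = ".csv")
  writeSurfaces(s, path)
  tab <- read.csv(path)
  drop <- which(tab$region == "B" & tab$year == 2007 &
                  tab$quarter == "Mar-May" & tab$variable == "prey")
  expect_length(drop, 1L)
  tab <- tab[-drop, ]
  write.csv(tab, path, row.names = FALSE)
  s2 <- readSurfaces(path, fr)
  # independent recomputation of the fill from the written table
  keep <- tab$region == "B" & tab$quarter == "Mar-May" & tab$variable == "prey"
  expected <- mean(tab$value[keep])
  got <- assay(s2, "prey")[match("B", regionLabels(fr)),
                           stepIndex(fr, 2007, "Mar-May")]
  expect_equal(unname(got), expected, tolerance = 1e-12)
  expect_equal(S4Vectors::metadata(s2)$nFilled, 1L)
})

test_that("invalid surface tables raise errors naming the offence", {
  s <- tinySurfaces()
  path <- withr::local_tempfile(fileext = ".csv")
  writeSurfaces(s, path)
  tab <- read.csv(path)
  bad <- tab
  bad$value[5] <- -1
  write.csv(bad, path, row.names = FALSE)
  expect_error(readSurfaces(path, tinyFrame()), "negative value for")
  bad <- rbind(tab, tab[7, ])
  write.csv(bad, path, row.names = FALSE)
  expect_error(readSurfaces(path, tinyFrame()), "duplicate cell")
  bad <- tab
  bad$region[1] <- "ATLANTIS"
  write.csv(bad, path, row.names = FALSE)
  expect_error(readSurfaces(path, tinyFrame()), "unknown region")
})

test_that("simulated datasets round-trip through the dataset directory", {
  sim <- smallSim()
  dir <- withr::local_tempdir()
  writeDataset(sim$individuals, sim$observations, dir, surfaces = sim$surfaces)
  dd <- readIndividuals(dir)
  expect_equal(dd$individuals$id, sim$individuals$id)
  expect_equal(dd$individuals$birthYear, sim$individuals$birthYear)
  for (s in c("sightings", "vha", "lengths", "entanglements", "strikes",
              "calvings", "deaths")) {
    a <- obsStream(dd$observations, s); b <- obsStream(sim$observations, s)
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b, tolerance = 1e-10, info = s)
  }
  expect_true(validateDataset(dir, sim$frame))
})

test_that("histories with sightings after death are rejected", {
  ind <- data.frame(id = "w1", sex = "F", birthYear = 2000L, deathStep = 10L)
  obs <- ObservationSet(sightings = data.frame(id = "w1", t = 12L, region = "A"))
  expect_error(validateHistories(ind, obs), "after its death step")
  # unknown labels are rejected at construction
  expect_error(ObservationSet(
    entanglements = data.frame(id = "w1", t = 3L, severity = "catastrophic",
                               gearSteps = 1L)), "unknown entanglement severity")
  expect_error(ObservationSet(
    strikes = data.frame(id = "w1", t = 3L, injury = "graze")), "unknown strike injury")
})

test_that("unknown birth years pass through unimputed", {
  ind <- data.frame(id = c("w1", "w2"), sex = c("F", "M"),
                    birthYear = c(NA_integer_, 2001L),
                    deathStep = c(NA_integer_, NA_integer_))
  obs <- ObservationSet(sightings = data.frame(id = c("w1", "w2"), t = c(3L, 4L),
                                               region = c("A", "B")))
  dir <- withr::local_tempdir()
  writeDataset(ind, obs, dir)
  dd <- readIndividuals(dir)
  expect_true(is.na(dd$individuals$birthYear[1]))
  # class falls back to adult when age is unknown
  expect_equal(demographicClass("F", NA, 2010), "adult female")
})

test_that("configuration defaults, overlays and fail-closed keys behave", {
  cfg <- loadConfig(NULL)
  expect_equal(cfg$frame$regions[1], "SEUS")
  expect_equal(length(cfg$frame$regions), 7L)
  expect_equal(cfg$frame$start_year, 1970L)
  expect_equal(cfg$frame$era_break_year, 2010L)
  fr <- configFrame(cfg)
  expect_equal(nSteps(fr), 200L)

  path <- withr::local_tempfile(fileext = ".yml")
  writeLines("frame:\n  era_break_year: 2005", path)
  cfg2 <- loadConfig(path)
  expect_equal(cfg2$frame$era_break_year, 2005L)
  expect_equal(eraBreakYear(configFrame(cfg2)), 2005L)

  writeLines("frame:\n  era_brake_year: 2005", path)
  expect_error(loadConfig(path), "unknown config key.*era_brake_year")
  expect_error(loadConfig(path), "valid keys")
})
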