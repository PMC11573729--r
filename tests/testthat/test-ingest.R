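test_that("records read back with parsed timestamps and preserved order", {
  f <- tempfile(fileext = ".csv")
  df <- data.frame(site = c("S2", "S1", "S1"),
                   kind = c("wildlife", "human", "wildlife"),
                   species = c("deer", NA, "civet"),
                   timestamp = c("2017-01-05 06:30:00", "2017-01-04 10:00:00",
                                 "2017-01-06 23:59:59"))
  write.csv(df, f, row.names = FALSE)
  r <- readCameraRecords(f)
  expect_equal(nrow(r), 3)
  expect_equal(r$site, df$site)
  expect_s3_class(r$timestamp, "POSIXct")
  expect_equal(format(r$timestamp[3], "%H:%M:%S"), "23:59:59")
})

test_that("schema and timestamp errors name the problem", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(site = "S1", species = "deer"), f, row.names = FALSE)
  expect_error(readCameraRecords(f), "timestamp")
  write.csv(data.frame(site = "S1", species = "deer",
                       timestamp = c("2017-01-02 08:00:00", "2017-13-45 99:00")),
            f, row.names = FALSE)
  expect_error(readCameraRecords(f), "row\\(s\\): 2")
  expect_error(makeRecordTable("S1", "wildebeest", "x", "2017-01-01 00:00:00"),
               "unknown record kind")
})

test_that("taxon grouping relabels mapped species and nothing else", {
  r <- makeRecordTable(site = "S1", species = c("Apodemus gorkha",
                                                "Mus cervicolor", "deer"),
                       timestamp = ts_("2017-01-01 08:00:00",
                                       "2017-01-02 08:00:00",
                                       "2017-01-03 08:00:00"))
  map <- c("Apodemus gorkha" = "Mouse spp.", "Mus cervicolor" = "Mouse spp.")
  out <- aggregateTaxa(r, map)
  expect_equal(out$species, c("Mouse spp.", "Mouse spp.", "deer"))
  expect_equal(nrow(out), nrow(r))
  expect_identical(aggregateTaxa(r, character(0)), r)
  expect_identical(aggregateTaxa(r, c("absent label" = "x"))$species, r$species)
})

test_that("independence filter applies the greedy one-hour rule", {
  mins <- c(0, 30, 60, 90, 120)
  r <- makeRecordTable(site = "S1", species = "deer",
                       timestamp = ts_("2017-01-01 08:00:00") + mins * 60)
  kept <- filterIndependent(r)
  expect_equal(nrow(kept), 3)          # retained at 0, 60, 120
  expect_equal(as.numeric(kept$timestamp - kept$timestamp[1], units = "mins"),
               c(0, 60, 120))
  # 30 min apart -> one record; exactly 61 min apart -> two
  two <- function(gapMin) filterIndependent(makeRecordTable(
    site = "S1", species = "deer",
    timestamp = ts_("2017-01-01 08:00:00") + c(0, gapMin * 60)))
  expect_equal(nrow(two(30)), 1)
  expect_equal(nrow(two(61)), 2)
  expect_equal(nrow(two(60)), 2)       # tie at the window is independent
  expect_error(filterIndependent(r, -5), "non-negative")
})

test_that("independence filter is idempotent, monotone in window, streams split", {
  set.seed(3)
  r <- makeRecordTable(
    site = sample(c("S1", "S2"), 60, TRUE),
    kind = sample(c("wildlife", "wildlife", "human", "livestock"), 60, TRUE),
    species = sample(c("deer", "civet"), 60, TRUE),
    timestamp = ts_("2017-01-01 00:00:00") + sort(runif(60, 0, 5 * 86400)))
  r$species[r$kind != "wildlife"] <- NA
  once <- filterIndependent(r)
  expect_identical(filterIndependent(once), once)
  expect_equal(nrow(filterIndependent(r, 0)), nrow(r))
  sizes <- vapply(c(0, 15, 60, 240, 1e5), function(wm)
    nrow(filterIndependent(r, wm)), integer(1))
  expect_true(all(diff(sizes) <= 0))
  # blanks pass through untouched
  b <- makeRecordTable("S1", "blank", NA,
                       ts_("2017-01-01 08:00:00") + c(0, 60))
  expect_equal(nrow(filterIndependent(b)), 2)
})

test_that("detection histories bin occasions correctly", {
  dh <- buildDetectionHistory(filterIndependent(toyRecords()),
                              toyDeployments())
  expect_s4_class(dh, "DetectionHistory")
  expect_equal(unname(effort(dh)), c(74L, 79L))   # inclusive day counts
  y <- detections(dh)
  expect_equal(y["deer", ], c(S1 = 1L, S2 = 1L))  # same-day burst collapses
  expect_equal(y["civet", ], c(S1 = 1L, S2 = 0L))
  # two independent records on one day still contribute 1 occasion
  r2 <- makeRecordTable("S1", species = "deer",
                        timestamp = ts_("2017-01-02 06:00:00",
                                        "2017-01-02 20:00:00"))
  y2 <- detections(buildDetectionHistory(r2, toyDeployments()))
  expect_equal(unname(y2["deer", "S1"]), 1L)
})

test_that("occasion binning matches a brute-force day-binning oracle", {
  set.seed(9)
  days <- sort(sample(0:73, 20, replace = TRUE))
  r <- makeRecordTable("S1", species = "deer",
                       timestamp = ts_("2017-01-01 12:00:00") + days * 86400)
  dep <- data.frame(site = "S1", x = 0, y = 0,
                    start = as.Date("2017-01-01"), end = as.Date("2017-03-15"))
  for (od in c(1L, 5L, 7L)) {
    dh <- buildDetectionHistory(r, dep, occasionDays = od)
    nOcc <- 74L %/% od
    occupiedOcc <- unique(days %/% od)
    occupiedOcc <- occupiedOcc[occupiedOcc < nOcc]   # trailing partial dropped
    expect_equal(unname(effort(dh)), nOcc)
    expect_equal(unname(detections(dh)[1, 1]), length(occupiedOcc))
  }
})

test_that("window violations and unknown sites are rejected", {
  r <- makeRecordTable("S1", species = "deer",
                       timestamp = ts_("2016-12-25 08:00:00"))
  expect_error(buildDetectionHistory(r, toyDeployments()),
               "outside the deployment window")
  r2 <- makeRecordTable("S9", species = "deer",
                        timestamp = ts_("2017-01-02 08:00:00"))
  expect_error(buildDetectionHistory(r2, toyDeployments()), "S9")
})

test_that("detection history is invariant to record order and respects y <= n", {
  set.seed(21)
  sim <- smallSim()
  rec <- simulateCameraRecords(sim, seed = 5)
  shuffled <- rec$records[sample(nrow(rec$records)), ]
  dh1 <- buildDetectionHistory(filterIndependent(rec$records), rec$deployments)
  dh2 <- buildDetectionHistory(filterIndependent(shuffled), rec$deployments)
  expect_equal(detections(dh1), detections(dh2))
  expect_true(all(sweep(detections(dh1), 2, effort(dh1)) <= 0))
})

test_that("detection categories and the undetected row follow the bin edges", {
  y <- matrix(0L, 5, 3, dimnames = list(paste0("sp", 1:5), paste0("S", 1:3)))
  y[1, ] <- c(60L, 60L, 3L)   # 123 -> Abundant
  y[2, ] <- c(5L, 6L, 0L)     # 11  -> Common
  y[3, ] <- c(1L, 1L, 0L)     # 2   -> Uncommon
  y[4, ] <- c(1L, 0L, 0L)     # 1   -> Rare
  y[5, ] <- c(50L, 50L, 0L)   # 100 -> Common (upper edge)
  dh <- camtrapMSOM:::newDetectionHistory(y, c(S1 = 80L, S2 = 80L, S3 = 80L))
  tab <- detectionCategories(dh, estRichness = 10)
  expect_equal(tab$speciesCount, c(1L, 2L, 1L, 1L, 5L))
  expect_error(detectionCategories(dh, 3), "estRichness")
})

test_that("naive estimates equal model-free proportions", {
  y <- matrix(c(2L, 0L, 3L, 1L, 0L, 0L), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), c("S1", "S2", "S3")))
  dh <- camtrapMSOM:::newDetectionHistory(y, c(S1 = 10L, S2 = 10L, S3 = 10L))
  ne <- naiveEstimates(dh)
  expect_equal(ne$naivePsi, c(2 / 3, 1 / 3))
  expect_equal(ne$naiveP, c(5 / 30, 1 / 30))
  # brute force on a toy record table: fraction of sites with any detection
  dh2 <- buildDetectionHistory(filterIndependent(toyRecords()),
                               toyDeployments())
  ne2 <- naiveEstimates(dh2)
  expect_equal(ne2$naivePsi[ne2$species == "deer"], 2 / 2)
  expect_equal(ne2$naivePsi[ne2$species == "civet"], 1 / 2)
})

test_that("detection history CSVs round-trip losslessly", {
  dh <- exampleDetectionHistory()
  hp <- tempfile(fileext = ".csv"); ep <- tempfile(fileext = ".csv")
  writeDetectionHistoryCsv(dh, hp, ep)
  back <- readDetectionHistoryCsv(hp, ep)
  expect_equal(detections(back), detections(dh))
  expect_equal(effort(back), effort(dh))
})
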