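test_that("reading the four tables preserves rows and normalises values", {
  paths <- writeTinyCsvs(withr::local_tempdir())
  db <- readSrsTables(paths)
  expect_s4_class(db, "SrsDatabase")
  expect_equal(nrow(demoTable(db)), 3)
  expect_equal(nrow(drugTable(db)), 5)
  expect_equal(nrow(reacTable(db)), 5)
  expect_equal(nrow(histTable(db)), 2)
  # the year-month start date survives at month precision
  p <- parsePartialDate(drugTable(db)$start_date[5])
  expect_equal(p$precision, "month")
})

test_that("empty data files yield an empty database, not an error", {
  dir <- withr::local_tempdir()
  paths <- writeTinyCsvs(dir, demo = tinyDemo()[0, ], drug = tinyDrug()[0, ],
                         reac = tinyReac()[0, ], hist = tinyHist()[0, ])
  db <- readSrsTables(paths)
  expect_equal(nrow(demoTable(db)), 0)
  expect_equal(nrow(reacTable(db)), 0)
  expect_equal(nrow(buildPairs(db)@pairs), 0)
})

test_that("missing files and missing mandatory columns are named errors", {
  paths <- writeTinyCsvs(withr::local_tempdir())
  bad <- paths
  bad$reac <- file.path(dirname(paths$reac), "nope.csv")
  expect_error(readSrsTables(bad), "REAC", class = "pv_io_error")

  noPt <- tinyReac()
  names(noPt)[names(noPt) == "pt"] <- "event"
  paths2 <- writeTinyCsvs(withr::local_tempdir(), reac = noPt)
  expect_error(readSrsTables(paths2), "pt", class = "pv_schema_error")
})

test_that("dialects map columns, involvement codes and outcome labels", {
  # JADER-like file: coded involvement, Japanese-style outcome labels,
  # renamed columns
  drug <- tinyDrug()
  names(drug) <- c("id", "medicinal_product", "code", "start", "end", "rt")
  drug$code <- c("1", "2", "1", "1", "1")
  reac <- tinyReac()
  names(reac) <- c("id", "ae_name", "onset", "transition")
  reac$transition <- c("kaifuku", "keikai", "kaifuku", "shibou", "fumei")
  dialect <- srsDialect(
    columns = list(
      drug = c(id = "case_id", medicinal_product = "drug_name",
               code = "involvement", start = "start_date",
               end = "end_date", rt = "route"),
      reac = c(id = "case_id", ae_name = "pt", onset = "onset_date",
               transition = "outcome")),
    involvement = c("1" = "suspect", "2" = "concomitant",
                    "3" = "interacting"),
    outcomes = c(kaifuku = "recovered", keikai = "remission",
                 mikaifuku = "not_recovered", koisho = "with_sequelae",
                 shibou = "death", fumei = "unclear"))
  paths <- writeTinyCsvs(withr::local_tempdir(), drug = drug, reac = reac)
  db <- readSrsTables(paths, dialect)
  expect_equal(drugTable(db)$involvement,
               c("suspect", "concomitant", "suspect", "suspect", "suspect"))
  expect_equal(reacTable(db)$outcome,
               c("recovered", "remission", "recovered", "death", "unclear"))
})

test_that("write/read round trip reproduces records field-for-field", {
  db <- tinyDb()
  dir <- withr::local_tempdir()
  paths <- writeSrsTables(db, dir)
  db2 <- readSrsTables(as.list(paths)[c("demo", "drug", "reac", "hist")])
  expect_equal(demoTable(db2), demoTable(db))
  expect_equal(drugTable(db2), drugTable(db))
  expect_equal(reacTable(db2), reacTable(db))
  expect_equal(histTable(db2), histTable(db))
})

test_that("linkCases conserves records and reports orphans", {
  reac <- rbind(tinyReac(),
                data.frame(case_id = "Z", pt = "Nausea",
                           onset_date = "20200101", outcome = "unclear"))
  db <- srsDatabase(tinyDemo(), tinyDrug(), reac, tinyHist())
  linked <- linkCases(db)
  expect_equal(length(linked$cases), 3)
  expect_equal(nrow(linked$orphans$reac), 1)
  expect_equal(linked$orphans$reac$case_id, "Z")
  # conservation: linked reactions + orphans = REAC rows
  nLinked <- sum(vapply(linked$cases,
                        function(cs) nrow(cs$reactions), 0L))
  expect_equal(nLinked + nrow(linked$orphans$reac), nrow(reacTable(db)))
  # case A has 2 drug rows
  expect_equal(nrow(linked$cases[["A"]]$drugs), 2)
})

test_that("linking a synthetic database conserves all reactions", {
  g <- generateSrs(generatorConfig(nCases = 1000, seed = 7))
  linked <- linkCases(g$db)
  expect_equal(length(linked$cases), 1000)
  nLinked <- sum(vapply(linked$cases,
                        function(cs) nrow(cs$reactions), 0L))
  expect_equal(nLinked, nrow(reacTable(g$db)))
  expect_equal(nrow(linked$orphans$reac), 0)
})
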