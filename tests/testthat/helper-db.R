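# Hand-built miniature databases used across the IO / pair / outcome tests.

tinyDemo <- function() data.frame(
  case_id = c("A", "B", "C"),
  sex = c("female", "female", "male"),
  age_band = c("50-59", "60-69", "70-79"),
  report_period = c("2020-Q1", "2020-Q2", "2021-Q1"),
  stringsAsFactors = FALSE)

tinyDrug <- function() data.frame(
  case_id = c("A", "A", "B", "B", "C"),
  drug_name = c("olaparib", "bevacizumab", "olaparib", "olaparib",
                "niraparib"),
  involvement = c("suspect", "concomitant", "suspect", "suspect",
                  "suspect"),
  start_date = c("20200110", "20200110", "20200201", "20200501",
                 "202103"),
  end_date = c("20200410", "20200410", "20200301", "20200801", ""),
  route = "oral",
  stringsAsFactors = FALSE)

tinyReac <- function() data.frame(
  case_id = c("A", "A", "B", "B", "C"),
  pt = c("Nausea", "Anaemia", "Anaemia", "Anaemia", "Nausea"),
  onset_date = c("20200110", "20200215", "20200520", "20200601",
                 "20210310"),
  outcome = c("recovered", "remission", "recovered", "death",
              "unclear"),
  stringsAsFactors = FALSE)

tinyHist <- function() data.frame(
  case_id = c("A", "B"),
  disease = c("ovarian cancer", "breast cancer"),
  stringsAsFactors = FALSE)

tinyDb <- function() srsDatabase(tinyDemo(), tinyDrug(), tinyReac(),
                                 tinyHist())

# write canonical tables as CSV files under a temp dir, return paths
writeTinyCsvs <- function(dir, demo = tinyDemo(), drug = tinyDrug(),
                          reac = tinyReac(), hist = tinyHist()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (tab in c("demo", "drug", "reac", "hist")) {
    df <- switch(tab, demo = demo, drug = drug, reac = reac, hist = hist)
    paths[[tab]] <- file.path(dir, paste0(tab, ".csv"))
    write.csv(df, paths[[tab]], row.names = FALSE)
  }
  paths
}
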