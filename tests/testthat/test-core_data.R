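test_that("age classes use half-open lower-inclusive bins", {
  expect_equal(as.character(assign_age_class(c(16, 19.99, 20, 39.9, 40,
                                               59.9, 60, 95))),
               c("<20", "<20", "20-39", "20-39", "40-59", "40-59",
                 ">=60", ">=60"))
  expect_error(assign_age_class(0), "positive")
  expect_error(assign_age_class(-3), "positive")
})

test_that("migration groups split residents by age and keep migrant labels", {
  expect_equal(as.character(assign_migration_group(39.9, "none")),
               "no_young")
  expect_equal(as.character(assign_migration_group(40, "none")), "no_old")
  expect_equal(as.character(assign_migration_group(60, "none")), "no_old")
  expect_equal(as.character(assign_migration_group(25, "temporary")),
               "temp")
  expect_equal(as.character(assign_migration_group(25, "permanent")),
               "perm")
  expect_error(assign_migration_group(25, "weird"), "migration_status")
})

test_that("the packaged fixture loads as a full 40-participant survey", {
  d <- read_interview_data(system.file("extdata", "demo",
                                       package = "ethnoindices"))
  expect_s3_class(d, "interview_data")
  expect_equal(nrow(d$participants), 40)
  expect_equal(nrow(d$species), 14)
  expect_true(all(table(d$participants$sex, d$participants$age_class) == 5))
})

test_that("load -> write -> load is the identity", {
  dir <- withr::local_tempdir()
  d <- tiny_data()
  write_interview_data(d, dir)
  d2 <- read_interview_data(dir)
  expect_equal(d2$participants, d$participants)
  expect_equal(d2$species, d$species)
  expect_equal(d2$freelists, d$freelists)
  expect_equal(d2$use_reports, d$use_reports)
})

test_that("empty use-reports are allowed", {
  d <- interview_data(tiny_participants(), tiny_species(),
                      tiny_freelists(), tiny_use_reports()[0, ])
  expect_equal(nrow(d$use_reports), 0)
  expect_equal(cultural_importance(d, "X", assume_all_asked = TRUE), 0)
})

test_that("validation rejects every single-field corruption", {
  # each corruption breaks exactly one field; the clean fixture passes
  expect_s3_class(tiny_data(), "interview_data")

  p <- tiny_participants(); p$sex[2] <- "m"
  expect_error(interview_data(p, tiny_species(), tiny_freelists(),
                              tiny_use_reports()), "sex")
  p <- tiny_participants(); p$age_years[1] <- -1
  expect_error(interview_data(p, tiny_species(), tiny_freelists(),
                              tiny_use_reports()), "age")
  p <- tiny_participants(); p$id[2] <- "A"
  expect_error(interview_data(p, tiny_species(), tiny_freelists(),
                              tiny_use_reports()), "duplicate")
  s <- tiny_species(); s$life_form[1] <- "liana"
  expect_error(interview_data(tiny_participants(), s, tiny_freelists(),
                              tiny_use_reports()), "life_form")
  f <- tiny_freelists(); f$species_code[2] <- "QQ"
  err <- tryCatch(interview_data(tiny_participants(), tiny_species(), f,
                                 tiny_use_reports()),
                  error = conditionMessage)
  expect_match(err, "QQ")
  expect_match(err, "row 2")
  f <- tiny_freelists(); f$participant_id[1] <- "ZZ"
  expect_error(interview_data(tiny_participants(), tiny_species(), f,
                              tiny_use_reports()), "ZZ")
  f <- tiny_freelists(); f$species_code[2] <- "X" # duplicate mention
  expect_error(interview_data(tiny_participants(), tiny_species(), f,
                              tiny_use_reports()), "twice")
  f <- tiny_freelists(); f$rank[3] <- 7L # non-contiguous ranks
  expect_error(interview_data(tiny_participants(), tiny_species(), f,
                              tiny_use_reports()), "1..L")
  u <- tiny_use_reports(); u$use_category[1] <- "cosmetics"
  expect_error(interview_data(tiny_participants(), tiny_species(),
                              tiny_freelists(), u), "use_category")
  u <- tiny_use_reports(); u$species_code[1] <- "QQ"
  expect_error(interview_data(tiny_participants(), tiny_species(),
                              tiny_freelists(), u), "QQ")
})

test_that("reader errors name the file", {
  dir <- withr::local_tempdir()
  write_interview_data(tiny_data(), dir)
  fl <- readr::read_csv(file.path(dir, "freelists.csv"),
                        show_col_types = FALSE)
  fl$species_code[4] <- "QQ"
  readr::write_csv(fl, file.path(dir, "freelists.csv"))
  expect_error(read_interview_data(dir), "freelists.csv")
})

test_that("use-type labels are case-folded and whitespace-normalized", {
  expect_equal(normalize_use_type(c("Stomach  ache ", "STOMACH ACHE")),
               rep("stomach ache", 2))
  d <- tiny_data()
  # the two spellings of stomach ache collapsed into one report
  expect_equal(nrow(d$use_reports), 6)
})

test_that("index tables round-trip through CSV at 6 decimals", {
  dir <- withr::local_tempdir()
  d <- tiny_data()
  tab <- salience_table(d, "sex")
  path <- file.path(dir, "tab.csv")
  write_index_table(tab, path)
  back <- read_index_table(path)
  for (col in names(tab)[-1]) {
    expect_equal(back[[col]], tab[[col]], tolerance = 1e-6)
  }
  # empty table -> header-only file
  write_index_table(tab[0, ], path)
  expect_equal(length(readLines(path)), 1)
  back0 <- read_index_table(path)
  expect_equal(nrow(back0), 0)
  # one species, one grouping level -> one data row
  one <- ci_table(tiny_data(), "none")[1, ]
  write_index_table(one, path)
  expect_equal(nrow(read_index_table(path)), 1)
})
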