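test_that("a small study round-trips through write_study/read_study", {
  study <- tiny_study(seed = 11L)
  dir <- withr::local_tempdir()
  write_study(study$features, study$samples, dir)
  back <- read_study(file.path(dir, "features.tsv"),
                     file.path(dir, "samples.tsv"))
  expect_identical(back$features$features$feature_id,
                   study$features$features$feature_id)
  expect_identical(back$samples$sample_id, study$samples$sample_id)
  expect_identical(back$samples$is_qc, study$samples$is_qc)
  # values agree within the 6-significant-digit serialization
  orig <- study$features$intensity
  got <- back$features$intensity[rownames(orig), colnames(orig)]
  rel <- abs(got - orig) / orig
  expect_lt(max(rel, na.rm = TRUE), 1e-5)
  expect_identical(is.na(got), is.na(orig))
})

test_that("read_study parses a toy TSV and rejects unknown sample columns", {
  dir <- withr::local_tempdir()
  meta <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                     subject_id = c("r1", "r2", "r1", "r2"),
                     group = "C", day = c(0, 0, 63, 63),
                     ion_mode = "POS", is_qc = 0)
  write.table(meta, file.path(dir, "samples.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  feat <- data.frame(feature_id = c("f1", "f2", "f3"),
                     metabolite_name = c("ala", "gly", "ser"),
                     ms2_score = c(0.9, 0.8, 0.7),
                     s1 = 1:3, s2 = 4:6, s3 = 7:9, s4 = 10:12)
  write.table(feat, file.path(dir, "features.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  study <- read_study(file.path(dir, "features.tsv"),
                      file.path(dir, "samples.tsv"))
  expect_equal(dim(study$features), c(3L, 4L))

  names(feat)[7] <- "s99"
  write.table(feat, file.path(dir, "features_bad.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(read_study(file.path(dir, "features_bad.tsv"),
                          file.path(dir, "samples.tsv")),
               "s99")
})

test_that("validation rejects duplicates, non-positive intensities and bad metadata", {
  ann <- data.frame(feature_id = c("f1", "f1"),
                    metabolite_name = c("a", "b"), ms2_score = 0.9)
  expect_error(feature_table(ann, matrix(1, 2, 1,
                                         dimnames = list(NULL, "s1"))),
               "duplicate feature_id")
  ann2 <- data.frame(feature_id = c("f1", "f2"),
                     metabolite_name = c("a", "b"), ms2_score = 0.9)
  expect_error(feature_table(ann2, matrix(c(1, 0), 2, 1,
                                          dimnames = list(NULL, "s1"))),
               "strictly positive")

  meta <- toy_meta(1:3, c(0, 63))
  expect_silent(validate_samples(meta))
  bad <- meta; bad$group[2] <- NA
  expect_error(validate_samples(bad), "lacking")
  dup <- meta; dup$sample_id[2] <- dup$sample_id[1]
  expect_error(validate_samples(dup), "duplicate sample_id")
  clash <- meta; clash$subject_id[2] <- clash$subject_id[1]
  clash$day[2] <- clash$day[1]
  expect_error(validate_samples(clash), "subject_id, day, ion_mode")
})

test_that("randomly corrupted non-QC metadata always fails validation", {
  meta <- tiny_study(seed = 3L)$samples
  nonqc_rows <- which(!meta$is_qc)
  for (i in seq_len(20)) {
    corrupt <- meta
    row <- withr::with_seed(1000L + i, sample(nonqc_rows, 1))
    col <- withr::with_seed(2000L + i,
                            sample(c("subject_id", "group", "day"), 1))
    corrupt[[col]][row] <- NA
    expect_error(validate_samples(corrupt), "lacking")
  }
})

test_that("write_table serializes empty tables and missing cells", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "empty.tsv")
  write_table(data.frame(metabolite_name = character(0),
                         s1 = numeric(0)), path)
  lines <- readLines(path)
  expect_length(lines, 1L)
  expect_match(lines, "metabolite_name\ts1")

  df <- data.frame(metabolite_name = c("a", "b"), s1 = c(1.5, NA))
  write_table(df, file.path(dir, "na.tsv"))
  got <- readLines(file.path(dir, "na.tsv"))
  expect_equal(got[3], "b\t")
})

test_that("a MetaboliteMatrix round-trips through its TSV form", {
  study <- tiny_study(seed = 5L)
  sub <- subset_ion_mode(study$features, study$samples, "POS")
  mm <- preprocess_study(sub$features, sub$samples)$matrix
  dir <- withr::local_tempdir()
  write_table(mm, file.path(dir, "m.tsv"))
  back <- read_metabolite_matrix(file.path(dir, "m.tsv"), sub$samples)
  expect_identical(rownames(back$intensity), rownames(mm$intensity))
  rel <- abs(back$intensity - mm$intensity) / mm$intensity
  expect_lt(max(rel, na.rm = TRUE), 1e-5)
})
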