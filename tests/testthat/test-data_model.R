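test_that("strip table round-trips through write/read exactly", {
  sd_ <- make_strip_data(drug = c(200, 50.123456789, 25, NA))
  path <- withr::local_tempfile(fileext = ".csv")
  write_strip_table(sd_, path)
  back <- read_strip_table(path)
  expect_equal(back$strips$sc_mass_mg, sd_$strips$sc_mass_mg)
  expect_identical(back$strips$strip_index, sd_$strips$strip_index)
  expect_equal(back$groups$drug_mass_ng, sd_$groups$drug_mass_ng)
  expect_identical(back$groups$blq, sd_$groups$blq)
  expect_equal(back$groups$sc_mass_total_mg, sd_$groups$sc_mass_total_mg)
  # a second write of the re-read object is byte-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_strip_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("well-formed 20-strip site yields 20 records in 4 groups", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_strip_table(make_strip_data(), path)
  x <- read_strip_table(path)
  expect_equal(nrow(x$strips), 20)
  expect_equal(nrow(x$groups), 4)
  expect_equal(x$groups$n_strips, c(2, 6, 6, 6))
})

test_that("strip table validation rejects bad rows by file line", {
  sd_ <- make_strip_data()
  path <- withr::local_tempfile(fileext = ".csv")

  sd_bad <- sd_
  sd_bad$strips$sc_mass_mg[3] <- -0.1
  sd_bad$groups$sc_mass_total_mg <- with(sd_bad$strips,
    vapply(split(sc_mass_mg, group_id), sum, numeric(1)))[
      sd_bad$groups$group_id]
  write_strip_table(sd_bad, path)
  expect_error(read_strip_table(path), "sc_mass_mg.*line.*4")

  sd_bad <- sd_
  sd_bad$strips$strip_index[5] <- 25L
  write_strip_table(sd_bad, path)
  expect_error(read_strip_table(path), "consecutive")

  # missing column
  df <- utils::read.csv(path)
  df$area_cm2 <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_strip_table(path), "missing column.*area_cm2")

  # BLQ row carrying a number
  write_strip_table(sd_, path)
  lines <- readLines(path)
  lines <- sub("^(S01,siteA,15,[^,]*,[^,]*,g4,),1$", "\\19.9,1", lines)
  writeLines(lines, path)
  expect_error(read_strip_table(path), "BLQ rows")
})

test_that("chromameter replicates average and table round-trips", {
  raw <- data.frame(
    subject_id = "S01", site_id = "sb1",
    role = rep(c("treated", "control1", "control2", "control3"),
               each = 4),
    time_h = rep(c("pre", "pre", "2", "2"), 4),
    a_star = rep(c(10.0, 10.4, 8.0, 8.2), 4),
    replicate = rep(1:2, 8))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(raw, path, row.names = FALSE, quote = FALSE)
  x <- read_chromameter_table(path)
  expect_equal(nrow(x), 8)              # 4 roles x (baseline + 1 time)
  expect_equal(unique(x$a_star[is.na(x$time_h)]), 10.2)
  expect_equal(unique(x$a_star[!is.na(x$time_h)]), 8.1)

  path2 <- withr::local_tempfile(fileext = ".csv")
  write_chromameter_table(x, path2)
  back <- read_chromameter_table(path2)
  expect_equal(back$a_star, x$a_star)
  expect_equal(back$time_h, x$time_h)
})

test_that("chromameter validation: missing control or baseline", {
  raw <- data.frame(
    subject_id = "S01", site_id = "sb1",
    role = rep(c("treated", "control1", "control2"), each = 2),
    time_h = rep(c("pre", "2"), 3),
    a_star = 10, replicate = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(raw, path, row.names = FALSE, quote = FALSE)
  expect_error(read_chromameter_table(path), "control3")

  raw$role <- rep(c("treated", "control1", "control2"), 2)
  raw$role[raw$role == "treated" & raw$time_h == "pre"][1] <- "control3"
  utils::write.csv(rbind(raw,
    data.frame(subject_id = "S01", site_id = "sb1", role = "control3",
               time_h = "2", a_star = 10, replicate = 1)),
    path, row.names = FALSE, quote = FALSE)
  expect_error(read_chromameter_table(path), "baseline")
})

test_that("run config round-trips and unit conversions hold", {
  cfg <- list(loq = 0.032, extraction_volume = 2, blq_policy = "zero",
              aaec_anchor = TRUE, seed = 42)
  path <- withr::local_tempfile(fileext = ".json")
  write_run_config(cfg, path)
  expect_equal(read_run_config(path), cfg)

  # mass unit discipline: LOQ concentration (ug/mL) x volume -> ng
  a <- assay_config()
  expect_equal(a$loq * a$extraction_volume * 1000, 64)  # 0.064 ug = 64 ng
  expect_error(assay_config(lod = 0.05), "lod")
})
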