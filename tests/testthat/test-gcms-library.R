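test_that("the packaged compound table loads with the expected structure", {
  lib <- load_gcms_table()
  expect_s3_class(lib, "gcms_library")
  expect_identical(nrow(lib$records), 74L)
  expect_identical(lib$groups, c("A", "B", "C"))
  expect_false(anyDuplicated(lib$records$name) > 0)
  expect_true(all(lib$records$retention_index > 0))

  # ND cells become exact zeros with the detected flag down
  hepta <- lib$records[lib$records$name == "Heptacosane", ]
  expect_identical(c(hepta$detected_A, hepta$detected_B, hepta$detected_C),
                   c(FALSE, FALSE, TRUE))
  expect_identical(c(hepta$mean_A, hepta$sd_A), c(0, 0))
  expect_equal(c(hepta$mean_C, hepta$sd_C), c(0.22, 0.39))

  # n.f. thresholds are missing, numeric ones parse through separators
  expect_true(is.na(lib$records$odor_threshold[
    lib$records$name == "P-menthan-1-ol"]))
  expect_equal(lib$records$odor_threshold[lib$records$name == "2-Butanone"],
               50000)

  # detected flags are consistent with stored zeros throughout
  for (g in lib$groups) {
    det <- lib$records[[paste0("detected_", g)]]
    expect_true(all(lib$records[[paste0("mean_", g)]][!det] == 0))
    expect_true(all(lib$records[[paste0("sd_", g)]][!det] == 0))
  }
})

test_that("malformed tables are rejected with informative errors", {
  write_tsv <- function(lines) {
    p <- tempfile(fileext = ".tsv")
    writeLines(lines, p)
    p
  }
  header <- paste("no", "name", "ri", "formula", "cas", "category",
                  "odor_description", "odor_threshold_ug_l",
                  "content_A", "content_B", "content_C", sep = "\t")
  row1 <- "1\tAlpha\t1000\tC1\t1-1-1\tKetones\tSweet\t2.0\t4.00 ± 1.00\t2.00 ± 0.50\tND"

  expect_error(load_gcms_table(write_tsv(header)), "no records")
  expect_error(load_gcms_table(write_tsv(c(header, row1, row1))),
               "duplicate")
  expect_error(load_gcms_table(write_tsv(c(header, sub("Ketones", "Acids",
                                                       row1)))),
               "unknown category.*Acids")
  expect_error(load_gcms_table(
    write_tsv(c(header, sub("4.00 ± 1.00", "4.00/1.00", row1, fixed = TRUE)))),
    "malformed.*content_A")
})

test_that("a load/write/load round trip reproduces the records exactly", {
  lib <- load_gcms_table()
  path <- tempfile(fileext = ".tsv")
  write_gcms_table(lib, path)
  lib2 <- load_gcms_table(path)
  expect_identical(lib$records, lib2$records)
  expect_identical(lib$groups, lib2$groups)
})

test_that("category distribution matches the published class percentages", {
  dist <- category_distribution(load_gcms_table())
  expect_identical(unname(dist$counts[c("Alcohols", "Ketones", "Aldehydes",
                                        "Esters", "Alkanes", "Heterocyclic",
                                        "Aromatics", "Alkenes")]),
                   c(20L, 15L, 13L, 6L, 6L, 6L, 5L, 3L))
  expect_equal(unname(dist$percents["Alcohols"]), 27.0)
  expect_equal(unname(dist$percents["Ketones"]), 20.2)
  expect_equal(unname(dist$percents["Aldehydes"]), 17.5)
  expect_equal(unname(dist$percents[c("Esters", "Alkanes", "Heterocyclic")]),
               c(8.1, 8.1, 8.1))
  expect_equal(unname(dist$percents["Aromatics"]), 6.7)
  expect_equal(unname(dist$percents["Alkenes"]), 4.0)
  expect_equal(sum(dist$counts), 74)
})

test_that("truncated percents stay within their arithmetic envelope", {
  # truncation can only lose mass: at most 0.1 per category
  for (seed in 1:20) {
    set.seed(seed)
    lib <- tiny_library()
    lib$records <- lib$records[sample(3, sample(1:3, 1)), , drop = FALSE]
    d <- category_distribution(lib)
    expect_lte(sum(d$percents), 100)
    expect_gte(sum(d$percents), 100 - 0.1 * length(d$percents))
  }
  single <- tiny_library()
  single$records <- single$records[1, , drop = FALSE]
  d <- category_distribution(single)
  expect_equal(unname(d$percents["Ketones"]), 100)
  expect_true(all(d$percents[names(d$percents) != "Ketones"] == 0))
})

test_that("descriptor presence and the flavor-characterized fraction", {
  expect_false(descriptor_presence(character(0)))
  expect_true(descriptor_presence("Pleasant"))
  expect_false(descriptor_presence("Alkane", exclude = "Alkane"))
  expect_true(descriptor_presence(c("Alkane", "Sweet"), exclude = "Alkane"))

  lib <- load_gcms_table()
  frac <- flavor_characterized_fraction(lib)
  expect_identical(frac$count, 52L)
  expect_equal(frac$percent, 70.27)

  # degenerate descriptor sets
  none <- lib
  none$records$odor_descriptors <- rep(list(character(0)), 74)
  expect_equal(flavor_characterized_fraction(none),
               list(count = 0L, percent = 0))
  all_lib <- lib
  all_lib$records$odor_descriptors <- rep(list("x"), 74)
  expect_equal(flavor_characterized_fraction(all_lib)$percent, 100)
})
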