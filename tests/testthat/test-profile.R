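test_that("the packaged comparison table loads as 8 profiles of 18 markers", {
  profiles <- table3_profiles()
  expect_length(profiles, 8L)
  expect_named(profiles, c("Col-GFP HSC", "AT-3", "YUMMER1.7-H2B-GFP5",
                           "DC2.4", "MS1", "YUMM1.7", "MCA-205", "MLTC-1"))
  for (p in profiles) {
    expect_length(non_empty_markers(p), 18L)
  }
  expect_identical(profiles[["AT-3"]]$accession, "CVCL_VR89")
})

test_that("the reference profile fixture types all 19 panel markers", {
  p <- colgfp_profile()
  expect_length(non_empty_markers(p), 19L)
  expect_setequal(non_empty_markers(p), panel_markers())
  expect_identical(p$accession, "CVCL_B7MI")
  expect_identical(genotype_at(p, "4-2"), "20.3")
  expect_identical(genotype_at(p, "7-1"), c("26.2", "27.2"))
  expect_identical(genotype_at(p, "9-2"), "18")
})

test_that("allele totals use set semantics over the requested markers", {
  profiles <- table3_profiles()
  markers <- non_empty_markers(profiles[["AT-3"]])
  expect_identical(allele_total(profiles[["Col-GFP HSC"]], markers), 20L)
  expect_identical(allele_total(profiles[["MCA-205"]], markers), 22L)
  # the tri-allelic locus contributes three distinct alleles
  expect_identical(allele_total(profiles[["MS1"]], "17-2"), 3L)
  expect_identical(allele_total(profiles[["MS1"]], character(0)), 0L)
})

test_that("allele totals are additive over disjoint marker sets", {
  profiles <- table3_profiles()
  markers <- panel_markers()
  set.seed(42)
  for (p in profiles[c("Col-GFP HSC", "MS1", "MLTC-1")]) {
    for (i in 1:5) {
      left <- sample(markers, sample(0:19, 1))
      right <- setdiff(markers, left)
      expect_identical(allele_total(p, left) + allele_total(p, right),
                       allele_total(p, markers))
    }
  }
})

test_that("profile CSV writing and reading round-trips genotype sets", {
  path <- withr::local_tempfile(fileext = ".csv")
  original <- table3_profiles()
  write_profiles(original, path)
  reread <- read_profiles(path)
  expect_named(reread, names(original))
  for (nm in names(original)) {
    expect_identical(reread[[nm]]$genotypes, original[[nm]]$genotypes,
                     info = nm)
  }
  # dialect is bit-exact against the packaged fixture (UTF-8, LF)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(strauth_fixture("table3_profiles.csv"), "raw",
                           file.size(strauth_fixture("table3_profiles.csv"))))
})

test_that("reading a fixture reproduces the published allele column verbatim", {
  tab <- utils::read.csv(strauth_fixture("colgfp_profile.csv"),
                         colClasses = "character", check.names = FALSE)
  p <- colgfp_profile()
  for (i in seq_len(nrow(tab))) {
    expect_identical(format_genotype(genotype_at(p, tab$marker[i])),
                     tab[["Col-GFP HSC"]][i])
  }
})

test_that("degenerate profile tables are handled explicitly", {
  header_only <- withr::local_tempfile(fileext = ".csv")
  writeLines("marker,LINE", header_only)
  profiles <- read_profiles(header_only)
  expect_length(profiles, 1L)
  expect_length(non_empty_markers(profiles[[1L]]), 0L)

  no_lines <- withr::local_tempfile(fileext = ".csv")
  writeLines("marker", no_lines)
  expect_length(read_profiles(no_lines), 0L)

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("marker,LINE", "1-1,16", "1-1,17"), dup)
  expect_error(read_profiles(dup), "duplicate marker")

  unknown <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("marker,LINE", "1-1,16", "99-9,12"), unknown)
  expect_warning(profiles <- read_profiles(unknown), "99-9")
  expect_identical(genotype_at(profiles[[1L]], "99-9"), "12")
})

test_that("profiles reject duplicate markers and missing markers read empty", {
  expect_error(str_profile("x", list(`1-1` = "16", `1–1` = "17")),
               "duplicate")
  p <- str_profile("x", list(`1-1` = "16"))
  expect_identical(genotype_at(p, "5-5"), character(0))
  expect_identical(allele_total(p, c("1-1", "5-5")), 1L)
})

test_that("the panel fixture matches the published marker metadata", {
  panel <- cellcheck_panel()
  expect_identical(nrow(panel), 19L)
  expect_true(all(panel$pigtail == "GTTTCTT"))
  expect_true(all(strauth:::allele_key(panel$range_min) <=
                    strauth:::allele_key(panel$range_max)))
  row <- panel[panel$marker == "1-1", ]
  expect_identical(row$range_min, "10")
  expect_identical(row$range_max, "19")
  expect_identical(row$chromosome, "1")
})
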