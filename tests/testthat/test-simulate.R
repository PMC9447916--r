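test_that("sim_config validates probabilities and seeds", {
  expect_error(sim_config(het_prob = 1.5), "het_prob")
  expect_error(sim_config(contaminant_fraction = -0.1),
               "contaminant_fraction")
  expect_identical(sim_config(seed = 7)$seed, 7L)
})

test_that("generated profiles respect ploidy under het_prob extremes", {
  hom <- generate_profile(config = sim_config(seed = 1, het_prob = 0))
  expect_length(non_empty_markers(hom), 19L)
  expect_true(all(lengths(hom$genotypes) == 1L))
  expect_identical(allele_total(hom, panel_markers()), 19L)

  het <- generate_profile(config = sim_config(seed = 1, het_prob = 1))
  expect_true(all(lengths(het$genotypes) >= 1L))
  expect_true(all(lengths(het$genotypes) <= 2L))
  expect_lte(allele_total(het, panel_markers()), 38L)
})

test_that("all generated alleles fall inside the known allele ranges", {
  panel <- cellcheck_panel()
  key <- strauth:::allele_key
  lo <- stats::setNames(key(panel$range_min), panel_markers(panel))
  hi <- stats::setNames(key(panel$range_max), panel_markers(panel))
  for (seed in 1:25) {
    p <- generate_profile(config = sim_config(seed = seed, het_prob = 0.5,
                                              microvariant_prob = 0.5))
    for (m in names(p$genotypes)) {
      k <- key(p$genotypes[[m]])
      expect_true(all(k >= lo[m] & k <= hi[m]),
                  info = sprintf("seed %d marker %s", seed, m))
    }
  }
})

test_that("equal configurations generate identical output", {
  cfg <- sim_config(seed = 99, het_prob = 0.3, microvariant_prob = 0.2,
                    dropout_rate = 0.2, shift_rate = 0.2)
  p1 <- generate_profile(config = cfg)
  p2 <- generate_profile(config = cfg)
  expect_identical(p1, p2)
  expect_identical(mutate_profile(p1, cfg), mutate_profile(p2, cfg))
  expect_identical(generate_peak_table(p1, cfg), generate_peak_table(p2, cfg))
  expect_false(identical(p1, generate_profile(config = sim_config(seed = 100,
                                                                  het_prob = 0.3))))
})

test_that("drift at zero rates is the identity, at full dropout the void", {
  p <- generate_profile(config = sim_config(seed = 5, het_prob = 0.5))
  same <- mutate_profile(p, sim_config(seed = 6))
  expect_identical(same$genotypes, p$genotypes)

  gone <- mutate_profile(p, sim_config(seed = 6, dropout_rate = 1))
  expect_true(all(lengths(gone$genotypes) == 0L))
  expect_error(tanabe_score(p, gone),
               class = "strauth_degenerate_comparison")
})

test_that("shifted alleles stay inside range and keep microvariants", {
  p <- generate_profile(config = sim_config(seed = 8, het_prob = 0.5,
                                            microvariant_prob = 0.6))
  panel <- cellcheck_panel()
  key <- strauth:::allele_key
  lo <- stats::setNames(key(panel$range_min), panel_markers(panel))
  hi <- stats::setNames(key(panel$range_max), panel_markers(panel))
  for (seed in 1:10) {
    drifted <- mutate_profile(p, sim_config(seed = seed, shift_rate = 1))
    for (m in names(drifted$genotypes)) {
      k <- key(drifted$genotypes[[m]])
      expect_true(all(k >= lo[m] & k <= hi[m]))
    }
  }
})

test_that("observed dropout fraction matches the configured rate", {
  base <- generate_profile(config = sim_config(seed = 123, het_prob = 0.5))
  rate <- 0.2
  n_total <- 0L
  n_lost <- 0L
  for (seed in 1:1000) {
    drifted <- mutate_profile(base, sim_config(seed = seed,
                                               dropout_rate = rate))
    n0 <- allele_total(base, names(base$genotypes))
    n1 <- allele_total(drifted, names(drifted$genotypes))
    n_total <- n_total + n0
    n_lost <- n_lost + (n0 - n1)
  }
  observed <- n_lost / n_total
  se <- sqrt(rate * (1 - rate) / n_total)
  expect_lt(abs(observed - rate), 3 * se)
})

test_that("peak tables carry one called peak per allele, none below 2x threshold", {
  p <- generate_profile(config = sim_config(seed = 21, het_prob = 0.5))
  peaks <- generate_peak_table(p, sim_config(seed = 21))
  expect_identical(nrow(peaks), allele_total(p, names(p$genotypes)))
  expect_true(all(peaks$height_rfu >= 200))
  expect_true(all(peaks$height_rfu <= 10000))
})

test_that("contaminant mixing surfaces extra alleles at detectable fractions", {
  host <- str_profile("host", list(`1-1` = "16", `5-5` = "17", `8-1` = "16",
                                   `6-7` = "15", `11-2` = "16",
                                   `12-1` = "17", `13-1` = "17",
                                   `19-2` = "13"))
  contaminant <- str_profile("cont", list(`1-1` = c("14", "15"),
                                          `5-5` = c("12", "13"),
                                          `8-1` = "16", `6-7` = "15",
                                          `11-2` = "16", `12-1` = "17",
                                          `13-1` = "17", `19-2` = "13"))
  # fraction 0: no contaminant peaks at all
  clean <- generate_peak_table(host, sim_config(seed = 2,
                                                contaminant_fraction = 0),
                               contaminant = contaminant)
  expect_identical(nrow(clean), allele_total(host, names(host$genotypes)))

  # fraction 0.5: contaminant heterozygosity shows up as multi-allelic calls
  mixed <- generate_peak_table(host, sim_config(seed = 2,
                                                contaminant_fraction = 0.5),
                               contaminant = contaminant)
  called <- call_profile(mixed)
  flags <- stats::setNames(called$qc$flags, called$qc$marker)
  expect_identical(unname(flags[["1-1"]]), "multi_allelic")
  expect_identical(unname(flags[["5-5"]]), "multi_allelic")
  expect_identical(unname(flags[["8-1"]]), "")
})
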