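# Literal brute-force percent-match oracle: explicit per-marker set
# intersection and totals, independent of the package's scoring path.
oracle_score <- function(query, reference,
                         algorithm = "tanabe", mode = "non_empty_both") {
  typed <- function(p) names(p$genotypes)[lengths(p$genotypes) > 0]
  markers <- switch(mode,
    non_empty_both = intersect(typed(query), typed(reference)),
    query_markers = typed(query),
    all_panel = panel_markers()
  )
  shared <- 0L
  n_q <- 0L
  n_r <- 0L
  for (m in markers) {
    gq <- query$genotypes[[m]]
    gr <- reference$genotypes[[m]]
    if (is.null(gq)) gq <- character(0)
    if (is.null(gr)) gr <- character(0)
    shared <- shared + length(intersect(gq, gr))
    n_q <- n_q + length(gq)
    n_r <- n_r + length(gr)
  }
  raw <- switch(algorithm,
    tanabe = 200 * shared / (n_q + n_r),
    masters_vs_query = 100 * shared / n_q,
    masters_vs_reference = 100 * shared / n_r
  )
  list(shared = shared, n_query = n_q, n_reference = n_r, raw = raw)
}

# A pair of related synthetic profiles: an independent draw plus a drifted
# copy of the first, so pairs span near-identical to unrelated.
random_profile_pair <- function(seed) {
  a <- generate_profile(config = sim_config(seed = seed, het_prob = 0.4),
                        name = paste0("A", seed))
  b <- if (seed %% 2 == 0) {
    generate_profile(config = sim_config(seed = seed + 10000L, het_prob = 0.4),
                     name = paste0("B", seed))
  } else {
    mutate_profile(a, sim_config(seed = seed + 20000L, dropout_rate = 0.1,
                                 shift_rate = 0.15))
  }
  list(a = a, b = b)
}

table3_query <- function() table3_profiles()[["Col-GFP HSC"]]

table3_references <- function() table3_profiles(include_query = FALSE)
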