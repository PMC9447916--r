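#' Configuration for synthetic profile generation
#'
#' Controls the generator that produces panel-conformant diploid mouse
#' genotypes, drifted variants and peak tables. Defaults describe a clean,
#' unperturbed line: heterozygosity and microvariant rates near those seen in
#' published mouse-line profiles, and no dropout, repeat shift or
#' contamination unless asked for.
#'
#' @param seed Integer seed; the same configuration always produces the same
#'   output.
#' @param het_prob Probability a marker is heterozygous (two alleles drawn
#'   instead of one).
#' @param microvariant_prob Probability a drawn allele carries a partial
#'   repeat (e.g. `.3`).
#' @param dropout_rate Per-allele loss probability applied by
#'   [mutate_profile()]; markers may become empty.
#' @param shift_rate Per-allele probability of a +/-1 repeat mutation applied
#'   by [mutate_profile()], clipped to the marker's known range.
#' @param contaminant_fraction Mixture proportion in `[0, 1]` scaling
#'   contaminant peak heights in [generate_peak_table()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, het_prob = 0.2, microvariant_prob = 0.15,
                       dropout_rate = 0, shift_rate = 0,
                       contaminant_fraction = 0) {
  probs <- c(het_prob = het_prob, microvariant_prob = microvariant_prob,
             dropout_rate = dropout_rate, shift_rate = shift_rate,
             contaminant_fraction = contaminant_fraction)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    bad <- names(probs)[!is.finite(probs) | probs < 0 | probs > 1]
    stop("probabilities must lie in [0, 1]: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(
    list(seed = as.integer(seed), het_prob = het_prob,
         microvariant_prob = microvariant_prob, dropout_rate = dropout_rate,
         shift_rate = shift_rate, contaminant_fraction = contaminant_fraction),
    class = "sim_config"
  )
}

# Clip an allele token into a marker's known range under the
# (repeats, microvariant) order.
clip_to_range <- function(token, range_min, range_max) {
  k <- allele_key(token)
  if (k < allele_key(range_min)) return(range_min)
  if (k > allele_key(range_max)) return(range_max)
  token
}

# Draw one allele uniformly over the whole repeat counts inside a marker's
# known range, attaching a 1-3 base microvariant with the configured
# probability (clipped back into range). Uniform sampling is a deliberate
# simplification: the panel has no published allele frequencies.
draw_allele <- function(range_min, range_max, microvariant_prob) {
  lo <- as.integer(sub("\\..*$", "", range_min))
  hi <- as.integer(sub("\\..*$", "", range_max))
  reps <- if (lo == hi) lo else sample(lo:hi, 1L)
  token <- as.character(reps)
  if (stats::runif(1) < microvariant_prob) {
    token <- paste0(reps, ".", sample(1:3, 1L))
  }
  clip_to_range(token, range_min, range_max)
}

#' Generate a synthetic STR profile
#'
#' Draws a diploid genotype for every panel marker: one allele, plus a second
#' with probability `het_prob`, each sampled inside the marker's known allele
#' range. Identical draws collapse, so a "heterozygous" draw may still print
#' one value, as in real homozygous loci.
#'
#' @param panel Panel data frame ([cellcheck_panel()] by default).
#' @param config A [sim_config()]; `config$seed` fixes the output.
#' @param name Profile name.
#' @return An `str_profile` with a non-empty genotype (1-2 alleles) at every
#'   panel marker.
#' @examples
#' generate_profile(config = sim_config(seed = 7, het_prob = 0.5))
#' @export
generate_profile <- function(panel = cellcheck_panel(),
                             config = sim_config(), name = "synthetic") {
  stopifnot(inherits(config, "sim_config"), nrow(panel) > 0L)
  set.seed(config$seed)
  genotypes <- lapply(seq_len(nrow(panel)), function(i) {
    n <- 1L + stats::rbinom(1L, 1L, config$het_prob)
    alleles <- replicate(n, draw_allele(panel$range_min[i], panel$range_max[i],
                                        config$microvariant_prob))
    sort_alleles(unique(alleles))
  })
  names(genotypes) <- panel_markers(panel)
  str_profile(name, genotypes)
}

#' Apply genetic drift to a profile
#'
#' Models the allele loss and repeat-length slippage that accumulate in
#' continuous culture: each allele is independently lost with probability
#' `dropout_rate` (a marker may become empty) and, if retained, shifted by
#' one repeat unit (direction chosen at random) with probability
#' `shift_rate`, clipped to the marker's known range. Shifts preserve any
#' microvariant suffix.
#'
#' @param profile An `str_profile`.
#' @param config A [sim_config()]; uses `dropout_rate`, `shift_rate`, `seed`.
#' @param panel Panel supplying the per-marker ranges for clipping.
#' @return A drifted `str_profile` (suffix `" (drifted)"` on the name).
#' @export
mutate_profile <- function(profile, config = sim_config(),
                           panel = cellcheck_panel()) {
  stopifnot(inherits(profile, "str_profile"), inherits(config, "sim_config"))
  set.seed(config$seed)
  ranges <- stats::setNames(
    split(panel[, c("range_min", "range_max")], seq_len(nrow(panel))),
    panel_markers(panel)
  )
  genotypes <- lapply(names(profile$genotypes), function(m) {
    g <- profile$genotypes[[m]]
    kept <- g[stats::runif(length(g)) >= config$dropout_rate]
    if (length(kept) == 0L) return(character(0))
    shifted <- vapply(kept, function(token) {
      if (stats::runif(1) < config$shift_rate) {
        reps <- as.integer(sub("\\..*$", "", token))
        mv <- if (grepl("\\.", token))
          sub("^[0-9]+", "", token) else ""
        token <- paste0(max(reps + sample(c(-1L, 1L), 1L), 0L), mv)
        if (!is.null(ranges[[m]])) {
          token <- clip_to_range(token, ranges[[m]]$range_min,
                                 ranges[[m]]$range_max)
        }
      }
      token
    }, character(1), USE.NAMES = FALSE)
    sort_alleles(unique(shifted))
  })
  names(genotypes) <- names(profile$genotypes)
  str_profile(paste0(profile$name, " (drifted)"), genotypes,
              species = profile$species)
}

#' Generate a peak table from a profile
#'
#' Produces one electropherogram peak per allele, with heights drawn
#' log-uniformly in `[2, 100] x threshold` so that noise-free calling at the
#' assay threshold is unambiguous. An optional contaminating profile
#' contributes its alleles with heights scaled by
#' `config$contaminant_fraction`, emulating a cell-line mixture: minor
#' contaminant peaks fall below the detection threshold when the fraction is
#' small, and surface as extra (multi-allelic) peaks when it is not.
#'
#' @param profile Host `str_profile` (panel-conformant).
#' @param config A [sim_config()]; uses `seed` and `contaminant_fraction`.
#' @param contaminant Optional second `str_profile` mixed into the sample.
#' @param threshold Detection threshold (RFU) the heights are anchored to;
#'   keep equal to the calling threshold (default 100).
#' @return Peak data frame (`marker`, `allele`, `height_rfu`).
#' @export
generate_peak_table <- function(profile, config = sim_config(),
                                contaminant = NULL, threshold = 100) {
  stopifnot(inherits(profile, "str_profile"))
  if (!inherits(config, "sim_config")) {
    stop("config must be a sim_config", call. = FALSE)
  }
  set.seed(config$seed)
  peak_rows <- function(p, scale) {
    markers <- names(p$genotypes)
    rows <- lapply(markers, function(m) {
      g <- p$genotypes[[m]]
      if (length(g) == 0L) return(NULL)
      height <- exp(stats::runif(length(g), log(2 * threshold),
                                 log(100 * threshold))) * scale
      data.frame(marker = m, allele = g, height_rfu = height)
    })
    do.call(rbind, rows)
  }
  peaks <- peak_rows(profile, 1)
  if (!is.null(contaminant) && config$contaminant_fraction > 0) {
    stopifnot(inherits(contaminant, "str_profile"))
    peaks <- rbind(peaks, peak_rows(contaminant, config$contaminant_fraction))
  }
  if (is.null(peaks)) {
    peaks <- data.frame(marker = character(0), allele = character(0),
                        height_rfu = numeric(0))
  }
  rownames(peaks) <- NULL
  peaks
}
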