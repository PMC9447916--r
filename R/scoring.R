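#' Configuration for a pairwise profile comparison
#'
#' @param algorithm Scoring statistic: `"tanabe"` (default; shared alleles
#'   doubled over the sum of both allele totals), `"masters_vs_query"`
#'   (shared over the query total) or `"masters_vs_reference"` (shared over
#'   the reference total).
#' @param marker_mode Which markers enter the comparison:
#'   `"non_empty_both"` (default; markers typed in both profiles),
#'   `"query_markers"` (markers typed in the query) or `"all_panel"`
#'   (all 19 panel markers).
#' @param rounding Decimal places for the reported score (default 2,
#'   half-up); the full-precision value is retained alongside it.
#' @return An object of class `match_config`.
#' @export
match_config <- function(algorithm = c("tanabe", "masters_vs_query",
                                       "masters_vs_reference"),
                         marker_mode = c("non_empty_both", "query_markers",
                                         "all_panel"),
                         rounding = 2L) {
  algorithm <- match.arg(algorithm)
  marker_mode <- match.arg(marker_mode)
  stopifnot(is.numeric(rounding), length(rounding) == 1L, rounding >= 0)
  structure(
    list(algorithm = algorithm, marker_mode = marker_mode,
         rounding = as.integer(rounding)),
    class = "match_config"
  )
}

# Round half away from zero (scores are non-negative, so half-up), the
# convention of printed percent-match tables; base round() would round
# half-to-even.
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Select the markers entering a comparison
#'
#' @param query,reference `str_profile` objects.
#' @param mode One of `"non_empty_both"`, `"query_markers"`, `"all_panel"`.
#' @param panel Panel data frame used for `"all_panel"` mode.
#' @return Character vector of marker ids.
#' @export
select_markers <- function(query, reference,
                           mode = c("non_empty_both", "query_markers",
                                    "all_panel"),
                           panel = cellcheck_panel()) {
  mode <- match.arg(mode)
  switch(mode,
    non_empty_both = intersect(non_empty_markers(query),
                               non_empty_markers(reference)),
    query_markers = non_empty_markers(query),
    all_panel = panel_markers(panel)
  )
}

#' Count alleles shared between two profiles
#'
#' Sum over the given markers of the size of the set intersection of the two
#' genotypes. Alleles are compared as exact tokens, so a microvariant allele
#' never matches its integral neighbour (27 does not match 27.2).
#'
#' @param query,reference `str_profile` objects.
#' @param markers Marker ids over which to count.
#' @return Non-negative integer.
#' @export
shared_allele_count <- function(query, reference, markers) {
  if (length(markers) == 0L) return(0L)
  markers <- normalize_marker_id(markers)
  key <- function(p) {
    unlist(lapply(markers, function(m) {
      g <- genotype_at(p, m)
      if (length(g) == 0L) character(0) else paste(m, g, sep = "\r")
    }), use.names = FALSE)
  }
  length(intersect(key(query), key(reference)))
}

#' Score a pair of STR profiles
#'
#' Computes the percent match between a questioned profile and a reference
#' profile. Under the Tanabe statistic this is
#' `100 * 2 * shared / (n_query + n_reference)`, where the allele totals
#' count distinct alleles over the selected markers; the Masters variants
#' normalize by one profile's total only.
#'
#' @param query,reference `str_profile` objects.
#' @param config A [match_config()].
#' @param panel Panel used when `marker_mode = "all_panel"`.
#' @return An object of class `match_result` with fields `query_name`,
#'   `reference_name`, `algorithm`, `markers_used`, `shared`, `n_query`,
#'   `n_reference`, `score` (rounded percent) and `score_raw`.
#' @details A comparison with zero usable markers is an error of class
#'   `strauth_degenerate_comparison`, not a 0% score: a silent zero would be
#'   indistinguishable from a genuine non-match.
#' @examples
#' profs <- table3_profiles()
#' score_profiles(profs[["Col-GFP HSC"]], profs[["AT-3"]])
#' @export
score_profiles <- function(query, reference, config = match_config(),
                           panel = cellcheck_panel()) {
  stopifnot(inherits(query, "str_profile"), inherits(reference, "str_profile"),
            inherits(config, "match_config"))
  markers <- select_markers(query, reference, config$marker_mode, panel)
  if (length(markers) == 0L) {
    stop(structure(
      class = c("strauth_degenerate_comparison", "error", "condition"),
      list(message = sprintf(
             "no usable markers between '%s' and '%s' (mode %s)",
             query$name, reference$name, config$marker_mode),
           call = sys.call(-1))
    ))
  }
  shared <- shared_allele_count(query, reference, markers)
  n_query <- allele_total(query, markers)
  n_reference <- allele_total(reference, markers)
  raw <- switch(config$algorithm,
    tanabe = 200 * shared / (n_query + n_reference),
    masters_vs_query = 100 * shared / n_query,
    masters_vs_reference = 100 * shared / n_reference
  )
  structure(
    list(query_name = query$name, reference_name = reference$name,
         algorithm = config$algorithm, marker_mode = config$marker_mode,
         markers_used = markers, shared = shared,
         n_query = n_query, n_reference = n_reference,
         score = round_half_up(raw, config$rounding), score_raw = raw),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %s vs %s\n", x$query_name, x$reference_name))
  cat(sprintf("  algorithm: %s, markers used: %d\n",
              x$algorithm, length(x$markers_used)))
  cat(sprintf("  shared alleles: %d, query total: %d, reference total: %d\n",
              x$shared, x$n_query, x$n_reference))
  cat(sprintf("  score: %.2f%%\n", x$score))
  invisible(x)
}

#' Tanabe percent match
#'
#' Convenience wrapper for [score_profiles()] with the Tanabe statistic.
#'
#' @inheritParams score_profiles
#' @param marker_mode,rounding Passed to [match_config()].
#' @return A `match_result`.
#' @export
tanabe_score <- function(query, reference, marker_mode = "non_empty_both",
                         rounding = 2L, panel = cellcheck_panel()) {
  score_profiles(query, reference,
                 match_config("tanabe", marker_mode, rounding), panel)
}

#' Masters percent match
#'
#' @inheritParams tanabe_score
#' @param versus Normalize by the `"query"` or the `"reference"` allele total.
#' @return A `match_result`.
#' @export
masters_score <- function(query, reference, versus = c("query", "reference"),
                          marker_mode = "non_empty_both", rounding = 2L,
                          panel = cellcheck_panel()) {
  versus <- match.arg(versus)
  algorithm <- paste0("masters_vs_", versus)
  score_profiles(query, reference,
                 match_config(algorithm, marker_mode, rounding), panel)
}
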