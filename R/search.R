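#' Configuration for a database search
#'
#' Defaults reproduce the published search settings: Tanabe scoring over
#' markers non-empty in both profiles, a 70% score filter, and at least 8
#' usable markers per comparison.
#'
#' @param match A [match_config()].
#' @param score_filter Minimum reported score (percent, 0-100) for a
#'   reference to be retained.
#' @param min_markers Minimum number of usable markers for a comparison to be
#'   retained (>= 1).
#' @return An object of class `search_config`.
#' @export
search_config <- function(match = match_config(), score_filter = 70,
                          min_markers = 8L) {
  stopifnot(inherits(match, "match_config"),
            is.numeric(score_filter), length(score_filter) == 1L,
            score_filter >= 0, score_filter <= 100,
            is.numeric(min_markers), length(min_markers) == 1L,
            min_markers >= 1)
  structure(
    list(match = match, score_filter = score_filter,
         min_markers = as.integer(min_markers)),
    class = "search_config"
  )
}

#' Search a profile database
#'
#' Compares a query profile against every reference profile, applies the
#' score and minimum-marker filters, and returns retained matches ranked by
#' score (ties broken by reference name, ascending). Excluded references are
#' reported with the reason rather than dropped: an authentication run is
#' audited on its negative evidence as much as its hits.
#'
#' @param query An `str_profile`.
#' @param database List of `str_profile` references.
#' @param config A [search_config()].
#' @param panel Panel used for `"all_panel"` marker mode.
#' @return An object of class `search_report`: `query_name`, `config`,
#'   `results` (data frame: reference, accession, shared, n_query,
#'   n_reference, n_markers, score), `excluded` (data frame: reference,
#'   reason) and `profiles` (the query and retained references, for
#'   rendering).
#' @examples
#' report <- str_search(colgfp_profile(), table3_profiles(include_query = FALSE))
#' report$results
#' @export
str_search <- function(query, database, config = search_config(),
                       panel = cellcheck_panel()) {
  stopifnot(inherits(query, "str_profile"), is.list(database),
            inherits(config, "search_config"))
  if (length(non_empty_markers(query)) < config$min_markers) {
    stop(sprintf(
      "query '%s' has %d typed marker(s); at least %d are required",
      query$name, length(non_empty_markers(query)), config$min_markers),
      call. = FALSE)
  }
  rows <- list()
  excluded <- list()
  kept_profiles <- list()
  for (reference in database) {
    res <- tryCatch(
      score_profiles(query, reference, config$match, panel),
      strauth_degenerate_comparison = function(e) NULL
    )
    if (is.null(res)) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(reference = reference$name, reason = "no usable markers")
      next
    }
    if (length(res$markers_used) < config$min_markers) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(reference = reference$name, reason = "below min markers")
      next
    }
    if (res$score < config$score_filter) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(reference = reference$name, reason = "below score filter")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      reference = res$reference_name,
      accession = if (is.na(reference$accession)) "" else reference$accession,
      shared = res$shared, n_query = res$n_query,
      n_reference = res$n_reference,
      n_markers = length(res$markers_used), score = res$score
    )
    kept_profiles[[reference$name]] <- reference
  }
  results <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(reference = character(0), accession = character(0),
               shared = integer(0), n_query = integer(0),
               n_reference = integer(0), n_markers = integer(0),
               score = numeric(0))
  results <- results[order(-results$score, results$reference), , drop = FALSE]
  rownames(results) <- NULL
  excluded <- if (length(excluded) > 0L) do.call(rbind, excluded) else
    data.frame(reference = character(0), reason = character(0))
  structure(
    list(query_name = query$name, config = config, results = results,
         excluded = excluded,
         profiles = c(stats::setNames(list(query), query$name),
                      kept_profiles[results$reference])),
    class = "search_report"
  )
}

#' Render a search report
#'
#' `"text"` mirrors the layout of a published comparison table: markers as
#' rows, the query and each retained reference as columns, and a footer row
#' of percent-match scores. `"csv"` emits the ranked results table in a
#' machine-parseable form carrying the same numbers.
#'
#' @param report A `search_report`.
#' @param fmt `"text"` or `"csv"`.
#' @return Character vector of document lines.
#' @export
render_report <- function(report, fmt = c("text", "csv")) {
  stopifnot(inherits(report, "search_report"))
  fmt <- match.arg(fmt)
  if (fmt == "csv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(report$results, con, row.names = FALSE, quote = FALSE)
    close(con)
    return(out)
  }
  profiles <- report$profiles
  markers <- unique(unlist(lapply(profiles, non_empty_markers)))
  markers <- c(intersect(panel_markers(), markers),
               setdiff(markers, panel_markers()))
  header <- c("STR Marker", vapply(profiles, `[[`, character(1), "name"))
  body <- matrix("", nrow = length(markers), ncol = length(profiles))
  for (i in seq_along(markers)) {
    body[i, ] <- vapply(profiles, function(p) {
      format_genotype(genotype_at(p, markers[i]))
    }, character(1))
  }
  score_for <- function(nm) {
    if (nm == report$query_name) return("query")
    sprintf("%.2f", report$results$score[report$results$reference == nm])
  }
  footer <- c("% match", vapply(names(profiles), score_for, character(1)))
  tab <- rbind(header, cbind(markers, body), footer)
  widths <- apply(nchar(tab), 2, max)
  lines <- apply(tab, 1, function(r) {
    padded <- mapply(formatC, r, width = widths,
                     MoreArgs = list(flag = "-"))
    paste(padded, collapse = "  ")
  })
  c(sprintf("Query: %s (scoring: %s, mode: %s, score filter: %g%%, min markers: %d)",
            report$query_name, report$config$match$algorithm,
            report$config$match$marker_mode, report$config$score_filter,
            report$config$min_markers),
    "", trimws(lines, which = "right"),
    if (nrow(report$excluded) > 0L) c(
      "",
      sprintf("Excluded: %s (%s)", report$excluded$reference,
              report$excluded$reason)
    ))
}

#' @export
print.search_report <- function(x, ...) {
  cat(render_report(x, "text"), sep = "\n")
  invisible(x)
}
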