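#' The CellCheck Mouse 19 STR marker panel
#'
#' Metadata for the 19-locus multiplex STR panel used to authenticate mouse
#' cell lines: marker label, chromosome, the known allele range at each locus
#' (the span of repeat counts observed at the polymorphic site), and the
#' multiplex PCR primer pair. Every reverse primer in the assay carries a
#' fixed 7-nucleotide "PIGtail" tag (`GTTTCTT`) that promotes complete
#' adenylation for consistent fragment sizing; the tag is reported in its own
#' column.
#'
#' @return A data frame with one row per marker and columns `marker`,
#'   `chromosome`, `range_min`, `range_max` (allele tokens bounding the known
#'   range), `forward_primer`, `reverse_primer`, `pigtail`.
#' @examples
#' panel <- cellcheck_panel()
#' nrow(panel) # 19 markers
#' @export
cellcheck_panel <- function() {
  path <- system.file("extdata", "cellcheck_panel.csv", package = "strauth",
                      mustWork = TRUE)
  panel <- utils::read.csv(path, colClasses = "character")
  panel$pigtail <- "GTTTCTT"
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  required <- c("marker", "chromosome", "range_min", "range_max",
                "forward_primer", "reverse_primer", "pigtail")
  missing <- setdiff(required, names(panel))
  if (length(missing) > 0L) {
    stop("panel is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(panel$marker)) {
    stop("panel marker ids must be unique", call. = FALSE)
  }
  bad <- allele_key(panel$range_min) > allele_key(panel$range_max)
  if (any(bad)) {
    stop("range_min exceeds range_max for marker(s): ",
         paste(panel$marker[bad], collapse = ", "), call. = FALSE)
  }
  if (!all(panel$pigtail == "GTTTCTT")) {
    stop("every panel marker must carry the GTTTCTT PIGtail tag",
         call. = FALSE)
  }
  invisible(panel)
}

#' Panel marker ids
#'
#' @param panel A panel data frame, by default [cellcheck_panel()].
#' @return Character vector of marker labels.
#' @export
panel_markers <- function(panel = cellcheck_panel()) {
  normalize_marker_id(panel$marker)
}
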