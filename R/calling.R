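#' Configuration for allele calling from peak tables
#'
#' @param rfu_threshold Minimum peak height, in relative fluorescence units
#'   (RFU), for an allele to be called (default 100, the assay's detection
#'   threshold). Peaks exactly at the threshold are called.
#' @param max_alleles_expected Alleles expected per locus (default 2,
#'   diploid); more survivors flag the marker as multi-allelic.
#' @return An object of class `calling_config`.
#' @export
calling_config <- function(rfu_threshold = 100, max_alleles_expected = 2L) {
  stopifnot(is.numeric(rfu_threshold), length(rfu_threshold) == 1L,
            rfu_threshold > 0,
            is.numeric(max_alleles_expected), max_alleles_expected >= 1)
  structure(
    list(rfu_threshold = rfu_threshold,
         max_alleles_expected = as.integer(max_alleles_expected)),
    class = "calling_config"
  )
}

validate_peaks <- function(peaks) {
  required <- c("marker", "allele", "height_rfu")
  missing <- setdiff(required, names(peaks))
  if (length(missing) > 0L) {
    stop("peak table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(peaks$height_rfu)) || any(peaks$height_rfu < 0)) {
    stop("peak heights must be non-negative RFU values", call. = FALSE)
  }
  peaks$marker <- normalize_marker_id(peaks$marker)
  peaks$allele <- if (nrow(peaks) > 0L)
    normalize_allele(as.character(peaks$allele)) else character(0)
  peaks
}

#' Read a peak table from CSV
#'
#' Expects the dialect `marker,allele,height_rfu`: one row per
#' electropherogram peak, alleles pre-binned to repeat tokens.
#'
#' @param path CSV file path.
#' @return Data frame with columns `marker`, `allele`, `height_rfu`.
#' @export
read_peaks <- function(path) {
  tab <- utils::read.csv(path, colClasses = c("character", "character",
                                              "numeric"))
  validate_peaks(tab)
}

#' Write a peak table to CSV
#'
#' @param peaks Peak data frame (`marker`, `allele`, `height_rfu`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  peaks <- validate_peaks(peaks)
  utils::write.csv(peaks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Call a genotype from one marker's peaks
#'
#' Alleles whose peak height reaches the detection threshold are called;
#' duplicate allele tokens are merged keeping the highest peak. Sub-threshold
#' peaks are never called but are counted in the QC output.
#'
#' @param peaks Peak data frame restricted to a single marker.
#' @param config A [calling_config()].
#' @return List with `genotype` (character vector of called allele tokens),
#'   `flags` (`"no_signal"` when nothing is called, `"multi_allelic"` when
#'   more alleles survive than expected for a diploid locus) and
#'   `n_subthreshold` (peaks seen but below threshold).
#' @export
call_marker <- function(peaks, config = calling_config()) {
  stopifnot(inherits(config, "calling_config"))
  peaks <- validate_peaks(peaks)
  if (length(unique(peaks$marker)) > 1L) {
    stop("call_marker received peaks for multiple markers: ",
         paste(unique(peaks$marker), collapse = ", "), call. = FALSE)
  }
  if (nrow(peaks) > 0L) {
    height <- tapply(peaks$height_rfu, peaks$allele, max)
    called <- names(height)[height >= config$rfu_threshold]
    n_sub <- sum(height < config$rfu_threshold)
  } else {
    called <- character(0)
    n_sub <- 0L
  }
  flags <- character(0)
  if (length(called) == 0L) flags <- c(flags, "no_signal")
  if (length(called) > config$max_alleles_expected) {
    flags <- c(flags, "multi_allelic")
  }
  list(genotype = sort_alleles(called), flags = flags,
       n_subthreshold = as.integer(n_sub))
}

#' Call a full STR profile from a peak table
#'
#' Groups peaks by marker, calls each locus with [call_marker()], and
#' assembles the result into a profile plus a per-marker QC summary. Markers
#' absent from the table are reported as gaps but not typed.
#'
#' @param peaks Peak data frame (`marker`, `allele`, `height_rfu`).
#' @param config A [calling_config()].
#' @param line_name Name for the resulting profile.
#' @param panel Panel data frame; peaks must use panel marker ids.
#' @return List with `profile` (an `str_profile` over the markers present in
#'   the table) and `qc` (data frame: marker, n_called, n_subthreshold,
#'   flags; plus one `missing` row per panel marker absent from the table).
#' @export
call_profile <- function(peaks, config = calling_config(),
                         line_name = "called", panel = cellcheck_panel()) {
  peaks <- validate_peaks(peaks)
  outside <- setdiff(unique(peaks$marker), panel_markers(panel))
  if (length(outside) > 0L) {
    stop("peak table contains non-panel marker(s): ",
         paste(outside, collapse = ", "), call. = FALSE)
  }
  present <- intersect(panel_markers(panel), unique(peaks$marker))
  calls <- lapply(present, function(m) {
    call_marker(peaks[peaks$marker == m, , drop = FALSE], config)
  })
  genotypes <- stats::setNames(lapply(calls, `[[`, "genotype"), present)
  qc_rows <- data.frame(
    marker = present,
    n_called = vapply(calls, function(x) length(x$genotype), integer(1)),
    n_subthreshold = vapply(calls, `[[`, integer(1), "n_subthreshold"),
    flags = vapply(calls, function(x) paste(x$flags, collapse = ";"),
                   character(1))
  )
  gaps <- setdiff(panel_markers(panel), present)
  if (length(gaps) > 0L) {
    qc_rows <- rbind(qc_rows, data.frame(
      marker = gaps, n_called = 0L, n_subthreshold = 0L, flags = "missing"
    ))
  }
  qc_rows <- qc_rows[match(panel_markers(panel), qc_rows$marker), ,
                     drop = FALSE]
  rownames(qc_rows) <- NULL
  list(profile = str_profile(line_name, genotypes), qc = qc_rows)
}
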