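# Packaged transcriptions of the published Col-GFP HSC profile tables.

cellosaurus_accessions <- c(
  "Col-GFP HSC" = "CVCL_B7MI",
  "AT-3" = "CVCL_VR89",
  "YUMMER1.7-H2B-GFP5" = "CVCL_A2AY",
  "DC2.4" = "CVCL_I409",
  "MS1" = "CVCL_6502",
  "YUMM1.7" = "CVCL_JK16",
  "MCA-205" = "CVCL_VR90",
  "MLTC-1" = "CVCL_3544"
)

#' Path to a packaged fixture file
#'
#' @param name One of `"cellcheck_panel.csv"`, `"colgfp_profile.csv"`,
#'   `"table3_profiles.csv"`.
#' @return Absolute path to the installed file.
#' @export
strauth_fixture <- function(name) {
  system.file("extdata", name, package = "strauth", mustWork = TRUE)
}

attach_accessions <- function(profiles) {
  for (nm in names(profiles)) {
    if (nm %in% names(cellosaurus_accessions)) {
      profiles[[nm]]$accession <- unname(cellosaurus_accessions[nm])
    }
  }
  profiles
}

#' Reference STR profile of Col-GFP HSC
#'
#' The full 19-marker profile of the immortalized mouse hepatic stellate cell
#' line Col-GFP HSC (Cellosaurus CVCL_B7MI), the query profile of the
#' package's worked example.
#'
#' @return An `str_profile` with 19 typed markers.
#' @export
colgfp_profile <- function() {
  attach_accessions(read_profiles(strauth_fixture("colgfp_profile.csv")))[[1L]]
}

#' Closest database matches to Col-GFP HSC
#'
#' The 18-marker comparison table from the published database search: the
#' Col-GFP HSC query column alongside its seven highest-scoring mouse cell
#' lines (marker 9-2, typed only in the query, is absent from this table).
#'
#' @param include_query Keep the Col-GFP HSC column (default `TRUE`).
#' @return Named list of `str_profile` objects.
#' @export
table3_profiles <- function(include_query = TRUE) {
  profiles <- attach_accessions(read_profiles(strauth_fixture("table3_profiles.csv")))
  if (!include_query) {
    profiles <- profiles[names(profiles) != "Col-GFP HSC"]
  }
  profiles
}

#' Materialize the packaged fixtures
#'
#' Copies the panel metadata, the Col-GFP HSC reference profile, and the
#' comparison table to a directory as plain CSV, so they can be edited or fed
#' back through the command line.
#'
#' @param dir Output directory (created if needed).
#' @return Character vector of the three written paths, invisibly.
#' @export
write_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c("cellcheck_panel.csv", "colgfp_profile.csv", "table3_profiles.csv")
  out <- file.path(dir, files)
  for (i in seq_along(files)) {
    file.copy(strauth_fixture(files[i]), out[i], overwrite = TRUE)
  }
  invisible(out)
}
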