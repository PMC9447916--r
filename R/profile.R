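#' Construct an STR profile
#'
#' An STR profile maps panel markers to genotypes (sets of alleles) for one
#' cell line. Markers absent from the map are treated as untyped (empty
#' genotype), matching how a database entry with a blank cell is read.
#'
#' @param name Cell-line label.
#' @param genotypes Named list: marker id -> genotype. Each genotype may be
#'   given as a character vector of allele tokens or as a single
#'   comma-separated string; both are normalized through [parse_genotype()].
#' @param species Species label (default `"Mus musculus"`).
#' @param accession Optional database identifier (e.g. a Cellosaurus
#'   accession).
#' @return An object of class `str_profile`.
#' @examples
#' p <- str_profile("example", list(`1-1` = "16", `18-3` = "16,17"))
#' allele_total(p, c("1-1", "18-3"))
#' @export
str_profile <- function(name, genotypes, species = "Mus musculus",
                        accession = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(genotypes) > 0L &&
      (is.null(names(genotypes)) || any(!nzchar(names(genotypes))))) {
    stop("genotypes must be a fully named list (marker id -> genotype)",
         call. = FALSE)
  }
  ids <- normalize_marker_id(names(genotypes))
  if (anyDuplicated(ids)) {
    stop("duplicate marker ids in profile '", name, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  parsed <- lapply(genotypes, function(g) {
    if (length(g) == 1L && (is.na(g) || grepl(",", g) || g == "")) {
      parse_genotype(as.character(g))
    } else if (length(g) == 0L) {
      character(0)
    } else {
      sort_alleles(unique(normalize_allele(as.character(g))))
    }
  })
  names(parsed) <- ids
  structure(
    list(name = name, accession = accession, species = species,
         genotypes = parsed),
    class = "str_profile"
  )
}

#' @export
print.str_profile <- function(x, ...) {
  typed <- non_empty_markers(x)
  cat(sprintf("<str_profile> %s (%s)%s\n", x$name, x$species,
              if (is.na(x$accession)) "" else paste0(" [", x$accession, "]")))
  cat(sprintf("  %d typed marker(s), %d allele(s)\n",
              length(typed), allele_total(x, typed)))
  for (m in names(x$genotypes)) {
    cat(sprintf("  %-5s %s\n", m, format_genotype(x$genotypes[[m]])))
  }
  invisible(x)
}

#' Genotype of a profile at one marker
#'
#' @param profile An `str_profile`.
#' @param marker_id Marker label; absent markers yield the empty genotype.
#' @return Character vector of allele tokens (possibly empty).
#' @export
genotype_at <- function(profile, marker_id) {
  g <- profile$genotypes[[normalize_marker_id(marker_id)]]
  if (is.null(g)) character(0) else g
}

#' Markers typed in a profile
#'
#' @param profile An `str_profile`.
#' @return Character vector of marker ids with at least one allele.
#' @export
non_empty_markers <- function(profile) {
  names(profile$genotypes)[lengths(profile$genotypes) > 0L]
}

#' Total allele count over a marker set
#'
#' Counts distinct alleles (set semantics): a homozygous marker contributes
#' one allele, a heterozygous marker two, and a multi-allelic (amplified)
#' marker one per distinct allele. This is the allele total entering the
#' percent-match denominators.
#'
#' @param profile An `str_profile`.
#' @param markers Character vector of marker ids.
#' @return Non-negative integer.
#' @export
allele_total <- function(profile, markers) {
  if (length(markers) == 0L) return(0L)
  sum(vapply(normalize_marker_id(markers),
             function(m) length(genotype_at(profile, m)), integer(1)))
}

#' Read STR profiles from a CSV table
#'
#' Reads the package's profile dialect: a `marker` column followed by one
#' column per cell line, each cell holding comma-separated allele tokens
#' (quoted when more than one), the layout used by published profile tables.
#'
#' @param path Path to a CSV file.
#' @param species Species label applied to every profile.
#' @return A named list of `str_profile` objects, one per cell-line column
#'   (empty list if the file holds only a header).
#' @details Duplicate marker rows are an error. Marker ids outside the
#'   19-marker panel are retained with a warning, so panels can be extended
#'   without silently dropping data.
#' @export
read_profiles <- function(path, species = "Mus musculus") {
  tab <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!"marker" %in% names(tab)) {
    stop("profile CSV must have a 'marker' column: ", path, call. = FALSE)
  }
  markers <- normalize_marker_id(tab$marker)
  if (anyDuplicated(markers)) {
    stop("duplicate marker rows in ", path, ": ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(markers, panel_markers())
  if (length(unknown) > 0L) {
    warning("marker id(s) outside the CellCheck panel retained: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  line_cols <- setdiff(names(tab), "marker")
  profiles <- lapply(line_cols, function(col) {
    genotypes <- lapply(tab[[col]], parse_genotype)
    names(genotypes) <- markers
    str_profile(col, genotypes, species = species)
  })
  names(profiles) <- line_cols
  profiles
}

#' Write STR profiles to a CSV table
#'
#' Emits the same dialect [read_profiles()] consumes, bit-exactly: header
#' `marker,<line1>,...`, one row per marker, multi-allele cells quoted,
#' UTF-8 with LF line endings. Rows cover the union of marker ids across the
#' profiles in panel order (panel markers first, extras after).
#'
#' @param profiles A list of `str_profile` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(length(profiles) > 0L)
  all_markers <- unique(unlist(lapply(profiles, function(p) names(p$genotypes))))
  ordered <- c(intersect(panel_markers(), all_markers),
               setdiff(all_markers, panel_markers()))
  quote_cell <- function(x) {
    if (grepl('[",]', x)) paste0('"', gsub('"', '""', x), '"') else x
  }
  header <- paste(vapply(c("marker", vapply(profiles, `[[`, character(1), "name")),
                         quote_cell, character(1)), collapse = ",")
  rows <- vapply(ordered, function(m) {
    cells <- vapply(profiles, function(p) {
      quote_cell(format_genotype(genotype_at(p, m)))
    }, character(1))
    paste(c(m, cells), collapse = ",")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
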