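#' Parse an STR allele token
#'
#' An STR allele is written as the whole number of repeat units, optionally
#' followed by a dot and a single digit counting extra bases beyond the last
#' complete repeat (a "microvariant", e.g. `20.3` = 20 repeats + 3 bases).
#' Microvariant alleles are distinct from their integral neighbours:
#' `27 != 27.2 != 26.2`.
#'
#' @param token Character scalar, e.g. `"16"` or `"20.3"`.
#' @return An object of class `str_allele` with fields `repeats`
#'   (non-negative integer) and `microvariant` (integer 0-9, or `NA` for an
#'   integral allele).
#' @examples
#' parse_allele("20.3")
#' parse_allele("16")
#' @export
parse_allele <- function(token) {
  if (length(token) != 1L || is.na(token) || !is.character(token)) {
    stop("allele token must be a single character string", call. = FALSE)
  }
  tok <- trimws(token)
  if (!grepl("^[0-9]+(\\.[0-9])?$", tok)) {
    stop(sprintf("malformed allele token: '%s'", token), call. = FALSE)
  }
  parts <- strsplit(tok, ".", fixed = TRUE)[[1L]]
  structure(
    list(
      repeats = as.integer(parts[1L]),
      microvariant = if (length(parts) == 2L) as.integer(parts[2L]) else NA_integer_
    ),
    class = "str_allele"
  )
}

#' @export
format.str_allele <- function(x, ...) {
  if (is.na(x$microvariant)) {
    as.character(x$repeats)
  } else {
    paste0(x$repeats, ".", x$microvariant)
  }
}

#' @export
print.str_allele <- function(x, ...) {
  cat("<str_allele>", format(x), "\n")
  invisible(x)
}

#' @export
`==.str_allele` <- function(e1, e2) {
  identical(e1$repeats, e2$repeats) &&
    identical(is.na(e1$microvariant), is.na(e2$microvariant)) &&
    (is.na(e1$microvariant) || e1$microvariant == e2$microvariant)
}

# Normalize a vector of allele tokens (strip leading zeros etc.); errors on
# any malformed token, naming it.
normalize_allele <- function(tokens) {
  vapply(tokens, function(t) format(parse_allele(t)), character(1),
         USE.NAMES = FALSE)
}

# Sort key: repeats + microvariant/10 puts 20 < 20.3 < 21; an absent
# microvariant counts as zero extra bases.
allele_key <- function(tokens) {
  reps <- as.numeric(sub("\\..*$", "", tokens))
  mv <- ifelse(grepl("\\.", tokens), as.numeric(sub("^[0-9]+\\.", "", tokens)), 0)
  reps + mv / 10
}

sort_alleles <- function(tokens) tokens[order(allele_key(tokens))]

#' Parse a genotype cell
#'
#' A genotype is the set of distinct alleles typed at one marker. In profile
#' tables a homozygous marker prints a single value, a heterozygous marker two
#' comma-separated values, and three or more values indicate the locus is
#' amplified (multi-allelic). Duplicate tokens collapse to one element; an
#' empty cell is the empty genotype (marker not typed).
#'
#' @param cell_text Character scalar: comma-separated allele tokens, possibly
#'   empty or `NA`.
#' @return Character vector of normalized allele tokens, sorted ascending by
#'   (repeats, microvariant); `character(0)` for an empty cell.
#' @examples
#' parse_genotype("26.2,27.2")
#' parse_genotype("17,17") # collapses to "17"
#' parse_genotype("")      # empty genotype
#' @export
parse_genotype <- function(cell_text) {
  if (length(cell_text) != 1L) {
    stop("genotype cell must be a single string", call. = FALSE)
  }
  if (is.na(cell_text) || !nzchar(trimws(cell_text))) {
    return(character(0))
  }
  tokens <- trimws(strsplit(cell_text, ",", fixed = TRUE)[[1L]])
  tokens <- tokens[nzchar(tokens)]
  sort_alleles(unique(normalize_allele(tokens)))
}

#' Format a genotype as a table cell
#'
#' Inverse of [parse_genotype()]: alleles joined by commas in ascending
#' (repeats, microvariant) order.
#'
#' @param genotype Character vector of allele tokens (possibly empty).
#' @return Character scalar; `""` for the empty genotype.
#' @export
format_genotype <- function(genotype) {
  if (length(genotype) == 0L) return("")
  paste(sort_alleles(normalize_allele(genotype)), collapse = ",")
}

# Marker labels appear with typographic en-dashes in print ("1–1");
# normalize to ASCII hyphen so ids compare as opaque labels.
normalize_marker_id <- function(marker_id) {
  gsub("–|—", "-", trimws(marker_id))
}
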