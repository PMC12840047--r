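# GC-MS compound library: loading, validation, category and descriptor
# summaries. The packaged table uses the publication's cell conventions:
# "mean ± sd" content cells, "ND" for not detected, "n.f." for a missing
# odor threshold, and "——" for an empty odor-descriptor list.

GCMS_CATEGORIES <- c("Aldehydes", "Ketones", "Alcohols", "Esters",
                     "Alkanes", "Alkenes", "Aromatics", "Heterocyclic")

# Parse one "mean ± sd" / "ND" content cell. Returns mean, sd, detected.
parse_mean_sd <- function(cell, row = NA, column = NA) {
  cell <- trimws(cell)
  if (identical(cell, "ND")) {
    return(list(mean = 0, sd = 0, detected = FALSE))
  }
  parts <- strsplit(cell, "±", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    stop(sprintf("malformed mean ± SD cell '%s' (row %s, column %s)",
                 cell, row, column))
  }
  m <- suppressWarnings(as.numeric(trimws(parts[1])))
  s <- suppressWarnings(as.numeric(trimws(parts[2])))
  if (is.na(m) || is.na(s)) {
    stop(sprintf("malformed mean ± SD cell '%s' (row %s, column %s)",
                 cell, row, column))
  }
  if (s < 0) stop(sprintf("negative SD in row %s, column %s", row, column))
  list(mean = m, sd = s, detected = TRUE)
}

parse_threshold <- function(cell) {
  cell <- trimws(cell)
  if (identical(cell, "n.f.")) return(NA_real_)
  as.numeric(gsub(",", "", cell, fixed = TRUE))
}

parse_descriptors <- function(cell) {
  cell <- trimws(cell)
  if (cell %in% c("——", "", "--")) return(character(0))
  trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
}

#' Load a GC-MS compound library table
#'
#' Reads a tab-separated compound table in the packaged schema (columns
#' \code{name}, \code{ri}, \code{formula}, \code{cas}, \code{category},
#' \code{odor_description}, \code{odor_threshold_ug_l} and one
#' \code{content_<group>} column per sample group) and returns a validated
#' library. \code{"ND"} content cells become mean 0, sd 0 with
#' \code{detected = FALSE}; \code{"n.f."} thresholds become \code{NA};
#' \code{"——"} descriptor cells become an empty descriptor list.
#'
#' @param path path to a UTF-8 TSV file. Defaults to the packaged table of
#'   74 rice volatiles.
#' @return An object of class \code{gcms_library}: a list with
#'   \item{records}{data frame with one row per compound; the per-group
#'     means/sds/detected flags live in columns \code{mean_<g>},
#'     \code{sd_<g>}, \code{detected_<g>}; \code{odor_descriptors} is a
#'     list column; raw content/threshold cell strings are retained for
#'     lossless round-tripping.}
#'   \item{groups}{character vector of group labels found in the header.}
#'   \item{internal_standard}{the semi-quantification internal standard
#'     (name, mass in \eqn{\mu}g, sample mass in g).}
#' @export
load_gcms_table <- function(path = aroma_extdata("table3_gcms.tsv")) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character",
                           fileEncoding = "UTF-8")
  if (nrow(raw) == 0) stop("no records in ", path)
  need <- c("name", "ri", "category", "odor_description",
            "odor_threshold_ug_l")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  content_cols <- grep("^content_", names(raw), value = TRUE)
  if (length(content_cols) == 0) stop("no content_<group> columns found")
  groups <- sub("^content_", "", content_cols)

  dup <- raw$name[duplicated(raw$name)]
  if (length(dup) > 0) {
    stop("duplicate compound names: ", paste(unique(dup), collapse = ", "))
  }
  bad_cat <- setdiff(unique(raw$category), GCMS_CATEGORIES)
  if (length(bad_cat) > 0) {
    stop("unknown category value(s): ", paste(bad_cat, collapse = ", "),
         " (rows ", paste(which(raw$category %in% bad_cat), collapse = ", "),
         ")")
  }

  records <- data.frame(
    name = raw$name,
    retention_index = as.numeric(raw$ri),
    formula = if ("formula" %in% names(raw)) raw$formula else NA_character_,
    cas = if ("cas" %in% names(raw)) raw$cas else NA_character_,
    category = raw$category,
    odor_threshold = vapply(raw$odor_threshold_ug_l, parse_threshold,
                            numeric(1), USE.NAMES = FALSE),
    threshold_raw = raw$odor_threshold_ug_l,
    descriptors_raw = raw$odor_description,
    stringsAsFactors = FALSE
  )
  if (any(is.na(records$retention_index)) ||
      any(records$retention_index <= 0)) {
    stop("retention index must be a positive number for every record")
  }
  records$odor_descriptors <- lapply(raw$odor_description, parse_descriptors)

  for (g in groups) {
    col <- paste0("content_", g)
    parsed <- lapply(seq_len(nrow(raw)), function(i) {
      parse_mean_sd(raw[[col]][i], row = i, column = col)
    })
    records[[paste0("mean_", g)]] <- vapply(parsed, `[[`, numeric(1), "mean")
    records[[paste0("sd_", g)]] <- vapply(parsed, `[[`, numeric(1), "sd")
    records[[paste0("detected_", g)]] <-
      vapply(parsed, `[[`, logical(1), "detected")
    records[[paste0("content_raw_", g)]] <- raw[[col]]
  }

  structure(
    list(records = records, groups = groups,
         internal_standard = list(name = "2-Methyl-3-heptanone",
                                  mass_ug = 0.816, sample_mass_g = 2.0)),
    class = "gcms_library"
  )
}

#' Write a GC-MS library back to its tabular form
#'
#' Emits the same TSV schema consumed by \code{\link{load_gcms_table}},
#' using the retained raw cell strings so that a load/write/load
#' round trip reproduces the records exactly.
#'
#' @param library a \code{gcms_library}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_gcms_table <- function(library, path) {
  stopifnot(inherits(library, "gcms_library"))
  rec <- library$records
  out <- data.frame(
    no = seq_len(nrow(rec)),
    name = rec$name,
    ri = rec$retention_index,
    formula = rec$formula,
    cas = rec$cas,
    category = rec$category,
    odor_description = rec$descriptors_raw,
    odor_threshold_ug_l = rec$threshold_raw,
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
  for (g in library$groups) {
    out[[paste0("content_", g)]] <- rec[[paste0("content_raw_", g)]]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.gcms_library <- function(x, ...) {
  cat(sprintf("GC-MS library: %d compounds, groups %s\n",
              nrow(x$records), paste(x$groups, collapse = "/")))
  cat(sprintf("internal standard: %s (%.3f ug in %.1f g sample)\n",
              x$internal_standard$name, x$internal_standard$mass_ug,
              x$internal_standard$sample_mass_g))
  invisible(x)
}

# Truncate toward zero at one decimal (27.027 -> 27.0, 20.27 -> 20.2).
truncate1 <- function(x) trunc(x * 10) / 10

#' Chemical category distribution of a library
#'
#' Counts compounds per chemical category and expresses each as a percent
#' of the library, truncated (not rounded) toward zero at one decimal.
#' All eight recognised categories are always reported, including empties.
#'
#' @param library a \code{gcms_library}.
#' @return A \code{category_distribution}: list with integer \code{counts}
#'   and numeric \code{percents}, both named by category, plus \code{total}.
#' @export
category_distribution <- function(library) {
  stopifnot(inherits(library, "gcms_library"))
  n <- nrow(library$records)
  if (n == 0) stop("empty library")
  counts <- vapply(GCMS_CATEGORIES, function(cat) {
    sum(library$records$category == cat)
  }, integer(1))
  percents <- truncate1(100 * counts / n)
  structure(list(counts = counts, percents = percents, total = n),
            class = "category_distribution")
}

#' @export
print.category_distribution <- function(x, ...) {
  ord <- order(-x$counts)
  for (i in ord) {
    cat(sprintf("%-13s %3d  (%.1f%%)\n", names(x$counts)[i],
                x$counts[i], x$percents[i]))
  }
  invisible(x)
}

#' Does a compound carry a flavor characteristic?
#'
#' TRUE when the odor-descriptor list is non-empty and is not composed
#' solely of descriptors in \code{exclude}. The default excludes nothing:
#' on the packaged 74-compound table the plain non-empty rule reproduces
#' the published count of 52 flavor-characterized compounds. An exclusion
#' list (e.g. bare chemical-class labels such as \code{"Alkane"}) can be
#' supplied for stricter readings.
#'
#' @param descriptors a character vector of descriptors, or a list of such
#'   vectors (one element per compound).
#' @param exclude descriptors that do not count as flavor characteristics.
#' @return Logical vector, one flag per compound.
#' @export
descriptor_presence <- function(descriptors, exclude = character()) {
  if (!is.list(descriptors)) descriptors <- list(descriptors)
  vapply(descriptors, function(d) {
    length(d) > 0 && !all(d %in% exclude)
  }, logical(1))
}

#' Fraction of library compounds with flavor characteristics
#'
#' @param library a \code{gcms_library}.
#' @param exclude passed to \code{\link{descriptor_presence}}.
#' @return List with \code{count} and \code{percent} (rounded to 2
#'   decimals).
#' @export
flavor_characterized_fraction <- function(library, exclude = character()) {
  stopifnot(inherits(library, "gcms_library"))
  n <- nrow(library$records)
  if (n == 0) stop("empty library")
  flags <- descriptor_presence(library$records$odor_descriptors, exclude)
  count <- sum(flags)
  list(count = count, percent = round(100 * count / n, 2))
}
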