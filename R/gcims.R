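# GC-IMS peak-table analysis: monomer/dimer parsing and pairing,
# chemical-class counts, fingerprint matrices and reference-difference
# matrices. Works from the peak tables the instrument software exports
# (signal name, retention index, retention time, RIP-normalized drift
# time, per-group peak volume); raw drift spectra are out of scope.

#' Load a GC-IMS peak table
#'
#' Signal names with a \code{-M} / \code{-D} suffix are split into a base
#' compound name plus monomer/dimer form; other signals are
#' \code{unspecified}. The packaged table holds the study's 55 signals
#' with per-aroma-type peak volumes.
#'
#' @param path TSV with columns name, ri, rt_s, drift_time_ms and one
#'   \code{volume_<group>} column per group.
#' @return Data frame of IMS peak records (one row per signal) with
#'   \code{base_name} and \code{form} columns; group labels are attached
#'   as attribute \code{"groups"}.
#' @export
load_ims_table <- function(path = aroma_extdata("table5_ims.tsv")) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("name", "ri", "rt_s", "drift_time_ms")
  if (!all(need %in% names(raw))) {
    stop("missing columns: ", paste(setdiff(need, names(raw)), collapse = ", "))
  }
  vol_cols <- grep("^volume_", names(raw), value = TRUE)
  if (length(vol_cols) == 0) stop("no volume_<group> columns found")
  for (col in c("ri", "rt_s", "drift_time_ms", vol_cols)) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (any(is.na(v))) {
      stop(sprintf("malformed numeric field in column %s, row(s) %s", col,
                   paste(which(is.na(v)), collapse = ", ")))
    }
    raw[[col]] <- v
  }
  if (any(raw$rt_s <= 0) || any(raw$drift_time_ms <= 0)) {
    stop("retention and drift times must be positive")
  }
  if (any(raw[vol_cols] < 0)) stop("peak volumes must be >= 0")

  is_m <- grepl("-M$", raw$name)
  is_d <- grepl("-D$", raw$name)
  raw$base_name <- ifelse(is_m | is_d, sub("-[MD]$", "", raw$name), raw$name)
  raw$form <- ifelse(is_m, "monomer", ifelse(is_d, "dimer", "unspecified"))
  attr(raw, "groups") <- sub("^volume_", "", vol_cols)
  raw
}

#' Load the curated IMS compound-class map
#'
#' Table 5-style exports carry no class column, so classes come from a
#' curated base-name to class map packaged with the library.
#'
#' @param path two-column TSV (base_name, class).
#' @return Named character vector: base name -> class.
#' @export
load_ims_class_map <- function(path = aroma_extdata("ims_class_map.tsv")) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE, fileEncoding = "UTF-8")
  stats::setNames(tab$class, tab$base_name)
}

#' Pair monomer and dimer signals of the same compound
#'
#' High-concentration or high-proton-affinity analytes produce both a
#' protonated monomer and a proton-bound dimer signal; this pairs them by
#' base compound name.
#'
#' @param records IMS records from \code{\link{load_ims_table}}.
#' @return List with \code{pairs} (data frame: base_name, monomer and
#'   dimer row indices) and \code{orphans} (monomer-only or dimer-only
#'   signals, flagged).
#' @export
pair_monomer_dimer <- function(records) {
  md <- records[records$form %in% c("monomer", "dimer"), , drop = FALSE]
  if (nrow(md) > 0) {
    key <- paste(md$base_name, md$form)
    if (anyDuplicated(key)) {
      stop("duplicate (base name, form) signal(s): ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
    }
  }
  bases <- unique(md$base_name)
  has_m <- vapply(bases, function(b) {
    any(md$base_name == b & md$form == "monomer")
  }, logical(1))
  has_d <- vapply(bases, function(b) {
    any(md$base_name == b & md$form == "dimer")
  }, logical(1))
  paired <- bases[has_m & has_d]
  pairs <- data.frame(
    base_name = paired,
    monomer_row = vapply(paired, function(b) {
      which(records$base_name == b & records$form == "monomer")
    }, integer(1)),
    dimer_row = vapply(paired, function(b) {
      which(records$base_name == b & records$form == "dimer")
    }, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  orphan_bases <- bases[xor(has_m, has_d)]
  orphans <- md[md$base_name %in% orphan_bases,
                c("base_name", "form"), drop = FALSE]
  rownames(orphans) <- NULL
  list(pairs = pairs, orphans = orphans)
}

#' Count IMS signals per chemical class
#'
#' Signals are the counting unit: monomer and dimer rows of the same
#' compound count separately, so the class counts sum to the number of
#' signal rows.
#'
#' @param records IMS records.
#' @param class_map named base_name -> class vector; every base name must
#'   be covered.
#' @return Named integer vector of per-class signal counts, in decreasing
#'   order.
#' @export
ims_class_counts <- function(records, class_map = load_ims_class_map()) {
  unmapped <- setdiff(unique(records$base_name), names(class_map))
  if (length(unmapped) > 0) {
    stop("unmapped compound name(s): ", paste(unmapped, collapse = ", "))
  }
  cls <- class_map[records$base_name]
  counts <- table(cls)
  out <- stats::setNames(as.integer(counts), names(counts))
  sort(out, decreasing = TRUE)
}

#' Build a groups x signals fingerprint matrix
#'
#' Rows are sample groups, columns are signals (base name + form),
#' ordered by retention time then drift time so the column order is
#' stable under input shuffling.
#'
#' @param records IMS records.
#' @return A \code{fingerprint_matrix}: numeric matrix with signal
#'   metadata attached as attribute \code{"signals"}.
#' @export
build_fingerprint <- function(records) {
  groups <- attr(records, "groups")
  if (is.null(groups)) {
    groups <- sub("^volume_", "", grep("^volume_", names(records),
                                       value = TRUE))
  }
  ord <- order(records$rt_s, records$drift_time_ms)
  rec <- records[ord, , drop = FALSE]
  if (anyDuplicated(rec$name)) stop("duplicate signal labels")
  m <- t(as.matrix(rec[, paste0("volume_", groups), drop = FALSE]))
  dimnames(m) <- list(groups, rec$name)
  structure(m, class = c("fingerprint_matrix", class(m)),
            signals = rec[, c("name", "base_name", "form", "ri", "rt_s",
                              "drift_time_ms")])
}

#' Difference fingerprint against a reference row
#'
#' Subtracts the reference group's signal volumes from every row: the
#' reference row maps to zeros, enrichment relative to the reference is
#' positive, depletion negative (the red/white/blue convention of
#' instrument difference plots).
#'
#' @param fingerprint a \code{\link{build_fingerprint}} matrix.
#' @param reference_row row (group) name to subtract.
#' @return Signed difference matrix of the same shape.
#' @export
difference_matrix <- function(fingerprint, reference_row) {
  if (!reference_row %in% rownames(fingerprint)) {
    stop("reference row '", reference_row, "' not present")
  }
  sweep(unclass(fingerprint), 2, fingerprint[reference_row, ])
}
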