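# Relative odor activity values (ROAV): rank each volatile's contribution
# to the overall aroma by its content-to-threshold ratio, scaled so the
# most odor-active compound in the sample scores exactly 100.

#' Compute relative odor activity values
#'
#' For every compound with a known odor threshold and a detected positive
#' content, the odor activity ratio C/OT is formed and rescaled so the
#' maximum over the sample is 100:
#' \deqn{ROAV_i = 100 \, (C_i/OT_i) / \max_j (C_j/OT_j).}
#' Contents here are IS-equivalent semi-quantified values (ug/kg) while
#' thresholds are detection thresholds in water (ug/L); the ratio is
#' treated as a unitless activity, as is conventional for ROAV screening.
#' Compounds with a missing threshold or no detected content are listed in
#' \code{excluded} rather than scored zero, so "not scorable" stays
#' distinguishable from "weak".
#'
#' @param contents named numeric vector of compound contents.
#' @param thresholds named numeric vector of odor thresholds (NA =
#'   unknown), aligned with \code{contents} by name.
#' @param group optional label carried into the result.
#' @return A \code{roav_result}: list with \code{scores} (named, included
#'   compounds only), \code{ratios} (raw C/OT), \code{reference_compound}
#'   (the compound scoring 100; ties broken alphabetically),
#'   \code{excluded} and \code{group}.
#' @export
compute_roav <- function(contents, thresholds, group = NA_character_) {
  if (is.null(names(contents)) || is.null(names(thresholds))) {
    stop("contents and thresholds must be named")
  }
  thresholds <- thresholds[names(contents)]
  eligible <- !is.na(contents) & contents > 0 &
    !is.na(thresholds) & thresholds > 0
  if (!any(eligible)) stop("no reference compound: no compound has both a ",
                           "detected content and a known threshold")
  ratios <- contents[eligible] / thresholds[eligible]
  mx <- max(ratios)
  top <- names(ratios)[ratios == mx]
  reference <- sort(top)[1]
  scores <- 100 * ratios / mx
  structure(list(group = group,
                 scores = scores,
                 ratios = ratios,
                 reference_compound = reference,
                 excluded = names(contents)[!eligible]),
            class = "roav_result")
}

#' ROAV of a library group's mean contents
#'
#' Convenience wrapper running \code{\link{compute_roav}} on the per-group
#' mean contents of a GC-MS library; not-detected compounds are excluded.
#'
#' @param library a \code{gcms_library}.
#' @param group one of the library's group labels.
#' @return A \code{roav_result}.
#' @export
roav_from_library <- function(library, group) {
  stopifnot(inherits(library, "gcms_library"))
  if (!group %in% library$groups) stop("unknown group: ", group)
  rec <- library$records
  contents <- stats::setNames(rec[[paste0("mean_", group)]], rec$name)
  contents[!rec[[paste0("detected_", group)]]] <- NA_real_
  thresholds <- stats::setNames(rec$odor_threshold, rec$name)
  compute_roav(contents, thresholds, group = group)
}

#' Classify an ROAV score
#'
#' ROAV >= 1: principal aroma compound; 0.1 <= ROAV < 1: flavor modifier;
#' below 0.1: minor contributor. Both lower boundaries are inclusive.
#'
#' @param score numeric ROAV score(s), >= 0.
#' @return Factor with levels principal/modifier/minor.
#' @export
classify_roav <- function(score) {
  if (any(score < 0)) stop("ROAV scores must be non-negative")
  cls <- ifelse(score >= 1, "principal",
                ifelse(score >= 0.1, "modifier", "minor"))
  factor(cls, levels = c("principal", "modifier", "minor"))
}

#' Long-format ROAV scatter data
#'
#' One row per (group, scored compound); excluded compounds are omitted.
#' This is the data behind the per-group ROAV scatter display.
#'
#' @param results a list of \code{roav_result} objects.
#' @return Data frame with columns group, compound, c_over_ot, roav,
#'   class.
#' @export
roav_scatter_data <- function(results) {
  if (length(results) == 0) {
    return(data.frame(group = character(0), compound = character(0),
                      c_over_ot = numeric(0), roav = numeric(0),
                      class = factor(character(0),
                                     levels = c("principal", "modifier",
                                                "minor"))))
  }
  out <- do.call(rbind, lapply(results, function(r) {
    stopifnot(inherits(r, "roav_result"))
    data.frame(group = r$group, compound = names(r$scores),
               c_over_ot = unname(r$ratios), roav = unname(r$scores),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$class <- classify_roav(out$roav)
  out
}
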