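# Synthetic per-sample data with the statistical structure the analysis
# assumes: truncated-normal compound concentrations around published group
# mean/SD summaries, half-point-grid QDA scores around archetype profiles,
# jittered retention-time peak lists, and lognormal GC-IMS peak volumes.
# Every generator is a pure function of (inputs, seed).

#' Study design of the sampling scheme
#'
#' Defaults encode the motivating study: 11 rice samples in three aroma
#' types of sizes 3 (A), 4 (B) and 4 (C), each measured in technical
#' triplicate.
#'
#' @param group_sizes named integer vector of samples per group.
#' @param replicates technical replicates per sample (averaged into one
#'   sample-level value).
#' @param seed integer seed; fans out to per-stream child seeds.
#' @return A \code{study_design} list.
#' @export
study_design <- function(group_sizes = c(A = 3, B = 4, C = 4),
                         replicates = 3, seed = 1) {
  if (any(group_sizes < 1)) stop("group sizes must be >= 1")
  if (replicates < 1) stop("replicates must be >= 1")
  if (is.null(names(group_sizes))) stop("group_sizes must be named")
  structure(list(group_sizes = group_sizes,
                 replicates = as.integer(replicates),
                 seed = seed),
            class = "study_design")
}

design_samples <- function(design) {
  groups <- rep(names(design$group_sizes), design$group_sizes)
  ids <- unlist(lapply(names(design$group_sizes), function(g) {
    paste0(g, seq_len(design$group_sizes[[g]]))
  }))
  data.frame(sample = ids, group = groups, stringsAsFactors = FALSE)
}

# Draws from a normal(mean, sd) truncated below at 0 via inverse-CDF.
# sd = 0 degenerates to the (non-negative) mean exactly.
rtruncnorm0 <- function(n, mean, sd) {
  if (any(sd < 0)) stop("negative sd")
  out <- numeric(n)
  if (length(mean) == 1) mean <- rep(mean, n)
  if (length(sd) == 1) sd <- rep(sd, n)
  deg <- sd == 0
  out[deg] <- pmax(mean[deg], 0)
  if (any(!deg)) {
    lo <- stats::pnorm(0, mean[!deg], sd[!deg])
    u <- stats::runif(sum(!deg), min = lo, max = 1)
    out[!deg] <- stats::qnorm(u, mean[!deg], sd[!deg])
    # guard against qnorm(1-eps) overshoot at extreme u
    out[!deg][!is.finite(out[!deg])] <- mean[!deg][!is.finite(out[!deg])]
  }
  out
}

#' Simulate a sample-by-compound concentration matrix
#'
#' For every sample in group g and compound i, replicate-level contents
#' are drawn from a normal with the library's group mean and SD, truncated
#' at zero, and averaged into one sample value. Compounds recorded as not
#' detected in a group stay exactly zero there. The split between
#' between-sample and replicate-level variability is not identifiable from
#' published summaries, so both scale factors are exposed; by default all
#' of the tabulated SD acts at replicate level.
#'
#' @param library a \code{gcms_library}.
#' @param design a \code{\link{study_design}}.
#' @param replicate_sd_frac fraction of the tabulated SD applied to
#'   replicate-level draws.
#' @param between_sample_sd_frac fraction of the tabulated SD applied to
#'   sample-level offsets (0 = none).
#' @return A \code{concentration_matrix}: list with \code{values}
#'   (samples x compounds), \code{groups} (named by sample) and
#'   \code{design}.
#' @export
simulate_concentrations <- function(library, design,
                                    replicate_sd_frac = 1,
                                    between_sample_sd_frac = 0) {
  stopifnot(inherits(library, "gcms_library"),
            inherits(design, "study_design"))
  if (replicate_sd_frac < 0 || between_sample_sd_frac < 0) {
    stop("negative sd scale")
  }
  samples <- design_samples(design)
  rec <- library$records
  set.seed(child_seed(design$seed, "concentrations"))
  values <- matrix(0, nrow(samples), nrow(rec),
                   dimnames = list(samples$sample, rec$name))
  for (si in seq_len(nrow(samples))) {
    g <- samples$group[si]
    mu <- rec[[paste0("mean_", g)]]
    sd <- rec[[paste0("sd_", g)]]
    det <- rec[[paste0("detected_", g)]]
    mu_s <- if (between_sample_sd_frac > 0) {
      rtruncnorm0(length(mu), mu, sd * between_sample_sd_frac)
    } else mu
    reps <- vapply(seq_len(design$replicates), function(r) {
      rtruncnorm0(length(mu), mu_s, sd * replicate_sd_frac)
    }, numeric(length(mu)))
    v <- rowMeans(matrix(reps, nrow = length(mu)))
    v[!det] <- 0
    values[si, ] <- v
  }
  structure(list(values = values,
                 groups = stats::setNames(samples$group, samples$sample),
                 design = design),
            class = "concentration_matrix")
}

#' Load archetype sensory profiles
#'
#' Reads the packaged (synthetic, hand-chosen) archetype table: one mean
#' QDA profile per aroma type over the ten study attributes.
#'
#' @param path TSV with an \code{archetype} column and one column per
#'   attribute.
#' @return List with \code{attributes} and a groups x attributes
#'   \code{means} matrix.
#' @export
load_archetypes <- function(path = aroma_extdata("sensory_archetypes_synthetic.tsv")) {
  tab <- utils::read.delim(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           fileEncoding = "UTF-8")
  means <- as.matrix(tab[, -1, drop = FALSE])
  rownames(means) <- tab$archetype
  if (any(means < 0 | means > 9)) stop("archetype means must lie in [0, 9]")
  list(attributes = colnames(means), means = means)
}

#' Simulate a QDA sensory panel
#'
#' Each panelist scores each sample as the group archetype mean plus
#' Gaussian noise, snapped to the nearest half point and clipped to the
#' 0-9 scale (0.5 is the minimum scoring increment on the ballot).
#'
#' @param archetypes as returned by \code{\link{load_archetypes}}; row
#'   names must cover the design's groups.
#' @param design a \code{\link{study_design}}.
#' @param n_panelists number of panelists (default 10).
#' @param noise_sd panelist noise SD in score units.
#' @return A \code{sensory_panel}: long data frame (panelist, sample,
#'   group, attribute, score) with the attribute list as an attribute.
#' @export
simulate_sensory <- function(archetypes, design, n_panelists = 10,
                             noise_sd = 0.5) {
  stopifnot(inherits(design, "study_design"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!all(names(design$group_sizes) %in% rownames(archetypes$means))) {
    stop("archetypes missing for some groups")
  }
  samples <- design_samples(design)
  attrs <- archetypes$attributes
  set.seed(child_seed(design$seed, "sensory"))
  grid <- expand.grid(panelist = paste0("P", seq_len(n_panelists)),
                      sample = samples$sample,
                      attribute = attrs,
                      stringsAsFactors = FALSE)
  grid$group <- samples$group[match(grid$sample, samples$sample)]
  mu <- archetypes$means[cbind(grid$group, grid$attribute)]
  raw <- mu + stats::rnorm(nrow(grid), 0, noise_sd)
  grid$score <- pmin(9, pmax(0, round(raw * 2) / 2))
  grid <- grid[, c("panelist", "sample", "group", "attribute", "score")]
  structure(grid, class = c("sensory_panel", "data.frame"),
            attributes_order = attrs)
}

#' Simulate a retention-time peak list from true retention indices
#'
#' Inverts the linear retention-index relation on a reference ladder to
#' produce retention times for given analyte RIs, optionally with Gaussian
#' timing jitter; useful as a self-consistency fixture for
#' \code{\link{retention_index}}.
#'
#' @param ladder a \code{\link{reference_ladder}}.
#' @param analyte_ris true retention indices (within the ladder span).
#' @param jitter_sd retention-time jitter SD, seconds.
#' @param seed integer seed.
#' @return Data frame with \code{ri_true} and \code{rt}.
#' @export
simulate_peak_list <- function(ladder, analyte_ris, jitter_sd = 0, seed = 1) {
  stopifnot(inherits(ladder, "reference_ladder"))
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  n <- ladder$carbon_number
  t <- ladder$retention_time
  if (any(analyte_ris < 100 * n[1] | analyte_ris > 100 * n[length(n)])) {
    stop("analyte RI outside ladder span")
  }
  frac <- analyte_ris / 100
  idx <- pmin(findInterval(frac, n), length(n) - 1)
  rt <- t[idx] + (frac - n[idx]) / (n[idx + 1] - n[idx]) *
    (t[idx + 1] - t[idx])
  set.seed(child_seed(seed, "peaks"))
  rt <- rt + if (jitter_sd > 0) stats::rnorm(length(rt), 0, jitter_sd) else 0
  data.frame(ri_true = analyte_ris, rt = rt)
}

#' Simulate per-sample GC-IMS peak volumes
#'
#' Draws lognormal volumes with median equal to the recorded per-type peak
#' volume and a given coefficient of variation; cv = 0 reproduces the
#' table exactly.
#'
#' @param records IMS peak records from \code{\link{load_ims_table}}.
#' @param cv coefficient of variation of the multiplicative noise.
#' @param design a \code{\link{study_design}}.
#' @return Data frame: one row per (sample, signal) with simulated
#'   \code{volume}.
#' @export
simulate_ims_volumes <- function(records, cv, design) {
  stopifnot(inherits(design, "study_design"))
  if (cv < 0) stop("cv must be >= 0")
  samples <- design_samples(design)
  sigma <- sqrt(log(1 + cv^2))
  set.seed(child_seed(design$seed, "ims"))
  out <- do.call(rbind, lapply(seq_len(nrow(samples)), function(si) {
    g <- samples$group[si]
    med <- records[[paste0("volume_", g)]]
    vol <- if (sigma > 0) {
      med * exp(stats::rnorm(length(med), 0, sigma))
    } else med
    data.frame(sample = samples$sample[si], group = g,
               signal = records$name, volume = vol,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
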