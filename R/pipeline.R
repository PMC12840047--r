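# End-to-end orchestration: one config drives simulate -> quantify ->
# ROAV -> sensory clustering -> differential screens -> GC-IMS
# fingerprints, and collects every stage's output into one structured,
# reproducible report.

#' Pipeline run configuration
#'
#' Consolidates the thresholds used across the analysis: differential
#' screen alpha and VIP cut, ROAV class boundaries, and the RI match
#' tolerance.
#'
#' @param seed integer seed driving every stochastic stage.
#' @param design a \code{\link{study_design}} (its seed is overridden by
#'   \code{seed}).
#' @param alpha t-test / ANOVA significance threshold (strict).
#' @param vip_min VIP threshold (strict).
#' @param roav_principal,roav_modifier ROAV class boundaries.
#' @param ri_tolerance retention-index match tolerance.
#' @param n_panelists,noise_sd sensory simulation settings.
#' @param ims_cv coefficient of variation for simulated IMS volumes.
#' @return A \code{run_config}.
#' @export
run_config <- function(seed = 1, design = study_design(),
                       alpha = 0.05, vip_min = 1.0,
                       roav_principal = 1.0, roav_modifier = 0.1,
                       ri_tolerance = 50, n_panelists = 10,
                       noise_sd = 0.5, ims_cv = 0.1) {
  if (any(c(vip_min, roav_principal, roav_modifier, ri_tolerance) <= 0) ||
      alpha < 0) {
    stop("thresholds must be positive (alpha may be 0)")
  }
  if (roav_modifier >= roav_principal) {
    stop("roav_modifier must be below roav_principal")
  }
  design$seed <- seed
  structure(list(seed = seed, design = design, alpha = alpha,
                 vip_min = vip_min, roav_principal = roav_principal,
                 roav_modifier = roav_modifier,
                 ri_tolerance = ri_tolerance, n_panelists = n_panelists,
                 noise_sd = noise_sd, ims_cv = ims_cv),
            class = "run_config")
}

#' Pairwise differential screen between two groups
#'
#' Pooled-variance Student t per compound, one OPLS-DA fit per comparison
#' supplying the VIP gate, and log2 fold changes (numerator group over
#' denominator group) with the matrix-wide pseudo-content for
#' non-detects. Compounds with zero variance across the two groups get
#' VIP 0 (they cannot carry class information).
#'
#' @param conc a \code{concentration_matrix}.
#' @param g_num,g_den group labels; fold changes are g_num over g_den.
#' @param alpha,vip_min strict screen thresholds.
#' @return As \code{\link{screen_differential}}.
#' @export
pairwise_screen <- function(conc, g_num, g_den, alpha = 0.05,
                            vip_min = 1) {
  keep <- conc$groups %in% c(g_num, g_den)
  X <- conc$values[keep, , drop = FALSE]
  grp <- conc$groups[keep]
  variable <- apply(X, 2, function(col) stats::sd(col) > 0)
  p <- vapply(colnames(X), function(cmp) {
    student_ttest(X[grp == g_num, cmp], X[grp == g_den, cmp])$p
  }, numeric(1))
  vip <- stats::setNames(rep(0, ncol(X)), colnames(X))
  if (sum(variable) >= 2) {
    model <- fit_oplsda(X[, variable, drop = FALSE],
                        as.numeric(grp == g_num), n_ortho = 1)
    vip[names(vip_scores(model))] <- vip_scores(model)
  }
  eps <- default_epsilon(conc$values)
  fc <- vapply(colnames(X), function(cmp) {
    log2_fold_change(mean(X[grp == g_num, cmp]),
                     mean(X[grp == g_den, cmp]), eps)
  }, numeric(1))
  screen_differential(p, vip, fc, alpha = alpha, vip_min = vip_min)
}

#' Run the full aroma-typing analysis
#'
#' Executes every stage on the packaged tables plus synthetic per-sample
#' data generated under the config's seed, and returns one structured
#' report. Identical configs produce identical reports.
#'
#' @param config a \code{\link{run_config}}.
#' @return An \code{aroma_report} list with sections \code{library}
#'   (category distribution, flavor-characterized fraction), \code{roav}
#'   (per-group tables and reference compounds), \code{sensory} (WCSS
#'   curve, elbow k, assignments, cluster profiles), \code{differential}
#'   (ANOVA screen, per-comparison screens, Venn regions) and \code{ims}
#'   (class counts, monomer/dimer pairs, difference sign summary).
#' @export
run_full_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  library_section <- stage("library", {
    lib <- load_gcms_table()
    dist <- category_distribution(lib)
    flav <- flavor_characterized_fraction(lib)
    list(lib = lib, n_compounds = nrow(lib$records),
         category_counts = dist$counts, category_percents = dist$percents,
         flavor_count = flav$count, flavor_percent = flav$percent)
  })
  lib <- library_section$lib
  library_section$lib <- NULL

  roav_section <- stage("roav", {
    res <- lapply(lib$groups, function(g) roav_from_library(lib, g))
    tab <- roav_scatter_data(res)
    list(table = tab,
         reference = stats::setNames(
           vapply(res, function(r) r$reference_compound, character(1)),
           lib$groups),
         n_principal = stats::setNames(vapply(res, function(r) {
           sum(r$scores >= config$roav_principal)
         }, integer(1)), lib$groups))
  })

  sensory_section <- stage("sensory", {
    panel <- simulate_sensory(load_archetypes(), config$design,
                              n_panelists = config$n_panelists,
                              noise_sd = config$noise_sd)
    profiles <- aggregate_qda(panel)
    curve <- wcss_curve(profiles, k_max = min(6, nrow(profiles)))
    k_star <- elbow_k(curve)
    cl <- ward_cluster(profiles, k = k_star)
    list(wcss = curve, elbow_k = k_star, assignments = cl$assignments,
         profiles = cluster_profiles(profiles, cl$assignments))
  })

  differential_section <- stage("differential", {
    conc <- simulate_concentrations(lib, config$design)
    screen <- anova_screen(conc, alpha = config$alpha)
    comparisons <- list(c("A", "B"), c("A", "C"), c("B", "C"))
    names(comparisons) <- vapply(comparisons, paste, character(1),
                                 collapse = "_vs_")
    pair <- lapply(comparisons, function(cc) {
      pairwise_screen(conc, cc[1], cc[2], config$alpha, config$vip_min)
    })
    sets <- lapply(pair, function(d) d$compound[d$verdict != "not significant"])
    list(anova = screen,
         n_anova_significant = sum(screen$significant),
         comparisons = pair,
         venn = venn_counts(sets))
  })

  ims_section <- stage("ims", {
    rec <- load_ims_table()
    fp <- build_fingerprint(rec)
    diffm <- difference_matrix(fp, "A")
    pairs <- pair_monomer_dimer(rec)
    list(n_signals = nrow(rec),
         class_counts = ims_class_counts(rec),
         n_pairs = nrow(pairs$pairs),
         pair_base_names = pairs$pairs$base_name,
         n_enriched_vs_A = apply(diffm > 0, 1, sum))
  })

  structure(list(config = list(seed = config$seed, alpha = config$alpha,
                               vip_min = config$vip_min,
                               noise_sd = config$noise_sd,
                               n_panelists = config$n_panelists),
                 library = library_section,
                 roav = roav_section,
                 sensory = sensory_section,
                 differential = differential_section,
                 ims = ims_section),
            class = "aroma_report")
}

#' Write a report as JSON
#'
#' @param report an \code{aroma_report}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "aroma_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
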