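#' Analyze one image end to end
#'
#' Runs the pipeline stages in their canonical order: background
#' estimation from the cell-free ROI, seeded-watershed segmentation into
#' plasma membrane / interiors, compartment-mask construction
#' (background-derived F66 threshold, maximum-entropy marker threshold),
#' pixelwise background-subtracted T*/N* ratio map, and per-cell
#' per-compartment median statistics with PM normalization. Deterministic
#' given its inputs.
#'
#' @param stack A [channel_stack()].
#' @param seeds A [seed_set()].
#' @param config A [run_config()].
#' @return List with `measurements` (data frame, see [measure_cells()])
#'   and `report` (thresholds, backgrounds, warnings, configuration echo).
#' @export
analyze <- function(stack, seeds, config = run_config()) {
  warnings_seen <- character()
  res <- withCallingHandlers({
    background <- estimate_background(stack, seeds$background_roi)
    segmentation <- segment_cells(stack, seeds, config)
    masks <- build_compartment_masks(stack, segmentation, background, config)
    measurements <- measure_cells(stack, segmentation, masks, background, config)
    list(background = background, segmentation = segmentation,
         masks = masks, measurements = measurements)
  }, warning = function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  report <- list(
    config = unclass(config),
    n_cells = length(res$segmentation$cell_ids),
    border_cells = names(res$segmentation$border_flag)[res$segmentation$border_flag],
    background = list(n = res$background$n, t = res$background$t,
                      marker = res$background$marker),
    f66_threshold = res$masks$f66_threshold,
    marker_threshold = res$masks$marker_threshold,
    marker_threshold_provenance = res$masks$marker_threshold_provenance,
    warnings = warnings_seen,
    version = as.character(utils::packageVersion("dipoleratio")))
  list(measurements = res$measurements, report = report,
       segmentation = res$segmentation, masks = res$masks,
       background = res$background)
}

#' Analyze every image of a (synthetic or on-disk) dataset
#'
#' Applies [analyze()] to each entry; a failing image is recorded in the
#' report and the batch continues. Border-flagged cells are excluded from
#' the returned table unless `config$include_border_cells` is set.
#'
#' @param dataset An [generate_experiment()] result, or any list of
#'   entries with `stack` and `seeds`.
#' @param config A [run_config()]; when the dataset carries an organelle
#'   label and the configuration does not, the label is adopted.
#' @return List with `measurements` (one data frame with an `image`
#'   column; `cell_id` is made globally unique via the image index),
#'   `reports` (per image), and `failures` (named error messages).
#' @export
analyze_dataset <- function(dataset, config = run_config()) {
  entries <- if (inherits(dataset, "f66_dataset")) dataset$images else dataset
  if (inherits(dataset, "f66_dataset") && is.null(config$organelle_label)) {
    config$organelle_label <- dataset$organelle
  }
  tables <- list()
  reports <- list()
  failures <- character()
  for (i in seq_along(entries)) {
    entry <- entries[[i]]
    res <- tryCatch(analyze(entry$stack, entry$seeds, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[as.character(i)]] <- conditionMessage(res)
      next
    }
    m <- res$measurements
    if (nrow(m)) {
      m$image <- i
      m$cell_uid <- paste(i, m$cell_id, sep = ".")
      tables[[length(tables) + 1]] <- m
    }
    reports[[i]] <- res$report
  }
  measurements <- if (length(tables)) do.call(rbind, tables) else
    data.frame()
  if (nrow(measurements) && !config$include_border_cells)
    measurements <- measurements[!measurements$border_flag, , drop = FALSE]
  list(measurements = measurements, reports = reports, failures = failures)
}

#' Statistical comparison of compartments from measurement tables
#'
#' Within one experiment (one organelle), compares plasma-membrane vs
#' organelle per-cell median ratios with Welch's t-test. Across
#' experiments (several organelles), compares PM-normalized per-cell
#' medians with one-way ANOVA followed by Tukey's HSD. The report is fully
#' regenerable from saved measurement tables.
#'
#' @param tables Named list of measurement data frames (names = organelle
#'   labels), each as returned by [analyze_dataset()]; or a single data
#'   frame for the within-experiment comparison alone.
#' @param include_border_cells Keep border-flagged cells (default FALSE).
#' @return List with per-organelle `welch` tests and `summaries`, and —
#'   when several organelles are given — `anova_tukey` on the normalized
#'   ratios plus per-organelle `normalized_summaries`.
#' @export
compare_compartments <- function(tables, include_border_cells = FALSE) {
  if (is.data.frame(tables)) tables <- list(organelle = tables)
  if (is.null(names(tables))) stop("tables must be named by organelle", call. = FALSE)
  organelles <- c("lysosome", "golgi", "er", "mitochondria")
  clean <- lapply(tables, function(d) {
    if (!include_border_cells && nrow(d)) d <- d[!d$border_flag, , drop = FALSE]
    d
  })
  welch <- list(); summaries <- list(); norm_groups <- list()
  for (nm in names(clean)) {
    d <- clean[[nm]]
    org_label <- intersect(unique(d$compartment), organelles)
    if (length(org_label) != 1)
      stop(sprintf("table '%s' must contain exactly one organelle compartment", nm),
           call. = FALSE)
    pm <- d$median_ratio[d$compartment == "PM"]
    org <- d$median_ratio[d$compartment == org_label]
    if (length(pm) < 2 || length(org) < 2)
      stop(sprintf("table '%s': insufficient cells for testing (PM n=%d, %s n=%d)",
                   nm, length(pm), org_label, length(org)), call. = FALSE)
    welch[[nm]] <- welch_t(pm, org)
    summaries[[nm]] <- list(pm = summarize_group(pm, paste0(nm, ":PM")),
                            organelle = summarize_group(org, paste0(nm, ":", org_label)))
    norm_groups[[nm]] <- d$normalized_ratio[d$compartment == org_label]
  }
  out <- list(welch = welch, summaries = summaries)
  if (length(norm_groups) >= 2) {
    out$anova_tukey <- anova_tukey(norm_groups)
    out$normalized_summaries <- lapply(names(norm_groups), function(nm)
      summarize_group(norm_groups[[nm]], nm))
    names(out$normalized_summaries) <- names(norm_groups)
  }
  out
}

#' Human-readable statistics report block
#'
#' @param comparison A [compare_compartments()] result.
#' @return Character vector of report lines, invisibly; printed as a side
#'   effect.
#' @export
format_comparison <- function(comparison) {
  lines <- character()
  for (nm in names(comparison$welch)) {
    w <- comparison$welch[[nm]]
    s <- comparison$summaries[[nm]]
    lines <- c(lines, sprintf(
      "%s: PM %.3f +/- %.3f (n=%d) vs organelle %.3f +/- %.3f (n=%d), Welch t=%.2f df=%.1f p=%.3g %s",
      nm, s$pm$mean, s$pm$sd, s$pm$n, s$organelle$mean, s$organelle$sd,
      s$organelle$n, w$statistic, w$df, w$p_value, p_stars(w$p_value)))
  }
  if (!is.null(comparison$anova_tukey)) {
    a <- comparison$anova_tukey$anova
    lines <- c(lines, sprintf("ANOVA (normalized ratios): F=%.2f p=%.3g %s",
                              a$statistic, a$p_value, p_stars(a$p_value)))
    pw <- comparison$anova_tukey$pairwise
    lines <- c(lines, sprintf("  Tukey %s: diff=%.3f p=%.3g %s",
                              pw$pair, pw$diff, pw$p_value, pw$stars))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
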