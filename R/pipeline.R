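#' Run the full analysis chain on one specimen
#'
#' Stage order: rigid registration of the sub-edge volume to the supra-edge
#' volume (skipped when the pair is already aligned), maximum-filter bone
#' expansion + K-edge subtraction + averaging + Li thresholding for the
#' vascular mask, the attenuation rule for the bone mask, ROI restriction,
#' then morphometry and the d.HAp distribution.
#'
#' @param pair A [dual_energy_pair] (in memory, or see [read_stack()]).
#' @param roi An [roi_spec]; `NULL` centers the default 720 x 300 um
#'   cylinder in the lattice.
#' @param cal A [calibration_line].
#' @param params A [segmentation_params].
#' @param register Estimate and apply the inter-energy alignment
#'   (default `TRUE`; set `FALSE` for already-registered or synthetic
#'   aligned pairs).
#' @param registration_args List of arguments for [register_volumes()].
#' @param prune_spur_vox Spur-pruning cutoff for [skeletonize()].
#' @param out_dir Optional directory: writes vessel/bone mask stacks, the
#'   per-specimen CSV row, and a JSON provenance record.
#' @param id Specimen identifier used in outputs.
#' @return An object of class `specimen_result`: `morphometry` (a
#'   `morphometry_result`), `density` (a `density_histogram`),
#'   `vessel_mask`, `bone_mask`, `roi_mask`, `transform`, `threshold`,
#'   `provenance`.
#' @export
run_specimen <- function(pair, roi = NULL, cal = calibration_line(),
                         params = segmentation_params(), register = TRUE,
                         registration_args = list(), prune_spur_vox = 2L,
                         out_dir = NULL, id = "specimen") {
  stopifnot(inherits(pair, "dual_energy_pair"))
  if (is.null(roi)) roi <- roi_spec()
  transform <- NULL
  if (register) {
    pair <- do.call(align_pair, c(list(pair), registration_args))
    transform <- attr(pair, "applied_transform")
  }
  roi_m <- roi_mask(roi, pair$low)
  vessels <- segment_vessels(pair, params, roi = roi_m)
  bone <- segment_bone(pair$low, vessels, cal, params, roi = roi_m)
  morpho <- morphometry(vessels, bone, roi_m, prune_spur_vox = prune_spur_vox)
  dens <- dhap_distribution(bone, pair$low, cal, roi = roi_m,
                            mean_filter_size = params$mean_filter_size)
  prov <- list(
    id = id,
    threshold_gray = as.numeric(attr(vessels, "threshold")),
    transform = if (is.null(transform)) NULL else
      list(translation = transform$translation,
           rotation_deg = transform$rotation_deg),
    params = unclass(params),
    calibration = unclass(cal),
    roi = unclass(roi),
    voxel_um = pair$low$voxel_um,
    n_vessel_voxels = sum(vessels$values),
    n_bone_voxels = sum(bone$values),
    package_version = as.character(utils::packageVersion("kesct")))
  res <- structure(list(morphometry = morpho, density = dens,
                        vessel_mask = vessels, bone_mask = bone,
                        roi_mask = roi_m, transform = transform,
                        threshold = prov$threshold_gray,
                        provenance = prov, id = id),
                   class = "specimen_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_stack(vessels, file.path(out_dir, paste0(id, "_vessel_mask.tif")))
    write_stack(bone, file.path(out_dir, paste0(id, "_bone_mask.tif")))
    utils::write.csv(cbind(id = id, as_morphometry_row(morpho)),
                     file.path(out_dir, paste0(id, "_morphometry.csv")),
                     row.names = FALSE)
    jsonlite::write_json(prov, file.path(out_dir, paste0(id, "_provenance.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' @export
print.specimen_result <- function(x, ...) {
  cat(sprintf("<specimen_result> %s (Li threshold %.2f gray)\n", x$id, x$threshold))
  print(x$morphometry)
  invisible(x)
}

#' Run a multi-group study
#'
#' Runs [run_specimen()] for each entry, assembles the per-specimen index
#' table, group mean +/- SEM summaries, Kruskal-Wallis tests with Dunn's
#' post hoc comparisons for every index, percent contrasts against a
#' reference group, and partition checks of the size-specific quantities.
#'
#' @param specimens A list; each element is a list with fields `id`,
#'   `group`, `pair` (a [dual_energy_pair]) and optionally `roi`.
#' @param reference_group Group used as the reference for percent
#'   contrasts; `NULL` picks the first group.
#' @param alpha Significance level for flagging post hoc pairs.
#' @param ... Passed to [run_specimen()].
#' @return An object of class `study_report`: `per_specimen` (data.frame),
#'   `summary`, `tests` (per-index Kruskal-Wallis + Dunn), `contrasts`,
#'   `partition_checks`, `density` (per-specimen histograms).
#' @export
run_study <- function(specimens, reference_group = NULL, alpha = 0.05, ...) {
  groups <- vapply(specimens, function(s) as.character(s$group), "")
  counts <- table(groups)
  rows <- list()
  dens <- list()
  part <- list()
  for (i in seq_along(specimens)) {
    sp <- specimens[[i]]
    res <- run_specimen(sp$pair, roi = sp$roi, id = sp$id, ...)
    rows[[i]] <- cbind(id = sp$id, group = as.character(sp$group),
                       as_morphometry_row(res$morphometry))
    dens[[sp$id]] <- res$density
    part[[length(part) + 1L]] <- data.frame(
      id = sp$id, index = "vvf_pct",
      discrepancy = partition_check(res$morphometry$per_bin$vvf_pct,
                                    res$morphometry$vvf_pct)$discrepancy)
    part[[length(part) + 1L]] <- data.frame(
      id = sp$id, index = "vseg_per_mm3",
      discrepancy = partition_check(res$morphometry$per_bin$seg_per_mm3,
                                    res$morphometry$vseg_per_mm3)$discrepancy)
  }
  per_specimen <- do.call(rbind, rows)
  summary_df <- group_summary(per_specimen)

  indices <- c("vvf_pct", "vd_um", "vseg_per_mm3", "bvf_pct", "bth_um",
               "bseg_per_mm3")
  tests <- NULL
  if (length(unique(groups)) >= 2) {
    tests <- list()
    for (ix in indices) {
      v <- per_specimen[[ix]]
      ok <- !is.na(v)
      if (length(unique(groups[ok])) < 2) next
      kw <- kruskal_wallis(v[ok], groups[ok])
      dn <- dunn_posthoc(v[ok], groups[ok])
      dn$significant <- dn$p_adjusted < alpha
      tests[[ix]] <- list(kruskal_wallis = kw, dunn = dn)
    }
  } else {
    message("single group: summaries only, tests skipped")
  }

  contrasts <- NULL
  if (length(unique(groups)) >= 2) {
    if (is.null(reference_group)) reference_group <- unique(groups)[1]
    cl <- list()
    for (ix in indices) {
      ref <- mean(per_specimen[[ix]][groups == reference_group], na.rm = TRUE)
      for (g in setdiff(unique(groups), reference_group)) {
        comp <- mean(per_specimen[[ix]][groups == g], na.rm = TRUE)
        if (is.na(ref) || ref == 0 || is.na(comp)) next
        pc <- percent_contrast(ref, comp)
        cl[[length(cl) + 1L]] <- data.frame(
          index = ix, reference = reference_group, group = g,
          reference_mean = ref, group_mean = comp,
          direction = pc$direction, percent = pc$percent)
      }
    }
    contrasts <- do.call(rbind, cl)
  }

  structure(list(per_specimen = per_specimen, summary = summary_df,
                 tests = tests, contrasts = contrasts,
                 partition_checks = do.call(rbind, part),
                 density = dens, group_counts = counts),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  print(x$group_counts)
  cat("\nGroup summaries (mean +/- SEM):\n")
  s <- x$summary
  s$mean <- signif(s$mean, 4)
  s$sem <- signif(s$sem, 3)
  print(s, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("\nKruskal-Wallis p-values:\n")
    for (ix in names(x$tests))
      cat(sprintf("  %-14s H = %6.2f, p = %.4f\n", ix,
                  x$tests[[ix]]$kruskal_wallis$H,
                  x$tests[[ix]]$kruskal_wallis$p_value))
  }
  invisible(x)
}

#' Simulate a phantom study
#'
#' Builds `n_per_group` phantoms per group from per-group
#' [phantom_spec()] argument lists, with per-specimen seeds derived from
#' `seed`, ready for [run_study()].
#'
#' @param group_args Named list: one entry per group, each a list of
#'   [phantom_spec()] arguments shared by that group's specimens.
#' @param n_per_group Specimens per group.
#' @param seed Base seed; specimen i of group g uses `seed + 1000 g + i`.
#' @return A list of specimen entries (`id`, `group`, `pair`, `roi`,
#'   `truth`).
#' @export
simulate_study <- function(group_args, n_per_group = 8L, seed = 1L) {
  specimens <- list()
  for (g in seq_along(group_args)) {
    gname <- names(group_args)[g]
    for (i in seq_len(n_per_group)) {
      args <- c(group_args[[g]], list(seed = seed + 1000L * g + i))
      spec <- do.call(phantom_spec, args)
      ph <- build_phantom(spec)
      specimens[[length(specimens) + 1L]] <- list(
        id = sprintf("%s_%02d", gname, i), group = gname,
        pair = ph$pair, roi = phantom_roi(spec), truth = ph$truth)
    }
  }
  specimens
}
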