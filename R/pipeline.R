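#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis.  The defaults reproduce
#' the canonical workflow: QC at MAF > 0.001, call rate > 98%, exact HWE at
#' 1e-6, per-sample missingness < 0.05; 10 GRM principal components plus age
#' and sex as fixed effects; Gaussian smoothing of the p-value map at
#' sigma = 0.5 voxels; significance threshold 0.05; significant-arm fractions
#' 10/20/30/100% and insignificant-arm fractions 10/20/30%; 26-connectivity.
#'
#' @param qc named list overriding [qc_filter()] thresholds
#' @param alpha voxel significance threshold
#' @param smoothing_sigma Gaussian kernel SD in voxels
#' @param fractions top fractions for the significant arm
#' @param insignificant_fractions top fractions for the insignificant arm
#' @param connectivity 6, 18 or 26
#' @param n_pcs number of population-structure PCs
#' @param covariate_columns covariate column names (beyond the PCs)
#' @param reml a [reml_options()]
#' @param min_voxels drop regions smaller than this (default 1 = keep all)
#' @param seed seed recorded for provenance (the pipeline itself is
#'   deterministic; only simulators consume randomness)
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(qc = list(), alpha = 0.05, smoothing_sigma = 0.5,
                            fractions = c(0.1, 0.2, 0.3, 1.0),
                            insignificant_fractions = c(0.1, 0.2, 0.3),
                            connectivity = 26, n_pcs = 10L,
                            covariate_columns = c("age", "sex"),
                            reml = reml_options(), min_voxels = 1L,
                            seed = 1L) {
  stopifnot(all(fractions > 0), all(fractions <= 1),
            all(insignificant_fractions > 0),
            all(insignificant_fractions <= 1))
  structure(list(qc = qc, alpha = alpha, smoothing_sigma = smoothing_sigma,
                 fractions = fractions,
                 insignificant_fractions = insignificant_fractions,
                 connectivity = connectivity, n_pcs = as.integer(n_pcs),
                 covariate_columns = covariate_columns, reml = reml,
                 min_voxels = as.integer(min_voxels),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full heritability-mapping pipeline
#'
#' Orchestrates, deterministically: genotype QC -> GRM -> population-structure
#' PCs -> voxelwise GREML -> heritability and p-value brain maps -> Gaussian
#' smoothing of the p-value map -> per-arm top-fraction voxel selection ->
#' 3D connected components -> region-averaged QTs -> region-level GREML with
#' the *same* GRM and covariates -> summary table.  The optional atlas arm
#' re-estimates heritability for atlas-defined region QTs.
#'
#' @param genotypes a [genotype_matrix()]
#' @param volumes named list of subject 3D arrays (names = sample IDs), or a
#'   `voxel_qt` already vectorized
#' @param covariates data frame with `sample_id` plus the configured columns
#' @param atlas optional label [brain_map()] for the comparison arm
#' @param config a [pipeline_config()]
#' @param out_dir optional directory; when given, intermediates are persisted
#'   (QC report JSON, PC TSV, voxel result TSV, NIfTI maps, region sets,
#'   region result TSV, summary JSON and Markdown report)
#' @return list of class `herimap_result`: `qc_report`, `grm`, `pcs`,
#'   `voxel_results`, `vqt`, `h2_map`, `p_map`, `p_map_smoothed`,
#'   `region_sets`, `region_results`, `summary`
#' @export
run_pipeline <- function(genotypes, volumes, covariates, atlas = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_herimap(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)), "herimap_pipeline_error")
    })
  }
  persist <- !is.null(out_dir)
  if (persist) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  qc <- stage("qc", do.call(qc_filter, c(list(genotypes), config$qc)))
  g <- qc$genotypes

  a <- stage("grm", compute_grm(g))
  pcs <- stage("pca", grm_pca(a, k = config$n_pcs))

  vqt <- stage("vectorize", {
    v <- if (inherits(volumes, "voxel_qt")) volumes else vectorize(volumes)
    keep <- match(g$samples, v$samples)
    if (anyNA(keep)) {
      stop_herimap("volumes missing for some post-QC samples",
                   "herimap_id_error")
    }
    v$values <- v$values[keep, , drop = FALSE]
    v$samples <- v$samples[keep]
    v
  })
  covariates <- covariates[match(g$samples, covariates$sample_id), ]
  x <- stage("covariates",
             build_covariates(covariates, pcs,
                              columns = config$covariate_columns))

  voxel_results <- stage("voxel_reml",
                         fit_reml_batch(vqt, x, a, config$reml))
  ok <- voxel_results$status == "ok"
  h2_map <- devectorize(ifelse(ok, voxel_results$h2, 0), vqt$index,
                        semantics = "heritability")
  p_map <- devectorize(ifelse(ok, voxel_results$p_value, 1), vqt$index,
                       semantics = "p_value")
  p_sm <- stage("smooth", smooth_pmap(p_map, config$smoothing_sigma))

  arms <- bind_rows(
    tibble(arm = "significant", fraction = config$fractions),
    tibble(arm = "insignificant", fraction = config$insignificant_fractions))
  region_sets <- list()
  region_results <- list()
  for (r in seq_len(nrow(arms))) {
    arm <- arms$arm[r]; fr <- arms$fraction[r]
    key <- sprintf("%s_%g", arm, fr)
    rs <- stage(paste0("extract_", key), {
      bin <- select_voxels(p_sm, vqt$index, alpha = config$alpha,
                           top_fraction = fr, arm = arm)
      cc <- connected_components(bin, config$connectivity,
                                 provenance = list(
                                   arm = arm, top_fraction = fr,
                                   alpha = config$alpha,
                                   smoothing_sigma = config$smoothing_sigma))
      if (config$min_voxels > 1L) {
        keep <- cc$regions$size >= config$min_voxels
        cc$voxels <- cc$voxels[keep]
        lab <- array(0L, dim(cc$labels$volume))
        for (i in seq_along(cc$voxels)) lab[cc$voxels[[i]] + 1L] <- i
        cc$labels <- brain_map(lab, "label", fill = 0)
        cc$regions <- tibble(region_id = seq_along(cc$voxels),
                             size = vapply(cc$voxels, nrow, integer(1)))
      }
      cc
    })
    region_sets[[key]] <- rs
    if (nrow(rs$regions) == 0) next
    qts <- stage(paste0("region_qts_", key), region_qts(rs, vqt))
    res <- stage(paste0("region_reml_", key),
                 fit_reml_batch(qts, x, a, config$reml))
    region_results[[key]] <- mutate(res, arm = arm, fraction = fr,
                                    size = rs$regions$size, .before = 1)
  }

  if (!is.null(atlas)) {
    at <- stage("atlas", atlas_regions(atlas, vqt))
    region_sets[["atlas"]] <- at$region_set
    res <- stage("atlas_reml", fit_reml_batch(at$qts, x, a, config$reml))
    region_results[["atlas"]] <-
      mutate(res, arm = "atlas", fraction = NA_real_,
             size = at$region_set$regions$size, .before = 1)
  }
  region_results <- list_rbind(unname(region_results))
  summary_tbl <- summarize_heritability(region_results)

  out <- structure(list(
    qc_report = qc$report, grm = a, pcs = pcs,
    voxel_results = voxel_results, vqt = vqt,
    h2_map = h2_map, p_map = p_map, p_map_smoothed = p_sm,
    region_sets = region_sets, region_results = region_results,
    summary = summary_tbl, config = config), class = "herimap_result")

  if (persist) {
    write_qc_report(qc$report, file.path(out_dir, "qc_report.json"))
    write.table(data.frame(sample_id = g$samples, pcs),
                file.path(out_dir, "pcs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_reml_tsv(voxel_results, file.path(out_dir, "voxel_results.tsv"))
    write_voxel_index(vqt$index, file.path(out_dir, "voxel_index.tsv"))
    write_brain_map(h2_map, file.path(out_dir, "h2_map.nii.gz"))
    write_brain_map(p_map, file.path(out_dir, "p_map.nii.gz"))
    write_brain_map(p_sm, file.path(out_dir, "p_map_smoothed.nii.gz"))
    for (key in names(region_sets)) {
      write_region_set(region_sets[[key]],
                       file.path(out_dir, sprintf("regions_%s.nii.gz", key)))
    }
    write_reml_tsv(region_results, file.path(out_dir, "region_results.tsv"))
    write_summary_json(summary_tbl, file.path(out_dir, "summary.json"))
    writeLines(format_summary_md(summary_tbl),
               file.path(out_dir, "report.md"))
  }
  out
}

#' @export
print.herimap_result <- function(x, ...) {
  cat(sprintf("<herimap_result> %d voxels fitted, %d region sets\n",
              nrow(x$voxel_results), length(x$region_sets)))
  print(x$summary)
  invisible(x)
}

#' Summarize region heritability estimates per arm and fraction
#'
#' Counts (and proportions, in percent) of regions whose estimated h2 exceeds
#' each upper threshold or falls below each lower threshold, per
#' (arm, fraction) group — the content of the standard comparison table.
#'
#' @param region_results tibble from [run_pipeline()] (`arm`, `fraction`,
#'   `h2` columns)
#' @param upper h2 thresholds counted as "greater than"
#' @param lower h2 thresholds counted as "less than"
#' @return tibble of class `herit_summary` with `roi_total` and paired
#'   `n_*` / `pct_*` columns
#' @export
summarize_heritability <- function(region_results,
                                   upper = c(0.9, 0.8, 0.5),
                                   lower = c(0.2, 0.1)) {
  grp <- group_by(region_results, .data$arm, .data$fraction)
  base <- summarise(grp, roi_total = n(), .groups = "drop")
  for (u in upper) {
    nm <- sprintf("gt_%g", 100 * u)
    cnt <- summarise(grp, n = sum(.data$h2 > u, na.rm = TRUE),
                     .groups = "drop")$n
    base[[paste0("n_", nm)]] <- cnt
    base[[paste0("pct_", nm)]] <- 100 * cnt / base$roi_total
  }
  for (l in lower) {
    nm <- sprintf("lt_%g", 100 * l)
    cnt <- summarise(grp, n = sum(.data$h2 < l, na.rm = TRUE),
                     .groups = "drop")$n
    base[[paste0("n_", nm)]] <- cnt
    base[[paste0("pct_", nm)]] <- 100 * cnt / base$roi_total
  }
  class(base) <- c("herit_summary", class(base))
  base
}

#' Write a heritability summary as JSON
#' @param summary a `herit_summary`
#' @param path output file
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(as.data.frame(summary), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Format a heritability summary as a Markdown table
#'
#' Threshold cells are rendered `count(percent%)`.
#' @param summary a `herit_summary`
#' @return character vector of Markdown lines
#' @export
format_summary_md <- function(summary) {
  ncols <- grep("^n_", names(summary), value = TRUE)
  hdr <- c("arm", "fraction", "roi_total", sub("^n_", "ROI_", ncols))
  lines <- c(paste0("| ", paste(hdr, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"))
  for (r in seq_len(nrow(summary))) {
    cells <- c(summary$arm[r],
               ifelse(is.na(summary$fraction[r]), "-",
                      sprintf("%g%%", 100 * summary$fraction[r])),
               summary$roi_total[r],
               vapply(ncols, function(cn) {
                 sprintf("%d(%.1f%%)", summary[[cn]][r],
                         summary[[sub("^n_", "pct_", cn)]][r])
               }, character(1)))
    lines <- c(lines, paste0("| ", paste(cells, collapse = " | "), " |"))
  }
  lines
}
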