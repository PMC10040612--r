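#' Default pipeline configuration
#'
#' All analysis defaults mirror the study constants: enhancement threshold
#' 0.6 x stalk maximum, dilation ratio threshold 1.5, wall band and
#' projection radius 1.5 mm (about two diagonals of the 0.7 mm voxels),
#' 100 samples over a 0.8 s cycle (step 0.008 s).
#'
#' @param seed master seed.
#' @param n_per_type synthetic cases per type (7 reproduces the clinical
#'   7 + 7 + 7 design).
#' @param out_dir output directory.
#' @return nested configuration list (see [run_pipeline()]).
#' @export
demo_cohort <- function(seed = 1L, n_per_type = 7L, out_dir = "fusiwall_out") {
  list(
    cohort = list(source = "synthetic", n_per_type = as.integer(n_per_type),
                  seed = as.integer(seed)),
    mesh = list(ring_spacing = 0.7, angular_res = 48L),
    flow = list(T_cycle = 0.8, n_t = 100L, q_peak = 4.95e-6,
                beta_osc = 0.5, noise_sd = 0.02),
    coupling = list(a = 0, b = 0.7, noise_sd = 0.15, I_stalk = 1000),
    analysis = list(threshold_factor = 0.6, ratio_threshold = 1.5,
                    wall_band_mm = 1.5, search_radius_mm = 1.5,
                    resample_spacing = 0.5, voxel_spacing = 0.7,
                    area_weighted = TRUE),
    output = list(dir = out_dir, write_wss = FALSE, write_volumes = FALSE)
  )
}

validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- demo_cohort()
  config <- utils::modifyList(base, config)
  tf <- config$analysis$threshold_factor
  if (!is.numeric(tf) || tf <= 0 || tf > 1)
    stop("threshold_factor must lie in (0, 1]", call. = FALSE)
  if (config$analysis$ratio_threshold <= 1)
    stop("ratio_threshold must exceed 1", call. = FALSE)
  if (!config$cohort$source %in% c("synthetic", "manifest"))
    stop("cohort source must be 'synthetic' or 'manifest'", call. = FALSE)
  if (config$cohort$source == "synthetic" && config$cohort$n_per_type < 1)
    stop("n_per_type must be >= 1", call. = FALSE)
  config
}

#' Analyze a single case
#'
#' Runs morphometrics, hemodynamic maps, parent normalization, enhancement
#' mapping and node-wise correlations on one (synthetic or ingested) case.
#'
#' @param case a case list as produced by [make_cohort()]: `case_id`,
#'   `ifa_type`, `centerline`, `mesh`, `wss`, `volume`.
#' @param analysis the `analysis` block of the configuration (see
#'   [demo_cohort()]).
#' @return list with `row` (one CohortTable data.frame row), `maps`,
#'   `enhancement` and `segment`.
#' @export
analyze_case <- function(case, analysis = demo_cohort()$analysis) {
  mesh <- case$mesh
  clr <- resample_centerline(case$centerline, analysis$resample_spacing)
  ct <- curvature_torsion(clr)
  rp <- local_radius(mesh, clr)
  seg <- segment_aneurysm(mesh, clr, analysis$ratio_threshold,
                          radius_profile = rp)
  in_seg_cl <- clr$arclength >= seg[1] & clr$arclength <= seg[2]
  maps <- hemodynamic_maps(case$wss, mesh)
  maps$TAWSS_norm <- normalize_tawss(maps$TAWSS, mesh, seg,
                                     cl = case$centerline)
  s_vtx <- vertex_arclength(mesh, case$centerline)
  seg_mask <- s_vtx >= seg[1] & s_vtx <= seg[2]
  enh <- enhancement_map(case$volume, mesh, case$centerline, seg,
                         threshold_factor = analysis$threshold_factor,
                         wall_band_mm = analysis$wall_band_mm,
                         search_radius_mm = analysis$search_radius_mm)
  nodecor <- node_correlations(enh$er, maps, seg_mask)
  va <- vertex_areas(mesh)
  region_mean <- function(map, mask) {
    keep <- mask & is.finite(map)
    if (!any(keep)) return(NA_real_)
    if (isTRUE(analysis$area_weighted))
      sum(map[keep] * va[keep]) / sum(va[keep]) else mean(map[keep])
  }
  idx <- c("TAWSS", "OSI", "GON", "RRT")
  seg_summary <- regional_summary(maps[idx], mesh, seg_mask,
                                  area_weighted = isTRUE(analysis$area_weighted))
  # parent-normalized TAWSS region means: the cross-patient comparable form
  norm_enh <- region_mean(maps$TAWSS_norm, seg_mask & enh$enhanced)
  norm_non <- region_mean(maps$TAWSS_norm, seg_mask & !enh$enhanced)
  row <- data.frame(case_id = case$case_id, ifa_type = case$ifa_type,
                    d_max = d_max(mesh, clr, seg, radius_profile = rp),
                    l_max = l_max(clr, seg),
                    kappa_max = max(ct$kappa[in_seg_cl]),
                    kappa_mean = mean(ct$kappa[in_seg_cl]),
                    tau_max = max(ct$tau[in_seg_cl]),
                    tau_mean = mean(ct$tau[in_seg_cl]),
                    cr_max = enh$cr_max,
                    enhancement_area = enh$enhancement_area,
                    proportion_enhanced = enh$proportion_enhanced,
                    stringsAsFactors = FALSE)
  for (nm in idx) {
    row[[paste0(nm, "_max")]] <- seg_summary$max[seg_summary$index == nm]
    row[[paste0(nm, "_mean")]] <- seg_summary$mean[seg_summary$index == nm]
    row[[paste0(nm, "_enh")]] <- region_mean(maps[[nm]],
                                             seg_mask & enh$enhanced)
    row[[paste0(nm, "_non")]] <- region_mean(maps[[nm]],
                                             seg_mask & !enh$enhanced)
    row[[paste0("rho_", nm)]] <- nodecor$rho[nodecor$index == nm]
    row[[paste0("p_", nm)]] <- nodecor$p[nodecor$index == nm]
  }
  row$TAWSS_norm_enh <- norm_enh
  row$TAWSS_norm_non <- norm_non
  list(row = row, maps = maps, enhancement = enh, segment = seg,
       node_correlations = nodecor)
}

#' Run the full pipeline
#'
#' Generates (or ingests) the cohort, analyzes every case, writes per-case
#' surface maps and the four cohort report tables. One case's failure is
#' logged and does not abort the others. Re-running with the same
#' configuration and seed reproduces identical CSV content.
#'
#' @param config a configuration list (see [demo_cohort()]) or the path of
#'   a YAML file with the same structure.
#' @return invisibly, a list with `status` (0 when every case succeeded),
#'   `table` (the per-case CohortTable), `reports` and `failed` case ids.
#' @export
run_pipeline <- function(config = demo_cohort()) {
  config <- validate_config(config)
  out_dir <- config$output$dir
  dir.create(file.path(out_dir, "cases"), recursive = TRUE,
             showWarnings = FALSE)
  cohort <- if (config$cohort$source == "synthetic") {
    make_cohort(n_per_type = config$cohort$n_per_type,
                seed = config$cohort$seed,
                flow = do.call(flow_params, config$flow),
                coupling = do.call(coupling_params, config$coupling),
                ring_spacing = config$mesh$ring_spacing,
                angular_res = config$mesh$angular_res,
                voxel_spacing = config$analysis$voxel_spacing)
  } else {
    read_cohort_manifest(config$cohort$manifest)
  }
  provenance <- sprintf("fusiwall %s | seed %s | config sha %s",
                        as.character(utils::packageVersion("fusiwall")),
                        config$cohort$seed, config_hash(config))
  rows <- list(); failed <- character(0)
  for (case in cohort) {
    res <- tryCatch(analyze_case(case, config$analysis), error = function(e) {
      message(sprintf("[fusiwall] case %s failed: %s", case$case_id,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(res)) { failed <- c(failed, case$case_id); next }
    rows[[length(rows) + 1L]] <- res$row
    mesh_out <- case$mesh
    mesh_out$point_data <- c(
      mesh_out$point_data[c("s")],
      list(TAWSS = res$maps$TAWSS, TAWSS_norm = res$maps$TAWSS_norm,
           OSI = res$maps$OSI, GON = res$maps$GON,
           RRT = ifelse(is.finite(res$maps$RRT), res$maps$RRT, -1),
           ER = res$enhancement$er,
           enhanced = as.numeric(res$enhancement$enhanced)))
    write_surface(mesh_out, file.path(out_dir, "cases",
                                      paste0(case$case_id, "_surface.vtk")))
    if (isTRUE(config$output$write_volumes) && !is.null(case$volume)) {
      write_volume(case$volume, file.path(out_dir, "cases",
                                          paste0(case$case_id, ".nii.gz")))
      awe_vol <- intensity_volume(res$enhancement$awe_mask * 1L,
                                  case$volume$affine)
      write_volume(awe_vol, file.path(out_dir, "cases",
                                      paste0(case$case_id, "_awe.nii.gz")))
    }
    if (isTRUE(config$output$write_wss))
      write_wss_series(case$wss, file.path(out_dir, "cases",
                                           paste0(case$case_id, "_wss.vtk")))
  }
  if (!length(rows)) stop("every case failed", call. = FALSE)
  tab <- do.call(rbind, rows)
  con <- file(file.path(out_dir, "cohort_cases.csv"), "w")
  writeLines(paste("#", provenance), con)
  utils::write.csv(tab, con, row.names = FALSE)
  close(con)
  reports <- cohort_report(tab, out_dir = file.path(out_dir, "reports"),
                           provenance = provenance)
  invisible(list(status = if (length(failed)) 1L else 0L, table = tab,
                 reports = reports, failed = failed))
}

config_hash <- function(config) {
  # stable short fingerprint of the configuration (not cryptographic)
  txt <- paste(deparse(config[setdiff(names(config), "output")]),
               collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)) %%
            .Machine$integer.max)
}

#' Read a cohort from a user-file manifest
#'
#' The manifest CSV needs columns `case_id`, `ifa_type`, `mesh` (STL/PLY/VTK
#' surface), `centerline` (CSV with columns x,y,z), `wss` (VTK polydata from
#' [write_wss_series()]) and `volume` (NIfTI with `_stalk`/`_lumen`
#' companions); relative paths resolve against the manifest's directory.
#'
#' @param path manifest CSV.
#' @return list of cases as in [make_cohort()].
#' @export
read_cohort_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("case_id", "ifa_type", "mesh", "centerline", "wss", "volume")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  root <- dirname(path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(root, p))
  lapply(seq_len(nrow(man)), function(i) {
    mesh <- read_surface(resolve(man$mesh[i]))
    clp <- utils::read.csv(resolve(man$centerline[i]))
    list(case_id = man$case_id[i], ifa_type = man$ifa_type[i], seed = NA,
         centerline = centerline(as.matrix(clp[, c("x", "y", "z")])),
         mesh = mesh,
         wss = read_wss_series(resolve(man$wss[i])),
         volume = read_volume(resolve(man$volume[i])))
  })
}

#' Write / read a WSS time series as legacy VTK polydata
#'
#' Each time sample is stored as a `VECTORS` point-data array named
#' `wss_<time>` (seconds, 6 decimals) on the series' mesh, making the
#' format readable by standard VTK viewers.
#'
#' @param series a [wss_series()].
#' @param path destination `.vtk` file.
#' @export
write_wss_series <- function(series, path) {
  mesh <- series$mesh
  pd <- list()
  for (t in seq_along(series$times))
    pd[[sprintf("wss_%010.6f", series$times[t])]] <- series$vectors[t, , ]
  write_surface(surface_mesh(mesh$vertices, mesh$faces, pd), path,
                format = "vtk")
}

#' @rdname write_wss_series
#' @export
read_wss_series <- function(path) {
  mesh <- read_surface(path, format = "vtk")
  nms <- grep("^wss_", names(mesh$point_data), value = TRUE)
  if (length(nms) < 2L)
    stop("no wss_<time> VECTORS arrays found in ", path, call. = FALSE)
  times <- as.numeric(sub("^wss_", "", nms))
  ord <- order(times)
  vec <- array(0, c(length(nms), nrow(mesh$vertices), 3))
  for (k in seq_along(ord))
    vec[k, , ] <- mesh$point_data[[nms[ord[k]]]]
  mesh$point_data <- mesh$point_data[!grepl("^wss_", names(mesh$point_data))]
  wss_series(times[ord], vec, mesh)
}
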