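# Two-group (CON vs MCT) synthetic study: generation to disk + full-pipeline
# analysis, closing the loop from fixtures to group-level effect directions.

#' Default CON/MCT group parameters for the synthetic study
#'
#' Group means are the reported study values; per-cell spreads are the
#' reported SEMs scaled by the square root of the reported cell counts (a
#' reconstruction of the per-cell SD, since only summary statistics are
#' published). Image parameters use a 10\% between-section coefficient of
#' variation. \code{directions} lists the effect directions the default
#' study is expected to reproduce (the statistically established effects
#' only).
#'
#' @return A nested list with per-group parameter blocks and the
#'   \code{directions} table.
#' @export
studyDefaults <- function() {
  list(
    cyto = list(   # 1 Hz Fura-2 ratio transients, pre-ISO and ISO
      CON = list(amp_pre = c(1.41, 0.49), amp_iso = c(1.99, 0.52),
                 tau_pre = c(0.27, 0.069), tau_iso = c(0.22, 0.049)),
      MCT = list(amp_pre = c(1.51, 0.55), amp_iso = c(1.67, 0.55),
                 tau_pre = c(0.26, 0.07), tau_iso = c(0.26, 0.07)),
      ttp = 0.15, diastolic = 1, noise_sd = 0.02, n_beats = 12L, n_last = 8L),
    caffeine = list(
      CON = list(store = c(0.59, 0.137), tau = c(6.07, 1.92)),
      MCT = list(store = c(0.78, 0.24), tau = c(4.75, 0.80)),
      diastolic = 1, noise_sd = 0.02, post_s = 30, pre_s = 5),
    mito = list(   # 0.1 Hz Rhod-2 dF/F0 transients
      CON = list(amp = c(0.025, 0.0063), ttp = c(0.165, 0.035)),
      MCT = list(amp = c(0.033, 0.0063), ttp = c(0.201, 0.047)),
      tau = 0.3, noise_sd = 0.005, n_beats = 6L, n_last = 4L),
    tom20 = list(  # STED TOM20 cluster images, 10% between-section CV
      CON = list(density = c(11.2, 1.12), area = c(0.034, 0.0034)),
      MCT = list(density = c(14.9, 1.49), area = c(0.027, 0.0027))),
    directions = data.frame(
      check = c("cyto_amp_iso_con", "cyto_tau_iso_con", "cyto_ror_iso_con",
                "mito_amp_mct_gt_con", "caff_store_mct_gt_con",
                "caff_tau_mct_lt_con", "tom20_area_mct_lt_con",
                "tom20_density_mct_gt_con"),
      description = c(
        "CON cytosolic amplitude increases with isoproterenol",
        "CON cytosolic decay tau decreases with isoproterenol",
        "CON cytosolic max rate-of-rise increases with isoproterenol",
        "mitochondrial dF/F0 amplitude larger in MCT",
        "caffeine store amplitude larger in MCT",
        "caffeine efflux tau smaller in MCT",
        "TOM20 cluster area smaller in MCT",
        "TOM20 cluster density larger in MCT"),
      stringsAsFactors = FALSE))
}

# Truncated-normal draw: non-positive (or sub-floor) values are redrawn.
.rtruncnorm <- function(n, mean, sd, floor_at = 0) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= floor_at)
  tries <- 0L
  while (length(bad) && tries < 100L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x <= floor_at)
    tries <- tries + 1L
  }
  if (length(bad)) x[bad] <- mean
  x
}

#' Generate a full two-group synthetic study to disk
#'
#' Writes, per group (CON, MCT): paced cytosolic ratio traces before and
#' during beta-adrenergic stimulation, caffeine-bolus traces, 0.1 Hz
#' mitochondrial dF/F0 traces and TOM20 STED-like images, with per-cell (or
#' per-section) parameters drawn around the group means. A
#' \code{manifest.json} records every drawn ground-truth value and the
#' expected effect directions.
#'
#' @param out_dir output directory (created).
#' @param n_cells cells per group for each trace assay.
#' @param n_images image sections per group.
#' @param params parameter block, see \code{\link{studyDefaults}}.
#' @param seed mandatory base seed; every fixture derives its own stream.
#' @return \code{out_dir}, invisibly; the manifest is
#'   \code{file.path(out_dir, "manifest.json")}.
#' @export
genGroupStudy <- function(out_dir, n_cells = 24L, n_images = 6L,
                          params = studyDefaults(), seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, n_cells = n_cells, n_images = n_images,
                   directions = params$directions, cells = list(),
                   images = list())
  k <- 0L
  for (grp in c("CON", "MCT")) {
    pc <- params$cyto[[grp]]; pf <- params$caffeine[[grp]]
    pm <- params$mito[[grp]]; pi_ <- params$tom20[[grp]]
    draws <- withSeed(deriveSeed(seed, match(grp, c("CON", "MCT"))), list(
      amp_pre = .rtruncnorm(n_cells, pc$amp_pre[1], pc$amp_pre[2], 0.05),
      amp_iso = .rtruncnorm(n_cells, pc$amp_iso[1], pc$amp_iso[2], 0.05),
      tau_pre = .rtruncnorm(n_cells, pc$tau_pre[1], pc$tau_pre[2], 0.03),
      tau_iso = .rtruncnorm(n_cells, pc$tau_iso[1], pc$tau_iso[2], 0.03),
      store = .rtruncnorm(n_cells, pf$store[1], pf$store[2], 0.05),
      tauc = .rtruncnorm(n_cells, pf$tau[1], pf$tau[2], 0.5),
      mamp = .rtruncnorm(n_cells, pm$amp[1], pm$amp[2], 0.002),
      mttp = .rtruncnorm(n_cells, pm$ttp[1], pm$ttp[2], 0.05),
      dens = .rtruncnorm(n_images, pi_$density[1], pi_$density[2], 1),
      area = .rtruncnorm(n_images, pi_$area[1], pi_$area[2], 0.005)))
    for (i in seq_len(n_cells)) {
      cell_id <- sprintf("%s_cell%02d", grp, i)
      for (cond in c("pre", "iso")) {
        k <- k + 1L
        amp <- draws[[paste0("amp_", cond)]][i]
        tau <- draws[[paste0("tau_", cond)]][i]
        tr <- genTransientTrace(
          n_beats = params$cyto$n_beats, stim_freq = 1,
          diastolic = params$cyto$diastolic, amplitude = amp,
          ttp = params$cyto$ttp, tau_decay = tau,
          noise_sd = params$cyto$noise_sd, mode = "ratiometric",
          seed = deriveSeed(seed, 100 + k))
        writeTrace(tr, file.path(out_dir, sprintf("cyto_%s_%s.csv", cell_id, cond)))
        manifest$cells[[length(manifest$cells) + 1L]] <- list(
          id = cell_id, group = grp, assay = "cyto", condition = cond,
          amplitude = amp, tau_decay = tau)
      }
      k <- k + 1L
      trc <- genCaffeineTrace(draws$store[i], draws$tauc[i],
                              diastolic = params$caffeine$diastolic,
                              pre_s = params$caffeine$pre_s,
                              post_s = params$caffeine$post_s,
                              noise_sd = params$caffeine$noise_sd,
                              seed = deriveSeed(seed, 100 + k))
      writeTrace(trc, file.path(out_dir, sprintf("caff_%s.csv", cell_id)))
      manifest$cells[[length(manifest$cells) + 1L]] <- list(
        id = cell_id, group = grp, assay = "caffeine",
        store_amplitude = draws$store[i], tau_efflux = draws$tauc[i])
      k <- k + 1L
      trm <- genTransientTrace(
        n_beats = params$mito$n_beats, stim_freq = 0.1, diastolic = 1,
        amplitude = draws$mamp[i], ttp = draws$mttp[i],
        tau_decay = params$mito$tau, noise_sd = params$mito$noise_sd,
        mode = "single", pre_s = 2, seed = deriveSeed(seed, 100 + k))
      writeTrace(trm, file.path(out_dir, sprintf("mito_%s.csv", cell_id)))
      manifest$cells[[length(manifest$cells) + 1L]] <- list(
        id = cell_id, group = grp, assay = "mito",
        amplitude = draws$mamp[i], ttp = draws$mttp[i])
    }
    for (j in seq_len(n_images)) {
      k <- k + 1L
      img <- genClusterImage(density_um2 = draws$dens[j],
                             mean_area_um2 = draws$area[j],
                             seed = deriveSeed(seed, 100 + k))
      writeLabelImage(img, file.path(out_dir,
                                     sprintf("tom20_%s_sec%02d.tif", grp, j)))
      manifest$images[[length(manifest$images) + 1L]] <- list(
        group = grp, section = j, density_um2 = draws$dens[j],
        mean_area_um2 = draws$area[j])
    }
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' Run the full pipeline over a generated study directory
#'
#' Reads every fixture back from disk, runs the matching analysis
#' (ratio/dF/F0 computation, beat segmentation, steady-state summaries,
#' caffeine assay, cluster segmentation and density), aggregates per group,
#' and evaluates the manifest's expected effect directions against the
#' recovered group means.
#'
#' @param dir a directory produced by \code{\link{genGroupStudy}}.
#' @return A list: \code{cells} (per-cell recovered parameters),
#'   \code{images} (per-section recovered density and area),
#'   \code{group_means}, and \code{directions} (data.frame with
#'   \code{check}, \code{expected}, \code{observed_ok}).
#' @export
analyzeGroupStudy <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  defaults <- studyDefaults()
  cells <- list()
  # Cells whose response falls below the acceptance noise floor are skipped
  # (non-responders), mirroring experimental practice.
  for (f in list.files(dir, pattern = "^cyto_.*\\.csv$", full.names = TRUE)) {
    parts <- strsplit(sub("\\.csv$", "", basename(f)), "_")[[1]]
    row <- tryCatch({
      ss <- steadyStateSummary(analyzeBeats(computeRatio(readTrace(f))),
                               n_last = defaults$cyto$n_last)
      data.frame(group = parts[2], assay = "cyto", condition = parts[4],
                 amplitude = ssMean(ss, "amplitude"),
                 tau = ssMean(ss, "tau_decay"),
                 ror = ssMean(ss, "max_rate_of_rise"),
                 ttp = ssMean(ss, "time_to_peak"))
    }, cardioflux_error = function(e) NULL)
    if (!is.null(row)) cells[[length(cells) + 1L]] <- row
  }
  for (f in list.files(dir, pattern = "^caff_.*\\.csv$", full.names = TRUE)) {
    parts <- strsplit(sub("\\.csv$", "", basename(f)), "_")[[1]]
    row <- tryCatch({
      tr <- readTrace(f)
      res <- analyzeCaffeine(makeRatioTrace(tr@time, tr@channels$F,
                                            events = tr@events))
      data.frame(group = parts[2], assay = "caffeine", condition = "caff",
                 amplitude = res$store_amplitude, tau = res$tau_efflux,
                 ror = NA_real_, ttp = NA_real_)
    }, cardioflux_error = function(e) NULL)
    if (!is.null(row)) cells[[length(cells) + 1L]] <- row
  }
  for (f in list.files(dir, pattern = "^mito_.*\\.csv$", full.names = TRUE)) {
    parts <- strsplit(sub("\\.csv$", "", basename(f)), "_")[[1]]
    row <- tryCatch({
      tr <- readTrace(f)
      dff <- computeDff(tr, c(0, tr@stimTimes[1]))
      ss <- steadyStateSummary(analyzeBeats(dff),
                               n_last = defaults$mito$n_last)
      data.frame(group = parts[2], assay = "mito", condition = "mito",
                 amplitude = ssMean(ss, "amplitude"),
                 tau = ssMean(ss, "tau_decay"),
                 ror = ssMean(ss, "max_rate_of_rise"),
                 ttp = ssMean(ss, "time_to_peak"))
    }, cardioflux_error = function(e) NULL)
    if (!is.null(row)) cells[[length(cells) + 1L]] <- row
  }
  cells <- do.call(rbind, cells)
  imgs <- list()
  for (f in list.files(dir, pattern = "^tom20_.*\\.tif$", full.names = TRUE)) {
    parts <- strsplit(sub("\\.tif$", "", basename(f)), "_")[[1]]
    cs <- segmentClusters(readLabelImage(f))
    dens <- clusterDensity(cs)
    imgs[[length(imgs) + 1L]] <- data.frame(
      group = parts[2], section = parts[3],
      density = dens$mean_per_tile,
      mean_area = mean(clusters(cs)$area_um2))
  }
  imgs <- do.call(rbind, imgs)
  gm <- function(assay, cond, grp, field)
    mean(cells[[field]][cells$assay == assay & cells$condition == cond &
                          cells$group == grp], na.rm = TRUE)
  gmi <- function(grp, field) mean(imgs[[field]][imgs$group == grp])
  group_means <- list(
    cyto_amp = c(CON_pre = gm("cyto", "pre", "CON", "amplitude"),
                 CON_iso = gm("cyto", "iso", "CON", "amplitude"),
                 MCT_pre = gm("cyto", "pre", "MCT", "amplitude"),
                 MCT_iso = gm("cyto", "iso", "MCT", "amplitude")),
    cyto_tau = c(CON_pre = gm("cyto", "pre", "CON", "tau"),
                 CON_iso = gm("cyto", "iso", "CON", "tau")),
    cyto_ror = c(CON_pre = gm("cyto", "pre", "CON", "ror"),
                 CON_iso = gm("cyto", "iso", "CON", "ror")),
    mito_amp = c(CON = gm("mito", "mito", "CON", "amplitude"),
                 MCT = gm("mito", "mito", "MCT", "amplitude")),
    caff_store = c(CON = gm("caffeine", "caff", "CON", "amplitude"),
                   MCT = gm("caffeine", "caff", "MCT", "amplitude")),
    caff_tau = c(CON = gm("caffeine", "caff", "CON", "tau"),
                 MCT = gm("caffeine", "caff", "MCT", "tau")),
    tom20_area = c(CON = gmi("CON", "mean_area"), MCT = gmi("MCT", "mean_area")),
    tom20_density = c(CON = gmi("CON", "density"), MCT = gmi("MCT", "density")))
  ok <- c(
    cyto_amp_iso_con = group_means$cyto_amp[["CON_iso"]] > group_means$cyto_amp[["CON_pre"]],
    cyto_tau_iso_con = group_means$cyto_tau[["CON_iso"]] < group_means$cyto_tau[["CON_pre"]],
    cyto_ror_iso_con = group_means$cyto_ror[["CON_iso"]] > group_means$cyto_ror[["CON_pre"]],
    mito_amp_mct_gt_con = group_means$mito_amp[["MCT"]] > group_means$mito_amp[["CON"]],
    caff_store_mct_gt_con = group_means$caff_store[["MCT"]] > group_means$caff_store[["CON"]],
    caff_tau_mct_lt_con = group_means$caff_tau[["MCT"]] < group_means$caff_tau[["CON"]],
    tom20_area_mct_lt_con = group_means$tom20_area[["MCT"]] < group_means$tom20_area[["CON"]],
    tom20_density_mct_gt_con = group_means$tom20_density[["MCT"]] > group_means$tom20_density[["CON"]])
  dirs <- as.data.frame(man$directions)
  dirs$observed_ok <- unname(ok[dirs$check])
  list(cells = cells, images = imgs, group_means = group_means,
       directions = dirs)
}
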