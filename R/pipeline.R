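## End-to-end orchestration: synthetic data -> calibration -> niche
## simulation -> scenarios -> statistics -> report, with a run manifest.

#' Run the full analysis pipeline
#'
#' Executes the stages in order and writes all artifacts beneath
#' \code{outDir}: \code{synthetic/} (per-nucleus intensities and binding
#' samples), \code{calibration/} (accepted rate pairs and summaries),
#' \code{signatures/} (wild-type steady states), \code{scenarios/}
#' (per-scenario signatures, flags and comparisons against wild type),
#' \code{stats/} (Kruskal-Wallis/Dunn letters on the synthetic
#' intensities), \code{report/} (heatmap and radar data, optional figures),
#' and a \code{manifest.json} with the configuration and per-file
#' checksums. Deterministic given the seed.
#'
#' @param outDir Output directory (created if needed).
#' @param seed Integer seed driving every stochastic stage.
#' @param scenarios Scenario names to run, default all nine.
#' @param abundanceConfig An \linkS4class{AbundanceConfig}; its seed is
#'   overridden by \code{seed}.
#' @param gridStep,tol Calibration grid settings (see
#'   \code{\link{scanRates}}); the defaults reproduce the reference scan.
#' @param policy Rate-selection policy.
#' @param makePlots Also render pdf figures (radar and heatmap).
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(outDir, seed = 1L,
                        scenarios = scenarioNames(),
                        abundanceConfig = defaultWtAbundance(),
                        gridStep = 2e-4, tol = 1e-5, policy = "random",
                        makePlots = FALSE) {
  seed <- as.integer(seed)
  dirs <- file.path(outDir, c("synthetic", "calibration", "signatures",
                              "scenarios", "stats", "report"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  put <- function(path) { written <<- c(written, path); path }

  ## synthetic measurement-level data
  cfg <- abundanceConfig
  cfg@seed <- seed
  intens <- sampleAbundances(cfg)
  utils::write.csv(intens, put(file.path(outDir, "synthetic", "intensities.csv")),
                   row.names = FALSE)
  bindTab <- publishedBindingTable()
  bs <- do.call(rbind, lapply(seq_len(nrow(bindTab)), function(i) {
    s <- sampleBinding(bindTab$mean[i], bindTab$sd[i], bindTab$n_typical[i],
                       seed = seed + i, label = bindTab$label[i])
    data.frame(sample_id = seq_along(s@samples), label = s@label,
               binding_pct = s@samples)
  }))
  utils::write.csv(bs, put(file.path(outDir, "synthetic", "binding_samples.csv")),
                   row.names = FALSE)

  ## calibration of the wild-type affinities
  aff <- wtAffinities()
  wtRates <- calibrateAll(aff, gridStep = gridStep, tol = tol,
                          policy = policy, seed = seed)
  calSummary <- lapply(wtRates@provenance, function(p)
    list(target = p$target, a = p$a, d = p$d, nAccepted = p$nAccepted))
  jsonlite::write_json(calSummary,
                       put(file.path(outDir, "calibration", "summary.json")),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(
    data.frame(rate = names(rateValues(wtRates)), value = rateValues(wtRates)),
    put(file.path(outDir, "calibration", "rates.csv")), row.names = FALSE)

  ## scenario runs (wild type reused for comparisons)
  dprdRates <- if (any(c("dprd") %in% scenarios))
    calibrateAll(deltaPrdAffinities(), gridStep = gridStep, tol = tol,
                 policy = policy, seed = seed) else NULL
  sigs <- list()
  for (sc in scenarios) {
    rs <- switch(sc, wt = wtRates, dprd = dprdRates, c4 = wtRates, NULL)
    sigs[[sc]] <- runScenario(sc, abundance = cfg, rates = rs,
                              gridStep = gridStep, tol = tol,
                              policy = policy, seed = seed)
    m <- signatureMatrix(sigs[[sc]])
    utils::write.csv(as.data.frame(m),
                     put(file.path(outDir, "scenarios", paste0(sc, "_signature.csv"))))
    jsonlite::write_json(as.list(signatureFlags(sigs[[sc]])),
                         put(file.path(outDir, "scenarios", paste0(sc, "_flags.json"))),
                         auto_unbox = TRUE)
  }
  if ("wt" %in% names(sigs)) {
    utils::write.csv(as.data.frame(signatureMatrix(sigs$wt)),
                     put(file.path(outDir, "signatures", "wt_signature.csv")))
    for (sc in setdiff(names(sigs), "wt")) {
      cmp <- compareSignatures(sigs$wt, sigs[[sc]])
      jsonlite::write_json(
        list(distance = cmp@distance, flagsA = as.list(cmp@flagsA),
             flagsB = as.list(cmp@flagsB)),
        put(file.path(outDir, "scenarios", paste0("wt_vs_", sc, ".json"))),
        auto_unbox = TRUE, digits = NA)
    }
  }

  ## statistics on the synthetic intensities: per protein across cell types
  statRows <- list()
  for (pr in PROTEINS) {
    sub <- intens[intens$protein == pr, ]
    agg <- stats::aggregate(root_mean ~ root_id + cell_type, sub, mean)
    kw <- kruskalWallis(agg$root_mean, agg$cell_type)
    dn <- dunnBH(agg$root_mean, agg$cell_type)
    statRows[[pr]] <- data.frame(protein = pr, cell_type = names(dn$letters),
                                 letters = unname(dn$letters),
                                 kw_H = kw$statistic, kw_p = kw$p.value)
  }
  utils::write.csv(do.call(rbind, statRows),
                   put(file.path(outDir, "stats", "intensity_groups.csv")),
                   row.names = FALSE)

  ## report data (+ optional figures)
  if ("wt" %in% names(sigs)) {
    hm <- heatmapMatrix(sigs$wt)
    utils::write.csv(as.data.frame(hm),
                     put(file.path(outDir, "report", "wt_heatmap.csv")))
    utils::write.csv(radarData(sigs$wt),
                     put(file.path(outDir, "report", "wt_radar.csv")),
                     row.names = FALSE)
    if ("dprd" %in% names(sigs)) {
      side <- cbind(WT = heatmapMatrix(sigs$wt, "none"),
                    dPrD = heatmapMatrix(sigs$dprd, "none"))
      utils::write.csv(as.data.frame(side),
                       put(file.path(outDir, "report", "wt_dprd_heatmap.csv")))
    }
    if (makePlots) {
      pdf_path <- file.path(outDir, "report", "signature_figures.pdf")
      grDevices::pdf(pdf_path, width = 7, height = 7)
      plotRadar(sigs$wt, main = "WT complex signatures")
      plotHeatmap(sigs$wt, main = "WT signature heatmap")
      if ("dprd" %in% names(sigs))
        plotRadar(sigs$dprd, main = "PLT3 dPrD complex signatures")
      grDevices::dev.off()
      put(pdf_path)
    }
  }

  manifest <- list(
    package = "SCNComplex",
    version = as.character(utils::packageVersion("SCNComplex")),
    seed = seed, scenarios = scenarios,
    gridStep = gridStep, tol = tol, policy = policy,
    checksums = as.list(tools::md5sum(sort(written))),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Rebuild the report files of a pipeline output directory
#'
#' Reads the per-scenario signature CSVs written by
#' \code{\link{runPipeline}} and regenerates the report artifacts: the
#' wild-type heatmap and radar data, a side-by-side wild-type /
#' PrD-deletion heatmap when both are present, and optional pdf figures.
#' With no scenario signatures present, only the calibration summary is
#' reported.
#'
#' @param outDir A directory previously populated by
#'   \code{\link{runPipeline}}.
#' @param makePlots Also render pdf figures.
#' @return Invisibly, the paths of the files written.
#' @export
renderReport <- function(outDir, makePlots = FALSE) {
  rep_dir <- file.path(outDir, "report")
  dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  readSig <- function(sc) {
    f <- file.path(outDir, "scenarios", paste0(sc, "_signature.csv"))
    if (!file.exists(f)) return(NULL)
    as.matrix(utils::read.csv(f, row.names = 1))
  }
  wt <- readSig("wt")
  if (is.null(wt)) {
    cal <- file.path(outDir, "calibration", "summary.json")
    if (!file.exists(cal)) stop("no signatures and no calibration found in ", outDir)
    file.copy(cal, file.path(rep_dir, "calibration_summary.json"), overwrite = TRUE)
    return(invisible(file.path(rep_dir, "calibration_summary.json")))
  }
  f1 <- file.path(rep_dir, "wt_heatmap.csv")
  utils::write.csv(as.data.frame(heatmapMatrix(wt)), f1)
  f2 <- file.path(rep_dir, "wt_radar.csv")
  utils::write.csv(radarData(wt), f2, row.names = FALSE)
  written <- c(f1, f2)
  dprd <- readSig("dprd")
  if (!is.null(dprd)) {
    f3 <- file.path(rep_dir, "wt_dprd_heatmap.csv")
    utils::write.csv(as.data.frame(cbind(WT = heatmapMatrix(wt, "none"),
                                         dPrD = heatmapMatrix(dprd, "none"))), f3)
    written <- c(written, f3)
  }
  if (makePlots) {
    f4 <- file.path(rep_dir, "signature_figures.pdf")
    grDevices::pdf(f4, width = 7, height = 7)
    plotRadar(wt, main = "WT complex signatures")
    plotHeatmap(wt, main = "WT signature heatmap")
    if (!is.null(dprd)) plotRadar(dprd, main = "PLT3 dPrD complex signatures")
    grDevices::dev.off()
    written <- c(written, f4)
  }
  invisible(written)
}

#' Base-graphics radar plot of complex levels
#'
#' @param signature A \linkS4class{NicheSignature}.
#' @param main Plot title.
#' @export
plotRadar <- function(signature, main = "") {
  m <- asSignatureMatrix(signature)
  complexes <- c("WOX5PLT3", "BRAVOPLT3", "BRAVOWOX5", "WOX5PLT3BRAVO")
  v <- m[complexes, , drop = FALSE]
  rmax <- max(v) * 1.05
  if (rmax == 0) rmax <- 1
  ang <- seq(0, 2 * pi, length.out = length(complexes) + 1)[-5]
  graphics::plot(0, 0, type = "n", xlim = c(-1.2, 1.2), ylim = c(-1.2, 1.2),
                 axes = FALSE, xlab = "", ylab = "", main = main, asp = 1)
  for (f in c(0.25, 0.5, 0.75, 1))
    graphics::polygon(f * cos(ang), f * sin(ang), border = "grey80")
  graphics::text(1.15 * cos(ang), 1.15 * sin(ang), complexes, cex = 0.7)
  cols <- c(SI = "purple", QC = "blue", CSC = "darkgreen", CC = "orange")
  for (ct in colnames(v)) {
    r <- v[, ct] / rmax
    graphics::polygon(r * cos(ang), r * sin(ang), border = cols[ct], lwd = 2)
  }
  graphics::legend("topright", legend = colnames(v), col = cols[colnames(v)],
                   lwd = 2, bty = "n", cex = 0.8)
}

#' Base-graphics heatmap of a signature
#'
#' @param signature A \linkS4class{NicheSignature}.
#' @param main Plot title.
#' @export
plotHeatmap <- function(signature, main = "") {
  hm <- heatmapMatrix(signature)
  graphics::image(t(hm[rev(seq_len(nrow(hm))), ]), axes = FALSE, main = main,
                  col = grDevices::hcl.colors(64, "Blue-Red"))
  graphics::axis(1, at = seq(0, 1, length.out = ncol(hm)), labels = colnames(hm))
  graphics::axis(2, at = seq(0, 1, length.out = nrow(hm)),
                 labels = rev(rownames(hm)), las = 2, cex.axis = 0.7)
}
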