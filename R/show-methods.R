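setMethod("show", "ModelParams", function(object) {
  v <- paramValues(object)
  cat("ModelParams:",
      paste(sprintf("%s=%.4g", names(v), v), collapse = ", "), "\n")
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: %d layers x %d particles, dLum=%d, ",
                     "%d steps x %g min, layer=%g mm, magnitude=%s, seed=%s\n"),
              object@d, object@w, object@dLum, object@nSteps, object@dtMin,
              object@layerHeightMm, object@magnitudeDist,
              ifelse(is.na(object@seed), "none", object@seed)))
})

setMethod("show", "LatticeState", function(object) {
  d <- length(object@tracer)
  cat(sprintf("LatticeState: %d layers, capacity %d, %d tracer / %d non-marked\n",
              d, object@capacity, sum(object@tracer), sum(object@nonmarked)))
})

setMethod("show", "ProfileSeries", function(object) {
  cat(sprintf(paste0("ProfileSeries: %d layers x %d time points ",
                     "(dt = %g min, layer = %g mm), total counts %g-%g\n"),
              nrow(object@counts), ncol(object@counts), object@dtMin,
              object@layerHeightMm,
              if (length(object@counts)) min(colSums(object@counts)) else 0,
              if (length(object@counts)) max(colSums(object@counts)) else 0))
})

setMethod("show", "FitResult", function(object) {
  free <- setdiff(paramNames(), object@fixed)
  v <- paramValues(object)[free]
  cat(sprintf("FitResult (%s): objective = %.6g\n", object@method,
              object@objective))
  for (nm in free) {
    if (length(object@paramSD) && !is.na(object@paramSD[nm]))
      cat(sprintf("  %s = %.4g +/- %.2g (n = %d replicates)\n", nm, v[nm],
                  object@paramSD[nm], nrow(object@replicates)))
    else
      cat(sprintf("  %s = %.4g\n", nm, v[nm]))
  }
  if (length(object@fixed))
    cat("  fixed:", paste(sprintf("%s=%.4g", object@fixed,
                                  paramValues(object)[object@fixed]),
                          collapse = ", "), "\n")
})

setMethod("show", "SensitivityGrid", function(object) {
  cat(sprintf(paste0("SensitivityGrid: %d distance x %d tracerdif values; ",
                     "minimum %.6g at distance=%.4g, tracerdif=%.4g\n"),
              length(object@distanceValues), length(object@tracerdifValues),
              min(object@objective), object@minDistance, object@minTracerdif))
})

setMethod("show", "DiffusionFit", function(object) {
  cat(sprintf(paste0("DiffusionFit: Db = %.6g layers^2/min ",
                     "(%.6g mm^2/min), objective = %.6g over %d time points\n"),
              object@db, object@dbMm2PerMin, object@objective,
              length(object@perTimeSos)))
})
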