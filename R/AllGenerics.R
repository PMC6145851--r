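#' Accessors for netdyn classes
#'
#' `tsData` returns the frames x regions matrix; `trSeconds` the repetition
#' time; `regionLabels` the region names; `nRegions`/`nFrames`/`nWindows`
#' the obvious counts; `coupling` the regions x regions x windows array;
#' `assignments` the windows x regions module-id matrix; `modularity` the
#' per-window Q; `moduleCounts` the per-window number of modules;
#' `participation` and `moduleDegree` the windows x regions B and W
#' matrices; `meanParticipation` the per-window mean B; `occupancy` the
#' histogram matrix of a cartographic profile.
#'
#' @param x an object of the relevant netdyn class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("tsData", function(x) standardGeneric("tsData"))
#' @rdname accessors
#' @export
setGeneric("trSeconds", function(x) standardGeneric("trSeconds"))
#' @rdname accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))
#' @rdname accessors
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))
#' @rdname accessors
#' @export
setGeneric("coupling", function(x) standardGeneric("coupling"))
#' @rdname accessors
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))
#' @rdname accessors
#' @export
setGeneric("modularity", function(x) standardGeneric("modularity"))
#' @rdname accessors
#' @export
setGeneric("moduleCounts", function(x) standardGeneric("moduleCounts"))
#' @rdname accessors
#' @export
setGeneric("participation", function(x) standardGeneric("participation"))
#' @rdname accessors
#' @export
setGeneric("moduleDegree", function(x) standardGeneric("moduleDegree"))
#' @rdname accessors
#' @export
setGeneric("meanParticipation", function(x) standardGeneric("meanParticipation"))
#' @rdname accessors
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))
#' @rdname accessors
#' @export
setGeneric("runMeta", function(x) standardGeneric("runMeta"))

setMethod("tsData", "ParcellatedTimeSeries", function(x) x@data)
setMethod("trSeconds", "ParcellatedTimeSeries", function(x) x@tr)
setMethod("regionLabels", "ParcellatedTimeSeries", function(x) x@regionLabels)
setMethod("nRegions", "ParcellatedTimeSeries", function(x) ncol(x@data))
setMethod("nFrames", "ParcellatedTimeSeries", function(x) nrow(x@data))
setMethod("runMeta", "ParcellatedTimeSeries", function(x) x@runMeta)

setMethod("coupling", "MTDTensor", function(x) x@coupling)
setMethod("regionLabels", "MTDTensor", function(x) x@regionLabels)
setMethod("nRegions", "MTDTensor", function(x) dim(x@coupling)[1])
setMethod("nWindows", "MTDTensor", function(x) dim(x@coupling)[3])
setMethod("trSeconds", "MTDTensor", function(x) x@tr)

setMethod("assignments", "WindowPartitionSet", function(x) x@assignments)
setMethod("modularity", "WindowPartitionSet", function(x) x@Q)
setMethod("moduleCounts", "WindowPartitionSet", function(x) x@nModules)
setMethod("nWindows", "WindowPartitionSet", function(x) nrow(x@assignments))
setMethod("nRegions", "WindowPartitionSet", function(x) ncol(x@assignments))
setMethod("regionLabels", "WindowPartitionSet", function(x) x@regionLabels)

setMethod("participation", "TopologySeries", function(x) x@B)
setMethod("moduleDegree", "TopologySeries", function(x) x@W)
setMethod("meanParticipation", "TopologySeries", function(x) x@meanB)
setMethod("nWindows", "TopologySeries", function(x) nrow(x@B))
setMethod("nRegions", "TopologySeries", function(x) ncol(x@B))
setMethod("regionLabels", "TopologySeries", function(x) x@regionLabels)

setMethod("occupancy", "CartographicProfile", function(x) x@occupancy)

setMethod("show", "ParcellatedTimeSeries", function(object) {
  cat("ParcellatedTimeSeries:", nrow(object@data), "frames x",
      ncol(object@data), "regions, TR =", object@tr, "s\n")
  if (length(object@runMeta))
    cat("  meta:", paste(names(object@runMeta), unlist(object@runMeta),
                         sep = "=", collapse = ", "), "\n")
})

setMethod("show", "MTDTensor", function(object) {
  d <- dim(object@coupling)
  cat("MTDTensor:", d[1], "x", d[2], "regions x", d[3], "windows (w =",
      object@window, "frames, stride =", object@stride, ")\n")
})

setMethod("show", "WindowPartitionSet", function(object) {
  cat("WindowPartitionSet:", nrow(object@assignments), "windows x",
      ncol(object@assignments), "regions, gamma =", object@gamma, "\n")
  cat("  modules per window:", round(mean(object@nModules), 2), "+/-",
      round(stats::sd(object@nModules), 2),
      if (object@matched) "(labels matched)" else "(labels unmatched)", "\n")
})

setMethod("show", "TopologySeries", function(object) {
  cat("TopologySeries:", nrow(object@B), "windows x", ncol(object@B),
      "regions; mean B =", round(mean(object@meanB), 3), "\n")
})

setMethod("show", "CartographicProfile", function(object) {
  cat("CartographicProfile:", nrow(object@occupancy), "B-bins x",
      ncol(object@occupancy), "W-bins;", object@nClipped,
      "samples clipped into edge bins\n")
})

setMethod("show", "PupilSeries", function(object) {
  cat("PupilSeries:", length(object@samples), "samples at", object@rate,
      "Hz;", round(100 * mean(object@interpolatedMask), 1),
      "% interpolated", if (object@zScored) "(z-scored)" else "", "\n")
})

setMethod("show", "VarModel", function(object) {
  cat("VarModel: order", object@order, "on", length(object@regionLabels),
      "regions (subspace dim", ncol(object@projection), ")\n")
})
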