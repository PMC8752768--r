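#' @include AllClasses.R
NULL

#' Write a table as TSV
#'
#' The package's interchange dialect: tab-separated, header line, `.`
#' decimal separator, no quoting, no row names.
#'
#' @param x data.frame.
#' @param path output path.
#' @export
writeTSV <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-event feature table
#'
#' Reads a TSV feature table (as written by the pipeline or by external
#' tools) and checks that the morphometric columns are present.
#'
#' @param path TSV path.
#' @param required columns that must be present.
#' @return data.frame.
#' @export
readFeatureTable <- function(path, required = c("L", "W", "A", "AR", "V")) {
  x <- utils::read.delim(path, check.names = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop("feature table misses columns: ", paste(miss, collapse = ", "))
  x
}

#' Read growth curves from a long-format TSV
#'
#' Expects columns `replicate`, `time_h`, `density`, `source`, `mM` (and
#' optionally `od`), one row per reading, and returns one
#' [GrowthCurve-class] per replicate x source x mM combination.
#'
#' @param path TSV path.
#' @return list of [GrowthCurve-class] objects.
#' @export
readGrowthCurves <- function(path) {
  x <- utils::read.delim(path)
  need <- c("replicate", "time_h", "density", "source", "mM")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("growth-curve table misses columns: ",
                         paste(miss, collapse = ", "))
  key <- interaction(x$replicate, x$source, x$mM, drop = TRUE)
  lapply(split(x, key), function(g) {
    g <- g[order(g$time_h), ]
    GrowthCurve(g$time_h, g$density, carbonSource = as.character(g$source[1]),
                carbonmM = g$mM[1], replicate = as.character(g$replicate[1]),
                od = if ("od" %in% names(g)) as.logical(g$od[1]) else FALSE)
  })
}

#' Flatten lineage trajectories to a long table
#'
#' @param trajectories list of [LineageTrajectory-class] objects.
#' @return data.frame with `lineage` and `condition` columns prepended to
#'   the per-transfer records.
#' @export
trajectoriesToLong <- function(trajectories) {
  if (is(trajectories, "LineageTrajectory")) trajectories <- list(trajectories)
  do.call(rbind, lapply(trajectories, function(tr) {
    cbind(data.frame(lineage = tr@lineage, condition = tr@condition),
          tr@records)
  }))
}

#' Rebuild lineage trajectories from a long table
#'
#' Inverse of [trajectoriesToLong()].
#'
#' @param x data.frame with `lineage` and `condition` columns.
#' @return list of [LineageTrajectory-class] objects.
#' @export
longToTrajectories <- function(x) {
  lapply(split(x, x$lineage), function(g) {
    rec <- g[order(g$transfer), setdiff(names(g), c("lineage", "condition")),
             drop = FALSE]
    rownames(rec) <- NULL
    LineageTrajectory(g$lineage[1], g$condition[1], rec)
  })
}

#' Write a two-channel event image as multi-page TIFF
#'
#' Page 1 is the fluorescence channel, page 2 the support-proxy channel;
#' both stored as 32-bit float, fluorescence normalized by the scale factor
#' returned invisibly.
#'
#' @param image a [CellImage-class].
#' @param path output TIFF path.
#' @export
writeCellImageTiff <- function(image, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF images")
  stopifnot(is(image, "CellImage"))
  sc <- max(image@fluor, 1e-12)
  tiff::writeTIFF(list(image@fluor / sc, pmin(image@mask, 1)), path,
                  bits.per.sample = 32L)
  invisible(sc)
}
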