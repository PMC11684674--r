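## The two-level staging model: six embryogenetic events (upper level)
## spanning seventeen stages (lower level), per-dataset stage boundaries,
## and duration statistics across datasets.

#' The two-level stage catalogue
#'
#' Seventeen stages (Arabic numerals) grouped into six consecutive
#' embryogenetic events (Roman numerals): (I) blastoderm formation,
#' stages 1-5; (II) early gastrulation, stages 6-7; (III) germband
#' elongation, stages 8-11; (IV) germband retraction, stage 12; (V)
#' dorsal closure, stages 13-15; (VI) muscular movement, stages 16-17.
#'
#' @return data.frame with columns `stage`, `event`, `eventName`.
#' @examples
#' stageCatalog()
#' @export
stageCatalog <- function() {
  events <- c(rep("I", 5), rep("II", 2), rep("III", 4), "IV",
              rep("V", 3), rep("VI", 2))
  names <- c(I = "blastoderm formation", II = "early gastrulation",
             III = "germband elongation", IV = "germband retraction",
             V = "dorsal closure", VI = "muscular movement")
  data.frame(stage = 1:17, event = events,
             eventName = unname(names[events]))
}

#' Event of a stage
#'
#' @param stage stage id(s) in 1-17.
#' @param catalog a stage catalogue (default [stageCatalog()]).
#' @return Event id(s) as Roman-numeral strings.
#' @examples
#' eventOf(12)   # "IV"
#' @export
eventOf <- function(stage, catalog = stageCatalog()) {
  if (any(!stage %in% catalog$stage))
    stop("stage out of range: stages run 1-17")
  catalog$event[match(stage, catalog$stage)]
}

.checkStagingTable <- function(table) {
  stopifnot(all(c("stage", "start_h", "end_h") %in% names(table)))
  table <- table[order(table$stage), ]
  if (!identical(as.integer(table$stage), 1:17))
    stop("staging table must contain exactly stages 1-17")
  if (any(table$end_h < table$start_h))
    stop("invalid boundaries: stage ", which(table$end_h < table$start_h)[1],
         " ends before it starts")
  gap <- which(abs(table$start_h[-1] - table$end_h[-17]) > 1e-9)
  if (length(gap))
    stop("invalid boundaries: stage ", gap[1], " -> ", gap[1] + 1,
         " boundary mismatch (end ", table$end_h[gap[1]], " vs start ",
         table$start_h[gap[1] + 1], ")")
  table
}

#' Per-stage durations of a staging table
#'
#' Absolute durations in hours or normalised durations (fraction of the
#' total development span, summing to exactly 1).
#'
#' @param table single-dataset staging table (columns stage, start_h,
#'   end_h).
#' @param normalized return normalised durations.
#' @return Named numeric vector of 17 durations.
#' @export
stageDurations <- function(table, normalized = FALSE) {
  table <- .checkStagingTable(table)
  d <- table$end_h - table$start_h
  if (normalized) d <- d / (table$end_h[17] - table$start_h[1])
  setNames(d, table$stage)
}

#' Aggregate staging tables across datasets
#'
#' Sample mean and standard deviation (n - 1) of the per-stage durations
#' and of the stage-boundary positions over a set of temporally aligned
#' datasets, in absolute hours and in normalised development time. The
#' boundary SDs localise the deviational peaks between datasets.
#'
#' @param tables data.frame with columns dataset, stage, start_h, end_h
#'   (as produced by [generateStageTables()] or [readStagingTable()]).
#' @return List with `stages` (stage, mean_h, sd_h, mean_norm, sd_norm)
#'   and `boundaries` (boundary 1-18 = start of stage 1 ... end of stage
#'   17, mean_h, sd_h, mean_norm, sd_norm).
#' @export
aggregateStaging <- function(tables) {
  split_ <- split(tables, tables$dataset)
  if (length(split_) < 2L) stop("at least two datasets are required")
  per <- lapply(split_, .checkStagingTable)
  durAbs <- vapply(per, function(t) t$end_h - t$start_h, numeric(17))
  durNorm <- vapply(per, function(t)
    (t$end_h - t$start_h) / (t$end_h[17] - t$start_h[1]), numeric(17))
  bAbs <- vapply(per, function(t) c(t$start_h, t$end_h[17]), numeric(18))
  bNorm <- vapply(per, function(t) {
    b <- c(t$start_h, t$end_h[17])
    (b - b[1]) / (b[18] - b[1])
  }, numeric(18))
  list(stages = data.frame(stage = 1:17,
                           mean_h = rowMeans(durAbs),
                           sd_h = apply(durAbs, 1, sd),
                           mean_norm = rowMeans(durNorm),
                           sd_norm = apply(durNorm, 1, sd)),
       boundaries = data.frame(boundary = 1:18,
                               mean_h = rowMeans(bAbs),
                               sd_h = apply(bAbs, 1, sd),
                               mean_norm = rowMeans(bNorm),
                               sd_norm = apply(bNorm, 1, sd)))
}

#' Stage and event containing a developmental time
#'
#' Stages own half-open intervals `[start, end)`, so every time inside
#' the development span maps to exactly one stage; the final boundary
#' (end of stage 17) is closed so that the full span is covered.
#'
#' @param t query time(s) in hours (or normalised units matching the
#'   table).
#' @param table single-dataset staging table.
#' @param catalog stage catalogue (default [stageCatalog()]).
#' @return data.frame: time, stage, event.
#' @export
classifyTime <- function(t, table, catalog = stageCatalog()) {
  table <- .checkStagingTable(table)
  b <- c(table$start_h, table$end_h[17])
  if (any(t < b[1] | t > b[18]))
    stop("time outside the table's development span [",
         b[1], ", ", b[18], "]")
  stage <- findInterval(t, b, rightmost.closed = TRUE)
  data.frame(time = t, stage = stage, event = eventOf(stage, catalog))
}
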