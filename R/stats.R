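#' Phase-state frequency summary over a dataset
#'
#' For each phase state appearing in any record: how many grid points
#' carry a strictly positive probability for it, and how many diagrams
#' (records) contain at least one such point. Because soft boundaries
#' give one point non-zero probability for several states, point counts
#' sum to at least the total number of points. States whose point count
#' falls below `floor` (as a fraction of all points, default 1%) are
#' flagged, not removed, mirroring the usual reporting cut.
#'
#' @param dataset A `phd_dataset`.
#' @param floor Reporting floor as a fraction of the total point count.
#' @return Data frame with columns `state`, `points`, `diagrams`,
#'   `under_floor`, sorted by decreasing point count; attribute
#'   `total_points` carries the dataset-wide point count. Empty dataset
#'   gives a zero-row table.
#' @export
state_frequencies <- function(dataset, floor = 0.01) {
  stopifnot(inherits(dataset, "phd_dataset"))
  empty <- data.frame(state = character(0), points = integer(0),
                      diagrams = integer(0), under_floor = logical(0))
  if (!length(dataset)) return(structure(empty, total_points = 0L))
  points <- integer(0)
  diagrams <- integer(0)
  total <- 0L
  for (rec in dataset) {
    tab <- phdat_table(rec)
    total <- total + nrow(tab)
    for (s in setdiff(names(tab), c("temperature", "composition"))) {
      k <- sum(tab[[s]] > 0)
      points[s] <- (if (is.na(points[s])) 0L else points[s]) + k
      if (k > 0)
        diagrams[s] <- (if (is.na(diagrams[s])) 0L else diagrams[s]) + 1L
    }
  }
  states <- names(points)
  out <- data.frame(state = states,
                    points = as.integer(points),
                    diagrams = as.integer(diagrams[states]),
                    stringsAsFactors = FALSE)
  out$diagrams[is.na(out$diagrams)] <- 0L
  out$under_floor <- out$points < floor * total
  out <- out[order(-out$points, out$state), ]
  rownames(out) <- NULL
  structure(out, total_points = total)
}
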