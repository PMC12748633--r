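#' Run the full digitization pipeline on one diagram
#'
#' Chains the stages: read and binarize the image, locate and rectify
#' the plot frame, apply manual edit primitives, keep the n largest line
#' components, thin, label regions, apply the curated region-to-state
#' mapping, sample the probability grid and assemble a PhDat record.
#' Deterministic for fixed inputs.
#'
#' @param config A list (or path to a JSON file) with entries:
#'   * `image`: path to the diagram image, or `mask`: an in-memory 0/1
#'     matrix (already binarized);
#'   * `t_data`, `w_data`: length-2 data ranges of the rectified frame's
#'     rows and columns (required); `t_log`, `w_log`: optional log flags;
#'   * `threshold` (binarization, default 0.5), `keep_n` (optional
#'     component filter), `edits` (list or JSON path, optional),
#'     `rectify` (default `TRUE`: detect the frame and rectify);
#'   * `region_states`: required named list/vector mapping region labels
#'     `"1"`..`"n"` to vocabulary states;
#'   * `grid`: optional `list(dt, dw, t_range, w_range)` (defaults: unit
#'     spacing over the calibrated ranges);
#'   * `kernel_threshold` (default `1e-3`), `weights` (default equal);
#'   * `meta`: fields for [phdat_record()] (`smiles`, `state`, `name`,
#'     `source`, `figure`, `method`, `type`, optional `purity`,
#'     `labels`);
#'   * `out`: optional path for the record JSON; `index`: record index
#'     used when writing (default `"1"`).
#' @param verbose Log per-stage counts to stderr.
#' @return The `phd_record`, invisibly when `out` is written; the
#'   labeled image, calibration and table are attached as attributes.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- jsonlite::fromJSON(config,
                                                         simplifyVector = FALSE)
  say <- function(...) if (verbose) message("phasedig: ", ...)
  if (!is.null(config$mask)) {
    mask <- check_mask(config$mask)
  } else if (!is.null(config$image)) {
    img <- read_diagram(config$image)
    mask <- binarize(img, config$threshold %||% 0.5)
  } else stop("config needs an 'image' path or a 'mask'")
  say("binary image ", nrow(mask), "x", ncol(mask), ", ",
      sum(mask), " boundary pixels")
  if (isTRUE(config$rectify %||% TRUE)) {
    quad <- find_plot_frame(mask)
    mask <- rectify(mask, quad)
    # the crop boundary is the frame: redraw it so sub-pixel placement
    # of the warped frame line cannot leave open slivers at the border
    mask <- overlay_curves(list(mask), nrow(mask), ncol(mask))
    say("rectified frame to ", nrow(mask), "x", ncol(mask))
  }
  cal <- axis_calibration(
    t_px = c(1, nrow(mask)), t_data = config$t_data %||%
      stop("config needs 't_data' (temperatures of the top/bottom rows)"),
    w_px = c(1, ncol(mask)), w_data = config$w_data %||%
      stop("config needs 'w_data' (compositions of the left/right cols)"),
    t_log = isTRUE(config$t_log), w_log = isTRUE(config$w_log))
  edits <- config$edits
  if (is.character(edits)) edits <- read_edits(edits)
  if (length(edits)) {
    mask <- apply_edits(mask, edits, cal)
    say("applied ", length(edits), " edit(s)")
  }
  if (!is.null(config$keep_n)) {
    mask <- keep_largest(mask, as.integer(config$keep_n))
    say("kept ", config$keep_n, " largest component(s)")
  }
  mask <- thin(mask)
  labeled <- label_regions(mask)
  n <- attr(labeled, "n")
  say("thinned; ", n, " phase region(s)")
  rs <- config$region_states
  if (is.null(rs)) stop("config needs the curated 'region_states' mapping")
  rs <- unlist(rs)
  missing <- setdiff(as.character(seq_len(n)), names(rs))
  if (length(missing))
    stop("region_states has no entry for region label(s): ",
         paste(missing, collapse = ", "),
         " (the image segmented into ", n, " regions)")
  states <- unname(rs[as.character(seq_len(n))])
  grid <- NULL
  if (!is.null(config$grid)) {
    g <- config$grid
    grid <- grid_spec(t_range = unlist(g$t_range) %||% sort(cal$temperature$data),
                      w_range = unlist(g$w_range) %||% sort(cal$composition$data),
                      dt = g$dt %||% 1, dw = g$dw %||% 1)
  }
  table <- sample_grid(labeled, cal, grid = grid, states = states,
                       threshold = config$kernel_threshold %||% 1e-3,
                       weights = unlist(config$weights) %||% c(1, 1))
  say("sampled ", nrow(table), " grid points")
  meta <- config$meta %||% stop("config needs record 'meta' fields")
  rec <- phdat_record(table, smiles = meta$smiles, state = meta$state,
                      name = meta$name, source = meta$source,
                      figure = meta$figure, method = meta$method,
                      type = meta$type, labels = meta$labels %||% list(),
                      purity = meta$purity)
  attr(rec, "labeled") <- labeled
  attr(rec, "calibration") <- cal
  attr(rec, "table") <- table
  if (!is.null(config$out)) {
    write_phdat(setNames(list(rec), as.character(config$index %||% "1")),
                config$out)
    say("wrote ", config$out)
    return(invisible(rec))
  }
  rec
}
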