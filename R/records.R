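#' Construct a PhDat record from metadata and a probability table
#'
#' A PhDat record holds one digitized source diagram: compound metadata
#' plus the gridded phase-state probabilities in columnar `keys`/`values`
#' layout. Probabilities are stored as percentages; the first two keys
#' are always temperature (degrees C) and composition (wt% surfactant).
#'
#' @param table A `phd_table` from [sample_grid()] (fractions), or any
#'   data frame with `temperature`, `composition` and per-state columns.
#' @param smiles SMILES string of the surfactant (stored verbatim; not
#'   assumed unique across records).
#' @param state `"complete"` or `"incomplete"` (some regions unknown);
#'   only incomplete diagrams may carry a `"U"` column.
#' @param name Compound name.
#' @param source Citation string for the source diagram.
#' @param figure Figure or page locator within the source.
#' @param method Measurement method code string; each letter must be one
#'   of A-F (A polarized optical microscopy, B X-ray, C proton NMR,
#'   D calorimetry, E other, F not available). Multi-letter codes such
#'   as `"AB"` are allowed.
#' @param type One of nonionic, anionic, cationic, zwitterionic, mixed.
#' @param labels Optional list of `c(original_label, dataset_label)`
#'   pairs recording the source-to-vocabulary mapping.
#' @param purity Optional free-text purity.
#' @param solvent Fixed to `"water"` in the published dataset.
#' @param fractions Are the table's probabilities fractions that must be
#'   converted to percentages (default `TRUE`)?
#' @param vocab Vocabulary used to check state columns.
#' @return An object of class `phd_record`.
#' @export
phdat_record <- function(table, smiles, state, name, source, figure,
                         method, type, labels = list(), purity = NULL,
                         solvent = "water", fractions = TRUE,
                         vocab = phase_vocabulary()) {
  mandatory <- list(smiles = smiles, state = state, name = name,
                    source = source, figure = figure, method = method,
                    type = type)
  for (f in names(mandatory))
    if (is.null(mandatory[[f]]) || !nzchar(as.character(mandatory[[f]])))
      stop("missing mandatory record field: ", f)
  if (!state %in% c("complete", "incomplete"))
    stop("state must be 'complete' or 'incomplete'")
  if (!type %in% c("nonionic", "anionic", "cationic", "zwitterionic",
                   "mixed"))
    stop("unknown compound type: ", type)
  if (!grepl("^[A-F]+$", method))
    stop("method must be a string of letters A-F")
  cols <- names(table)
  if (!all(c("temperature", "composition") %in% cols[1:2]))
    stop("table must start with temperature and composition columns")
  statecols <- setdiff(cols, c("temperature", "composition"))
  bad <- statecols[!is_valid_state(statecols, vocab)]
  if (length(bad))
    stop("table columns are not vocabulary-valid states: ",
         paste(bad, collapse = ", "))
  if ("U" %in% statecols && state == "complete")
    stop("a complete diagram must not carry a 'U' column")
  vals <- lapply(table, as.numeric)
  if (fractions)
    vals[statecols] <- lapply(vals[statecols], function(x) 100 * x)
  rec <- structure(
    list(smiles = as.character(smiles),
         state = state,
         name = as.character(name),
         source = as.character(source),
         figure = as.character(figure),
         purity = if (is.null(purity)) NULL else as.character(purity),
         method = method,
         type = type,
         solvent = solvent,
         labels = lapply(labels, function(p) as.character(unlist(p))),
         keys = c("temperature", "composition", statecols),
         values = unname(vals[c("temperature", "composition", statecols)])),
    class = "phd_record"
  )
  rec
}

#' @export
print.phd_record <- function(x, ...) {
  cat("PhDat record: ", x$name, " (", x$smiles, "), ", x$state, ", ",
      length(x$values[[1]]), " grid points, states: ",
      paste(setdiff(x$keys, c("temperature", "composition")),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.phd_dataset <- function(x, ...) {
  cat("PhDat dataset:", length(x), "record(s)\n")
  invisible(x)
}

record_to_json_list <- function(rec) {
  out <- list(smiles = jsonlite::unbox(rec$smiles),
              state = jsonlite::unbox(rec$state),
              name = jsonlite::unbox(rec$name),
              source = jsonlite::unbox(rec$source),
              figure = jsonlite::unbox(rec$figure))
  if (!is.null(rec$purity)) out$purity <- jsonlite::unbox(rec$purity)
  out$method <- jsonlite::unbox(rec$method)
  out$type <- jsonlite::unbox(rec$type)
  out$solvent <- jsonlite::unbox(rec$solvent)
  out$labels <- rec$labels
  out$keys <- rec$keys
  out$values <- rec$values
  out
}

#' Write records as PhDat JSON
#'
#' Serializes one record or a whole dataset in the published dialect: a
#' top-level object keyed by record index, each record a dictionary with
#' a fixed field order and columnar `keys`/`values` data. Numbers are
#' written at full precision, so write -> read -> write is byte-stable.
#'
#' @param x A `phd_record`, a `phd_dataset`, or a named list of records
#'   (names are the record indices; a single unnamed record gets index
#'   `"1"`).
#' @param path Output file; when `NULL` the JSON text is returned.
#' @return The JSON text (invisibly when written to a file).
#' @export
write_phdat <- function(x, path = NULL) {
  if (inherits(x, "phd_record")) x <- setNames(list(x), "1")
  if (!length(names(x)) || any(!nzchar(names(x))))
    stop("records must be named by their index")
  body <- lapply(x, record_to_json_list)
  txt <- jsonlite::toJSON(body, digits = NA, pretty = TRUE,
                          auto_unbox = FALSE, null = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path, useBytes = TRUE)
  invisible(txt)
}

parse_record <- function(raw, idx) {
  need <- c("smiles", "state", "name", "source", "figure", "method",
            "type", "solvent", "keys", "values")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("record ", idx, " is missing field(s): ",
         paste(missing, collapse = ", "))
  keys <- as.character(unlist(raw$keys))
  values <- lapply(raw$values, function(v) as.numeric(unlist(v)))
  if (length(values) != length(keys))
    stop("record ", idx, ": keys and values have different lengths")
  structure(
    list(smiles = as.character(raw$smiles),
         state = as.character(raw$state),
         name = as.character(raw$name),
         source = as.character(raw$source),
         figure = as.character(raw$figure),
         purity = if (is.null(raw$purity)) NULL
                  else as.character(raw$purity),
         method = as.character(raw$method),
         type = as.character(raw$type),
         solvent = as.character(raw$solvent),
         labels = lapply(raw$labels, function(p) as.character(unlist(p))),
         keys = keys,
         values = values),
    class = "phd_record"
  )
}

#' Read a PhDat JSON dataset
#'
#' Accepts the published map form (top-level object keyed by record
#' index) or a list form where each element carries an explicit `index`
#' field. Malformed records are collected into an error report (attached
#' as attribute `errors`) instead of aborting the load.
#'
#' @param x Path to a JSON file, or JSON text.
#' @return A `phd_dataset`: named list of `phd_record`s, with attribute
#'   `errors` (character vector, empty when everything parsed).
#' @export
read_phdat <- function(x) {
  raw <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  if (!is.list(raw))
    stop("PhDat format error: top level must be a record map or list")
  if (is.null(names(raw))) {
    idx <- vapply(raw, function(r) as.character(r$index %||% NA_character_),
                  "")
    if (anyNA(idx))
      stop("PhDat format error: list-form records need 'index' fields")
    names(raw) <- idx
    raw <- lapply(raw, function(r) r[setdiff(names(r), "index")])
  }
  if (anyDuplicated(names(raw)))
    stop("PhDat format error: duplicated record indices")
  records <- list()
  errors <- character(0)
  for (idx in names(raw)) {
    rec <- tryCatch(parse_record(raw[[idx]], idx), error = function(e)
      conditionMessage(e))
    if (is.character(rec)) errors <- c(errors, rec)
    else records[[idx]] <- rec
  }
  structure(records, class = "phd_dataset", errors = errors)
}

#' Extract a record's data as a wide data frame
#'
#' @param rec A `phd_record`.
#' @param percent Keep probabilities as percentages (default); otherwise
#'   convert to fractions.
#' @return Data frame with temperature, composition and one column per
#'   phase state.
#' @export
phdat_table <- function(rec, percent = TRUE) {
  stopifnot(inherits(rec, "phd_record"))
  out <- as.data.frame(setNames(rec$values, rec$keys),
                       check.names = FALSE, optional = TRUE)
  statecols <- setdiff(rec$keys, c("temperature", "composition"))
  if (!percent) out[statecols] <- out[statecols] / 100
  out
}

#' Validate a PhDat dataset against the record contract
#'
#' Checks each record for: compositions outside `[0, 100]` wt%,
#' probability rows not summing to 100% within `tol`, probabilities
#' outside `[0, 100]`, phase-state columns that are not
#' vocabulary-valid, `U` columns on complete diagrams, unequal value
#' lengths, bad method/type/state/solvent fields. Problems are report
#' rows, not errors; an empty report means the dataset is valid.
#'
#' @param dataset A `phd_dataset` (or single `phd_record`).
#' @param vocab Vocabulary for state-column checks.
#' @param tol Tolerance on the per-row percentage sum (percentage
#'   points).
#' @return Data frame with columns `record`, `check`, `message`; zero
#'   rows when valid. Parse errors from [read_phdat()] are included.
#' @export
validate_phdat <- function(dataset, vocab = phase_vocabulary(),
                           tol = 0.1) {
  if (inherits(dataset, "phd_record"))
    dataset <- structure(list("1" = dataset), class = "phd_dataset")
  rows <- list()
  flag <- function(record, check, message)
    rows[[length(rows) + 1L]] <<- data.frame(record = record,
                                             check = check,
                                             message = message)
  for (err in attr(dataset, "errors") %||% character(0))
    flag(NA_character_, "parse", err)
  for (idx in names(dataset)) {
    rec <- dataset[[idx]]
    lens <- lengths(rec$values)
    if (length(unique(lens)) > 1L) {
      flag(idx, "lengths", paste0("value lists have unequal lengths (",
                                  paste(unique(lens), collapse = ", "),
                                  ")"))
      next
    }
    if (!rec$state %in% c("complete", "incomplete"))
      flag(idx, "state", paste0("unknown diagram state '", rec$state, "'"))
    if (!grepl("^[A-F]+$", rec$method))
      flag(idx, "method", paste0("method '", rec$method,
                                 "' is not a string of letters A-F"))
    if (!rec$type %in% c("nonionic", "anionic", "cationic",
                         "zwitterionic", "mixed"))
      flag(idx, "type", paste0("unknown compound type '", rec$type, "'"))
    if (!identical(rec$solvent, "water"))
      flag(idx, "solvent", paste0("solvent is '", rec$solvent,
                                  "', expected 'water'"))
    statecols <- setdiff(rec$keys, c("temperature", "composition"))
    bad <- statecols[!is_valid_state(statecols, vocab)]
    for (b in bad)
      flag(idx, "label", paste0("unknown phase-state column '", b, "'"))
    if ("U" %in% statecols && identical(rec$state, "complete"))
      flag(idx, "unknown-phase",
           "complete diagram carries a 'U' column")
    tab <- phdat_table(rec)
    if (!"composition" %in% names(tab) || !"temperature" %in% names(tab)) {
      flag(idx, "keys", "missing temperature/composition keys")
      next
    }
    outw <- tab$composition < 0 | tab$composition > 100
    if (any(outw))
      flag(idx, "composition", paste0(sum(outw),
           " row(s) with composition outside [0, 100] wt%"))
    pm <- as.matrix(tab[statecols])
    if (length(pm)) {
      if (any(pm < 0 | pm > 100))
        flag(idx, "probability",
             "probabilities outside [0, 100] percent")
      ss <- rowSums(pm)
      nbad <- sum(abs(ss - 100) > tol)
      if (nbad > 0)
        flag(idx, "normalization", paste0(nbad,
             " row(s) do not sum to 100% within ", tol))
    }
  }
  if (!length(rows))
    return(data.frame(record = character(0), check = character(0),
                      message = character(0)))
  do.call(rbind, rows)
}

#' Filter a PhDat dataset by record-level fields
#'
#' Non-destructive record-level filtering; point-level filtering (ranges,
#' dropping unknown-phase points) is done by [phdat_points()].
#'
#' @param dataset A `phd_dataset`.
#' @param smiles,type,state Optional exact-match filters.
#' @return The filtered `phd_dataset`.
#' @export
query_phdat <- function(dataset, smiles = NULL, type = NULL,
                        state = NULL) {
  stopifnot(inherits(dataset, "phd_dataset"))
  keep <- rep(TRUE, length(dataset))
  field <- function(f) vapply(dataset, function(r) r[[f]], "")
  if (!is.null(smiles)) keep <- keep & field("smiles") %in% smiles
  if (!is.null(type)) keep <- keep & field("type") %in% type
  if (!is.null(state)) keep <- keep & field("state") %in% state
  structure(dataset[keep], class = "phd_dataset",
            errors = attr(dataset, "errors"))
}

#' Extract grid points from records, with point-level filters
#'
#' @param x A `phd_dataset` or single `phd_record`.
#' @param t_range,w_range Optional inclusive `[min, max]` filters on
#'   temperature (degrees C) and composition (wt%).
#' @param drop_u Remove points with a non-zero probability of the
#'   unknown state `U` (useful for incomplete diagrams).
#' @param tidy Return one row per (record, point, state) with a
#'   `probability` column; otherwise a wide table per record bound
#'   together (columns absent from a record are `NA`).
#' @return A data frame; tidy form has columns `record`, `temperature`,
#'   `composition`, `state`, `probability` (percent).
#' @export
phdat_points <- function(x, t_range = NULL, w_range = NULL,
                         drop_u = FALSE, tidy = FALSE) {
  recs <- if (inherits(x, "phd_record"))
    structure(list("1" = x), class = "phd_dataset") else x
  stopifnot(inherits(recs, "phd_dataset"))
  out <- list()
  for (idx in names(recs)) {
    tab <- phdat_table(recs[[idx]])
    if (!is.null(t_range))
      tab <- tab[tab$temperature >= t_range[1] &
                 tab$temperature <= t_range[2], , drop = FALSE]
    if (!is.null(w_range))
      tab <- tab[tab$composition >= w_range[1] &
                 tab$composition <= w_range[2], , drop = FALSE]
    if (drop_u && "U" %in% names(tab))
      tab <- tab[tab$U == 0, , drop = FALSE]
    if (!nrow(tab)) next
    if (tidy) {
      statecols <- setdiff(names(tab), c("temperature", "composition"))
      long <- do.call(rbind, lapply(statecols, function(s)
        data.frame(record = idx, temperature = tab$temperature,
                   composition = tab$composition, state = s,
                   probability = tab[[s]], stringsAsFactors = FALSE)))
      out[[idx]] <- long
    } else {
      out[[idx]] <- cbind(record = idx, tab, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(record = character(0), temperature = numeric(0),
                      composition = numeric(0)))
  common <- Reduce(union, lapply(out, names))
  out <- lapply(out, function(d) {
    d[setdiff(common, names(d))] <- NA
    d[common]
  })
  rows <- do.call(rbind, out)
  rownames(rows) <- NULL
  rows
}
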