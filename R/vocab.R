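#' Controlled vocabulary of phase-state labels
#'
#' A binary surfactant-water diagram is partitioned into regions that are
#' either a single phase (e.g. the micellar solution `L1`, the lamellar
#' mesophase `La`, hexagonal `H1`, solid hydrates `X1`, `X2`, ...) or a
#' two-phase coexistence region written as the two single-phase codes
#' joined by `"+"` in alphabetical order (e.g. `L1+W` for the cloud
#' region). The packaged vocabulary carries the single-phase label set
#' with descriptions and literature aliases, and the canonical list of
#' 118 observed phase states. The reserved label `"U"` marks unknown
#' regions of incomplete diagrams and is excluded from the canonical
#' state list.
#'
#' @param file Path to a vocabulary JSON file. Defaults to the packaged
#'   vocabulary. A custom file must carry `labels` (objects with `code`,
#'   `description`, `aliases`) and `states` (character array).
#' @return An object of class `phd_vocab`: a list with elements `labels`
#'   (data frame of `code`, `description`, `provisional`), `single_phase`
#'   (character vector of codes), `alias_map` (named character vector of
#'   normalized alias to code), `states` (canonical state strings) and
#'   `provenance` (free-text note on how the packaged list was derived).
#' @examples
#' v <- phase_vocabulary()
#' length(v$states)
#' @export
phase_vocabulary <- function(file = NULL) {
  if (is.null(file)) {
    if (!is.null(the$vocab)) return(the$vocab)
    file <- system.file("extdata", "phase_vocab.json", package = "phasedig",
                        mustWork = TRUE)
    the$vocab <- read_vocabulary_file(file)
    return(the$vocab)
  }
  read_vocabulary_file(file)
}

read_vocabulary_file <- function(file) {
  raw <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  labs <- data.frame(
    code = vapply(raw$labels, function(x) x$code, ""),
    description = vapply(raw$labels, function(x) x$description, ""),
    provisional = vapply(raw$labels, function(x) isTRUE(x$provisional), TRUE),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(labs$code))
    stop("vocabulary file contains duplicated label codes")
  alias_map <- character(0)
  for (x in raw$labels) {
    al <- unique(c(x$code, unlist(x$aliases)))
    alias_map[normalize_alias(al)] <- x$code
  }
  states <- unlist(raw$states)
  v <- structure(
    list(labels = labs,
         single_phase = labs$code,
         alias_map = alias_map,
         states = states,
         provenance = raw$provenance %||% ""),
    class = "phd_vocab"
  )
  check_vocabulary(v)
  v
}

check_vocabulary <- function(v) {
  used <- unique(unlist(strsplit(v$states, "+", fixed = TRUE)))
  missing <- setdiff(used, v$single_phase)
  if (length(missing))
    stop("canonical states use labels absent from the vocabulary: ",
         paste(missing, collapse = ", "))
  if (any(grepl("U", v$states, fixed = TRUE) &
          vapply(strsplit(v$states, "+", fixed = TRUE),
                 function(p) "U" %in% p, TRUE)))
    stop("the reserved label 'U' must not appear in canonical states")
  invisible(v)
}

#' @export
print.phd_vocab <- function(x, ...) {
  cat("Phase-state vocabulary:", nrow(x$labels), "single-phase labels,",
      length(x$states), "canonical states\n")
  invisible(x)
}

# Literature labels vary typographically (subscripts, case, Greek letters,
# dashes); normalization folds these before lookup.
normalize_alias <- function(x) {
  x <- trimws(x)
  x <- chartr("αβ", "ab", x)        # alpha, beta -> a, b
  x <- gsub("’|′|'", "", x)          # primes/apostrophes
  x <- gsub("[_\\-]", "", x)
  x <- gsub("\\s+", " ", x)
  tolower(x)
}

#' Canonicalize a phase state from its constituent labels
#'
#' States carry at most two single-phase labels; the canonical string
#' joins them with `"+"` in alphabetical order (case-insensitive, fixed
#' C-locale ordering), so `c("X1", "W")` and `c("W", "X1")` both yield
#' `"W+X1"`.
#'
#' @param labels Character vector of one or two vocabulary codes.
#' @param vocab A `phd_vocab`; defaults to the packaged vocabulary.
#' @return The canonical state string.
#' @examples
#' canonical_state(c("X1", "W"))
#' canonical_state("L1")
#' @export
canonical_state <- function(labels, vocab = phase_vocabulary()) {
  labels <- as.character(labels)
  if (length(labels) < 1L || length(labels) > 2L)
    stop("a phase state has one or two labels, got ", length(labels))
  valid <- c(vocab$single_phase, "U")
  unknown <- setdiff(labels, valid)
  if (length(unknown))
    stop("unknown phase label(s): ", paste(unknown, collapse = ", "))
  if (length(labels) == 2L && labels[1] == labels[2])
    stop("a two-phase state needs two distinct labels")
  ord <- order(tolower(labels), method = "radix")
  paste(labels[ord], collapse = "+")
}

#' Split a phase-state string into its labels
#'
#' @param state A state string such as `"L1+W"`.
#' @return Character vector of labels.
#' @export
parse_state <- function(state) {
  stopifnot(is.character(state), length(state) == 1L, nzchar(state))
  strsplit(state, "+", fixed = TRUE)[[1]]
}

#' Resolve a literature phase label to its vocabulary code
#'
#' Sources label the same phase in different ways (a lamellar region may
#' appear as `D`, `G` or `L_alpha`); resolution is case-, subscript- and
#' punctuation-insensitive. Unknown aliases return `NA_character_` rather
#' than a guess.
#'
#' @param lit_label Character vector of source labels.
#' @inheritParams canonical_state
#' @return Character vector of codes, `NA` where unmapped.
#' @examples
#' resolve_alias("L_α")
#' resolve_alias("Zebra")
#' @export
resolve_alias <- function(lit_label, vocab = phase_vocabulary()) {
  if (!is.character(lit_label)) stop("literature labels must be character")
  if (any(!nzchar(trimws(lit_label))))
    stop("empty literature label")
  out <- unname(vocab$alias_map[normalize_alias(lit_label)])
  out
}

#' Enumerate the canonical phase states
#'
#' Returns the packaged ordered list of observed one- and two-phase
#' states (the reserved unknown label `"U"` is excluded).
#'
#' @inheritParams canonical_state
#' @return Character vector of canonical state strings.
#' @examples
#' length(enumerate_states())
#' @export
enumerate_states <- function(vocab = phase_vocabulary()) {
  vocab$states
}

#' Check state strings against the vocabulary
#'
#' @param state Character vector of state strings.
#' @inheritParams canonical_state
#' @param allow_u Accept the reserved label `"U"` as a valid state.
#' @return Logical vector: is every label known and the arity at most two?
#' @export
is_valid_state <- function(state, vocab = phase_vocabulary(),
                           allow_u = TRUE) {
  valid <- vocab$single_phase
  if (allow_u) valid <- c(valid, "U")
  vapply(state, function(s) {
    p <- strsplit(s, "+", fixed = TRUE)[[1]]
    length(p) >= 1L && length(p) <= 2L && all(p %in% valid) &&
      !anyDuplicated(p)
  }, TRUE, USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
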