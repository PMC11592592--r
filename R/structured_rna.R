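# The canonical input record: an RNA sequence with its secondary structure
# in Vienna dot-bracket notation, plus an optional binary class label
# (1 = pre-miRNA). Structures are restricted to nested pairings with a
# single terminal loop (a stem-loop), which is what the bar-image encoding
# can represent.

#' Construct a structured RNA record
#'
#' @param id record identifier. Generator functions append planted
#'   structural metadata after a `|` separator; see [planted_meta()].
#' @param sequence RNA string over `A`, `C`, `G`, `U`
#' @param structure dot-bracket string of the same length
#' @param label optional binary class label (1 = pre-miRNA)
#' @return An object of class `structured_rna`.
#' @examples
#' structured_rna("toy", "GGGAAACCC", "(((...)))", label = 1L)
#' @export
structured_rna <- function(id, sequence, structure, label = NA_integer_) {
  sequence <- toupper(sequence)
  stopifnot(is.character(id), length(id) == 1L,
            nchar(sequence) == nchar(structure))
  if (grepl("[^ACGU]", sequence)) {
    stop("sequence must use the RNA alphabet {A,C,G,U}: ", id)
  }
  parse_pairs(structure)  # validates balance and nesting
  out <- list(id = id, sequence = sequence, structure = structure,
              label = as.integer(label))
  class(out) <- "structured_rna"
  out
}

#' @export
print.structured_rna <- function(x, ...) {
  cat(sprintf("<structured_rna> %s (%d nt, label=%s)\n%s\n%s\n",
              x$id, nchar(x$sequence),
              ifelse(is.na(x$label), "?", x$label),
              x$sequence, x$structure))
  invisible(x)
}

#' Parse a dot-bracket string into a base-pair table
#'
#' @param structure dot-bracket string (only `(`, `)` and `.`)
#' @return Integer matrix with columns `i`, `j` (1-based, i < j), one row
#'   per pair, ordered outermost first. Errors on unbalanced brackets.
#' @keywords internal
#' @export
parse_pairs <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  if (length(chars) && any(!chars %in% c("(", ")", "."))) {
    stop("structure may only contain '(', ')' and '.'")
  }
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j")))
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      stack <- c(stack, k)
    } else if (chars[k] == ")") {
      if (!length(stack)) stop("unbalanced structure: unmatched ')' at ", k)
      pairs <- rbind(pairs, c(stack[length(stack)], k))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced structure: unmatched '(' at ", stack[1])
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  pairs
}

# TRUE when the pairing is a single nested stem-loop (at most one hairpin
# loop, no multiloops); unpaired-only structures count as degenerate
# stem-loops.
is_single_stemloop <- function(structure) {
  pairs <- parse_pairs(structure)
  if (!nrow(pairs)) return(TRUE)
  all(diff(pairs[, 1L]) > 0 & diff(pairs[, 2L]) < 0)
}

#' Planted metadata recorded in a generated record's id
#'
#' Generator functions record the realized structural parameters (stem
#' length, loop length, pair fraction, bulges, mechanism) in the id string
#' so that feature-recovery tests can compare extracted features against
#' the planted truth.
#'
#' @param rna a `structured_rna`
#' @return Named list of planted values (possibly empty).
#' @export
planted_meta <- function(rna) {
  parts <- strsplit(rna$id, "|", fixed = TRUE)[[1]]
  if (length(parts) < 2L) return(list())
  kv <- strsplit(parts[-1L], "=", fixed = TRUE)
  out <- lapply(kv, function(p) {
    v <- suppressWarnings(as.numeric(p[2]))
    if (is.na(v)) p[2] else v
  })
  names(out) <- vapply(kv, `[`, "", 1L)
  out
}
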