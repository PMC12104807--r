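#' Construct a family-by-clade presence/absence matrix
#'
#' A `presence_matrix` records, for each gene family (rows) and each terminal
#' clade (columns), one of three states: `"present"`, `"absent"` or
#' `"uncertain"`. The `uncertain` state is first-class: it encodes families
#' observed in a clade but failing a positive criterion (here, opsins lacking
#' the conserved K296 lysine), so that alternative scoring scenarios can be
#' derived from a single source matrix with a policy switch rather than a
#' second hand-edited table.
#'
#' @param states character matrix with values in `c("present","absent","uncertain")`,
#'   rownames = family identifiers, colnames = clade identifiers. Both must be
#'   unique and non-empty.
#' @param notes optional character matrix of the same shape carrying free-text
#'   provenance per cell (e.g. `"lacks K296"`); `""` means no note.
#' @return object of class `presence_matrix` with elements `families`,
#'   `clades`, `states`, `notes`.
#' @export
presence_matrix <- function(states, notes = NULL) {
  if (!is.matrix(states) || !is.character(states))
    stop("`states` must be a character matrix")
  fams <- rownames(states)
  clades <- colnames(states)
  if (is.null(fams) || is.null(clades) || any(!nzchar(fams)) || any(!nzchar(clades)))
    stop("`states` must have non-empty row (family) and column (clade) names")
  if (anyDuplicated(fams))
    stop("duplicate family identifier: ", fams[duplicated(fams)][1L])
  if (anyDuplicated(clades))
    stop("duplicate clade identifier: ", clades[duplicated(clades)][1L])
  bad <- !states %in% c("present", "absent", "uncertain")
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid state %s at (%s, %s)",
                 dQuote(states[bad][1L]), fams[idx[1L]], clades[idx[2L]]))
  }
  if (is.null(notes)) {
    notes <- matrix("", nrow(states), ncol(states), dimnames = dimnames(states))
  } else {
    stopifnot(is.matrix(notes), identical(dim(notes), dim(states)))
    dimnames(notes) <- dimnames(states)
    notes[is.na(notes)] <- ""
  }
  structure(list(families = fams, clades = clades, states = states, notes = notes),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence_matrix: %d families x %d clades\n",
              length(x$families), length(x$clades)))
  sym <- matrix(c(present = "1", absent = "0", uncertain = "?")[x$states],
                nrow(x$states), dimnames = dimnames(x$states))
  print(sym, quote = FALSE)
  invisible(x)
}

state_tokens <- c(present = "1", absent = "0", uncertain = "?")

#' Read a presence/absence matrix from TSV
#'
#' Expected layout: a header row whose first field is `family` and remaining
#' fields are clade identifiers; each subsequent row names a family and gives
#' one cell token per clade, with `1` = present, `0` = absent, `?` = uncertain.
#' `read_matrix()` followed by [write_matrix()] round-trips byte-identically.
#'
#' @param path path to a tab-separated file.
#' @return a [presence_matrix()].
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("matrix file needs a header and at least one family row")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  clades <- header[-1L]
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  fams <- vapply(rows, `[[`, "", 1L)
  states <- matrix("absent", length(fams), length(clades),
                   dimnames = list(fams, clades))
  for (i in seq_along(rows)) {
    cells <- rows[[i]][-1L]
    if (length(cells) != length(clades))
      stop(sprintf("row %d (%s): expected %d cells, got %d",
                   i + 1L, fams[i], length(clades), length(cells)))
    ok <- cells %in% state_tokens
    if (any(!ok))
      stop(sprintf("unknown cell token %s at row %d, column %s",
                   dQuote(cells[!ok][1L]), i + 1L, clades[which(!ok)[1L]]))
    states[i, ] <- names(state_tokens)[match(cells, state_tokens)]
  }
  presence_matrix(states)
}

#' Write a presence/absence matrix as TSV
#'
#' Inverse of [read_matrix()]; cell notes are not serialized (the TSV dialect
#' carries states only).
#'
#' @param x a [presence_matrix()].
#' @param path output path.
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "presence_matrix"))
  header <- paste(c("family", x$clades), collapse = "\t")
  body <- vapply(seq_along(x$families), function(i) {
    paste(c(x$families[i], state_tokens[x$states[i, ]]), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Resolve uncertain cells under a scoring policy
#'
#' The primary analysis retains uncertain families as present (the
#' conservative reading of K296-less sequences); the alternative scenario
#' scores them absent. Returns a matrix whose cells are only
#' `present`/`absent`.
#'
#' @param x a [presence_matrix()].
#' @param uncertain one of `"present"` or `"absent"`: the state uncertain
#'   cells resolve to.
#' @return a [presence_matrix()] with no uncertain cells.
#' @export
apply_uncertain_policy <- function(x, uncertain = c("present", "absent")) {
  stopifnot(inherits(x, "presence_matrix"))
  uncertain <- match.arg(uncertain)
  st <- x$states
  st[st == "uncertain"] <- uncertain
  presence_matrix(st, x$notes)
}

count_state <- function(x, clade, state, families = NULL,
                        uncertain = c("present", "absent", "uncertain")) {
  stopifnot(inherits(x, "presence_matrix"))
  uncertain <- match.arg(uncertain)
  if (!clade %in% x$clades) stop("unknown clade: ", clade)
  if (is.null(families)) families <- x$families
  if (length(families) == 0L) return(0L)
  missing_f <- setdiff(families, x$families)
  if (length(missing_f)) stop("unknown family: ", missing_f[1L])
  st <- x$states[families, clade]
  if (uncertain != "uncertain") st[st == "uncertain"] <- uncertain
  sum(st == state)
}

#' Count families in a given state for one clade
#'
#' `count_present()` applies an uncertainty policy first (default: uncertain
#' counts as present, matching the primary scenario); `count_absent()` and
#' `count_uncertain()` are the companions. For every clade,
#' `count_present(..., uncertain = "uncertain") + count_absent(...) +
#' count_uncertain(...)` equals the number of families.
#'
#' @param x a [presence_matrix()].
#' @param clade a clade identifier present in `x`.
#' @param families optional subset of family identifiers (default: all).
#' @param uncertain policy for uncertain cells: counted as `"present"`
#'   (default), as `"absent"`, or kept as their own `"uncertain"` category.
#' @return a non-negative integer count.
#' @export
count_present <- function(x, clade, families = NULL,
                          uncertain = c("present", "absent", "uncertain")) {
  count_state(x, clade, "present", families, match.arg(uncertain))
}

#' @rdname count_present
#' @export
count_absent <- function(x, clade, families = NULL,
                         uncertain = c("uncertain", "present", "absent")) {
  count_state(x, clade, "absent", families, match.arg(uncertain))
}

#' @rdname count_present
#' @export
count_uncertain <- function(x, clade, families = NULL) {
  count_state(x, clade, "uncertain", families, "uncertain")
}

#' Cells at which two presence matrices differ
#'
#' @param a,b two [presence_matrix()] objects over identical families/clades.
#' @return data.frame with columns `family`, `clade`, `state_a`, `state_b`,
#'   one row per differing cell (zero rows when identical).
#' @export
matrix_diff <- function(a, b) {
  stopifnot(inherits(a, "presence_matrix"), inherits(b, "presence_matrix"))
  if (!identical(a$families, b$families) || !identical(a$clades, b$clades))
    stop("matrices must share family and clade sets")
  idx <- which(a$states != b$states, arr.ind = TRUE)
  data.frame(
    family = a$families[idx[, 1L]],
    clade = a$clades[idx[, 2L]],
    state_a = a$states[idx],
    state_b = b$states[idx],
    stringsAsFactors = FALSE
  )
}
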