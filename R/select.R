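#' Select atoms with a boolean expression grammar
#'
#' Resolves a selection expression against a structure and returns an
#' `AtomIndexSet`: sorted unique 1-based indices into the atom table plus
#' the expression that produced them. The same structure and expression
#' always yield the same index set.
#'
#' Grammar (case-sensitive keywords, whitespace-separated):
#' \itemize{
#'   \item `chain <id>` — chain identifier match (case-sensitive)
#'   \item `resid <a>-<b>` or `resid <a>` (several ranges may follow) —
#'     author residue numbers, inclusive
#'   \item `name <atom>` — atom name, e.g. `CA`, `OD1`
#'   \item `element <sym>` — element symbol, e.g. `C`, `N`
#'   \item `backbone` — atoms named N, CA, C, O
#'   \item `sidechain` — non-backbone heavy atoms; for residues without any
#'     (glycine) the C-alpha stands in
#'   \item `calpha` — heavy atoms named CA
#'   \item `protein` / `het` — ATOM vs HETATM records
#'   \item `and`, `or`, `not`, parentheses
#' }
#'
#' A syntactically valid expression matching no atoms returns an empty set
#' (not an error); a malformed expression raises a syntax error naming the
#' offending position.
#'
#' @param structure a `Structure`.
#' @param expression selection string.
#' @return an `AtomIndexSet`: list with `indices` (sorted unique integers)
#'   and `expression`.
#' @export
select_atoms <- function(structure, expression) {
  stopifnot(inherits(structure, "Structure"), is.character(expression),
            length(expression) == 1L)
  toks <- tokenize_selection(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- parse_or(st, structure)
  if (st$pos <= nrow(st$toks))
    sel_error(expression, st$toks$start[st$pos], "unexpected token '",
              st$toks$text[st$pos], "'")
  new_atom_index_set(which(mask), expression)
}

#' Construct an AtomIndexSet directly from indices
#' @param indices integer atom indices (1-based).
#' @param expression optional provenance string.
#' @return an `AtomIndexSet`.
#' @export
new_atom_index_set <- function(indices, expression = "<manual>") {
  structure(list(indices = sort(unique(as.integer(indices))),
                 expression = expression),
            class = "AtomIndexSet")
}

#' @export
print.AtomIndexSet <- function(x, ...) {
  cat("AtomIndexSet:", length(x$indices), "atoms  [", x$expression, "]\n")
  invisible(x)
}

# coerce AtomIndexSet or plain integer vector to indices, range-checked
as_indices <- function(x, structure) {
  idx <- if (inherits(x, "AtomIndexSet")) x$indices else as.integer(x)
  if (length(idx) && (min(idx) < 1L || max(idx) > n_atoms(structure)))
    stop("atom indices out of range [1, ", n_atoms(structure), "]")
  idx
}

sel_error <- function(expr, at, ...) {
  stop("selection syntax error at position ", at, " in \"", expr, "\": ",
       ..., call. = FALSE)
}

tokenize_selection <- function(expression) {
  m <- gregexpr("\\(|\\)|[^()[:space:]]+", expression)[[1]]
  if (m[1] == -1L) sel_error(expression, 1, "empty expression")
  text <- regmatches(expression, gregexpr("\\(|\\)|[^()[:space:]]+",
                                          expression))[[1]]
  data.frame(text = text, start = as.integer(m), stringsAsFactors = FALSE)
}

peek <- function(st) if (st$pos <= nrow(st$toks)) st$toks$text[st$pos] else NA_character_
advance <- function(st) { st$pos <- st$pos + 1L; invisible(NULL) }

parse_or <- function(st, s) {
  left <- parse_and(st, s)
  while (identical(peek(st), "or")) {
    advance(st)
    left <- left | parse_and(st, s)
  }
  left
}

parse_and <- function(st, s) {
  left <- parse_not(st, s)
  while (identical(peek(st), "and")) {
    advance(st)
    left <- left & parse_not(st, s)
  }
  left
}

parse_not <- function(st, s) {
  if (identical(peek(st), "not")) {
    advance(st)
    return(!parse_not(st, s))
  }
  parse_primary(st, s)
}

parse_primary <- function(st, s) {
  tok <- peek(st)
  expr <- paste(st$toks$text, collapse = " ")
  if (is.na(tok)) sel_error(expr, nchar(expr) + 1L, "unexpected end of expression")
  if (tok == "(") {
    advance(st)
    inner <- parse_or(st, s)
    if (!identical(peek(st), ")"))
      sel_error(expr, if (st$pos <= nrow(st$toks)) st$toks$start[st$pos]
                else nchar(expr) + 1L, "expected ')'")
    advance(st)
    return(inner)
  }
  a <- s$atoms
  pred_arg <- function() {
    advance(st)
    v <- peek(st)
    if (is.na(v) || v %in% c("and", "or", "not", "(", ")"))
      sel_error(expr, st$toks$start[st$pos - 1L], "'", tok, "' needs an argument")
    advance(st)
    v
  }
  switch(tok,
    chain = a$chain == pred_arg(),
    name = a$name == pred_arg(),
    element = a$element == pred_arg(),
    resid = parse_resid(st, s, expr),
    backbone = { advance(st); a$name %in% c("N", "CA", "C", "O") },
    calpha = { advance(st); a$name == "CA" & heavy_mask(s) },
    sidechain = { advance(st); sidechain_mask(s) },
    protein = { advance(st); !a$het },
    het = { advance(st); a$het },
    sel_error(expr, st$toks$start[st$pos], "unknown keyword '", tok, "'"))
}

parse_resid <- function(st, s, expr) {
  advance(st)
  rng <- "^[0-9]+(-[0-9]+)?(,[0-9]+(-[0-9]+)?)*$"
  got <- character(0)
  while (!is.na(peek(st)) && grepl(rng, peek(st))) {
    got <- c(got, strsplit(peek(st), ",", fixed = TRUE)[[1]])
    advance(st)
  }
  if (length(got) == 0L)
    sel_error(expr, st$toks$start[min(st$pos, nrow(st$toks))],
              "'resid' needs a number or range like 5-8")
  wanted <- unlist(lapply(got, function(g) {
    ab <- as.integer(strsplit(g, "-", fixed = TRUE)[[1]])
    if (length(ab) == 1L) ab else seq.int(ab[1], ab[2])
  }))
  s$atoms$resid %in% wanted
}

# non-backbone heavy atoms; CA stands in for residues with none (Gly)
sidechain_mask <- function(s) {
  hv <- heavy_mask(s)
  sc <- hv & !(s$atoms$name %in% BACKBONE_NAMES)
  key <- atom_residue_key(s)
  has_sc <- key %in% key[sc]
  sc | (hv & s$atoms$name == "CA" & !has_sc)
}
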