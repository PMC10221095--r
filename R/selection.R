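#' Atom selection expressions
#'
#' Resolves a small selection language against the atom table of an
#' [md_structure], returning the matching atom indices in file order
#' (deterministic and order-stable; selecting twice gives the same indices).
#'
#' Grammar:
#' \preformatted{
#'   expr   := term {"or" term}
#'   term   := factor {"and" factor}
#'   factor := "not" factor | "(" expr ")" | test
#'   test   := "all"
#'           | "name"    value[,value...]
#'           | "chain"   value[,value...]
#'           | "resname" value[,value...]
#'           | "elem"    value[,value...]
#'           | "resseq"  n | a-b  [,more]
#' }
#' so e.g. `"name CA and chain A"`, `"resseq 50-60 and chain B"` (a loop
#' residue window), `"not (chain A or chain B)"`.
#'
#' @param structure an [md_structure].
#' @param expression selection string.
#' @return integer vector of atom indices (possibly empty, with a warning).
#' @export
select_atoms <- function(structure, expression) {
  stopifnot(inherits(structure, "md_structure"))
  at <- structure$atoms
  toks <- .sel_tokenize(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L
  mask <- .sel_expr(st, at)
  if (st$pos <= length(st$toks)) {
    stop("select_atoms: unexpected token '", st$toks[st$pos], "' in '", expression, "'")
  }
  idx <- which(mask)
  if (length(idx) == 0L) warning("select_atoms: empty selection for '", expression, "'")
  idx
}

.sel_tokenize <- function(expression) {
  if (!is.character(expression) || length(expression) != 1L || !nzchar(trimws(expression)))
    stop("select_atoms: expression must be a non-empty string")
  s <- gsub("\\(", " ( ", expression)
  s <- gsub("\\)", " ) ", s)
  toks <- strsplit(trimws(s), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

.sel_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
.sel_next <- function(st) { t <- .sel_peek(st); st$pos <- st$pos + 1L; t }

.sel_expr <- function(st, at) {
  m <- .sel_term(st, at)
  while (!is.na(.sel_peek(st)) && tolower(.sel_peek(st)) == "or") {
    .sel_next(st)
    m <- m | .sel_term(st, at)
  }
  m
}

.sel_term <- function(st, at) {
  m <- .sel_factor(st, at)
  while (!is.na(.sel_peek(st)) && tolower(.sel_peek(st)) == "and") {
    .sel_next(st)
    m <- m & .sel_factor(st, at)
  }
  m
}

.sel_factor <- function(st, at) {
  t <- .sel_peek(st)
  if (is.na(t)) stop("select_atoms: unexpected end of expression")
  tl <- tolower(t)
  if (tl == "not") { .sel_next(st); return(!.sel_factor(st, at)) }
  if (t == "(") {
    .sel_next(st)
    m <- .sel_expr(st, at)
    if (!identical(.sel_next(st), ")")) stop("select_atoms: missing ')'")
    return(m)
  }
  .sel_test(st, at)
}

.sel_values <- function(st, keyword) {
  t <- .sel_next(st)
  if (is.na(t) || t %in% c("(", ")") || tolower(t) %in% c("and", "or", "not"))
    stop("select_atoms: keyword '", keyword, "' needs a value")
  strsplit(t, ",")[[1]]
}

.sel_test <- function(st, at) {
  kw <- tolower(.sel_next(st))
  switch(kw,
    all = rep(TRUE, nrow(at)),
    name = at$name %in% .sel_values(st, "name"),
    chain = {
      v <- .sel_values(st, "chain")
      unknown <- setdiff(v, unique(at$chain_id))
      if (length(unknown)) stop("select_atoms: unknown chain '", unknown[1], "'")
      at$chain_id %in% v
    },
    resname = {
      v <- toupper(.sel_values(st, "resname"))
      unknown <- setdiff(v, unique(toupper(at$res_name)))
      if (length(unknown)) stop("select_atoms: unknown residue name '", unknown[1], "'")
      toupper(at$res_name) %in% v
    },
    elem = toupper(at$element) %in% toupper(.sel_values(st, "elem")),
    resseq = {
      v <- .sel_values(st, "resseq")
      keep <- rep(FALSE, nrow(at))
      for (spec in v) {
        if (grepl("^-?[0-9]+--?[0-9]+$", spec)) {
          ab <- as.numeric(strsplit(sub("^(-?[0-9]+)-", "\\1 ", spec), " ")[[1]])
          keep <- keep | (at$res_seq >= ab[1] & at$res_seq <= ab[2])
        } else if (grepl("^-?[0-9]+$", spec)) {
          keep <- keep | at$res_seq == as.numeric(spec)
        } else stop("select_atoms: bad resseq token '", spec, "'")
      }
      keep
    },
    stop("select_atoms: unknown keyword '", kw, "'")
  )
}
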