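#' Atom selections
#'
#' Selections are written in a small declarative language and resolve to a
#' deterministic, order-preserving vector of atom indices on a structure.
#'
#' Grammar (case-insensitive keywords):
#' \preformatted{
#'   expr    := term { "or" term }
#'   term    := factor { "and" factor }
#'   factor  := "not" factor | "(" expr ")" | primary
#'   primary := "all" | "none" | "protein" | "nucleic" | "het"
#'            | "backbone" | "calpha"
#'            | "chain"   id[,id...]
#'            | "name"    name[,name...]
#'            | "resname" name[,name...]
#'            | "elem"    sym[,sym...]
#'            | "resid"   n | a:b [,...]
#' }
#' Examples: `"chain A and name CA"`, `"not (chain B or het)"`,
#' `"resid 5:8"`.
#'
#' @param structure A structure tibble.
#' @param selection A selection string (or an integer index vector, returned
#'   as-is after range checking).
#' @return Integer vector of atom indices, in structure order.
#' @export
select_atoms <- function(structure, selection) {
  if (is.numeric(selection)) {
    idx <- as.integer(selection)
    if (length(idx) > 0 && (min(idx) < 1 || max(idx) > nrow(structure))) {
      abort("selection indices out of range")
    }
    return(idx)
  }
  mask <- eval_selection(structure, selection)
  which(mask)
}

eval_selection <- function(structure, selection) {
  toks <- tokenize_selection(selection)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- parse_or(structure, st)
  if (st$pos <= length(st$toks)) {
    abort(paste0("trailing tokens in selection: ",
                 paste(st$toks[st$pos:length(st$toks)], collapse = " ")))
  }
  mask
}

tokenize_selection <- function(s) {
  if (!is.character(s) || length(s) != 1 || is.na(s) || !nzchar(trimws(s))) {
    abort("selection must be a non-empty string")
  }
  s <- gsub("\\(", " ( ", s)
  s <- gsub("\\)", " ) ", s)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks[nzchar(toks)]
}

peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
advance <- function(st) { t <- peek(st); st$pos <- st$pos + 1L; t }

parse_or <- function(structure, st) {
  m <- parse_and(structure, st)
  while (!is.na(peek(st)) && tolower(peek(st)) == "or") {
    advance(st)
    m <- m | parse_and(structure, st)
  }
  m
}

parse_and <- function(structure, st) {
  m <- parse_factor(structure, st)
  while (!is.na(peek(st)) && tolower(peek(st)) == "and") {
    advance(st)
    m <- m & parse_factor(structure, st)
  }
  m
}

parse_factor <- function(structure, st) {
  t <- peek(st)
  if (is.na(t)) abort("unexpected end of selection")
  if (tolower(t) == "not") {
    advance(st)
    return(!parse_factor(structure, st))
  }
  if (t == "(") {
    advance(st)
    m <- parse_or(structure, st)
    if (is.na(peek(st)) || peek(st) != ")") abort("unbalanced parenthesis")
    advance(st)
    return(m)
  }
  parse_primary(structure, st)
}

protein_backbone_names <- c("N", "CA", "C", "O")
nucleic_backbone_names <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'")

parse_primary <- function(structure, st) {
  kw <- tolower(advance(st))
  n <- nrow(structure)
  resnames_of <- function() unique(structure$resname)
  switch(
    kw,
    "all" = rep(TRUE, n),
    "none" = rep(FALSE, n),
    "het" = structure$het,
    "protein" = structure$resname %in% protein_resnames(),
    "nucleic" = structure$resname %in% nucleic_resnames(),
    "backbone" = structure$name %in% c(protein_backbone_names,
                                       nucleic_backbone_names),
    "calpha" = structure$name == "CA" & !structure$het,
    "chain" = {
      vals <- parse_value_list(st)
      m <- structure$chain %in% vals
      if (!any(m)) warn(paste0("selection matches no atoms: chain ",
                               paste(vals, collapse = ",")))
      m
    },
    "name" = structure$name %in% parse_value_list(st),
    "resname" = structure$resname %in% parse_value_list(st),
    "elem" = structure$element %in% toupper(parse_value_list(st)),
    "resid" = structure$resid %in% parse_resid_list(st),
    abort(paste0("unknown selection keyword: ", kw))
  )
}

parse_value_list <- function(st) {
  t <- advance(st)
  if (is.na(t)) abort("selection keyword needs an argument")
  strsplit(t, ",")[[1]]
}

parse_resid_list <- function(st) {
  parts <- parse_value_list(st)
  out <- integer(0)
  for (p in parts) {
    if (grepl(":", p, fixed = TRUE)) {
      ab <- as.integer(strsplit(p, ":", fixed = TRUE)[[1]])
      if (length(ab) != 2 || any(is.na(ab))) abort(paste0("bad resid range: ", p))
      out <- c(out, seq(ab[1], ab[2]))
    } else {
      v <- suppressWarnings(as.integer(p))
      if (is.na(v)) abort(paste0("bad resid: ", p))
      out <- c(out, v)
    }
  }
  out
}

protein_resnames <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
    "ALX")
}

nucleic_resnames <- function() {
  c("A", "U", "G", "C", "DA", "DT", "DG", "DC", "NUX")
}
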