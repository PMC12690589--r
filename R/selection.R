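#' Atom selection by expression
#'
#' Resolves a selection expression against the atom table of an ensemble and
#' returns the matching atom indices. The grammar is the familiar
#' trajectory-analysis selection mini-language:
#'
#' * keywords: `all`, `protein`, `backbone`
#' * fields: `name <values...>`, `resname <values...>`, `resid <values...>`
#'   (values may be single numbers or ranges `10-50` / `10:50`),
#'   `chain <values...>`, `segid <values...>`
#' * boolean combination: `and`, `or`, `not`, parentheses
#'
#' e.g. `"protein and name CA"`, `"resid 10-50 and not name O"`.
#'
#' Resolution is deterministic given the atom table; resolving the same
#' expression twice yields identical index lists.
#'
#' @param ensemble a [structure_ensemble()].
#' @param expression selection string (non-empty).
#' @return An object of class `atom_selection`: list with `expression` and
#'   `indices` (sorted unique 1-based atom indices).
#' @export
#' @examples
#' ref <- make_reference_peptide(5, atoms_per_residue = "backbone")
#' sel <- select_atoms(
#'   make_gaussian_ensemble(ref, sigma = 0, n_frames = 1, seed = 1),
#'   "name CA and resid 2-4")
#' sel$indices
select_atoms <- function(ensemble, expression) {
  if (!is.character(expression) || length(expression) != 1L ||
      !nzchar(trimws(expression))) {
    stop("selection expression must be a non-empty string", call. = FALSE)
  }
  mask <- eval_selection(expression, ensemble$atoms)
  idx <- which(mask)
  if (!length(idx)) {
    stop("selection '", expression, "' matches zero atoms", call. = FALSE)
  }
  structure(list(expression = expression, indices = as.integer(idx)),
            class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat("<atom_selection> '", x$expression, "' -> ", length(x$indices),
      " atom(s)\n", sep = "")
  invisible(x)
}

# coerce a user-facing selection argument (string or atom_selection) to
# an atom_selection resolved against `ensemble`
as_atom_selection <- function(ensemble, selection) {
  if (inherits(selection, "atom_selection")) {
    if (length(selection$indices) &&
        max(selection$indices) > n_atoms(ensemble)) {
      stop("selection indices exceed the ensemble atom count", call. = FALSE)
    }
    return(selection)
  }
  select_atoms(ensemble, selection)
}

## ---- selection grammar ----------------------------------------------------

SEL_KEYWORDS <- c("all", "protein", "backbone",
                  "name", "resname", "resid", "chain", "segid",
                  "and", "or", "not", "(", ")")

# residue names treated as protein (standard amino acids plus common
# force-field protonation/terminal variants)
PROTEIN_RESNAMES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HID", "HIE", "HIP", "HSD", "HSE", "HSP", "CYX", "CYM", "ASH", "GLH",
  "LYN", "MSE", "ACE", "NME", "NMA"
)

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

tokenize_selection <- function(expression) {
  padded <- gsub("\\)", " ) ", gsub("\\(", " ( ", expression))
  toks <- strsplit(trimws(padded), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

eval_selection <- function(expression, atoms) {
  toks <- tokenize_selection(expression)
  if (!length(toks)) {
    stop("selection expression must be a non-empty string", call. = FALSE)
  }
  state <- new.env(parent = emptyenv())
  state$toks <- toks
  state$pos <- 1L
  mask <- parse_or(state, atoms)
  if (state$pos <= length(state$toks)) {
    stop("selection syntax error: unexpected token '",
         state$toks[state$pos], "'", call. = FALSE)
  }
  mask
}

peek_tok <- function(state) {
  if (state$pos > length(state$toks)) NA_character_ else state$toks[state$pos]
}
take_tok <- function(state) {
  tok <- peek_tok(state)
  state$pos <- state$pos + 1L
  tok
}

parse_or <- function(state, atoms) {
  mask <- parse_and(state, atoms)
  while (identical(tolower(peek_tok(state)), "or")) {
    take_tok(state)
    mask <- mask | parse_and(state, atoms)
  }
  mask
}

parse_and <- function(state, atoms) {
  mask <- parse_not(state, atoms)
  while (identical(tolower(peek_tok(state)), "and")) {
    take_tok(state)
    mask <- mask & parse_not(state, atoms)
  }
  mask
}

parse_not <- function(state, atoms) {
  if (identical(tolower(peek_tok(state)), "not")) {
    take_tok(state)
    return(!parse_not(state, atoms))
  }
  parse_primary(state, atoms)
}

parse_primary <- function(state, atoms) {
  tok <- take_tok(state)
  if (is.na(tok)) {
    stop("selection syntax error: expression ends unexpectedly",
         call. = FALSE)
  }
  low <- tolower(tok)
  if (low == "(") {
    mask <- parse_or(state, atoms)
    closing <- take_tok(state)
    if (!identical(closing, ")")) {
      stop("selection syntax error: missing ')' (found '",
           ifelse(is.na(closing), "<end>", closing), "')", call. = FALSE)
    }
    return(mask)
  }
  n <- nrow(atoms)
  switch(low,
    all = rep(TRUE, n),
    protein = toupper(atoms$resname) %in% PROTEIN_RESNAMES,
    backbone = toupper(atoms$resname) %in% PROTEIN_RESNAMES &
      toupper(trimws(atoms$elety)) %in% BACKBONE_NAMES,
    name = match_field(state, toupper(trimws(atoms$elety)), "name"),
    resname = match_field(state, toupper(atoms$resname), "resname"),
    chain = match_field(state, as.character(atoms$chain), "chain"),
    segid = match_field(state, as.character(atoms$segid), "segid"),
    resid = match_resid(state, atoms$resid),
    stop("selection syntax error: unknown token '", tok, "'", call. = FALSE)
  )
}

# consume value tokens until the next keyword/paren/end
collect_values <- function(state, field) {
  vals <- character(0)
  repeat {
    tok <- peek_tok(state)
    if (is.na(tok) || tolower(tok) %in% SEL_KEYWORDS || tok %in% c("(", ")")) {
      break
    }
    vals <- c(vals, take_tok(state))
  }
  if (!length(vals)) {
    stop("selection syntax error: '", field, "' requires at least one value",
         call. = FALSE)
  }
  vals
}

match_field <- function(state, column, field) {
  vals <- collect_values(state, field)
  column %in% toupper(vals)
}

match_resid <- function(state, resid) {
  vals <- collect_values(state, "resid")
  mask <- rep(FALSE, length(resid))
  for (v in vals) {
    if (grepl("^-?[0-9]+$", v)) {
      mask <- mask | (resid == as.integer(v))
    } else if (grepl("^-?[0-9]+[-:][0-9]+$", v)) {
      parts <- strsplit(sub("([0-9])-([0-9])", "\\1:\\2", v), ":")[[1]]
      lo <- as.integer(parts[1]); hi <- as.integer(parts[2])
      if (is.na(lo) || is.na(hi) || lo > hi) {
        stop("selection syntax error: bad resid range '", v, "'",
             call. = FALSE)
      }
      mask <- mask | (resid >= lo & resid <= hi)
    } else {
      stop("selection syntax error: bad resid value '", v, "'",
           call. = FALSE)
    }
  }
  mask
}
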