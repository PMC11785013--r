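#' All-atom structures as tibbles
#'
#' A structure is a tibble with one row per atom and columns `serial`, `name`,
#' `element`, `resname`, `chain`, `resid`, `insert`, `x`, `y`, `z`,
#' `occupancy`, `b_factor` and `het`. Coordinates are in Angstrom. Atoms are
#' ordered by chain, then residue. Author (PDB-style) chain identifiers and
#' residue numbers are used throughout, so selections match what a molecular
#' viewer displays.
#'
#' @param atoms A data frame with at least `name`, `resname`, `chain`,
#'   `resid`, `x`, `y`, `z`. Missing optional columns are filled with
#'   defaults.
#' @param source Character label recording where the structure came from.
#' @param model Model number the coordinates were taken from.
#' @return A tibble of class `sbm_structure`.
#' @export
new_structure <- function(atoms, source = "memory", model = 1L) {
  req <- c("name", "resname", "chain", "resid", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0) {
    abort(paste0("structure is missing columns: ", paste(miss, collapse = ", ")))
  }
  atoms <- tibble::as_tibble(atoms)
  n <- nrow(atoms)
  fill <- function(col, default) {
    v <- if (col %in% names(atoms)) atoms[[col]] else rep(default, n)
    v[is.na(v)] <- default
    v
  }
  atoms$serial <- as.integer(fill("serial", NA)) # NA serials renumbered below
  if (anyNA(atoms$serial)) atoms$serial <- seq_len(n)
  if (!("element" %in% names(atoms))) atoms$element <- guess_element(atoms$name)
  atoms$element[is.na(atoms$element)] <- guess_element(atoms$name[is.na(atoms$element)])
  atoms$insert <- fill("insert", "")
  atoms$occupancy <- fill("occupancy", 1)
  atoms$b_factor <- fill("b_factor", 0)
  atoms$het <- fill("het", FALSE)
  atoms <- atoms[, c("serial", "name", "element", "resname", "chain", "resid",
                     "insert", "x", "y", "z", "occupancy", "b_factor", "het")]
  xyz <- coords(atoms)
  if (any(!is.finite(xyz))) abort("structure has non-finite coordinates")
  key <- paste(atoms$chain, atoms$resid, atoms$insert, atoms$name)
  if (anyDuplicated(key) > 0) {
    abort("duplicate (chain, residue, atom name) after altloc resolution")
  }
  attr(atoms, "source") <- source
  attr(atoms, "model") <- as.integer(model)
  class(atoms) <- c("sbm_structure", class(atoms))
  atoms
}

# Element symbol from an atom name: strip digits and primes, take the
# leading alphabetic run; two-letter elements only for common cases.
guess_element <- function(name) {
  nm <- gsub("[0-9'*\"]", "", trimws(name))
  first <- toupper(substr(nm, 1, 1))
  two <- toupper(substr(nm, 1, 2))
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CA") &
           nchar(nm) == 2 & nm == two, two, first)
}

#' Read an all-atom structure from PDB or mmCIF
#'
#' Parses the file with bio3d, keeps the requested model, strips hydrogens
#' and waters, and resolves alternate locations. Heteroatoms other than water
#' are retained and flagged in the `het` column.
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif` file.
#' @param model Model number to keep (default: first).
#' @param altloc_policy Either `"occupancy"` (keep the highest-occupancy
#'   altloc, ties broken in favour of altloc "A") or `"first"`.
#' @return An [new_structure()] tibble.
#' @export
read_structure <- function(path, model = 1L,
                           altloc_policy = c("occupancy", "first")) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    if (ext == "cif") bio3d::read.cif(path, multi = TRUE, rm.alt = FALSE)
    else suppressWarnings(bio3d::read.pdb(path, multi = TRUE,
                                          rm.alt = FALSE)),
    error = function(e) abort(paste0("could not parse structure file: ",
                                     conditionMessage(e)))
  )
  at <- pdb$atom
  n_models <- max(1L, nrow(pdb$xyz))
  if (model > n_models) {
    abort(paste0("model ", model, " not found (file has ", n_models, ")"))
  }
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  at$x <- xyz[, 1]
  at$y <- xyz[, 2]
  at$z <- xyz[, 3]

  elem <- at$elesy
  elem[is.na(elem) | elem == ""] <- guess_element(at$elety[is.na(elem) | elem == ""])
  elem <- toupper(trimws(elem))
  at$element <- elem

  keep <- at$element != "H" & !(at$resid %in% c("HOH", "WAT", "DOD"))
  at <- at[keep, , drop = FALSE]

  # altloc resolution
  at$row0 <- seq_len(nrow(at))
  alt <- trimws(ifelse(is.na(at$alt), "", at$alt))
  occ <- ifelse(is.na(at$o), 1, at$o)
  grp <- paste(at$chain, at$resno,
               trimws(ifelse(is.na(at$insert), "", at$insert)), at$elety)
  if (any(alt != "")) {
    ord <- if (altloc_policy == "occupancy") {
      order(-occ, alt != "A", alt, at$row0)
    } else {
      order(at$row0)
    }
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(grp[ord]), , drop = FALSE]
    at <- at[order(at$row0), , drop = FALSE]
  }

  new_structure(
    tibble::tibble(
      serial = seq_len(nrow(at)),
      name = trimws(at$elety),
      element = at$element,
      resname = trimws(at$resid),
      chain = ifelse(is.na(at$chain), "A", at$chain),
      resid = as.integer(at$resno),
      insert = trimws(ifelse(is.na(at$insert), "", at$insert)),
      x = at$x, y = at$y, z = at$z,
      occupancy = ifelse(is.na(at$o), 1, at$o),
      b_factor = ifelse(is.na(at$b), 0, at$b),
      het = at$type == "HETATM"
    ),
    source = path, model = model
  )
}

#' Write a structure to a PDB file
#'
#' Emits standard ATOM/HETATM records with coordinates to three decimals,
#' TER records between chains, and END. Serial numbers above 99,999 are
#' written in uppercase hexadecimal (the widefile convention), and the file
#' remains re-readable by [read_structure()].
#'
#' @param structure A structure tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(structure, path) {
  if (nrow(structure) == 0) abort("refusing to write an empty structure")
  s <- structure
  fmt_serial <- function(i) {
    ifelse(i <= 99999L, sprintf("%5d", i), sprintf("%5X", i))
  }
  fmt_name <- function(nm) {
    # names shorter than 4 chars start in column 14
    ifelse(nchar(nm) >= 4, substr(sprintf("%-4s", nm), 1, 4),
           sprintf(" %-3s", nm))
  }
  rec <- ifelse(s$het, "HETATM", "ATOM  ")
  lines <- sprintf(
    "%s%s %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, fmt_serial(s$serial), fmt_name(s$name), "",
    substr(s$resname, 1, 3), s$chain, s$resid,
    ifelse(s$insert == "", " ", s$insert),
    s$x, s$y, s$z, s$occupancy, s$b_factor, s$element
  )
  # TER after the last atom of each chain
  out <- character(0)
  chains <- s$chain
  for (ch in unique(chains)) {
    out <- c(out, lines[chains == ch], "TER")
  }
  out <- c(out, "END")
  con <- tryCatch(file(path, "w"), error = function(e)
    abort(paste0("cannot open for writing: ", path)))
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Write a trajectory as a multi-MODEL PDB file
#'
#' @param traj An `sbm_trajectory`.
#' @param structure The structure the trajectory topology refers to.
#' @param path Output path.
#' @param stride Keep every `stride`-th frame.
#' @return Invisibly, `path`.
#' @export
write_trajectory_pdb <- function(traj, structure, path, stride = 1L) {
  frames <- traj$frames
  idx <- seq(1, dim(frames)[1], by = stride)
  con <- file(path, "w")
  on.exit(close(con))
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  for (k in seq_along(idx)) {
    writeLines(sprintf("MODEL %8d", k), con)
    write_structure(set_coords(structure, frames[idx[k], , ]), tf)
    body <- readLines(tf)
    writeLines(body[body != "END"], con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @export
print.sbm_structure <- function(x, ...) {
  cat(sprintf("# An all-atom structure: %d atoms, %d residues, chains %s\n",
              nrow(x),
              nrow(unique(x[, c("chain", "resid", "insert")])),
              paste(unique(x$chain), collapse = ",")))
  NextMethod()
}
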