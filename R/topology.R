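#' Export a force field as plain-text topology + coordinates
#'
#' Writes a GROMACS-dialect topology (bracketed `[ section ]` blocks for
#' atoms, bonds, angles, impropers, planars, dihedrals, pairs, restraints,
#' exclusions and scales) and a gro-style coordinate file (positions in nm,
#' extended precision so the round trip is lossless). Contact `sigma`
#' values are the 0.96-scaled native distances.
#'
#' @param ff An `sbm_forcefield`.
#' @param path Basename for output; writes `<path>.top` and `<path>.gro`.
#' @return Invisibly, the two file paths.
#' @export
export_topology <- function(ff, path) {
  top <- paste0(path, ".top")
  gro <- paste0(path, ".gro")
  con <- file(top, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  num <- function(x) sprintf("%.12g", x)

  w("; structure-based model topology (sbmotion)")
  s <- ff$structure
  w("[ atoms ]")
  w("; index name resname chain resid insert het")
  for (i in seq_len(nrow(s))) {
    w("%d %s %s %s %d %s %d", i, s$name[i], s$resname[i], s$chain[i],
      s$resid[i], ifelse(s$insert[i] == "", ".", s$insert[i]),
      as.integer(s$het[i]))
  }
  w("[ bonds ]")
  for (q in seq_len(nrow(ff$bonds))) {
    w("%d %d %s %s", ff$bonds$i[q], ff$bonds$j[q], num(ff$bonds$r0[q]),
      num(ff$bonds$weight[q]))
  }
  w("[ angles ]")
  for (q in seq_len(nrow(ff$angles))) {
    w("%d %d %d %s %s", ff$angles$i[q], ff$angles$j[q], ff$angles$k[q],
      num(ff$angles$theta0[q]), num(ff$angles$weight[q]))
  }
  w("[ impropers ]")
  for (q in seq_len(nrow(ff$impropers))) {
    w("%d %d %d %d %s %s", ff$impropers$i[q], ff$impropers$j[q],
      ff$impropers$k[q], ff$impropers$l[q], num(ff$impropers$chi0[q]),
      num(ff$impropers$weight[q]))
  }
  w("[ planars ]")
  for (q in seq_len(nrow(ff$planars))) {
    w("%d %d %d %d %s", ff$planars$i[q], ff$planars$j[q], ff$planars$k[q],
      ff$planars$l[q], num(ff$planars$weight[q]))
  }
  w("[ dihedrals ]")
  for (q in seq_len(nrow(ff$dihedrals))) {
    w("%d %d %d %d %s %s %s", ff$dihedrals$i[q], ff$dihedrals$j[q],
      ff$dihedrals$k[q], ff$dihedrals$l[q], num(ff$dihedrals$phi0[q]),
      num(ff$dihedrals$weight[q]), ff$dihedrals$class[q])
  }
  w("[ pairs ]")
  for (q in seq_len(nrow(ff$contacts))) {
    w("%d %d %s %s %s", ff$contacts$i[q], ff$contacts$j[q],
      num(ff$contacts$sigma[q]), num(ff$contacts$weight[q]),
      num(ff$contacts$r0[q]))
  }
  w("[ restraints ]")
  for (q in seq_len(nrow(ff$restraints))) {
    w("%d %d %s %s", ff$restraints$i[q], ff$restraints$j[q],
      num(ff$restraints$r_min[q]), num(ff$restraints$k[q]))
  }
  w("[ exclusions ]")
  for (q in seq_len(nrow(ff$exclusions))) {
    w("%d %d", ff$exclusions[q, 1], ff$exclusions[q, 2])
  }
  w("[ scales ]")
  for (nm in names(ff$scales)) w("%s %s", nm, num(ff$scales[[nm]]))

  # gro-style coordinates, nm, extended precision
  gcon <- file(gro, "w")
  on.exit(close(gcon), add = TRUE)
  writeLines("sbmotion coordinates (nm, extended precision)", gcon)
  writeLines(sprintf("%d", nrow(s)), gcon)
  writeLines(sprintf("%5d%-5s%5s%5d %15.9f %15.9f %15.9f",
                     s$resid %% 100000L, substr(s$resname, 1, 5),
                     substr(s$name, 1, 5), s$serial %% 100000L,
                     s$x / 10, s$y / 10, s$z / 10), gcon)
  writeLines("  0.0  0.0  0.0", gcon)
  invisible(c(top, gro))
}

#' Import a force field written by [export_topology()]
#'
#' @param path Basename used at export time.
#' @return An `sbm_forcefield`.
#' @export
import_topology <- function(path) {
  top <- paste0(path, ".top")
  gro <- paste0(path, ".gro")
  if (!file.exists(top) || !file.exists(gro)) {
    abort("topology files not found")
  }
  lines <- readLines(top)
  lines <- lines[!grepl("^;", lines) & nzchar(trimws(lines))]
  sec_at <- grep("^\\[", lines)
  sec_names <- gsub("[][ ]", "", lines[sec_at])
  blocks <- list()
  for (q in seq_along(sec_at)) {
    from <- sec_at[q] + 1
    to <- if (q < length(sec_at)) sec_at[q + 1] - 1 else length(lines)
    blocks[[sec_names[q]]] <- if (from <= to) lines[from:to] else character(0)
  }
  split_cols <- function(v) {
    if (length(v) == 0) return(list())
    do.call(rbind, strsplit(trimws(v), "\\s+"))
  }

  g <- readLines(gro)
  n <- as.integer(g[2])
  gl <- g[3:(2 + n)]
  xyz <- matrix(as.numeric(c(substr(gl, 21, 36), substr(gl, 37, 52),
                             substr(gl, 53, 68))), ncol = 3) * 10

  am <- split_cols(blocks$atoms)
  structure_tbl <- new_structure(tibble::tibble(
    name = am[, 2], resname = am[, 3], chain = am[, 4],
    resid = as.integer(am[, 5]),
    insert = ifelse(am[, 6] == ".", "", am[, 6]),
    het = am[, 7] == "1",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  ), source = top)

  tb <- function(block, cols, types) {
    m <- split_cols(blocks[[block]])
    if (length(m) == 0) {
      out <- lapply(types, function(t) vector(t, 0))
      names(out) <- cols
      return(tibble::as_tibble(out))
    }
    out <- purrr::map2(seq_along(cols), types, function(q, t) {
      v <- m[, q]
      if (t == "integer") as.integer(v)
      else if (t == "numeric") as.numeric(v)
      else v
    })
    names(out) <- cols
    tibble::as_tibble(out)
  }
  scl <- split_cols(blocks$scales)
  scales <- as.list(as.numeric(scl[, 2]))
  names(scales) <- scl[, 1]
  exm <- split_cols(blocks$exclusions)
  exclusions <- if (length(exm) == 0) {
    matrix(integer(0), 0, 2)
  } else {
    matrix(as.integer(exm), ncol = 2)
  }

  ff <- list(
    structure = structure_tbl,
    bonds = tb("bonds", c("i", "j", "r0", "weight"),
               c("integer", "integer", "numeric", "numeric")),
    angles = tb("angles", c("i", "j", "k", "theta0", "weight"),
                c("integer", "integer", "integer", "numeric", "numeric")),
    impropers = tb("impropers", c("i", "j", "k", "l", "chi0", "weight"),
                   c("integer", "integer", "integer", "integer", "numeric",
                     "numeric")),
    planars = tb("planars", c("i", "j", "k", "l", "weight"),
                 c("integer", "integer", "integer", "integer", "numeric")),
    dihedrals = tb("dihedrals",
                   c("i", "j", "k", "l", "phi0", "weight", "class"),
                   c("integer", "integer", "integer", "integer", "numeric",
                     "numeric", "character")),
    contacts = tb("pairs", c("i", "j", "sigma", "weight", "r0"),
                  c("integer", "integer", "numeric", "numeric", "numeric")),
    restraints = tb("restraints", c("i", "j", "r_min", "k"),
                    c("integer", "integer", "numeric", "numeric")),
    exclusions = exclusions,
    scales = scales,
    log = list(imported_from = top)
  )
  ff$provenance <- list(source = top, n_atoms = n,
                        hash = content_hash(list(ff$bonds$r0,
                                                 ff$angles$theta0,
                                                 ff$dihedrals$phi0,
                                                 ff$contacts$r0, n)))
  class(ff) <- "sbm_forcefield"
  ff
}
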