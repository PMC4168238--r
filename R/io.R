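## Readers/writers for XYZ (plain and multi-frame) and PDB (ATOM/HETATM +
## CONECT).  PDB coordinate records are parsed with bio3d; CONECT records,
## which bio3d does not expose, are scanned here.

#' Read a molecular structure
#'
#' @param path Path to an existing file.
#' @param format `"xyz"` or `"pdb"`; guessed from the file extension when
#'   missing.
#' @param infer_bonds_if_missing Infer bonds by covalent-radius cutoff when
#'   the file carries no connectivity (default `TRUE`).
#' @param bond_scale Cutoff multiplier passed to [infer_bonds()].
#' @return A [molecule()].
#' @export
read_structure <- function(path, format = c("auto", "xyz", "pdb"),
                           infer_bonds_if_missing = TRUE, bond_scale = 1.3) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xyz = "xyz", pdb = "pdb",
                     stop("cannot guess format from extension '", ext,
                          "'; pass format explicitly"))
  }
  mol <- switch(format, xyz = read_xyz_frames(path, first_only = TRUE)[[1]],
                pdb = read_pdb_molecule(path))
  if (infer_bonds_if_missing && nrow(mol$bonds) == 0 && n_atoms(mol) > 1)
    mol <- infer_bonds(mol, scale = bond_scale)
  mol
}

#' Write a molecular structure
#'
#' XYZ files carry elements and coordinates; PDB files additionally carry
#' the bond list as CONECT records.
#'
#' @param mol A [molecule()].
#' @param path Output path.
#' @param format `"xyz"` or `"pdb"`; guessed from the extension when
#'   missing.
#' @param comment Comment line for XYZ output.
#' @return Invisibly `path`.
#' @export
write_structure <- function(mol, path, format = c("auto", "xyz", "pdb"),
                            comment = "written by egopull") {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xyz = "xyz", pdb = "pdb",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  switch(format,
         xyz = write_xyz_frames(list(mol), path, comments = comment),
         pdb = write_pdb_molecule(mol, path))
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' @param path Path to a (possibly multi-frame) XYZ file.
#' @return List of [molecule()]s, one per frame (no bonds inferred).
#' @export
read_trajectory <- function(path) read_xyz_frames(path, first_only = FALSE)

#' Write a trajectory as multi-frame XYZ
#'
#' @param frames List of [molecule()]s (or a single molecule).
#' @param path Output path.
#' @param comments Character vector of per-frame comment lines (recycled).
#' @return Invisibly `path`.
#' @export
write_trajectory <- function(frames, path, comments = "frame") {
  if (inherits(frames, "molecule")) frames <- list(frames)
  write_xyz_frames(frames, path, comments = comments)
}

read_xyz_frames <- function(path, first_only = FALSE) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  ln <- 1L
  while (ln <= length(lines)) {
    if (!nzchar(trimws(lines[ln])) && ln == length(lines)) break
    nat <- suppressWarnings(as.integer(trimws(lines[ln])))
    if (is.na(nat) || nat < 1)
      stop(sprintf("XYZ parse error at line %d: expected atom count, got '%s'",
                   ln, lines[ln]))
    if (ln + 1L + nat > length(lines))
      stop(sprintf(paste0("XYZ parse error: frame starting at line %d declares",
                          " %d atoms but the file ends early"), ln, nat))
    body <- lines[(ln + 2L):(ln + 1L + nat)]
    toks <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(toks, length, 0L) < 4)
    if (length(bad))
      stop(sprintf("XYZ parse error at line %d: need 'element x y z'",
                   ln + 1L + bad[1]))
    el <- vapply(toks, `[[`, "", 1)
    xyz <- t(vapply(toks, function(t) {
      v <- suppressWarnings(as.numeric(t[2:4]))
      v
    }, numeric(3)))
    if (anyNA(xyz)) {
      bad <- which(apply(is.na(xyz), 1, any))[1]
      stop(sprintf("XYZ parse error at line %d: non-numeric coordinate",
                   ln + 1L + bad))
    }
    frames[[length(frames) + 1L]] <- molecule(el, xyz)
    ln <- ln + 2L + nat
    while (ln <= length(lines) && !nzchar(trimws(lines[ln]))) ln <- ln + 1L
    if (first_only) break
  }
  if (!length(frames)) stop("XYZ parse error: no frames in ", path)
  frames
}

write_xyz_frames <- function(frames, path, comments = "frame") {
  comments <- rep_len(comments, length(frames))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    mol <- frames[[k]]
    writeLines(as.character(n_atoms(mol)), con)
    writeLines(comments[k], con)
    writeLines(sprintf("%-3s %14.8f %14.8f %14.8f", mol$elements,
                       mol$coords[, 1], mol$coords[, 2], mol$coords[, 3]),
               con)
  }
  invisible(path)
}

read_pdb_molecule <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("PDB parse error in ", path, ": ",
                                           conditionMessage(e)))
  el <- trimws(pdb$atom$elesy)
  if (any(!nzchar(el) | is.na(el))) {
    # fall back to the first letter of the atom name
    nm <- gsub("[^A-Za-z].*", "", trimws(pdb$atom$elety))
    el <- ifelse(!nzchar(el) | is.na(el), substr(nm, 1, 1), el)
  }
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 99)))
  xyz <- cbind(pdb$atom$x, pdb$atom$y, pdb$atom$z)
  serial <- pdb$atom$eleno
  bonds <- read_pdb_conect(path, serial)
  molecule(el, xyz, bonds = bonds)
}

# CONECT records: columns of atom serial numbers; map serials back to row
# indices of the ATOM/HETATM table.
read_pdb_conect <- function(path, serial) {
  lines <- grep("^CONECT", readLines(path, warn = FALSE), value = TRUE)
  if (!length(lines)) return(NULL)
  pairs <- list()
  for (l in lines) {
    f <- suppressWarnings(as.integer(strsplit(trimws(sub("^CONECT", "", l)),
                                              "\\s+")[[1]]))
    f <- f[!is.na(f)]
    if (length(f) < 2) next
    for (p in f[-1]) pairs[[length(pairs) + 1L]] <- c(f[1], p)
  }
  if (!length(pairs)) return(NULL)
  m <- do.call(rbind, pairs)
  i <- match(m[, 1], serial); j <- match(m[, 2], serial)
  ok <- !is.na(i) & !is.na(j) & i != j
  if (!any(ok)) return(NULL)
  b <- unique(data.frame(i = pmin(i[ok], j[ok]), j = pmax(i[ok], j[ok])))
  b$order <- 1
  b
}

write_pdb_molecule <- function(mol, path) {
  n <- n_atoms(mol)
  elety <- paste0(mol$elements, seq_len(n))
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(mol$coords)),
                   type = rep("HETATM", n),
                   resno = rep(1L, n), resid = rep("LIG", n),
                   eleno = seq_len(n), elety = elety,
                   chain = rep("A", n), elesy = mol$elements,
                   end = FALSE, verbose = FALSE)
  if (nrow(mol$bonds)) {
    nb <- split(c(mol$bonds$j, mol$bonds$i), c(mol$bonds$i, mol$bonds$j))
    con <- file(path, "a")
    on.exit(close(con))
    for (a in sort(as.integer(names(nb)))) {
      ns <- sort(nb[[as.character(a)]])
      for (chunk in split(ns, ceiling(seq_along(ns) / 4))) {
        writeLines(sprintf("CONECT%5d%s", a,
                           paste0(sprintf("%5d", chunk), collapse = "")), con)
      }
    }
    writeLines("END", con)
  } else {
    cat("END\n", file = path, append = TRUE)
  }
  invisible(path)
}
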