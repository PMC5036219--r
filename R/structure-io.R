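# PDB coordinate handling. Parsing is delegated to bio3d's PDB reader;
# the package's own container keeps one row per atom with altloc
# filtering (highest occupancy wins, ties resolved to 'A') and waters
# excluded by default.

#' Construct a structure model from an atom table
#'
#' @param atoms Data frame with columns `serial`, `name`, `element`,
#'   `resname`, `resno`, `insert`, `chain`, `x`, `y`, `z`, `occupancy`,
#'   `altloc`.
#' @return A `structure_model` object; `$atoms` is the atom table,
#'   `$sequence` the per-chain one-letter sequence (from CA atoms).
#' @export
structure_model <- function(atoms) {
  need <- c("serial", "name", "element", "resname", "resno", "insert",
            "chain", "x", "y", "z", "occupancy", "altloc")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) .stop2("atom table lacks column(s): ",
                           paste(miss, collapse = ", "))
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    .stop2("non-finite coordinates")
  atoms <- .filter_altloc(atoms)
  ca <- atoms[atoms$name == "CA", ]
  seqs <- if (nrow(ca)) {
    split_ca <- split(ca, ca$chain)
    vapply(split_ca, function(d) {
      d <- d[order(d$resno), ]
      paste(.aa3to1(d$resname), collapse = "")
    }, character(1))
  } else character(0)
  structure(list(atoms = atoms, sequence = seqs), class = "structure_model")
}

# keep at most one altloc per (chain, resno, insert, name):
# highest occupancy, ties to 'A' (then first)
.filter_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name, sep = "|")
  if (!anyDuplicated(key)) return(atoms)
  pick <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(i) {
    if (length(i) == 1L) return(i)
    occ <- atoms$occupancy[i]
    best <- i[occ == max(occ)]
    if (length(best) > 1L) {
      a <- best[atoms$altloc[best] == "A"]
      best <- if (length(a)) a[1L] else best[1L]
    }
    best
  }), use.names = FALSE)
  out <- atoms[sort(pick), ]
  rownames(out) <- NULL
  out
}

.AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
          GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
          LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
          SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.aa3to1 <- function(res) {
  out <- .AA3[toupper(res)]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records, keeps the highest-occupancy alternate
#' location per atom, and excludes waters by default.
#'
#' @param path PDB file path.
#' @param keep_waters Keep HOH/WAT residues (default FALSE).
#' @return A `structure_model`.
#' @export
read_structure <- function(path, keep_waters = FALSE) {
  if (!file.exists(path)) .stop2("file not found: ", path)
  # pre-scan coordinate records so a malformed line is reported by number
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) .stop2("no ATOM/HETATM records in ", path)
  bad <- which(rec)[vapply(which(rec), function(i) {
    l <- lines[i]
    nchar(l) < 54 ||
      anyNA(suppressWarnings(as.numeric(c(substr(l, 31, 38),
                                          substr(l, 39, 46),
                                          substr(l, 47, 54)))))
  }, logical(1))]
  if (length(bad))
    .stop2("unparseable coordinate line ", bad[1L], ": ",
           substr(lines[bad[1L]], 1, 30), "...")
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  if (!keep_waters) a <- a[!a$resid %in% c("HOH", "WAT", "DOD"), ]
  if (nrow(a) == 0L) .stop2("no atoms left after filtering")
  elem <- a$elesy
  fix <- which(is.na(elem) | elem == "")
  if (length(fix)) elem[fix] <- substr(gsub("[0-9]", "", a$elety[fix]), 1, 1)
  atoms <- data.frame(serial = a$eleno, name = a$elety, element = elem,
                      resname = a$resid, resno = a$resno,
                      insert = ifelse(is.na(a$insert), "", a$insert),
                      chain = ifelse(is.na(a$chain), "A", a$chain),
                      x = a$x, y = a$y, z = a$z,
                      occupancy = ifelse(is.na(a$o), 1, a$o),
                      altloc = ifelse(is.na(a$alt), "", a$alt),
                      stringsAsFactors = FALSE)
  structure_model(atoms)
}

#' Write a structure model as a PDB file
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  # PDB atom-name column convention: names of <4 chars start in col 14
  nm <- ifelse(nchar(a$name) >= 4, a$name, sprintf(" %-3s", a$name))
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial %% 100000, nm, substr(a$altloc, 1, 1), a$resname, a$chain,
    a$resno %% 10000, substr(a$insert, 1, 1), a$x, a$y, a$z,
    a$occupancy, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' @export
print.structure_model <- function(x, ...) {
  cat("Structure model: ", nrow(x$atoms), " atoms, ",
      length(unique(paste(x$atoms$chain, x$atoms$resno, x$atoms$insert))),
      " residues, chain(s) ",
      paste(unique(x$atoms$chain), collapse = ","), "\n", sep = "")
  invisible(x)
}
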