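# Minimal wwPDB v3.3 coordinate-file reader/writer: ATOM/HETATM/TER/MODEL/
# ENDMDL records, fixed columns, first model only.  mmCIF is out of scope.

AA3_TO_1 <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
  HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
  PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
  TRP = "W", TYR = "Y",
  MSE = "M",  # selenomethionine, routinely deposited as HETATM
  UNK = "X")

AA1_TO_3 <- c(
  A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
  H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
  P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
  W = "TRP", Y = "TYR", X = "UNK")

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Parse a PDB coordinate file
#'
#' Reads ATOM and HETATM records from a PDB-format file (wwPDB v3.3 fixed
#' columns).  Only the first MODEL of multi-model files is kept.  Alternate
#' locations other than `' '` and `'A'` are dropped.
#'
#' @param path path to a PDB file (or a character vector of lines via `text`).
#' @param pdb_code 4-character structure identifier; defaults to the HEADER
#'   record id code, falling back to the first 4 characters of the file name.
#' @param text optional character vector of PDB lines, used instead of `path`.
#' @return An object of class `pdb_structure`: a list with `pdb_code`,
#'   `source` and `atoms` (a data frame with one row per kept atom record).
#' @export
parse_pdb <- function(path = NULL, pdb_code = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(path) || !file.exists(path))
      fp_data_error("PDB file not found: %s", if (is.null(path)) "<NULL>" else path)
    text <- readLines(path, warn = FALSE)
  }
  rec <- substr(text, 1, 6)

  # first model only
  mstart <- which(rec == "MODEL ")
  if (length(mstart) > 0L) {
    mend <- which(rec == "ENDMDL")
    last <- if (length(mend) > 0L) mend[1L] else length(text)
    keep_range <- seq.int(mstart[1L], last)
    pre <- seq_len(mstart[1L] - 1L)     # header lines before MODEL 1
    text <- text[c(pre, keep_range)]
    rec <- substr(text, 1, 6)
  }

  if (is.null(pdb_code)) {
    hdr <- text[rec == "HEADER"]
    if (length(hdr) > 0L && nchar(hdr[1L]) >= 66) {
      code <- trimws(substr(hdr[1L], 63, 66))
      if (nchar(code) == 4L) pdb_code <- code
    }
    if (is.null(pdb_code) && !is.null(path)) {
      base <- sub("\\.(pdb|ent)(\\.gz)?$", "", basename(path), ignore.case = TRUE)
      pdb_code <- toupper(substr(sprintf("%-4s", base), 1, 4))
    }
    if (is.null(pdb_code)) pdb_code <- "XXXX"
  }
  pdb_code <- toupper(pdb_code)

  is_atom <- rec %in% c("ATOM  ", "HETATM")
  lines <- text[is_atom]
  if (length(lines) > 0L && any(nchar(lines) < 54))
    fp_data_error("truncated ATOM/HETATM record in %s",
                  if (is.null(path)) "<text>" else path)

  xyz_num <- function(s) {
    v <- suppressWarnings(as.numeric(s))
    if (anyNA(v))
      fp_data_error("unparseable coordinate field in %s",
                    if (is.null(path)) "<text>" else path)
    v
  }

  atoms <- data.frame(
    record = trimws(substr(lines, 1, 6)),
    name = trimws(substr(lines, 13, 16)),
    altloc = substr(lines, 17, 17),
    resname = trimws(substr(lines, 18, 20)),
    chain = substr(lines, 22, 22),
    resno = suppressWarnings(as.integer(substr(lines, 23, 26))),
    icode = substr(lines, 27, 27),
    x = xyz_num(substr(lines, 31, 38)),
    y = xyz_num(substr(lines, 39, 46)),
    z = xyz_num(substr(lines, 47, 54)),
    stringsAsFactors = FALSE)
  if (anyNA(atoms$resno))
    fp_data_error("unparseable residue number in %s",
                  if (is.null(path)) "<text>" else path)
  atoms <- atoms[atoms$altloc %in% c(" ", "A", ""), , drop = FALSE]
  rownames(atoms) <- NULL

  structure(
    list(pdb_code = pdb_code,
         source = if (is.null(path)) "<text>" else path,
         atoms = atoms),
    class = "pdb_structure")
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat(sprintf("<pdb_structure %s: %d atom records, chains %s>\n",
              x$pdb_code, nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

format_atom_line <- function(serial, name, resname, chain, resno, icode,
                             x, y, z) {
  # short atom names start in column 14 by convention
  name_f <- if (nchar(name) < 4L) sprintf(" %-3s", name) else sprintf("%-4s", name)
  element <- substr(name, 1, 1)
  sprintf("ATOM  %5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name_f, resname, chain, resno, icode, x, y, z,
          1.00, 0.00, element)
}

#' Write a parsed structure back to PDB text
#'
#' @param s a `pdb_structure`.
#' @param path output file; when `NULL` the lines are returned invisibly only.
#' @return The PDB lines, invisibly.
#' @export
write_pdb <- function(s, path = NULL) {
  a <- s$atoms
  lines <- character(nrow(a))
  for (i in seq_len(nrow(a))) {
    lines[i] <- format_atom_line(i, a$name[i], a$resname[i], a$chain[i],
                                 a$resno[i], a$icode[i], a$x[i], a$y[i], a$z[i])
  }
  lines <- c(lines, "TER", "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
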