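# Compact binary database format ("FRGR").
#
# Little-endian throughout.  Header: magic "FRGR", format version u16,
# atom-convention tag u8 (1 = N,CA,C,O), fragment length u32, fragment count
# u64, continuity cutoff f64, then the source manifest (length-prefixed
# strings), then one fixed-size record per fragment: pdb_code (4 bytes),
# chain (1), per-residue residue numbers (L x i32) and insertion codes
# (L bytes), sequence (L bytes), coordinates (4*L*3 float32, residue-major
# x,y,z).  float32 preserves PDB 3-decimal precision for |coord| < 1e4.
# Per-residue ids (not just the window start) are stored so that insertion
# codes and numbering gaps survive the round trip losslessly.

BIN_MAGIC <- charToRaw("FRGR")
BIN_VERSION <- 1L
IDX_MAGIC <- charToRaw("FRGX")
IDX_VERSION <- 1L
CONVENTION_TAGS <- c("N,CA,C,O" = 1L)

fp_binary_error <- function(subclass, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(subclass, "fragpick_data_error", "error")))
}

w_u16 <- function(con, v) writeBin(as.integer(v), con, size = 2, endian = "little")
w_u32 <- function(con, v) writeBin(as.integer(v), con, size = 4, endian = "little")
w_u64 <- function(con, v) { w_u32(con, v); w_u32(con, 0L) }  # counts < 2^31
w_f32 <- function(con, v) writeBin(as.numeric(v), con, size = 4, endian = "little")
w_f64 <- function(con, v) writeBin(as.numeric(v), con, size = 8, endian = "little")
w_chr <- function(con, s, width) {
  r <- charToRaw(sprintf(paste0("%-", width, "s"), s))[seq_len(width)]
  writeBin(r, con)
}
w_lpstr <- function(con, s) {
  r <- charToRaw(s)
  w_u16(con, length(r))
  writeBin(r, con)
}

# read helpers that treat short reads as truncation
r_expect <- function(con, what, n, size, where, type = "integer") {
  v <- readBin(con, type, n = n, size = size, endian = "little",
               signed = !(type == "integer" && size <= 2))
  if (length(v) < n)
    fp_binary_error("fragpick_truncated_stream",
                    "truncated stream while reading %s", where)
  v
}
r_raw <- function(con, n, where) {
  r <- readBin(con, "raw", n = n)
  if (length(r) < n)
    fp_binary_error("fragpick_truncated_stream",
                    "truncated stream while reading %s", where)
  r
}
r_lpstr <- function(con, where) {
  n <- r_expect(con, "len", 1, 2, where)
  rawToChar(r_raw(con, n, where))
}

#' Write a fragment database in the binary format
#'
#' @param db a `fragment_db`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_binary()]
#' @export
write_binary <- function(db, path) {
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(BIN_MAGIC, con)
  w_u16(con, BIN_VERSION)
  writeBin(as.raw(CONVENTION_TAGS[db$params$atom_convention]), con)
  w_u32(con, db$fragment_length)
  w_u64(con, db$n)
  w_f64(con, db$params$continuity_cutoff)
  w_u32(con, nrow(db$manifest))
  for (i in seq_len(nrow(db$manifest))) {
    w_lpstr(con, db$manifest$pdb_code[i])
    w_lpstr(con, db$manifest$path[i])
    w_u32(con, ifelse(is.na(db$manifest$n_chains[i]), -1L, db$manifest$n_chains[i]))
    w_u32(con, ifelse(is.na(db$manifest$n_fragments[i]), -1L, db$manifest$n_fragments[i]))
  }
  for (f in db$fragments) w_fragment(con, f)
  invisible(path)
}

w_fragment <- function(con, f) {
  w_chr(con, f$pdb_code, 4L)
  w_chr(con, f$chain, 1L)
  w_u32(con, f$resno)
  writeBin(charToRaw(paste(f$icode, collapse = "")), con)
  writeBin(charToRaw(f$sequence), con)
  w_f32(con, as.vector(t(f$coords)))
}

r_fragment <- function(con, L, where, fragment_id = NA_integer_) {
  pdb_code <- trimws(rawToChar(r_raw(con, 4, where)))
  chain <- rawToChar(r_raw(con, 1, where))
  resno <- r_expect(con, "resno", L, 4, where)
  icode <- strsplit(rawToChar(r_raw(con, L, where)), "")[[1]]
  sequence <- rawToChar(r_raw(con, L, where))
  xyz <- r_expect(con, "coords", 4L * L * 3L, 4, where, type = "double")
  new_fragment(pdb_code, chain, resno, icode, sequence,
               matrix(xyz, ncol = 3L, byrow = TRUE), fragment_id = fragment_id)
}

#' Read a fragment database from the binary format
#'
#' Bad magic bytes, an unsupported format version and a truncated stream
#' raise distinct classed errors (`fragpick_bad_magic`,
#' `fragpick_bad_version`, `fragpick_truncated_stream`).
#'
#' @param path path to a file written by [write_binary()].
#' @return The `fragment_db`, field-identical to the one written (coordinates
#'   at float32, i.e. PDB 3-decimal, precision).
#' @export
read_binary <- function(path) {
  if (!file.exists(path)) fp_data_error("binary database not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- r_raw(con, 4, "magic")
  if (!identical(magic, BIN_MAGIC))
    fp_binary_error("fragpick_bad_magic",
                    "not a fragment database (bad magic bytes): %s", path)
  ver <- r_expect(con, "version", 1, 2, "header")
  if (ver != BIN_VERSION)
    fp_binary_error("fragpick_bad_version",
                    "unsupported database format version %d (expected %d)",
                    ver, BIN_VERSION)
  conv_tag <- as.integer(r_raw(con, 1, "header"))
  conv <- names(CONVENTION_TAGS)[match(conv_tag, CONVENTION_TAGS)]
  if (is.na(conv))
    fp_binary_error("fragpick_bad_version",
                    "unknown atom-convention tag %d", conv_tag)
  L <- r_expect(con, "L", 1, 4, "header")
  n <- r_expect(con, "count.lo", 1, 4, "header")
  r_expect(con, "count.hi", 1, 4, "header")
  cutoff <- r_expect(con, "cutoff", 1, 8, "header", type = "double")
  nman <- r_expect(con, "manifest count", 1, 4, "header")
  manifest <- data.frame(pdb_code = character(nman), path = character(nman),
                         n_chains = integer(nman), n_fragments = integer(nman),
                         stringsAsFactors = FALSE)
  for (i in seq_len(nman)) {
    manifest$pdb_code[i] <- r_lpstr(con, "manifest")
    manifest$path[i] <- r_lpstr(con, "manifest")
    v <- r_expect(con, "manifest ints", 2, 4, "manifest")
    manifest$n_chains[i] <- if (v[1] < 0) NA_integer_ else v[1]
    manifest$n_fragments[i] <- if (v[2] < 0) NA_integer_ else v[2]
  }
  fragments <- vector("list", n)
  for (i in seq_len(n)) {
    fragments[[i]] <- r_fragment(con, L, sprintf("fragment %d of %d", i - 1L, n),
                                 fragment_id = i - 1L)
  }
  new_fragment_db(L, fragments, manifest, cutoff)
}
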