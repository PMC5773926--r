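# Fragment and fragment-database containers, and window extraction from
# parsed PDB structures.
#
# A fragment is a window of L consecutive, peptide-bonded residues from one
# chain, represented by the 4-atom backbone (N, CA, C, O) of each residue.
# Coordinates are stored residue-major as a (4*L) x 3 matrix.  Consecutiveness
# is geometric (C_i -- N_{i+1} distance), never author-numbering arithmetic:
# insertion codes and renumbered files make numbering unsafe.

CONTINUITY_CUTOFF <- 2.0   # Angstrom; peptide C-N bond is ~1.33
ATOM_CONVENTION <- "N,CA,C,O"

#' Construct a backbone fragment
#'
#' Low-level constructor used by [extract_fragments()] and the synthetic
#' generators.  Most users never call it directly.
#'
#' @param pdb_code 4-character source structure id (uppercased).
#' @param chain one-character chain identifier.
#' @param resno integer vector of residue sequence numbers, one per residue.
#' @param icode character vector of insertion codes (`" "` when absent).
#' @param sequence string of one-letter amino-acid codes, one per residue.
#' @param coords numeric (4*L) x 3 matrix, residue-major, atoms ordered
#'   N, CA, C, O within each residue; Angstrom.
#' @param fragment_id integer id within a database (0-based), `NA` when free.
#' @return An object of class `fragment`.
#' @export
new_fragment <- function(pdb_code, chain, resno, icode, sequence, coords,
                         fragment_id = NA_integer_) {
  L <- nchar(sequence)
  if (L < 3L) fp_data_error("fragment length %d < 3", L)
  if (length(resno) != L || length(icode) != L)
    fp_data_error("residue id vectors must have length %d", L)
  if (!is.matrix(coords) || nrow(coords) != 4L * L || ncol(coords) != 3L)
    fp_data_error("coords must be a %d x 3 matrix", 4L * L)
  if (!all(is.finite(coords)))
    fp_data_error("fragment coordinates must be finite")
  if (!all(strsplit(sequence, "")[[1]] %in% names(AA1_TO_3)))
    fp_data_error("sequence contains letters outside the 20 standard codes + X")
  structure(
    list(fragment_id = as.integer(fragment_id),
         pdb_code = toupper(pdb_code),
         chain = chain,
         resno = as.integer(resno),
         icode = icode,
         sequence = sequence,
         coords = unname(coords)),
    class = "fragment")
}

#' @export
print.fragment <- function(x, ...) {
  cat(sprintf("<fragment %s %s/%s %d%s..%d%s  L=%d  %s>\n",
              ifelse(is.na(x$fragment_id), "-", x$fragment_id),
              x$pdb_code, x$chain,
              x$resno[1], trimws(x$icode[1]),
              x$resno[length(x$resno)], trimws(x$icode[length(x$icode)]),
              nchar(x$sequence), x$sequence))
  invisible(x)
}

fragment_length <- function(f) nchar(f$sequence)

# ---- residue table from a parsed structure ---------------------------------

# One row per eligible residue (all 4 backbone atoms present, standard amino
# acid or MSE/UNK), in resolved (file) order, with backbone coordinates.
eligible_residues <- function(s) {
  a <- s$atoms
  a <- a[a$resname %in% names(AA3_TO_1) & a$name %in% BACKBONE_ATOMS, ,
         drop = FALSE]
  if (nrow(a) == 0L)
    return(data.frame(chain = character(0), resno = integer(0),
                      icode = character(0), aa = character(0)))
  key <- paste(a$chain, a$resno, a$icode, sep = "\r")
  keys <- unique(key)   # resolved order = order of first appearance
  n <- length(keys)
  out <- data.frame(chain = character(n), resno = integer(n),
                    icode = character(n), aa = character(n),
                    stringsAsFactors = FALSE)
  coords <- matrix(NA_real_, nrow = 4L * n, ncol = 3L)
  keep <- logical(n)
  for (i in seq_len(n)) {
    rows <- a[key == keys[i], , drop = FALSE]
    present <- !duplicated(rows$name)
    rows <- rows[present, , drop = FALSE]
    if (!all(BACKBONE_ATOMS %in% rows$name)) next
    m <- match(BACKBONE_ATOMS, rows$name)
    coords[(4L * (i - 1L) + 1L):(4L * i), ] <-
      cbind(rows$x[m], rows$y[m], rows$z[m])
    out$chain[i] <- rows$chain[1]
    out$resno[i] <- rows$resno[1]
    out$icode[i] <- rows$icode[1]
    out$aa[i] <- unname(AA3_TO_1[rows$resname[1]])
    keep[i] <- TRUE
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  idx <- which(keep)
  rows_keep <- as.vector(vapply(idx, function(i) (4L * (i - 1L) + 1L):(4L * i),
                                integer(4)))
  attr(out, "coords") <- coords[rows_keep, , drop = FALSE]
  out
}

# Split residue indices of one chain into geometric-continuity runs.
continuity_runs <- function(res, coords, cutoff = CONTINUITY_CUTOFF) {
  n <- nrow(res)
  if (n == 0L) return(list())
  breaks <- integer(0)
  for (i in seq_len(n - 1L)) {
    c_i <- coords[4L * (i - 1L) + 3L, ]   # C of residue i
    n_next <- coords[4L * i + 1L, ]       # N of residue i+1
    if (sqrt(sum((c_i - n_next)^2)) > cutoff) breaks <- c(breaks, i)
  }
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  Map(function(s, e) s:e, starts, ends)
}

# ---- extraction ------------------------------------------------------------

#' Extract all fragments of one length from parsed structures
#'
#' Slides a window of `length` residues over every geometric-continuity run of
#' every protein chain of every input structure, in deterministic order
#' (input order, then chain order of appearance, then window start).  Windows
#' spanning a chain break (C--N distance above the cutoff) are excluded, as
#' are residues missing any backbone atom.
#'
#' @param structures a `pdb_structure` or list of them (see [parse_pdb()]).
#' @param length fragment length L (residues), >= 3.
#' @param continuity_cutoff maximal C(i)--N(i+1) distance (Angstrom) for two
#'   residues to count as peptide-bonded; default 2.0.
#' @return An object of class `fragment_db` holding the fragments (ids
#'   0..n-1), a source manifest, and the creation parameters.
#' @examples
#' db <- extract_fragments(make_helix_chain(10), length = 3)
#' db$n  # 8 windows
#' @export
extract_fragments <- function(structures, length,
                              continuity_cutoff = CONTINUITY_CUTOFF) {
  if (inherits(structures, "pdb_structure")) structures <- list(structures)
  if (!is.list(structures) || length(structures) == 0L)
    fp_data_error("no input structures")
  L <- as.integer(length)
  if (is.na(L) || L < 3L) fp_data_error("fragment length must be >= 3, got %s",
                                        as.character(length))

  fragments <- list()
  manifest <- data.frame(pdb_code = character(0), path = character(0),
                         n_chains = integer(0), n_fragments = integer(0),
                         stringsAsFactors = FALSE)
  for (s in structures) {
    if (!inherits(s, "pdb_structure"))
      fp_data_error("inputs must be pdb_structure objects")
    res <- eligible_residues(s)
    coords <- attr(res, "coords")
    chains <- unique(res$chain)
    count_before <- length(fragments)
    for (ch in chains) {
      in_ch <- which(res$chain == ch)
      res_ch <- res[in_ch, , drop = FALSE]
      rows_ch <- as.vector(vapply(in_ch, function(i) (4L * (i - 1L) + 1L):(4L * i),
                                  integer(4)))
      co_ch <- coords[rows_ch, , drop = FALSE]
      runs <- continuity_runs(res_ch, co_ch, continuity_cutoff)
      for (run in runs) {
        m <- length(run)
        if (m < L) next
        for (start in seq_len(m - L + 1L)) {
          win <- run[start:(start + L - 1L)]
          atom_rows <- as.vector(vapply(win, function(i) (4L * (i - 1L) + 1L):(4L * i),
                                        integer(4)))
          fragments[[length(fragments) + 1L]] <- new_fragment(
            pdb_code = s$pdb_code, chain = ch,
            resno = res_ch$resno[win], icode = res_ch$icode[win],
            sequence = paste(res_ch$aa[win], collapse = ""),
            coords = co_ch[atom_rows, , drop = FALSE])
        }
      }
    }
    got <- length(fragments) - count_before
    if (got == 0L)
      warning(sprintf("structure %s contributed no fragments at L=%d",
                      s$pdb_code, L), call. = FALSE)
    manifest <- rbind(manifest, data.frame(
      pdb_code = s$pdb_code, path = s$source,
      n_chains = length(chains), n_fragments = got,
      stringsAsFactors = FALSE))
  }
  for (i in seq_along(fragments)) fragments[[i]]$fragment_id <- i - 1L
  new_fragment_db(L, fragments, manifest, continuity_cutoff)
}

new_fragment_db <- function(L, fragments, manifest, continuity_cutoff) {
  db <- structure(
    list(fragment_length = as.integer(L),
         n = length(fragments),
         fragments = fragments,
         manifest = manifest,
         params = list(length = as.integer(L),
                       atom_convention = ATOM_CONVENTION,
                       continuity_cutoff = continuity_cutoff),
         content_hash = NA_character_),
    class = "fragment_db")
  db$content_hash <- db_content_hash(db)
  db
}

#' Build a fragment database directly from fragment objects
#'
#' Used by tests and synthetic pipelines; [extract_fragments()] is the
#' PDB-file route.  Fragment ids are (re)assigned 0..n-1 in list order.
#'
#' @param fragments list of `fragment` objects of identical length.
#' @inheritParams extract_fragments
#' @return A `fragment_db`.
#' @export
fragment_db <- function(fragments, continuity_cutoff = CONTINUITY_CUTOFF) {
  if (length(fragments) > 0L) {
    Ls <- vapply(fragments, fragment_length, integer(1))
    if (length(unique(Ls)) != 1L)
      fp_data_error("all fragments must share one length; got %s",
                    paste(unique(Ls), collapse = ","))
    L <- Ls[1]
  } else {
    fp_data_error("fragment_db needs at least one fragment; use extract_fragments for file input")
  }
  for (i in seq_along(fragments)) fragments[[i]]$fragment_id <- i - 1L
  codes <- unique(vapply(fragments, function(f) f$pdb_code, character(1)))
  manifest <- data.frame(pdb_code = codes, path = "<in-memory>",
                         n_chains = NA_integer_, n_fragments = NA_integer_,
                         stringsAsFactors = FALSE)
  new_fragment_db(L, fragments, manifest, continuity_cutoff)
}

#' @export
print.fragment_db <- function(x, ...) {
  cat(sprintf("<fragment_db: %d fragments of length %d from %d structures>\n",
              x$n, x$fragment_length, nrow(x$manifest)))
  invisible(x)
}

# Canonical md5 over database content: binds an index to its database.
# Coordinates enter the hash at float32 (the binary storage precision), which
# is idempotent, so the hash survives binary round trips exactly.
db_content_hash <- function(db) {
  canon <- list(
    L = db$fragment_length,
    conv = db$params$atom_convention,
    frags = lapply(db$fragments, function(f)
      list(f$pdb_code, f$chain, f$resno, f$icode, f$sequence,
           as_float32(f$coords))))
  tf <- tempfile(fileext = ".ser")
  on.exit(unlink(tf), add = TRUE)
  con <- file(tf, "wb")
  serialize(canon, con, version = 3L)
  close(con)
  unname(tools::md5sum(tf))
}

# ---- lookup and sampling ---------------------------------------------------

#' Fetch a fragment by id
#' @param db a `fragment_db`.
#' @param id 0-based fragment id.
#' @return The `fragment`.
#' @export
get_fragment <- function(db, id) {
  id <- as.integer(id)
  if (is.na(id) || id < 0L || id >= db$n)
    fp_data_error("fragment id %s outside 0..%d", as.character(id), db$n - 1L)
  db$fragments[[id + 1L]]
}

#' Find a fragment by provenance
#'
#' Looks a fragment up by its source structure, chain and first residue.
#'
#' @inheritParams get_fragment
#' @param pdb_code,chain,start_resno,start_icode provenance of the first
#'   residue of the wanted window.
#' @return The matching `fragment`, or an error when absent.
#' @export
find_fragment <- function(db, pdb_code, chain, start_resno, start_icode = " ") {
  pdb_code <- toupper(pdb_code)
  for (f in db$fragments) {
    if (f$pdb_code == pdb_code && f$chain == chain &&
        f$resno[1] == start_resno && f$icode[1] == start_icode)
      return(f)
  }
  fp_data_error("no fragment %s/%s starting at %d%s in database",
                pdb_code, chain, start_resno, trimws(start_icode))
}

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Sample fragments without replacement
#'
#' Uniform sampling without replacement; identical `(db, n, seed)` yields an
#' identical list.  The caller's RNG state is left untouched.
#'
#' @inheritParams get_fragment
#' @param n number of fragments, `0 <= n <= db$n`.
#' @param seed integer seed.
#' @return List of `n` distinct `fragment` objects.
#' @export
get_random_fragments <- function(db, n, seed) {
  n <- as.integer(n)
  if (is.na(n) || n < 0L || n > db$n)
    fp_data_error("cannot sample %s fragments from %d", as.character(n), db$n)
  if (n == 0L) return(list())
  ids <- with_seed(seed, sample.int(db$n, n)) - 1L
  lapply(ids, function(i) db$fragments[[i + 1L]])
}

# ---- fragment -> PDB text --------------------------------------------------

#' Write a fragment as PDB-format text
#'
#' Emits standard ATOM records (N, CA, C, O per residue) with the original
#' chain id, residue numbers and insertion codes, occupancy 1.00, B-factor
#' 0.00 and the element column filled, terminated by TER and END, so the
#' output is directly usable by downstream structure tools.
#'
#' @param f a `fragment`.
#' @param path output file; omit to just get the text.
#' @return The PDB lines, invisibly.
#' @export
fragment_to_pdb <- function(f, path = NULL) {
  L <- fragment_length(f)
  seq3 <- unname(AA1_TO_3[strsplit(f$sequence, "")[[1]]])
  lines <- character(4L * L)
  serial <- 0L
  for (i in seq_len(L)) {
    for (j in seq_len(4L)) {
      serial <- serial + 1L
      row <- 4L * (i - 1L) + j
      lines[serial] <- format_atom_line(
        serial, BACKBONE_ATOMS[j], seq3[i], f$chain, f$resno[i], f$icode[i],
        f$coords[row, 1], f$coords[row, 2], f$coords[row, 3])
    }
  }
  lines <- c(lines, "TER", "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a single continuous fragment from a parsed structure
#'
#' Interprets a whole structure (typically a small query PDB) as one
#' fragment: eligible residues of one chain forming a single continuity run.
#'
#' @param s a `pdb_structure`.
#' @param chain chain to use; default: the first chain present.
#' @return A `fragment` (id `NA`).
#' @export
fragment_from_structure <- function(s, chain = NULL) {
  res <- eligible_residues(s)
  if (nrow(res) == 0L) fp_data_error("%s: no eligible residues", s$pdb_code)
  if (is.null(chain)) chain <- res$chain[1]
  in_ch <- which(res$chain == chain)
  if (length(in_ch) == 0L) fp_data_error("%s: no chain %s", s$pdb_code, chain)
  res_ch <- res[in_ch, , drop = FALSE]
  rows <- as.vector(vapply(in_ch, function(i) (4L * (i - 1L) + 1L):(4L * i),
                           integer(4)))
  co <- attr(res, "coords")[rows, , drop = FALSE]
  runs <- continuity_runs(res_ch, co)
  if (length(runs) != 1L)
    fp_data_error("%s chain %s: %d continuity runs; a query fragment must be continuous",
                  s$pdb_code, chain, length(runs))
  new_fragment(s$pdb_code, chain, res_ch$resno, res_ch$icode,
               paste(res_ch$aa, collapse = ""), co)
}

# stack fragment coordinates into the compiled kernel's pool layout
db_pool_matrix <- function(db, atom_rows = NULL) {
  coords <- lapply(db$fragments, function(f)
    if (is.null(atom_rows)) f$coords else f$coords[atom_rows, , drop = FALSE])
  coords_pool_matrix(coords)
}

# atom row indices selected by a 1-based residue mask
mask_atom_rows <- function(mask, L) {
  mask <- sort(unique(as.integer(mask)))
  if (length(mask) < 3L)
    fp_data_error("mask must select at least 3 residues")
  if (any(mask < 1L) || any(mask > L))
    fp_data_error("mask positions must lie in 1..%d", L)
  as.vector(vapply(mask, function(p) (4L * (p - 1L) + 1L):(4L * p), integer(4)))
}
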