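# Structural queries: triangle-inequality pruning against the index,
# sequence/provenance filters, exact refinement, ranking, result limits,
# automatic threshold widening, and the masked (gapped-query) linear-scan
# path.
#
# Pipeline for a full-length query q with threshold d_q:
#   1. for every reference r_j, d = rmsd(q, r_j); only fragments whose
#      indexed distance to r_j lies in [max(0, d - d_q) - eps, d + d_q + eps]
#      can match (triangle inequality; eps covers float32 storage rounding);
#      candidate sets from all references are intersected;
#   2. fragments from excluded PDB codes are dropped;
#   3. fragments whose sequence fails the (anchored) regular expression are
#      dropped -- sequence filtering happens after pruning, before the
#      expensive exact pass;
#   4. exact refinement keeps candidates with rmsd(q, f) <= d_q;
#   5. matches are sorted ascending by rmsd, ties by fragment id;
#   6. an optional result limit ("N best" / "N first") is applied.
# The result provably equals a brute-force scan: pruning never loses a match.

#' Construct a structural query
#'
#' @param query the query fragment: a `fragment`, or a bare (4*L) x 3
#'   backbone coordinate matrix (residue-major, N/CA/C/O per residue).
#' @param threshold RMSD threshold d_q in Angstrom, >= 0.
#' @param mask optional integer vector of 1-based residue positions to use
#'   (gapped query); at least 3 positions.  Masked queries are answered by a
#'   linear scan, see [query_fragments()].
#' @param seq_regex optional regular expression over one-letter amino-acid
#'   codes; anchored, i.e. it must describe the entire L-letter sequence of a
#'   matching fragment (write `A.{11}G` for "starts with Ala, ends with Gly"
#'   at L = 13).
#' @param exclude_pdb optional character vector of 4-letter PDB codes whose
#'   fragments may not match.
#' @param limit_mode,limit_n optional result limit: `"best"` keeps the N
#'   lowest-RMSD matches; `"first"` keeps the first N fragments (in fragment
#'   id order) that pass refinement, then sorts them by RMSD.
#' @param auto_widen optional list `(target, step, ceiling)` for automatic
#'   threshold widening, see [query_auto_widen()].
#' @return An object of class `structural_query`.
#' @export
structural_query <- function(query, threshold, mask = NULL, seq_regex = NULL,
                             exclude_pdb = NULL, limit_mode = NULL,
                             limit_n = NULL, auto_widen = NULL) {
  if (inherits(query, "fragment")) {
    coords <- query$coords
  } else if (is.matrix(query)) {
    coords <- query
    if (nrow(coords) %% 4L != 0L)
      fp_data_error("query coordinate matrix must have 4 rows per residue")
  } else fp_data_error("query must be a fragment or a coordinate matrix")
  if (!is.numeric(threshold) || is.na(threshold) || threshold < 0)
    fp_data_error("threshold must be a non-negative RMSD in Angstrom")
  L <- nrow(coords) %/% 4L
  if (!is.null(mask)) mask_atom_rows(mask, L)  # validates
  if (!is.null(limit_mode)) {
    if (!limit_mode %in% c("best", "first"))
      fp_data_error("limit mode must be 'best' or 'first'")
    if (is.null(limit_n) || limit_n < 1L)
      fp_data_error("limit N must be >= 1")
  }
  if (!is.null(auto_widen)) {
    aw <- auto_widen
    if (!all(c("target", "step", "ceiling") %in% names(aw)) ||
        aw$target < 1L || aw$step <= 0 || aw$ceiling < threshold)
      fp_data_error("auto_widen needs target >= 1, step > 0, ceiling >= threshold")
  }
  structure(list(coords = unname(coords), length = L,
                 threshold = threshold, mask = mask,
                 seq_regex = seq_regex,
                 exclude_pdb = if (is.null(exclude_pdb)) NULL else toupper(exclude_pdb),
                 limit_mode = limit_mode,
                 limit_n = if (is.null(limit_n)) NULL else as.integer(limit_n),
                 auto_widen = auto_widen),
            class = "structural_query")
}

anchored_grepl <- function(pattern, x) {
  anchored <- paste0("^(?:", pattern, ")$")
  tryCatch(suppressWarnings(grepl(anchored, x, perl = TRUE)),
           error = function(e)
             fp_data_error("invalid regular expression: %s", pattern))
}

match_df <- function(db, ids, rmsd) {
  frs <- lapply(ids, function(i) db$fragments[[i + 1L]])
  out <- data.frame(
    fragment_id = as.integer(ids),
    pdb_code = vapply(frs, function(f) f$pdb_code, character(1)),
    chain = vapply(frs, function(f) f$chain, character(1)),
    start_resno = vapply(frs, function(f) f$resno[1], integer(1)),
    start_icode = vapply(frs, function(f) f$icode[1], character(1)),
    rmsd = as.numeric(rmsd),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("fragment_matches", "data.frame")
  out
}

empty_matches <- function() match_df(list(fragments = list()), integer(0), numeric(0))

# candidate ids surviving provenance + sequence filters, ascending id order
apply_filters <- function(db, ids, sq) {
  if (length(ids) == 0L) return(ids)
  if (!is.null(sq$exclude_pdb)) {
    codes <- vapply(ids, function(i) db$fragments[[i + 1L]]$pdb_code, character(1))
    ids <- ids[!(codes %in% sq$exclude_pdb)]
  }
  if (!is.null(sq$seq_regex) && length(ids) > 0L) {
    seqs <- vapply(ids, function(i) db$fragments[[i + 1L]]$sequence, character(1))
    ids <- ids[anchored_grepl(sq$seq_regex, seqs)]
  }
  ids
}

# refinement + ordering + limit over a candidate id set (ascending ids)
refine_and_rank <- function(db, sq, ids, threshold, atom_rows = NULL) {
  if (length(ids) == 0L) return(empty_matches())
  qc <- if (is.null(atom_rows)) sq$coords else sq$coords[atom_rows, , drop = FALSE]
  pool <- coords_pool_matrix(lapply(ids, function(i) {
    co <- db$fragments[[i + 1L]]$coords
    if (is.null(atom_rows)) co else co[atom_rows, , drop = FALSE]
  }))
  rmsd <- qcp_rmsd_one_vs_many(qc, pool)
  pass <- rmsd <= threshold
  ids <- ids[pass]
  rmsd <- rmsd[pass]
  if (!is.null(sq$limit_mode) && sq$limit_mode == "first" &&
      length(ids) > sq$limit_n) {
    keep <- order(ids)[seq_len(sq$limit_n)]   # scan order = fragment id order
    ids <- ids[keep]
    rmsd <- rmsd[keep]
  }
  ord <- order(rmsd, ids)
  m <- match_df(db, ids[ord], rmsd[ord])
  if (!is.null(sq$limit_mode) && sq$limit_mode == "best")
    m <- m[seq_len(min(nrow(m), sq$limit_n)), , drop = FALSE]
  rownames(m) <- NULL
  class(m) <- c("fragment_matches", "data.frame")
  m
}

#' Query a fragment database
#'
#' Answers a structural query against an indexed database: triangle-
#' inequality pruning, PDB-code exclusion, sequence-regex filtering, exact
#' RMSD refinement and ranking (ascending RMSD, ties by fragment id).  The
#' result is identical -- membership and order -- to a brute-force scan over
#' all fragments; pruning affects only speed.
#'
#' When the query carries a mask (a gapped query), the index is bypassed and
#' all fragments are scanned linearly: the index bounds hold for the
#' full-length RMSD metric only, and masked RMSD is a different metric.
#' Direct scanning is fast enough for such one-off tasks.
#'
#' @param db a `fragment_db`.
#' @param index an `rmsd_index` built on `db` (may be `NULL` for masked
#'   queries).
#' @param sq a [structural_query()].
#' @return A `fragment_matches` data frame (fragment_id, pdb_code, chain,
#'   start_resno, start_icode, rmsd) with attribute `threshold`.
#' @export
query_fragments <- function(db, index, sq) {
  if (!inherits(sq, "structural_query")) fp_data_error("sq must be a structural_query")
  if (sq$length != db$fragment_length)
    fp_data_error("query length %d != database fragment length %d",
                  sq$length, db$fragment_length)
  if (!is.null(sq$mask)) return(query_masked(db, sq))
  if (is.null(index)) fp_data_error("a full-length query needs an index; build one with build_index()")
  check_index_db(index, db)

  dq <- sq$threshold
  cand <- NULL
  for (j in seq_along(index$tables)) {
    d <- qcp_rmsd(sq$coords, index$refs$references[[j]]$coords)
    ids_j <- range_candidates(index, j,
                              max(0, d - dq) - INDEX_EPS, d + dq + INDEX_EPS)
    cand <- if (is.null(cand)) ids_j else intersect(cand, ids_j)
    if (length(cand) == 0L) break
  }
  cand <- sort(cand)
  n_pruned <- length(cand)            # survivors of the fuzzy (pruning) pass
  cand <- apply_filters(db, cand, sq)
  out <- refine_and_rank(db, sq, cand, dq)
  attr(out, "threshold") <- dq
  attr(out, "n_candidates") <- n_pruned
  attr(out, "n_refined") <- length(cand)
  out
}

#' Masked (gapped) query by linear scan
#'
#' Distance is the superposition RMSD restricted to the backbone atoms of the
#' masked residue positions of both query and candidate.  Filters, threshold,
#' ordering and limits behave as in [query_fragments()].
#'
#' @inheritParams query_fragments
#' @return A `fragment_matches` data frame.
#' @export
query_masked <- function(db, sq) {
  if (is.null(sq$mask)) fp_data_error("query_masked needs a mask")
  if (sq$length != db$fragment_length)
    fp_data_error("query length %d != database fragment length %d",
                  sq$length, db$fragment_length)
  rows <- mask_atom_rows(sq$mask, sq$length)
  ids <- apply_filters(db, seq_len(db$n) - 1L, sq)
  out <- refine_and_rank(db, sq, ids, sq$threshold, atom_rows = rows)
  attr(out, "threshold") <- sq$threshold
  out
}

#' Apply an "N best" / "N first" result limit
#'
#' `mode = "best"` keeps the N lowest-RMSD matches of the ranked list.
#' `mode = "first"` keeps the N matches with the smallest fragment ids (the
#' first to pass refinement in scan order) and re-sorts them by RMSD.  An N
#' larger than the list returns the whole list.
#'
#' @param matches a `fragment_matches` data frame (ranked).
#' @param mode `"best"` or `"first"`.
#' @param n limit, >= 1.
#' @return The limited `fragment_matches`.
#' @export
apply_limit <- function(matches, mode, n) {
  if (!mode %in% c("best", "first")) fp_data_error("limit mode must be 'best' or 'first'")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) fp_data_error("limit N must be >= 1")
  if (nrow(matches) <= n) return(matches)
  out <- if (mode == "best") {
    matches[seq_len(n), , drop = FALSE]
  } else {
    kept <- matches[order(matches$fragment_id)[seq_len(n)], , drop = FALSE]
    kept[order(kept$rmsd, kept$fragment_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("fragment_matches", "data.frame")
  out
}

#' Query with automatic threshold widening
#'
#' Re-runs the query at d_q, d_q + step, d_q + 2 step, ... until at least
#' `target` matches are found or the next threshold would exceed `ceiling`.
#' Match sets are nested in the threshold (monotonicity), so the final list
#' equals a fresh query at the final threshold.
#'
#' @inheritParams query_fragments
#' @param target minimal number of matches wanted (>= 1).
#' @param step threshold increment in Angstrom (> 0).
#' @param ceiling largest threshold to try (>= the query's threshold).
#' @return A list with `matches`, `threshold` (the final one) and
#'   `under_target` (`TRUE` when the ceiling was reached short of target --
#'   not an error).
#' @export
query_auto_widen <- function(db, index, sq, target = NULL, step = NULL,
                             ceiling = NULL) {
  aw <- sq$auto_widen
  if (is.null(target)) target <- aw$target
  if (is.null(step)) step <- if (!is.null(aw$step)) aw$step else 0.25
  if (is.null(ceiling)) ceiling <- if (!is.null(aw$ceiling)) aw$ceiling else 10
  if (is.null(target) || target < 1L) fp_data_error("auto-widen target must be >= 1")
  if (step <= 0) fp_data_error("auto-widen step must be > 0")
  if (ceiling < sq$threshold) fp_data_error("auto-widen ceiling below initial threshold")

  d <- sq$threshold
  repeat {
    sq$threshold <- d
    m <- query_fragments(db, index, sq)
    if (nrow(m) >= target)
      return(list(matches = m, threshold = d, under_target = FALSE))
    if (d + step > ceiling)
      return(list(matches = m, threshold = d, under_target = TRUE))
    d <- d + step
  }
}

#' Write matches as TSV
#'
#' Columns: rank, fragment_id, pdb_code, chain, start_residue, rmsd (6
#' decimals); `start_residue` is the residue number with any insertion code
#' appended.
#'
#' @param matches a `fragment_matches` data frame.
#' @param path output file, or `""` for standard output.
#' @return `path`, invisibly.
#' @export
write_matches_tsv <- function(matches, path = "") {
  out <- data.frame(
    rank = seq_len(nrow(matches)),
    fragment_id = matches$fragment_id,
    pdb_code = matches$pdb_code,
    chain = matches$chain,
    start_residue = paste0(matches$start_resno, trimws(matches$start_icode)),
    rmsd = sprintf("%.6f", matches$rmsd),
    stringsAsFactors = FALSE)
  write.table(out, file = path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
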