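# One-versus-many backbone RMSD ranking.  A thin facade over the shared QCP
# kernel that needs no database or index: for one-off tasks, extracting
# fragments and ranking them directly is fast enough to skip indexing
# entirely.

#' Rank many fragments against one query
#'
#' Computes the (optionally masked) superposition RMSD of the query against
#' every pool member and returns the pool sorted ascending by RMSD, ties
#' broken by pool ordinal.
#'
#' @param query a `fragment` or (4*L) x 3 backbone coordinate matrix.
#' @param pool list of `fragment` objects (or coordinate matrices) of a
#'   length compatible with the query.
#' @param mask optional 1-based residue positions (>= 3) used for the
#'   distance; e.g. anchors-only ranking for loop grafting.
#' @return A data frame with columns `ordinal` (1-based pool position),
#'   `rmsd`, and provenance columns when the pool members carry them.
#' @export
rank_one_vs_many <- function(query, pool, mask = NULL) {
  qco <- if (inherits(query, "fragment")) query$coords else query
  if (!is.matrix(qco) || ncol(qco) != 3L)
    fp_data_error("query must be a fragment or an N x 3 coordinate matrix")
  L <- nrow(qco) %/% 4L
  rows <- if (is.null(mask)) seq_len(nrow(qco)) else mask_atom_rows(mask, L)
  n <- length(pool)
  if (n == 0L)
    return(data.frame(ordinal = integer(0), pdb_code = character(0),
                      chain = character(0), start_resno = integer(0),
                      rmsd = numeric(0), stringsAsFactors = FALSE))
  coords <- vector("list", n)
  for (i in seq_len(n)) {
    co <- if (inherits(pool[[i]], "fragment")) pool[[i]]$coords else pool[[i]]
    if (!is.matrix(co) || nrow(co) != nrow(qco))
      fp_data_error("pool member %d is incompatible with the query (%s vs %d atoms)",
                    i, if (is.matrix(co)) nrow(co) else "non-matrix", nrow(qco))
    coords[[i]] <- co[rows, , drop = FALSE]
  }
  rmsd <- qcp_rmsd_one_vs_many(qco[rows, , drop = FALSE],
                               coords_pool_matrix(coords))
  is_frag <- vapply(pool, inherits, logical(1), what = "fragment")
  out <- data.frame(
    ordinal = seq_len(n),
    pdb_code = ifelse(is_frag,
                      vapply(pool, function(f) if (inherits(f, "fragment")) f$pdb_code else NA_character_, character(1)),
                      NA_character_),
    chain = ifelse(is_frag,
                   vapply(pool, function(f) if (inherits(f, "fragment")) f$chain else NA_character_, character(1)),
                   NA_character_),
    start_resno = ifelse(is_frag,
                         vapply(pool, function(f) if (inherits(f, "fragment")) f$resno[1] else NA_integer_, integer(1)),
                         NA_integer_),
    rmsd = rmsd,
    stringsAsFactors = FALSE)
  out <- out[order(out$rmsd, out$ordinal), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank pool fragments from files against a query PDB
#'
#' The pool is either a directory / vector of PDB files (each file read as
#' one fragment) or a binary fragment database; the binary route skips text
#' parsing entirely, which is why it is the fast path for large pools.
#'
#' @param query_pdb path to a PDB file holding the (continuous) query
#'   fragment.
#' @param pool_pdbs character vector of PDB file paths (one fragment each);
#'   mutually exclusive with `pool_db`.
#' @param pool_db path to a binary database from [write_binary()].
#' @param mask optional 1-based residue positions for the distance.
#' @param out optional TSV output path (`""` for standard output).
#' @return The ranking data frame of [rank_one_vs_many()], invisibly when
#'   `out` is given.
#' @export
rank_from_files <- function(query_pdb, pool_pdbs = NULL, pool_db = NULL,
                            mask = NULL, out = NULL) {
  if (is.null(pool_pdbs) == is.null(pool_db))
    fp_usage_error("exactly one of pool_pdbs / pool_db is required")
  query <- fragment_from_structure(parse_pdb(query_pdb))
  pool <- if (!is.null(pool_db)) {
    read_binary(pool_db)$fragments
  } else {
    lapply(pool_pdbs, function(p)
      tryCatch(fragment_from_structure(parse_pdb(p)),
               error = function(e)
                 fp_data_error("failed to read pool file %s: %s",
                               p, conditionMessage(e))))
  }
  ranking <- rank_one_vs_many(query, pool, mask = mask)
  if (!is.null(out)) {
    tsv <- data.frame(rank = seq_len(nrow(ranking)), ranking,
                      stringsAsFactors = FALSE)
    tsv$rmsd <- sprintf("%.6f", ranking$rmsd)
    write.table(tsv, file = out, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(ranking))
  }
  ranking
}
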