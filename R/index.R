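# Reference-fragment selection and the per-reference RMSD index.
#
# The index stores, for each reference fragment r_j, the RMSD of every
# database fragment to r_j as a table sorted ascending by distance.  Because
# superposition RMSD obeys the triangle inequality, a query q with threshold
# d_q can only match fragments whose stored distance to r_j lies in
# [d(q, r_j) - d_q, d(q, r_j) + d_q]; the sorted tables answer that interval
# question by binary search.

# distances are stored at float32 precision; route values through a float32
# round trip so stored and recomputed distances compare exactly
as_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4, endian = "little"),
          "double", n = length(x), size = 4, endian = "little")
}

# outward safety margin added to pruning intervals at query time, covering
# float32 storage rounding; refinement removes any false positives
INDEX_EPS <- 1e-4

#' Build a reference set
#'
#' Wraps user-chosen reference fragments for [build_index()].
#'
#' @param references list of `fragment` objects (any n >= 1).
#' @param method provenance tag: `"given"`, `"random"` or `"far-apart"`.
#' @param seed seed used when the set was drawn, `NA` otherwise.
#' @return An object of class `reference_set`.
#' @export
reference_set <- function(references, method = "given", seed = NA_integer_) {
  if (length(references) < 1L) fp_data_error("need at least 1 reference fragment")
  Ls <- vapply(references, fragment_length, integer(1))
  if (length(unique(Ls)) != 1L)
    fp_data_error("reference fragments must share one length")
  structure(list(references = references, method = method,
                 seed = as.integer(seed)),
            class = "reference_set")
}

#' Select three far-apart reference fragments
#'
#' Implements the far-apart heuristic: pick a fragment f_i uniformly at
#' random (seeded), compute its RMSD to every database fragment, and take the
#' furthest fragment as f_j and the fragment at the median of that distance
#' list as f_k.  Three mutually distant references prune the search space
#' much better than one.  With even counts the lower median (element at
#' 0-based index `floor((n-1)/2)` of the sorted list) is used; ties are
#' broken by the lowest fragment id.  Deterministic given `(db, seed)`.
#'
#' @param db a `fragment_db` with at least 3 fragments.
#' @param seed integer seed for the random first pick.
#' @return A `reference_set` of 3 fragments (f_i, f_j, f_k) tagged
#'   `"far-apart"`.
#' @export
select_references <- function(db, seed) {
  if (db$n < 3L) fp_data_error("reference selection needs >= 3 fragments, have %d", db$n)
  i <- with_seed(seed, sample.int(db$n, 1L)) - 1L   # 0-based id
  fi <- db$fragments[[i + 1L]]
  d <- qcp_rmsd_one_vs_many(fi$coords, db_pool_matrix(db))
  j <- which.max(d) - 1L                            # first max = lowest id
  ord <- order(d, seq_along(d))                     # ties -> lowest id
  k <- ord[(db$n - 1L) %/% 2L + 1L] - 1L            # lower median, 0-based
  reference_set(list(fi, db$fragments[[j + 1L]], db$fragments[[k + 1L]]),
                method = "far-apart", seed = seed)
}

#' Build the per-reference RMSD index
#'
#' Computes the superposition RMSD of every database fragment to every
#' reference and stores each reference's distances sorted ascending
#' (float32).  The index records the database content hash so that querying
#' with a mismatched database is rejected.
#'
#' @param db a `fragment_db`.
#' @param refs a `reference_set`, or a plain list of `fragment` objects.
#' @return An object of class `rmsd_index`.
#' @export
build_index <- function(db, refs) {
  if (!inherits(refs, "reference_set")) refs <- reference_set(refs)
  if (fragment_length(refs$references[[1L]]) != db$fragment_length)
    fp_data_error("reference length %d != database fragment length %d",
                  fragment_length(refs$references[[1L]]), db$fragment_length)
  pool <- db_pool_matrix(db)
  tables <- lapply(refs$references, function(r) {
    d <- as_float32(qcp_rmsd_one_vs_many(r$coords, pool))
    ord <- order(d, seq_along(d))
    list(dist = d[ord], id = ord - 1L)
  })
  structure(list(db_hash = db$content_hash,
                 fragment_length = db$fragment_length,
                 n_fragments = db$n,
                 refs = refs,
                 tables = tables),
            class = "rmsd_index")
}

#' @export
print.rmsd_index <- function(x, ...) {
  cat(sprintf("<rmsd_index: %d references over %d fragments of length %d (%s)>\n",
              length(x$tables), x$n_fragments, x$fragment_length,
              x$refs$method))
  invisible(x)
}

check_index_db <- function(index, db) {
  if (!inherits(index, "rmsd_index")) fp_data_error("not an rmsd_index")
  if (!identical(index$db_hash, db$content_hash))
    fp_data_error("index/database mismatch: index was built for a different database (hash %s != %s)",
                  index$db_hash, db$content_hash)
  invisible(TRUE)
}

#' Range query on one reference table
#'
#' Returns exactly the fragment ids whose stored distance to the chosen
#' reference lies in the closed interval `[d_inf, d_sup]`, by binary search
#' on the sorted table.
#'
#' @param index an `rmsd_index`.
#' @param ref_ordinal 1-based reference number.
#' @param d_inf,d_sup interval bounds (Angstrom), `d_inf <= d_sup`.
#' @return Sorted integer vector of 0-based fragment ids.
#' @export
range_candidates <- function(index, ref_ordinal, d_inf, d_sup) {
  ref_ordinal <- as.integer(ref_ordinal)
  if (is.na(ref_ordinal) || ref_ordinal < 1L || ref_ordinal > length(index$tables))
    fp_data_error("unknown reference ordinal %s (index has %d references)",
                  as.character(ref_ordinal), length(index$tables))
  if (d_inf > d_sup) fp_data_error("d_inf (%g) > d_sup (%g)", d_inf, d_sup)
  tab <- index$tables[[ref_ordinal]]
  lo <- findInterval(d_inf, tab$dist, left.open = TRUE) + 1L  # first >= d_inf
  hi <- findInterval(d_sup, tab$dist)                        # last  <= d_sup
  if (lo > hi) return(integer(0))
  sort(tab$id[lo:hi])
}

# ---- persistence ("FRGX") --------------------------------------------------

#' Write an RMSD index to disk
#' @param index an `rmsd_index`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_index <- function(index, path) {
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(IDX_MAGIC, con)
  w_u16(con, IDX_VERSION)
  w_lpstr(con, index$db_hash)
  w_u32(con, index$fragment_length)
  w_u32(con, index$n_fragments)
  w_lpstr(con, index$refs$method)
  w_u32(con, ifelse(is.na(index$refs$seed), -1L, index$refs$seed))
  w_u32(con, length(index$tables))
  for (r in index$refs$references) w_fragment(con, r)
  for (tab in index$tables) {
    w_f32(con, tab$dist)
    w_u32(con, tab$id)
  }
  invisible(path)
}

#' Read an RMSD index written by [write_index()]
#' @param path path to an index file.
#' @return The `rmsd_index`.
#' @export
read_index <- function(path) {
  if (!file.exists(path)) fp_data_error("index file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- r_raw(con, 4, "magic")
  if (!identical(magic, IDX_MAGIC))
    fp_binary_error("fragpick_bad_magic", "not an RMSD index (bad magic bytes): %s", path)
  ver <- r_expect(con, "version", 1, 2, "header")
  if (ver != IDX_VERSION)
    fp_binary_error("fragpick_bad_version",
                    "unsupported index format version %d (expected %d)", ver, IDX_VERSION)
  db_hash <- r_lpstr(con, "header")
  L <- r_expect(con, "L", 1, 4, "header")
  n <- r_expect(con, "n", 1, 4, "header")
  method <- r_lpstr(con, "header")
  seed <- r_expect(con, "seed", 1, 4, "header")
  if (seed < 0) seed <- NA_integer_
  nref <- r_expect(con, "nref", 1, 4, "header")
  refs <- vector("list", nref)
  for (i in seq_len(nref)) refs[[i]] <- r_fragment(con, L, sprintf("reference %d", i))
  tables <- vector("list", nref)
  for (i in seq_len(nref)) {
    d <- r_expect(con, "dist", n, 4, sprintf("table %d", i), type = "double")
    id <- r_expect(con, "ids", n, 4, sprintf("table %d", i))
    tables[[i]] <- list(dist = d, id = id)
  }
  structure(list(db_hash = db_hash, fragment_length = L, n_fragments = n,
                 refs = reference_set(refs, method = method, seed = seed),
                 tables = tables),
            class = "rmsd_index")
}
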