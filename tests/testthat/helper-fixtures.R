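# Shared builders and independent oracles.  Everything here is deterministic
# under explicit seeds; no fixture files are read from disk.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_point_set <- function(n, scale = 5) {
  matrix(rnorm(3 * n, sd = scale), ncol = 3)
}

random_rigid_copy <- function(coords) {
  coords %*% t(fragpick:::random_rotation()) +
    matrix(rnorm(3, sd = 10), nrow = nrow(coords), ncol = 3, byrow = TRUE)
}

# mixed decoy database: decoys of several helix windows at several noise
# scales, with varied synthetic pdb codes and random sequences, so that
# provenance and regex filters bite
make_test_db <- function(n_total, L = 9, seed = 1,
                         sigmas = c(0.2, 0.5, 1.0, 2.0)) {
  base_db <- extract_fragments(make_helix_chain(L + 8, pdb_code = "BASE"),
                               length = L)
  per <- ceiling(n_total / length(sigmas))
  set.seed(seed)
  seqs <- replicate(64, paste(sample(AA20, L, replace = TRUE), collapse = ""))
  codes <- sprintf("S%03d", 0:39)
  frags <- list()
  for (i in seq_along(sigmas)) {
    frags <- c(frags,
               make_decoy_pool(get_fragment(base_db, i - 1L), per, sigmas[i],
                               seed = seed + i, pdb_codes = codes,
                               sequences = seqs))
  }
  fragment_db(frags[seq_len(n_total)])
}

# independent linear-scan oracle for query_fragments/query_masked: pairwise
# qcp_rmsd to every fragment, filters, threshold, sort, limits
oracle_query <- function(db, sq) {
  ids <- seq_len(db$n) - 1L
  rows <- if (is.null(sq$mask)) NULL else fragpick:::mask_atom_rows(sq$mask, sq$length)
  rmsd <- vapply(db$fragments, function(f) {
    if (is.null(rows)) qcp_rmsd(sq$coords, f$coords)
    else qcp_rmsd(sq$coords[rows, , drop = FALSE],
                  f$coords[rows, , drop = FALSE])
  }, numeric(1))
  keep <- rep(TRUE, db$n)
  if (!is.null(sq$exclude_pdb)) {
    codes <- vapply(db$fragments, function(f) f$pdb_code, character(1))
    keep <- keep & !(codes %in% sq$exclude_pdb)
  }
  if (!is.null(sq$seq_regex)) {
    seqs <- vapply(db$fragments, function(f) f$sequence, character(1))
    keep <- keep & grepl(paste0("^(?:", sq$seq_regex, ")$"), seqs, perl = TRUE)
  }
  keep <- keep & rmsd <= sq$threshold
  ids <- ids[keep]
  rmsd <- rmsd[keep]
  if (!is.null(sq$limit_mode) && sq$limit_mode == "first" &&
      length(ids) > sq$limit_n) {
    sel <- order(ids)[seq_len(sq$limit_n)]
    ids <- ids[sel]; rmsd <- rmsd[sel]
  }
  ord <- order(rmsd, ids)
  out <- data.frame(fragment_id = ids[ord], rmsd = rmsd[ord])
  if (!is.null(sq$limit_mode) && sq$limit_mode == "best")
    out <- utils::head(out, sq$limit_n)
  rownames(out) <- NULL
  out
}

tempfile_with <- function(raw_bytes) {
  p <- tempfile()
  writeBin(raw_bytes, p)
  p
}

expect_matches_equal_oracle <- function(m, o) {
  expect_identical(m$fragment_id, as.integer(o$fragment_id))
  expect_equal(m$rmsd, o$rmsd, tolerance = 1e-12)
}
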