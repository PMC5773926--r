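# Query engine: oracle equivalence of the pruned pipeline, filters, limits,
# auto-widening and the masked (gapped) path.

query_db <- make_test_db(250, L = 9, seed = 31)
query_idx <- build_index(query_db, select_references(query_db, seed = 31))

test_that("querying with a database fragment at d_q = 0 returns it first", {
  for (id in c(0L, 17L, 133L, 249L)) {
    sq <- structural_query(get_fragment(query_db, id), threshold = 0)
    m <- query_fragments(query_db, query_idx, sq)
    expect_gte(nrow(m), 1)
    expect_identical(m$fragment_id[1], id)
    expect_equal(m$rmsd[1], 0)
  }
})

test_that("a threshold beyond the database diameter returns everything, ranked", {
  sq <- structural_query(get_fragment(query_db, 5L), threshold = 1e4)
  m <- query_fragments(query_db, query_idx, sq)
  expect_equal(nrow(m), query_db$n)
  expect_false(is.unsorted(m$rmsd))
  expect_matches_equal_oracle(m, oracle_query(query_db, sq))
})

test_that("query output is membership- and order-identical to the oracle", {
  set.seed(32)
  regexes <- c(NA, ".*", "[AC].*", ".*G", "[^W]{9}", "A.{8}|.{8}A")
  for (case in 1:40) {
    q <- get_fragment(query_db, sample(query_db$n, 1) - 1L)$coords +
      matrix(rnorm(108, sd = runif(1, 0.05, 2)), ncol = 3)
    rx <- sample(regexes, 1)
    excl <- if (runif(1) < 0.5) sample(sprintf("S%03d", 0:39), 8) else NULL
    sq <- structural_query(q, threshold = runif(1, 0.1, 5),
                           seq_regex = if (is.na(rx)) NULL else rx,
                           exclude_pdb = excl)
    m <- query_fragments(query_db, query_idx, sq)
    expect_matches_equal_oracle(m, oracle_query(query_db, sq))
    expect_lte(attr(m, "n_candidates"), query_db$n)
  }
})

test_that("match sets are nested as the threshold grows", {
  q <- get_fragment(query_db, 40L)$coords +
    matrix(rnorm(108, sd = 0.8), ncol = 3)
  prev <- integer(0)
  for (d in c(0.5, 1, 2, 4)) {
    m <- query_fragments(query_db, query_idx,
                         structural_query(q, threshold = d))
    expect_true(all(prev %in% m$fragment_id))
    prev <- m$fragment_id
  }
})

test_that("filters commute and compose", {
  q <- get_fragment(query_db, 3L)
  base <- structural_query(q, threshold = 6)
  both <- structural_query(q, threshold = 6, seq_regex = "[^W].*",
                           exclude_pdb = c("S001", "S002"))
  m_base <- query_fragments(query_db, query_idx, base)
  m_both <- query_fragments(query_db, query_idx, both)
  codes <- vapply(m_both$fragment_id, function(i)
    get_fragment(query_db, i)$pdb_code, character(1))
  expect_false(any(codes %in% c("S001", "S002")))
  # filtered result = unfiltered result minus filtered-out ids (same order)
  keep <- vapply(m_base$fragment_id, function(i) {
    f <- get_fragment(query_db, i)
    !(f$pdb_code %in% c("S001", "S002")) &&
      grepl("^(?:[^W].*)$", f$sequence, perl = TRUE)
  }, logical(1))
  expect_identical(m_both$fragment_id, m_base$fragment_id[keep])
})

test_that("an invalid regex names the offending pattern", {
  sq <- structural_query(get_fragment(query_db, 0L), threshold = 3,
                         seq_regex = "([A")
  expect_error(query_fragments(query_db, query_idx, sq),
               "invalid regular expression.*\\(\\[A")
})

test_that("N-best and N-first limits match their oracles", {
  set.seed(33)
  q <- get_fragment(query_db, 60L)$coords +
    matrix(rnorm(108, sd = 0.6), ncol = 3)
  full <- query_fragments(query_db, query_idx,
                          structural_query(q, threshold = 4))
  expect_gt(nrow(full), 10)

  best5 <- query_fragments(query_db, query_idx,
                           structural_query(q, threshold = 4,
                                            limit_mode = "best", limit_n = 5))
  expect_identical(best5$fragment_id, full$fragment_id[1:5])

  first5 <- query_fragments(query_db, query_idx,
                            structural_query(q, threshold = 4,
                                             limit_mode = "first", limit_n = 5))
  # the 5 passing candidates with smallest fragment ids, re-sorted by rmsd
  ids5 <- sort(full$fragment_id)[1:5]
  sub <- full[full$fragment_id %in% ids5, ]
  expect_identical(first5$fragment_id, sub$fragment_id[order(sub$rmsd, sub$fragment_id)])

  # apply_limit on an existing list agrees, and N >= length is the identity
  expect_identical(apply_limit(full, "best", 5)$fragment_id, best5$fragment_id)
  expect_identical(apply_limit(full, "first", 5)$fragment_id, first5$fragment_id)
  expect_identical(apply_limit(full, "best", nrow(full) + 10), full)
})

test_that("auto-widen equals a fresh query at the final threshold", {
  set.seed(34)
  q <- get_fragment(query_db, 80L)$coords +
    matrix(rnorm(108, sd = 0.5), ncol = 3)
  sq <- structural_query(q, threshold = 0.05,
                         auto_widen = list(target = 12, step = 0.4, ceiling = 8))
  res <- query_auto_widen(query_db, query_idx, sq)
  expect_false(res$under_target)
  expect_gte(nrow(res$matches), 12)
  fresh <- query_fragments(query_db, query_idx,
                           structural_query(q, threshold = res$threshold))
  expect_identical(res$matches$fragment_id, fresh$fragment_id)
  expect_equal(res$matches$rmsd, fresh$rmsd)
  # widening was actually needed
  expect_gt(res$threshold, 0.05)

  # unreachable target: under-target flag, not an error
  res2 <- query_auto_widen(query_db, query_idx,
                           structural_query(q, threshold = 0.05,
                                            auto_widen = list(target = query_db$n + 1L,
                                                              step = 2, ceiling = 6)))
  expect_true(res2$under_target)
  expect_lt(nrow(res2$matches), query_db$n + 1L)

  # target already met at the initial threshold: threshold unchanged
  res3 <- query_auto_widen(query_db, query_idx,
                           structural_query(q, threshold = 5,
                                            auto_widen = list(target = 1,
                                                              step = 0.25, ceiling = 10)))
  expect_identical(res3$threshold, 5)
})

test_that("a full mask reproduces the unmasked query", {
  q <- get_fragment(query_db, 90L)$coords +
    matrix(rnorm(108, sd = 0.4), ncol = 3)
  plain <- query_fragments(query_db, query_idx,
                           structural_query(q, threshold = 3))
  masked <- query_fragments(query_db, NULL,
                            structural_query(q, threshold = 3, mask = 1:9))
  expect_identical(masked$fragment_id, plain$fragment_id)
  expect_equal(masked$rmsd, plain$rmsd, tolerance = 1e-12)
})

test_that("anchor-masked query retrieves a planted loop-closure match", {
  L <- 13
  base_db <- extract_fragments(make_helix_chain(L + 6, pdb_code = "SCAF"),
                               length = L)
  query <- get_fragment(base_db, 2L)
  # planted fragment: same anchor residues (1-3, 11-13), rebuilt middle
  planted <- query
  planted$pdb_code <- "PLNT"
  mid_rows <- fragpick:::mask_atom_rows(4:10, L)
  planted$coords[mid_rows, ] <- planted$coords[mid_rows, ] +
    matrix(rnorm(length(mid_rows) * 3, sd = 1.5), ncol = 3)
  planted$coords <- random_rigid_copy(planted$coords)   # scramble the pose
  decoys <- make_decoy_pool(query, 60, 1.0, seed = 35)
  db <- fragment_db(c(decoys, list(planted)))

  mask <- c(1:3, (L - 2):L)
  sq <- structural_query(query, threshold = 0.5, mask = mask)
  m <- query_masked(db, sq)
  expect_identical(m$fragment_id[1], db$n - 1L)   # the planted fragment
  expect_lt(m$rmsd[1], 1e-6)
  expect_matches_equal_oracle(m, oracle_query(db, sq))

  # whole-fragment distance to the planted match is NOT ~0 (middle rebuilt)
  expect_gt(qcp_rmsd(query$coords, get_fragment(db, db$n - 1L)$coords), 0.5)
})

test_that("masked queries validate their mask", {
  q <- get_fragment(query_db, 0L)
  expect_error(structural_query(q, 1, mask = c(1, 2)), "at least 3")
  expect_error(structural_query(q, 1, mask = c(1, 2, 10)), "1..9")
  expect_error(query_masked(query_db, structural_query(q, 1)), "needs a mask")
})

test_that("length mismatches between query and database are rejected", {
  short_db <- make_test_db(20, L = 6, seed = 36)
  sq <- structural_query(get_fragment(query_db, 0L), threshold = 1)
  expect_error(query_fragments(short_db, query_idx, sq), "length")
})
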