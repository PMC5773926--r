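# Extraction from parsed structures, PDB text round trips, binary
# persistence, and sampling.

test_that("window counts follow sum(max(0, m - L + 1)) over runs", {
  s <- make_helix_chain(10)
  expect_equal(extract_fragments(s, 3)$n, 8)
  expect_equal(extract_fragments(s, 10)$n, 1)
  expect_warning(db11 <- extract_fragments(s, 11), "no fragments")
  expect_equal(db11$n, 0)

  two_runs <- make_break_chain(c(5, 5), gap = 4.0)
  expect_equal(extract_fragments(two_runs, 4)$n, 4)       # 2 + 2
  expect_equal(extract_fragments(two_runs, 5)$n, 2)
  continuous <- make_break_chain(c(5, 5), gap = 1.9)      # below 2.0 cutoff
  expect_equal(extract_fragments(continuous, 4)$n, 7)
})

test_that("a missing backbone atom splits the chain into runs", {
  s <- delete_atoms(make_helix_chain(10), resno = 5, names = "O")
  db <- extract_fragments(s, 3)
  expect_equal(db$n, 5)                                   # runs of 4 and 5
  starts <- vapply(db$fragments, function(f) f$resno[1], integer(1))
  expect_identical(starts, c(1L, 2L, 6L, 7L, 8L))

  tiny <- delete_atoms(make_helix_chain(3), resno = 2, names = "O")
  expect_warning(db0 <- extract_fragments(tiny, 3), "no fragments")
  expect_equal(db0$n, 0)
})

test_that("windows never span a geometric break even when numbering lies", {
  # numbering jumps at the break AND the geometry is broken (4.2 A)
  s <- make_break_chain(c(6, 6), gap = 4.2, numbering_jump = 1L)
  db <- extract_fragments(s, 4)
  junction_free <- vapply(db$fragments, function(f) all(diff(f$resno) == 1L),
                          logical(1))
  expect_true(all(junction_free))
  expect_equal(db$n, 6)                                   # 3 + 3
  # same numbering jump but continuous geometry: numbering must NOT split
  s2 <- make_break_chain(c(6, 6), gap = 1.329, numbering_jump = 7L)
  expect_equal(extract_fragments(s2, 4)$n, 9)             # one run of 12
})

test_that("extraction equals independent window enumeration on a fixture", {
  s <- make_helix_chain(14, jitter = 0.05, seed = 42)
  L <- 5
  db <- extract_fragments(s, L)
  # independent enumeration straight off the atom table
  at <- s$atoms
  expected <- list()
  for (start in 1:(14 - L + 1)) {
    rows <- at[at$resno %in% start:(start + L - 1), ]
    expected[[length(expected) + 1]] <- list(
      start = start,
      seq = paste(fragpick:::AA3_TO_1[rows$resname[rows$name == "CA"]],
                  collapse = ""),
      coords = cbind(rows$x, rows$y, rows$z))
  }
  expect_equal(db$n, length(expected))
  for (i in seq_along(expected)) {
    f <- db$fragments[[i]]
    expect_equal(f$resno[1], expected[[i]]$start)
    expect_equal(f$sequence, expected[[i]]$seq)
    expect_equal(f$coords, expected[[i]]$coords, tolerance = 1e-12)
  }
})

test_that("parser handles altlocs, MSE, multi-model and insertion codes", {
  lines <- c(
    "MODEL        1",
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  CA BALA A   1      99.000  99.000  99.000  0.50  0.00           C",
    "ATOM      4  C   ALA A   1      12.759   7.092  -4.937  1.00  0.00           C",
    "ATOM      5  O   ALA A   1      13.221   7.768  -5.863  1.00  0.00           O",
    "HETATM    6  N   MSE A   2      13.209   7.193  -3.694  1.00  0.00           N",
    "HETATM    7  CA  MSE A   2      14.274   8.145  -3.380  1.00  0.00           C",
    "HETATM    8  C   MSE A   2      15.613   7.678  -3.953  1.00  0.00           C",
    "HETATM    9  O   MSE A   2      15.717   6.541  -4.411  1.00  0.00           O",
    "HETATM   10  O   HOH A 101      20.000  20.000  20.000  1.00  0.00           O",
    "ATOM     11  N   GLY A   2A     16.000   8.000  -3.000  1.00  0.00           N",
    "ATOM     12  CA  GLY A   2A     16.500   8.500  -2.500  1.00  0.00           C",
    "ATOM     13  C   GLY A   2A     17.000   9.000  -2.000  1.00  0.00           C",
    "ATOM     14  O   GLY A   2A     17.500   9.500  -1.500  1.00  0.00           O",
    "ENDMDL",
    "MODEL        2",
    "ATOM     15  N   TRP A   9      99.000  99.000  99.000  1.00  0.00           N",
    "ENDMDL")
  s <- parse_pdb(text = lines, pdb_code = "TST1")
  expect_false(any(s$atoms$altloc == "B"))
  expect_false(any(s$atoms$resno == 9))       # model 2 dropped
  res <- fragpick:::eligible_residues(s)
  expect_identical(res$aa, c("A", "M", "G"))  # water skipped, MSE -> M
  expect_identical(res$icode, c(" ", " ", "A"))
})

test_that("fragment -> PDB text -> fragment round trips at 3 decimals", {
  db <- extract_fragments(make_helix_chain(8, jitter = 0.08, seed = 3), 3)
  f <- get_fragment(db, 2L)
  f$icode[2] <- "A"                           # exercise insertion codes
  lines <- fragment_to_pdb(f)
  expect_length(lines, 14)                    # 12 ATOM + TER + END
  expect_equal(sum(startsWith(lines, "ATOM")), 12)
  expect_identical(substr(lines[5], 27, 27), "A")   # icode in column 27
  expect_identical(substr(lines[5], 22, 22), "A")   # chain in column 22
  back <- fragment_from_structure(parse_pdb(text = lines, pdb_code = f$pdb_code))
  expect_equal(back$coords, round(f$coords, 3), tolerance = 1e-9)
  expect_identical(back$sequence, f$sequence)
  expect_identical(back$resno, f$resno)
  expect_identical(back$icode, f$icode)
})

test_that("binary round trip is lossless field by field", {
  db <- make_test_db(100, L = 6, seed = 7)
  db$fragments[[4]]$icode[2] <- "B"           # non-trivial insertion code
  db$fragments[[4]]$resno <- c(7L, 8L, 8L, 9L, 12L, 13L)  # odd numbering
  db <- fragment_db(db$fragments)             # rebuild hash
  path <- tempfile(fileext = ".bin")
  write_binary(db, path)
  back <- read_binary(path)
  expect_identical(back$fragment_length, db$fragment_length)
  expect_identical(back$n, db$n)
  expect_identical(back$manifest, db$manifest)
  expect_identical(back$params, db$params)
  expect_identical(back$content_hash, db$content_hash)
  for (i in seq_len(db$n)) {
    f <- db$fragments[[i]]; g <- back$fragments[[i]]
    expect_identical(g[c("fragment_id", "pdb_code", "chain", "resno",
                         "icode", "sequence")],
                     f[c("fragment_id", "pdb_code", "chain", "resno",
                         "icode", "sequence")])
    expect_lt(max(abs(g$coords - f$coords)), 1e-4)  # float32 ~ PDB precision
  }
})

test_that("empty database round trips", {
  s <- make_helix_chain(4)
  expect_warning(db <- extract_fragments(s, 5), "no fragments")
  path <- tempfile(fileext = ".bin")
  write_binary(db, path)
  back <- read_binary(path)
  expect_equal(back$n, 0)
  expect_identical(back$fragment_length, 5L)
  expect_identical(back$manifest, db$manifest)
})

test_that("binary reader raises distinct, identifiable errors", {
  db <- make_test_db(10, L = 5, seed = 8)
  path <- tempfile(fileext = ".bin")
  write_binary(db, path)

  full <- readBin(path, "raw", file.size(path))
  bad <- full; bad[1:4] <- charToRaw("NOPE")
  p1 <- tempfile(); writeBin(bad, p1)
  expect_error(read_binary(p1), "magic", class = "fragpick_bad_magic")

  badv <- full; badv[5:6] <- as.raw(c(99, 0))
  p2 <- tempfile(); writeBin(badv, p2)
  expect_error(read_binary(p2), "version", class = "fragpick_bad_version")

  # cut inside the last fragment: error must name the failing ordinal
  p3 <- tempfile(); writeBin(full[1:(length(full) - 5)], p3)
  err <- expect_error(read_binary(p3), class = "fragpick_truncated_stream")
  expect_match(conditionMessage(err), "fragment 9 of 10")
})

test_that("random fragment sampling is uniform-without-replacement and seeded", {
  db <- make_test_db(40, L = 5, seed = 9)
  expect_identical(get_random_fragments(db, 0, 1), list())
  all40 <- get_random_fragments(db, 40, 5)
  expect_setequal(vapply(all40, function(f) f$fragment_id, integer(1)),
                  0:39)
  a <- get_random_fragments(db, 7, 123)
  b <- get_random_fragments(db, 7, 123)
  expect_identical(a, b)
  expect_error(get_random_fragments(db, 41, 1), "cannot sample")
  # RNG state of the caller untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(get_random_fragments(db, 3, 7)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("fragments are found by id and by provenance", {
  db <- extract_fragments(make_helix_chain(10, pdb_code = "HLX9"), 4)
  f <- get_fragment(db, 3L)
  expect_identical(f$fragment_id, 3L)
  g <- find_fragment(db, "hlx9", "A", start_resno = 4)
  expect_identical(g, f)
  expect_error(get_fragment(db, 99L), "outside")
  expect_error(find_fragment(db, "HLX9", "B", 1), "no fragment")
})

test_that("extraction is deterministic: same inputs, byte-identical binaries", {
  p1 <- tempfile(); p2 <- tempfile()
  write_binary(extract_fragments(make_helix_chain(12, jitter = 0.05, seed = 4), 5), p1)
  write_binary(extract_fragments(make_helix_chain(12, jitter = 0.05, seed = 4), 5), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})
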