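# Deterministic synthetic-structure generators.  Every other module is
# testable on these without downloading a single real structure: an ideal
# alpha-helical backbone built by internal-coordinate (NeRF) placement with
# canonical bond lengths and angles, chains with deliberate geometric
# breaks, and jittered decoy pools at controlled distance scales.

# canonical backbone internal coordinates (Angstrom / degrees)
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
BOND_C_O <- 1.231
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.8
HELIX_PHI <- -57
HELIX_PSI <- -47
OMEGA_TRANS <- 180

CYCLE_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

deg <- function(x) x * pi / 180

# place atom d given a-b-c, bond |c-d|, angle b-c-d, torsion a-b-c-d (NeRF)
nerf_place <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- deg(angle_deg); tor <- deg(torsion_deg)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# backbone coordinates for n residues at fixed (phi, psi, omega):
# (4n) x 3 matrix, residue-major N, CA, C, O
build_backbone <- function(n, phi = HELIX_PHI, psi = HELIX_PSI,
                           omega = OMEGA_TRANS) {
  co <- matrix(NA_real_, nrow = 4L * n, ncol = 3L)
  N <- c(0, 0, 0)
  CA <- c(BOND_N_CA, 0, 0)
  virt <- c(-0.5, -1.2, 0)               # virtual pre-N atom for residue 1
  C <- nerf_place(virt, N, CA, BOND_CA_C, ANGLE_N_CA_C, phi)
  for (i in seq_len(n)) {
    co[4L * (i - 1L) + 1L, ] <- N
    co[4L * (i - 1L) + 2L, ] <- CA
    co[4L * (i - 1L) + 3L, ] <- C
    co[4L * (i - 1L) + 4L, ] <- nerf_place(N, CA, C, BOND_C_O,
                                           ANGLE_CA_C_O, psi + 180)
    if (i == n) break
    Nn <- nerf_place(N, CA, C, BOND_C_N, ANGLE_CA_C_N, psi)
    CAn <- nerf_place(CA, C, Nn, BOND_N_CA, ANGLE_C_N_CA, omega)
    Cn <- nerf_place(C, Nn, CAn, BOND_CA_C, ANGLE_N_CA_C, phi)
    N <- Nn; CA <- CAn; C <- Cn
  }
  co
}

backbone_structure <- function(coords, n, chain_id, sequence, pdb_code,
                               resno = seq_len(n)) {
  seq1 <- strsplit(sequence, "")[[1]]
  atoms <- data.frame(
    record = "ATOM",
    name = rep(BACKBONE_ATOMS, n),
    altloc = " ",
    resname = rep(unname(AA1_TO_3[seq1]), each = 4L),
    chain = chain_id,
    resno = rep(as.integer(resno), each = 4L),
    icode = " ",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    stringsAsFactors = FALSE)
  structure(list(pdb_code = toupper(pdb_code), source = "<synthetic>",
                 atoms = atoms),
            class = "pdb_structure")
}

resolve_sequence <- function(sequence, n) {
  if (is.null(sequence))
    sequence <- paste(CYCLE_AA[(seq_len(n) - 1L) %% length(CYCLE_AA) + 1L],
                      collapse = "")
  if (nchar(sequence) != n)
    fp_data_error("sequence length %d != residue count %d", nchar(sequence), n)
  sequence
}

#' Generate an ideal alpha-helical chain
#'
#' Builds an n-residue backbone at canonical helical torsions
#' (phi = -57, psi = -47, omega = 180 degrees) with standard bond geometry,
#' optionally perturbed by seeded Gaussian coordinate jitter.  With jitter
#' sigma <= 0.1 A the chain always passes the extraction continuity check.
#'
#' @param n_residues chain length, >= 3.
#' @param chain_id one-character chain id.
#' @param seed seed for the jitter (required when `jitter > 0`).
#' @param jitter Gaussian coordinate noise sigma in Angstrom (default 0).
#' @param sequence optional n-letter sequence; default cycles through the 20
#'   standard amino acids.
#' @param pdb_code synthetic 4-character structure id.
#' @return A `pdb_structure`.
#' @examples
#' db <- extract_fragments(make_helix_chain(10), length = 3)  # 8 fragments
#' @export
make_helix_chain <- function(n_residues, chain_id = "A", seed = NULL,
                             jitter = 0, sequence = NULL, pdb_code = "HLX0") {
  n <- as.integer(n_residues)
  if (is.na(n) || n < 3L) fp_data_error("n_residues must be >= 3")
  co <- build_backbone(n)
  if (jitter > 0) {
    if (is.null(seed)) fp_data_error("jitter > 0 requires a seed")
    co <- co + with_seed(seed, matrix(rnorm(length(co), sd = jitter),
                                      ncol = 3L))
  }
  backbone_structure(co, n, chain_id, resolve_sequence(sequence, n), pdb_code)
}

#' Generate a chain with deliberate backbone breaks
#'
#' Builds one helical chain and rigidly translates each successive run so
#' that the C--N distance across run boundaries equals `gap` exactly; a gap
#' above the continuity cutoff (2.0 A) splits extraction runs, a gap below it
#' does not.  Residue numbering also jumps by `numbering_jump` at each break.
#'
#' @param run_lengths integer vector of residue counts per continuity run.
#' @param gap C--N distance across run boundaries, Angstrom (default 4.0).
#' @param numbering_jump extra residue-number offset at each break.
#' @inheritParams make_helix_chain
#' @return A `pdb_structure`.
#' @export
make_break_chain <- function(run_lengths, gap = 4.0, chain_id = "A",
                             seed = NULL, jitter = 0, sequence = NULL,
                             numbering_jump = 5L, pdb_code = "BRK0") {
  run_lengths <- as.integer(run_lengths)
  if (any(is.na(run_lengths)) || any(run_lengths < 1L))
    fp_data_error("run lengths must be positive")
  n <- sum(run_lengths)
  co <- build_backbone(n)
  last <- cumsum(run_lengths)
  resno <- seq_len(n)
  for (b in head(last, -1L)) {
    c_i <- co[4L * (b - 1L) + 3L, ]
    n_next <- co[4L * b + 1L, ]
    u <- n_next - c_i
    u <- u / sqrt(sum(u^2))
    shift <- (gap - sqrt(sum((n_next - c_i)^2))) * u
    rows_after <- (4L * b + 1L):(4L * n)
    co[rows_after, ] <- sweep(co[rows_after, , drop = FALSE], 2, -shift)
    resno[(b + 1L):n] <- resno[(b + 1L):n] + numbering_jump
  }
  if (jitter > 0) {
    if (is.null(seed)) fp_data_error("jitter > 0 requires a seed")
    co <- co + with_seed(seed, matrix(rnorm(length(co), sd = jitter),
                                      ncol = 3L))
  }
  backbone_structure(co, n, chain_id, resolve_sequence(sequence, n),
                     pdb_code, resno = resno)
}

#' Delete atoms from a parsed structure
#'
#' Test helper for missing-backbone-atom fixtures.
#'
#' @param s a `pdb_structure`.
#' @param resno residue number(s) to hit.
#' @param names atom name(s) to delete (e.g. `"O"`).
#' @param chain restrict to one chain (default: all).
#' @return The modified `pdb_structure`.
#' @export
delete_atoms <- function(s, resno, names, chain = NULL) {
  drop <- s$atoms$resno %in% resno & s$atoms$name %in% names
  if (!is.null(chain)) drop <- drop & s$atoms$chain %in% chain
  s$atoms <- s$atoms[!drop, , drop = FALSE]
  rownames(s$atoms) <- NULL
  s
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Generate a pool of jittered decoys of a base fragment
#'
#' Each decoy is the base fragment with i.i.d. Gaussian coordinate noise
#' followed by a random proper rigid motion, so its superposition RMSD to
#' the base scales with `sigma` while its absolute pose is scrambled.
#' Deterministic under `(base, n, sigma, seed)`.
#'
#' @param base a `fragment`.
#' @param n number of decoys.
#' @param sigma per-coordinate Gaussian noise, Angstrom.
#' @param seed integer seed.
#' @param pdb_codes optional codes assigned to decoys (recycled); default
#'   `D000, D001, ...` cycling at 1000.
#' @param sequences optional sequences assigned to decoys (recycled); default
#'   the base sequence.
#' @return List of `n` `fragment` objects.
#' @export
make_decoy_pool <- function(base, n, sigma, seed, pdb_codes = NULL,
                            sequences = NULL) {
  if (!inherits(base, "fragment")) fp_data_error("base must be a fragment")
  n <- as.integer(n)
  if (is.na(n) || n < 0L) fp_data_error("n must be >= 0")
  if (is.null(pdb_codes))
    pdb_codes <- sprintf("D%03d", (seq_len(max(n, 1L)) - 1L) %% 1000L)
  if (is.null(sequences)) sequences <- base$sequence
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      co <- base$coords + matrix(rnorm(length(base$coords), sd = sigma),
                                 ncol = 3L)
      co <- co %*% t(random_rotation())
      co <- sweep(co, 2, -rnorm(3, sd = 10))
      new_fragment(pdb_codes[(i - 1L) %% length(pdb_codes) + 1L],
                   base$chain, base$resno, base$icode,
                   sequences[(i - 1L) %% length(sequences) + 1L], co)
    })
  })
}
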