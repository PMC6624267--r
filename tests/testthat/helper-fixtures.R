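# Shared fixtures: random rigid motions, simple pseudo-atom models, and a
# build-from-dihedrals backbone constructor used as the geometry oracle.

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to det +1
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# n pseudo-atoms, one residue each, single chain
point_model <- function(xyz, chain = "A", element = "C") {
  xyz <- as.matrix(xyz)
  new_model(data.frame(atom = "C", element = element, res_name = "PSA",
                       res_seq = seq_len(nrow(xyz)), chain = chain,
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

random_point_model <- function(n, spread = 20, chain = "A") {
  point_model(matrix(runif(3 * n, 0, spread), n, 3), chain = chain)
}

# NeRF atom placement: D such that |CD| = r, angle(B,C,D) = theta_deg and
# dihedral(A,B,C,D) = chi_deg under the package's (IUPAC) sign convention
place_atom <- function(A, B, C, r, theta_deg, chi_deg) {
  th <- theta_deg * pi / 180
  ch <- chi_deg * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + r * (-cos(th) * bc + sin(th) * cos(ch) * m + sin(th) * sin(ch) * n)
}

# ideal-geometry polypeptide backbone with prescribed (phi, psi) per residue;
# phi[1] and psi[n] are unused (undefined at termini)
build_backbone <- function(phi, psi, chain = "A") {
  stopifnot(length(phi) == length(psi))
  nres <- length(phi)
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329
  a_ncac <- 111.2; a_cacn <- 116.2; a_cnca <- 121.7
  atoms <- list()
  N <- c(0, 0, 0)
  CA <- c(b_nca, 0, 0)
  th <- a_ncac * pi / 180
  C <- CA + b_cac * c(-cos(th), sin(th), 0)
  atoms[[1]] <- rbind(N, CA, C)
  for (i in seq_len(nres - 1) + 1) {
    prevN <- atoms[[i - 1]][1, ]; prevCA <- atoms[[i - 1]][2, ]
    prevC <- atoms[[i - 1]][3, ]
    N <- place_atom(prevN, prevCA, prevC, b_cn, a_cacn, psi[i - 1])
    CA <- place_atom(prevCA, prevC, N, b_nca, a_cnca, 180)
    C <- place_atom(prevC, N, CA, b_cac, a_ncac, phi[i])
    atoms[[i]] <- rbind(N, CA, C)
  }
  xyz <- do.call(rbind, atoms)
  new_model(data.frame(atom = rep(c("N", "CA", "C"), nres),
                       element = rep(c("N", "C", "C"), nres),
                       res_name = "ALA",
                       res_seq = rep(seq_len(nres), each = 3),
                       chain = chain,
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

# deterministic default perturbation dataset used by several tests
default_perturbation_dataset <- function(seed = 1L) {
  make_perturbation_dataset(rng_seed = seed)
}

default_toy_filament <- function(n_subunits = 10L, rise = 5.1,
                                 twist = -101.6, seed = 1L) {
  build_filament(make_toy_protomer(rng_seed = seed),
                 helical_parameters(rise, twist), n_subunits)
}
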