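# Rigid transforms use the row-vector convention: y = x %*% R + t, with x an
# n x 3 coordinate matrix. Screw decomposition internally works on the
# column-convention matrix t(R), where a rotation by angle a about unit axis n
# is I cos(a) + sin(a) [n]x + (1 - cos(a)) n n^T.

#' Rigid-body transform constructor
#'
#' @param rotation 3x3 rotation matrix (row-vector convention,
#'   `y = x %*% rotation + translation`); must be orthonormal with det +1.
#' @param translation length-3 numeric.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop("rotation is not a proper orthonormal matrix")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param x n x 3 coordinate matrix (or length-3 vector).
#' @param tf a [rigid_transform()].
#' @return transformed coordinates, same shape as `x`.
#' @export
apply_transform <- function(x, tf) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, 1L, 3L)
  y <- x %*% tf$rotation + matrix(tf$translation, nrow(x), 3L, byrow = TRUE)
  if (vec) drop(y) else y
}

#' Compose two rigid transforms (first `a`, then `b`)
#' @param a,b [rigid_transform()] objects.
#' @return the composite transform.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$translation %*% b$rotation) + b$translation)
}

#' Kabsch least-squares superposition
#'
#' Finds the rigid transform minimizing the RMSD between `mobile` (after
#' transformation) and `reference`. At least 3 non-degenerate (rank >= 2)
#' points are required.
#'
#' @param mobile,reference n x 3 coordinate matrices with matched rows.
#' @return list with `transform` (a [rigid_transform()]) and `rmsd` (Angstrom,
#'   the minimized value).
#' @export
kabsch_superpose <- function(mobile, reference) {
  P <- unname(as.matrix(mobile)); Q <- unname(as.matrix(reference))
  stopifnot(ncol(P) == 3L, ncol(Q) == 3L, nrow(P) == nrow(Q))
  n <- nrow(P)
  if (n < 3L) stop("need at least 3 points for superposition")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  H <- crossprod(Pc, Qc)                       # 3x3
  s <- svd(H)
  if (s$d[2L] < 1e-10 * max(s$d[1L], 1))
    stop("degenerate (collinear) point set; superposition is ill-defined")
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)     # Pc %*% R ~ Qc
  t <- cq - drop(cp %*% R)
  dev <- Pc %*% R - Qc
  list(transform = rigid_transform(R, t),
       rmsd = sqrt(sum(dev^2) / n))
}

#' RMSD between two matched coordinate sets (no fitting)
#' @param a,b n x 3 matrices.
#' @return root-mean-square deviation.
#' @export
rmsd <- function(a, b) sqrt(sum((as.matrix(a) - as.matrix(b))^2) / nrow(as.matrix(a)))

#' Ensemble RMSD statistics
#'
#' Computes coordinate spread of a multi-model ensemble over a selection,
#' either as RMSD to the iteratively superposed mean structure (`to_mean`,
#' the common convention for NMR ensembles) or as the average over all
#' pairwise superpositions (`mean_pairwise`).
#'
#' For `to_mean`, models are superposed onto a running mean structure until
#' the mean moves by less than `tol` Angstrom (max `max_iter` iterations);
#' the statistic is the average RMSD of the superposed models to that mean.
#'
#' @param ensemble an `hc_ensemble`.
#' @param chain,res_range,res_seq,atoms,heavy_only selection passed to
#'   [select_atoms()]; defaults select all atoms.
#' @param mode `"to_mean"` or `"mean_pairwise"`.
#' @param tol,max_iter convergence controls for the iterative mean fit.
#' @return list with `mean_rmsd`, `per_model` (for `to_mean`) or `per_pair`
#'   (for `mean_pairwise`), `mode`, and `n_atoms`.
#' @export
ensemble_rmsd <- function(ensemble, chain = NULL, res_range = NULL,
                          res_seq = NULL, atoms = NULL, heavy_only = FALSE,
                          mode = c("to_mean", "mean_pairwise"),
                          tol = 1e-6, max_iter = 100L) {
  mode <- match.arg(mode)
  stopifnot(inherits(ensemble, "hc_ensemble"))
  nm <- n_models(ensemble)
  if (nm < 2L) stop("ensemble RMSD needs at least 2 models")
  m1 <- get_model(ensemble, 1L)
  sel <- select_atoms(m1, chain = chain, res_range = res_range,
                      res_seq = res_seq, atoms = atoms, heavy_only = heavy_only)
  idx <- as.integer(rownames(sel))
  if (!length(idx)) stop("selection is empty")
  X <- lapply(ensemble$xyz, function(z) z[idx, , drop = FALSE])

  if (mode == "mean_pairwise") {
    pairs <- utils::combn(nm, 2L)
    per <- apply(pairs, 2L, function(p) kabsch_superpose(X[[p[1L]]], X[[p[2L]]])$rmsd)
    return(list(mean_rmsd = mean(per),
                per_pair = data.frame(i = pairs[1L, ], j = pairs[2L, ], rmsd = per),
                mode = mode, n_atoms = length(idx)))
  }

  ref <- X[[1L]]
  fitted <- X
  for (it in seq_len(max_iter)) {
    fitted <- lapply(X, function(x)
      apply_transform(x, kabsch_superpose(x, ref)$transform))
    newref <- Reduce(`+`, fitted) / nm
    shift <- sqrt(max(rowSums((newref - ref)^2)))
    ref <- newref
    if (shift < tol) break
  }
  per <- vapply(fitted, function(x) rmsd(x, ref), numeric(1L))
  list(mean_rmsd = mean(per),
       per_model = data.frame(model = seq_len(nm), rmsd = per),
       mode = mode, n_atoms = length(idx))
}

# rotation about unit axis n by ang (radians), column convention
.axis_rotation <- function(n, ang) {
  n <- n / sqrt(sum(n^2))
  K <- matrix(c(0, -n[3L], n[2L], n[3L], 0, -n[1L], -n[2L], n[1L], 0),
              3L, 3L, byrow = TRUE)
  diag(3) * cos(ang) + sin(ang) * K + (1 - cos(ang)) * tcrossprod(n)
}

#' Build a screw (helical) transform
#'
#' Constructs the rigid transform that rotates by `twist` degrees about the
#' axis through `axis_point` along unit vector `axis_dir` and translates by
#' `rise` Angstrom along that axis.
#'
#' @param twist degrees, signed by the right-hand rule about `axis_dir`
#'   (negative = left-handed for a filament growing along `axis_dir`).
#' @param rise Angstrom, signed translation along `axis_dir`.
#' @param axis_dir length-3 direction (normalized internally); default +z.
#' @param axis_point a point on the axis; default origin.
#' @return a [rigid_transform()].
#' @export
screw_transform <- function(twist, rise, axis_dir = c(0, 0, 1),
                            axis_point = c(0, 0, 0)) {
  n <- axis_dir / sqrt(sum(axis_dir^2))
  Rc <- .axis_rotation(n, twist * pi / 180)
  t <- rise * n + drop((diag(3) - Rc) %*% axis_point)
  rigid_transform(t(Rc), t)
}

#' Screw-axis decomposition of a rigid transform
#'
#' Decomposes a rigid transform into rotation angle (twist) about a unique
#' axis, translation along that axis (rise), the axis direction, and a point
#' on the axis. The axis sign is chosen so the rise is non-negative; for a
#' pure rotation (rise ~ 0) the axis component of largest magnitude is made
#' positive. Twist is reported in (-180, 180] degrees. An identity transform
#' with zero translation has no defined axis and raises an error.
#'
#' @param tf a [rigid_transform()].
#' @return object of class `screw_parameters`: list with `twist` (degrees),
#'   `rise` (Angstrom), `axis_dir`, `axis_point`.
#' @export
screw_transform_params <- function(tf) {
  Rc <- t(tf$rotation)                          # column convention
  tr <- sum(diag(Rc))
  ang <- acos(min(1, max(-1, (tr - 1) / 2)))    # [0, pi]
  tvec <- tf$translation

  if (ang < 1e-7) {                             # pure translation (or identity)
    len <- sqrt(sum(tvec^2))
    if (len < 1e-9)
      stop("identity transform with zero translation: screw axis undefined")
    n <- tvec / len
    return(structure(list(twist = 0, rise = len, axis_dir = n,
                          axis_point = c(0, 0, 0)),
                     class = "screw_parameters"))
  }

  if (ang > pi - 1e-6) {                        # 180 deg: antisymmetric part vanishes
    M <- (Rc + diag(3)) / 2                     # = n n^T at ang = pi
    k <- which.max(diag(M))
    n <- M[, k] / sqrt(M[k, k])
  } else {
    n <- c(Rc[3L, 2L] - Rc[2L, 3L],
           Rc[1L, 3L] - Rc[3L, 1L],
           Rc[2L, 1L] - Rc[1L, 2L]) / (2 * sin(ang))
  }
  n <- n / sqrt(sum(n^2))
  rise <- sum(tvec * n)
  sgn <- 1
  if (rise < -1e-9) sgn <- -1
  else if (abs(rise) <= 1e-9 && n[which.max(abs(n))] < 0) sgn <- -1
  n <- sgn * n; rise <- sgn * rise
  twist <- sgn * ang * 180 / pi                 # signed about final axis
  if (twist <= -180) twist <- twist + 360
  # axis point: solve (I - Rc) p = t_perp in the plane orthogonal to n
  t_perp <- tvec - sum(tvec * n) * n
  u <- if (abs(n[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- u - sum(u * n) * n; u <- u / sqrt(sum(u^2))
  v <- c(n[2L] * u[3L] - n[3L] * u[2L],
         n[3L] * u[1L] - n[1L] * u[3L],
         n[1L] * u[2L] - n[2L] * u[1L])
  B <- cbind(u, v)
  A2 <- t(B) %*% (diag(3) - Rc) %*% B
  b2 <- drop(t(B) %*% t_perp)
  p2 <- solve(A2, b2)
  p <- drop(B %*% p2)
  structure(list(twist = twist, rise = rise, axis_dir = n, axis_point = p),
            class = "screw_parameters")
}

#' @export
print.screw_parameters <- function(x, ...) {
  hand <- if (x$twist < 0) "left-handed" else "right-handed"
  cat(sprintf("<screw> rise %.4f A, twist %.4f deg (%s), axis [%.3f %.3f %.3f]\n",
              x$rise, abs(x$twist), hand,
              x$axis_dir[1L], x$axis_dir[2L], x$axis_dir[3L]))
  invisible(x)
}

#' Dihedral angle of four points
#' @param p1,p2,p3,p4 length-3 coordinates.
#' @return angle in degrees in (-180, 180] about the p2-p3 bond.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2L] * b2[3L] - b1[3L] * b2[2L],
          b1[3L] * b2[1L] - b1[1L] * b2[3L],
          b1[1L] * b2[2L] - b1[2L] * b2[1L])
  n2 <- c(b2[2L] * b3[3L] - b2[3L] * b3[2L],
          b2[3L] * b3[1L] - b2[1L] * b3[3L],
          b2[1L] * b3[2L] - b2[2L] * b3[1L])
  m1 <- c(n1[2L] * b2[3L] - n1[3L] * b2[2L],
          n1[3L] * b2[1L] - n1[1L] * b2[3L],
          n1[1L] * b2[2L] - n1[2L] * b2[1L]) / sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi  # IUPAC sign
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone phi/psi dihedrals of one chain
#'
#' Computes per-residue Ramachandran angles from N, CA, C atoms. The first
#' residue has undefined phi and the last undefined psi; residues with
#' missing backbone atoms, or not consecutive in numbering, are flagged
#' undefined (NA) rather than failing.
#'
#' @param model a model data.frame.
#' @param chain chain identifier (default: the model's first chain).
#' @return data.frame with `chain`, `res_seq`, `res_name`, `phi`, `psi`
#'   (degrees, NA where undefined).
#' @export
backbone_dihedrals <- function(model, chain = NULL) {
  if (is.null(chain)) chain <- model$chain[1L]
  m <- select_atoms(model, chain = chain, atoms = c("N", "CA", "C"))
  res <- unique(m$res_seq)
  res <- res[order(res)]
  getxyz <- function(r, a) {
    row <- m[m$res_seq == r & m$atom == a, , drop = FALSE]
    if (nrow(row) != 1L) return(NULL)
    c(row$x, row$y, row$z)
  }
  out <- data.frame(chain = chain, res_seq = res,
                    res_name = vapply(res, function(r)
                      m$res_name[m$res_seq == r][1L], character(1L)),
                    phi = NA_real_, psi = NA_real_)
  for (i in seq_along(res)) {
    r <- res[i]
    N <- getxyz(r, "N"); CA <- getxyz(r, "CA"); C <- getxyz(r, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    if (i > 1L && res[i - 1L] == r - 1L) {
      Cp <- getxyz(r - 1L, "C")
      if (!is.null(Cp)) out$phi[i] <- dihedral_angle(Cp, N, CA, C)
    }
    if (i < length(res) && res[i + 1L] == r + 1L) {
      Nn <- getxyz(r + 1L, "N")
      if (!is.null(Nn)) out$psi[i] <- dihedral_angle(N, CA, C, Nn)
    }
  }
  out
}
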