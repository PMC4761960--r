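# Pairwise nonbonded energetics and structural deviation series.
#
# Energies are post-hoc pairwise sums in vacuum with plain cutoff
# truncation -- no Ewald summation, no reaction field -- so absolute values
# are comparable to engine output in trend only. Units: nm, kJ/mol, e;
# kcal/mol exports divide by 4.184.

KJ_PER_KCAL <- 4.184
COULOMB_CONSTANT <- 138.935458   # kJ mol^-1 nm e^-2

#' 12-6 Lennard-Jones pair energy
#'
#' `4 eps_ij [ (sig_ij/r)^12 - (sig_ij/r)^6 ]` with Lorentz-Berthelot
#' combination: arithmetic-mean sigma, geometric-mean epsilon. The well
#' depth is `-eps_ij` at `r = 2^(1/6) sig_ij` and the zero crossing is at
#' `r = sig_ij`.
#'
#' @param r distance(s) in nm, > 0.
#' @param pi,pj parameter sets with fields `epsilon` (kJ/mol) and `sigma`
#'   (nm) -- e.g. single rows of a `nonbonded_params` table.
#' @return energy in kJ/mol (vectorized over `r`).
#' @export
lj_pair <- function(r, pi, pj) {
  if (any(r <= 0)) stop("pair distance must be > 0")
  eps <- sqrt(pi$epsilon * pj$epsilon)
  sig <- (pi$sigma + pj$sigma) / 2
  sr6 <- (sig / r)^6
  4 * eps * (sr6^2 - sr6)
}

#' Coulomb pair energy
#'
#' `f qi qj / r` with `f = 138.935458 kJ mol^-1 nm e^-2` (vacuum
#' permittivity, no reaction field).
#'
#' @param r distance(s) in nm, > 0.
#' @param qi,qj charges in e.
#' @return energy in kJ/mol (vectorized over `r`).
#' @export
coulomb_pair <- function(r, qi, qj) {
  if (any(r <= 0)) stop("pair distance must be > 0")
  COULOMB_CONSTANT * qi * qj / r
}

#' Tube-protein interaction-energy series
#'
#' Per frame, sums [lj_pair()] and [coulomb_pair()] over all cross pairs
#' between the two groups within the cutoff (plain truncation, the
#' trajectory-analysis analogue of a 1.0 nm vdW cutoff). Deterministic.
#'
#' @param trajectory an `md_trajectory`.
#' @param groupA,groupB disjoint `md_selection`s.
#' @param params a `nonbonded_params` table covering every atom of the
#'   topology (see [assign_nonbonded_params()]).
#' @param cutoff pair cutoff in nm.
#' @return `energy_series` data.frame: `time_ps`, `vdw_kJmol`,
#'   `coulomb_kJmol`, `vdw_kcalmol`, `coulomb_kcalmol`.
#' @export
interaction_energy_series <- function(trajectory, groupA, groupB, params,
                                      cutoff = 1.0) {
  ia <- selection_indices(groupA)
  ib <- selection_indices(groupB)
  if (length(ia) == 0 || length(ib) == 0) stop("empty selection")
  if (length(intersect(ia, ib)) > 0) stop("groups must be disjoint")
  if (nrow(params) < n_atoms(trajectory$topology)) {
    stop("params table does not cover the topology")
  }
  if (cutoff <= 0) stop("cutoff must be > 0")
  eps_ij <- sqrt(outer(params$epsilon[ia], params$epsilon[ib]))
  sig_ij <- outer(params$sigma[ia], params$sigma[ib], function(a, b) (a + b) / 2)
  qq <- outer(params$charge[ia], params$charge[ib])
  nf <- n_frames(trajectory)
  vdw <- numeric(nf); coul <- numeric(nf)
  for (k in seq_len(nf)) {
    f <- trajectory$frames[[k]]
    d <- cross_dist(f[ia, , drop = FALSE], f[ib, , drop = FALSE])
    m <- d <= cutoff & d > 0
    if (any(m)) {
      sr6 <- (sig_ij[m] / d[m])^6
      vdw[k] <- sum(4 * eps_ij[m] * (sr6^2 - sr6))
      coul[k] <- sum(COULOMB_CONSTANT * qq[m] / d[m])
    }
  }
  out <- data.frame(time_ps = trajectory$times, vdw_kJmol = vdw,
                    coulomb_kJmol = coul,
                    vdw_kcalmol = vdw / KJ_PER_KCAL,
                    coulomb_kcalmol = coul / KJ_PER_KCAL)
  class(out) <- c("energy_series", "data.frame")
  out
}

#' Optimal rotation by the Kabsch algorithm
#'
#' Least-squares rotation taking centered `P` onto centered `Q`, with the
#' reflection guard (sign flip of the smallest singular vector) so the
#' result is always a proper rotation, det = +1.
#'
#' @param P,Q n x 3 coordinate matrices (already centered).
#' @return 3 x 3 rotation matrix `R` such that `P %*% R` best fits `Q`.
#' @export
kabsch_rotation <- function(P, Q) {
  sv <- svd(crossprod(P, Q))
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  sv$u %*% D %*% t(sv$v)
}

#' C-alpha RMSD series after optimal superposition
#'
#' Each frame's selected atoms are superposed onto the reference frame by
#' the Kabsch algorithm (translation + proper rotation) before the RMSD is
#' taken, so rigid-body motion contributes nothing.
#'
#' @param trajectory an `md_trajectory`.
#' @param reference reference frame index (1-based; default the first
#'   frame, i.e. the initial configuration).
#' @param selection atoms to superpose and measure; default all C-alpha
#'   atoms (`name == CA`).
#' @return `rmsd_series` data.frame: `time_ps`, `rmsd_nm`.
#' @export
rmsd_series <- function(trajectory, reference = 1L, selection = NULL) {
  st <- trajectory$topology
  if (is.null(selection)) selection <- resolve_selection(st, "name == CA")
  idx <- selection_indices(selection)
  if (length(idx) < 3) stop("superposition needs at least 3 selected atoms")
  if (reference < 1 || reference > n_frames(trajectory)) {
    stop("invalid reference frame index")
  }
  ref <- trajectory$frames[[reference]][idx, , drop = FALSE]
  ref_c <- sweep(ref, 2, colMeans(ref))
  rmsd <- vapply(trajectory$frames, function(f) {
    mob <- f[idx, , drop = FALSE]
    mob_c <- sweep(mob, 2, colMeans(mob))
    rot <- kabsch_rotation(mob_c, ref_c)
    sqrt(mean(rowSums((mob_c %*% rot - ref_c)^2)))
  }, 1.0)
  out <- data.frame(time_ps = trajectory$times, rmsd_nm = rmsd)
  class(out) <- c("rmsd_series", "data.frame")
  out
}
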