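# Independent brute-force oracles used to check the package detectors.
# These are deliberately naive (double/triple loops, closed forms,
# alternative algorithms) and never call the code paths they verify.

oracle_contact_count <- function(xyz, ia, ib, cutoff, heavy) {
  count <- 0L
  for (i in ia) {
    for (j in ib) {
      if (!heavy[i] || !heavy[j]) next
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff) count <- count + 1L
    }
  }
  count
}

oracle_hbonds <- function(xyz, donors, hydrogens, acceptors, da_cutoff,
                          angle_min) {
  out <- list()
  for (k in seq_along(donors)) {
    for (a in acceptors) {
      if (a == donors[k] || a == hydrogens[k]) next
      dda <- sqrt(sum((xyz[donors[k], ] - xyz[a, ])^2))
      if (dda > da_cutoff) next
      v1 <- xyz[donors[k], ] - xyz[hydrogens[k], ]
      v2 <- xyz[a, ] - xyz[hydrogens[k], ]
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang >= angle_min) {
        out[[length(out) + 1L]] <- c(donors[k], hydrogens[k], a)
      }
    }
  }
  if (length(out) == 0) matrix(integer(0), ncol = 3) else do.call(rbind, out)
}

oracle_min_dist <- function(xyz, idx, point) {
  best <- Inf
  for (i in idx) best <- min(best, sqrt(sum((xyz[i, ] - point)^2)))
  best
}

# Horn's quaternion method: an independent optimal-superposition algorithm
oracle_quaternion_rmsd <- function(P, Q) {
  P <- sweep(P, 2, colMeans(P))
  Q <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(P, Q)
  K <- matrix(0, 4, 4)
  K[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  K[1, 2] <- K[2, 1] <- M[2, 3] - M[3, 2]
  K[1, 3] <- K[3, 1] <- M[3, 1] - M[1, 3]
  K[1, 4] <- K[4, 1] <- M[1, 2] - M[2, 1]
  K[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  K[2, 3] <- K[3, 2] <- M[1, 2] + M[2, 1]
  K[2, 4] <- K[4, 2] <- M[1, 3] + M[3, 1]
  K[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  K[3, 4] <- K[4, 3] <- M[2, 3] + M[3, 2]
  K[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  lambda <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lambda) / nrow(P)
  sqrt(max(0, msd))
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

apply_rigid <- function(xyz, rot, shift) {
  sweep(xyz %*% t(rot), 2, shift, "+")
}

# a small random structure with plausible metadata, for property tests
random_test_structure <- function(n = 40, seed = 1) {
  set.seed(seed)
  elements <- sample(c("C", "N", "O", "H"), n, replace = TRUE,
                     prob = c(0.5, 0.2, 0.2, 0.1))
  md_structure(data.frame(
    name = paste0(elements, seq_len(n)),
    element = elements,
    residue_name = "UNK",
    residue_id = rep(seq_len(ceiling(n / 4)), each = 4)[seq_len(n)],
    chain_id = "A",
    x = stats::runif(n, 0, 3), y = stats::runif(n, 0, 3),
    z = stats::runif(n, 0, 3),
    formal_charge = 0, stringsAsFactors = FALSE))
}

default_validation_events <- function(n_frames) {
  list(
    scenario_event("channel_block", floor(n_frames / 3), n_frames),
    scenario_event("stack_parallel", 0, floor(0.6 * n_frames)),
    scenario_event("salt_bridge", floor(n_frames / 5), floor(0.8 * n_frames)),
    scenario_event("hbond", floor(n_frames / 10), floor(0.9 * n_frames)))
}
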