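# shared fixtures and independent oracles for the test suite

# breadth-first reachability over 8-neighbour adjacency on a logical
# passable matrix; start = 0-based row-major cell ids
reachable_cells <- function(passable, grid, start) {
  nr <- nrow(passable); nc <- ncol(passable)
  seen <- matrix(FALSE, nr, nc)
  rc <- cell_to_rowcol(grid, start)
  queue <- cbind(rc[, "row"] + 1L, rc[, "col"] + 1L)
  queue <- queue[passable[queue], , drop = FALSE]
  seen[queue] <- TRUE
  while (nrow(queue)) {
    cur <- queue[1L, ]; queue <- queue[-1L, , drop = FALSE]
    for (dr in -1:1) for (dc in -1:1) {
      r <- cur[1L] + dr; c <- cur[2L] + dc
      if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
          passable[r, c] && !seen[r, c]) {
        seen[r, c] <- TRUE
        queue <- rbind(queue, c(r, c))
      }
    }
  }
  seen
}

# exact enumeration oracle for a 1 x k strip of suitabilities `s`, origin
# at 0-based cell `origin`, T iterations: enumerates every Bernoulli
# success pattern (2^k per step) and returns exact occupancy probabilities
# at T and the exact mean and variance of the replicate accessibility score
# a(c) = (T + 1 - t_first) / (T + 1), 0 if never occupied.
strip_oracle <- function(s, origin, iterations) {
  k <- length(s)
  patterns <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
  pat_prob <- apply(patterns, 1L, function(p) prod(ifelse(p, s, 1 - s)))
  # state: occupancy vector + t_first vector
  acc_mean <- numeric(k); acc_m2 <- numeric(k); occ_prob <- numeric(k)
  recurse <- function(occ, tfirst, t, prob) {
    if (t > iterations) {
      a <- ifelse(is.na(tfirst), 0, (iterations + 1 - tfirst) /
                    (iterations + 1))
      acc_mean <<- acc_mean + prob * a
      acc_m2 <<- acc_m2 + prob * a^2
      occ_prob <<- occ_prob + prob * occ
      return(invisible())
    }
    dil <- vapply(seq_len(k), function(c) {
      any(occ[max(1L, c - 1L):min(k, c + 1L)] > 0)
    }, logical(1))
    for (pi in seq_len(nrow(patterns))) {
      nxt <- as.numeric(dil & patterns[pi, ])
      nxt[origin + 1L] <- 1
      tf <- tfirst
      newly <- which(nxt == 1 & is.na(tf))
      tf[newly] <- t
      recurse(nxt, tf, t + 1L, prob * pat_prob[pi])
    }
  }
  occ0 <- numeric(k); occ0[origin + 1L] <- 1
  tf0 <- rep(NA_real_, k); tf0[origin + 1L] <- 0
  recurse(occ0, tf0, 1L, 1)
  list(occupancy_prob = occ_prob, a_mean = acc_mean,
       a_var = acc_m2 - acc_mean^2)
}

# run simulate_accessibility replicate-wise and return per-cell mean over
# R replicates (thin wrapper used where a specific replicate count matters)
strip_surface <- function(s_values) {
  g <- lattice_grid(1, length(s_values), land_fraction = 1)
  surface(g, matrix(s_values, 1))
}

# small deterministic predictor table
toy_table <- function(n = 60, seed = 1, p = 3) {
  set.seed(seed)
  d <- as.data.frame(matrix(rnorm(n * p), n,
                            dimnames = list(NULL, paste0("x", seq_len(p)))))
  d
}

# queen-adjacency weights on an r x c unit lattice (via the package's
# distance band at 1.5 units)
lattice_weights <- function(r, c, standardize = TRUE) {
  xy <- expand.grid(x = seq_len(c), y = seq_len(r))
  distance_band_neighbors(as.matrix(xy), d = 1.5, standardize = standardize)
}
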