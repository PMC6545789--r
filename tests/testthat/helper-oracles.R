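# Independent reference implementations used as oracles. These deliberately
# avoid the package's C++ paths: bond counting by array shifting or literal
# pair enumeration, components by R flood fill, energies by the tension
# formula applied to oracle counts.

oracle_offsets <- function(connectivity = 26) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  if (connectivity == 18) g <- g[rowSums(abs(g)) <= 2, , drop = FALSE]
  g
}

# Ordered neighbor tabulation by array shifting, halved to unordered counts.
oracle_bond_counts <- function(arr, n_types) {
  d <- dim(arr)
  off <- oracle_offsets()
  lev <- 0:(n_types - 1)
  N <- matrix(0, n_types, n_types)
  for (k in seq_len(nrow(off))) {
    dx <- off[k, 1]; dy <- off[k, 2]; dz <- off[k, 3]
    if (max(1, 1 - dx) > min(d[1], d[1] - dx) || max(1, 1 - dy) > min(d[2], d[2] - dy) ||
        max(1, 1 - dz) > min(d[3], d[3] - dz)) next
    xs <- max(1, 1 - dx):min(d[1], d[1] - dx)
    ys <- max(1, 1 - dy):min(d[2], d[2] - dy)
    zs <- max(1, 1 - dz):min(d[3], d[3] - dz)
    a <- arr[xs, ys, zs]
    b <- arr[xs + dx, ys + dy, zs + dz]
    N <- N + table(factor(a, lev), factor(b, lev))
  }
  M <- N
  M[upper.tri(M) | lower.tri(M)] <- N[upper.tri(N) | lower.tri(N)]
  diag(M) <- diag(N) / 2
  (M + t(M)) / 2
}

# Literal enumeration over all site pairs (for tiny lattices only).
oracle_pair_enum <- function(arr, n_types) {
  d <- dim(arr)
  xyz <- arrayInd(seq_along(arr), d)
  n <- nrow(xyz)
  N <- matrix(0, n_types, n_types)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (max(abs(xyz[i, ] - xyz[j, ])) != 1L) next
    a <- arr[i]; b <- arr[j]
    lo <- min(a, b) + 1L; hi <- max(a, b) + 1L
    N[lo, hi] <- N[lo, hi] + 1
  }
  (N + t(N)) - diag(diag(N))
}

oracle_gamma <- function(eps, a, b) {
  0.5 * (eps[a + 1, a + 1] + eps[b + 1, b + 1]) - eps[a + 1, b + 1]
}

oracle_total_energy <- function(arr, eps, counts = NULL) {
  n_types <- nrow(eps)
  if (is.null(counts)) counts <- oracle_bond_counts(arr, n_types)
  E <- 0
  for (a in 0:(n_types - 1)) for (b in a:(n_types - 1)) {
    if (a == b) next
    E <- E + oracle_gamma(eps, a, b) * counts[a + 1, b + 1]
  }
  E
}

# Queue-based flood fill.
oracle_components <- function(arr, phase_sigmas, connectivity = 26) {
  d <- dim(arr)
  off <- oracle_offsets(connectivity)
  inphase <- array(arr %in% phase_sigmas, d)
  lab <- array(0L, d)
  cur <- 0L
  for (start in which(inphase & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      s <- queue[1]; queue <- queue[-1]
      p <- arrayInd(s, d)
      for (k in seq_len(nrow(off))) {
        q <- p + off[k, ]
        if (any(q < 1) || any(q > d)) next
        qi <- q[1] + d[1] * (q[2] - 1L) + d[1] * d[2] * (q[3] - 1L)
        if (inphase[qi] && lab[qi] == 0L) {
          lab[qi] <- cur
          queue <- c(queue, qi)
        }
      }
    }
  }
  list(labels = lab, n_components = cur)
}

random_sites <- function(dims, n_types, p = NULL) {
  array(sample(0:(n_types - 1), prod(dims), replace = TRUE, prob = p), dims)
}

random_eps <- function(n_types) {
  e <- matrix(stats::runif(n_types^2, 0, 3), n_types)
  e <- (e + t(e)) / 2
  e[1, ] <- e[, 1] <- 0 # medium contacts carry no work of adhesion
  e
}

# Lattice whose registry marks every non-medium type as a cell.
as_cell_lattice <- function(sites, n_types) {
  types <- type_registry(c("medium", paste0("cell", seq_len(n_types - 1))),
                         c("medium", rep("cell", n_types - 1)))
  mmc_lattice(sites, types = types)
}
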