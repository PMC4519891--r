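# Independent oracles and small fixture builders used across the suite.
# The oracles deliberately avoid the package's code paths: plain
# double-loop / first-principles implementations.

aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

random_aa <- function(n) paste(sample(aa20, n, replace = TRUE), collapse = "")

# brute-force contact oracle: all-pairs distance check
oracle_contacts <- function(coords) {
  n <- nrow(coords)
  out <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j < i + 2) next
    d <- coords[i, ] - coords[j, ]
    if (sum(d * d) == 2) out <- rbind(out, c(i, j))
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

# naive double-loop distance-matrix RMSD
oracle_drmsd <- function(a, b) {
  n <- nrow(a)
  ss <- 0; m <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    da <- sqrt(sum((a[i, ] - a[j, ])^2))
    db <- sqrt(sum((b[i, ] - b[j, ])^2))
    ss <- ss + (da - db)^2
    m <- m + 1
  }
  sqrt(ss / m)
}

# exhaustive pairwise-dominance front ranks
oracle_ranks <- function(obj) {
  n <- nrow(obj)
  dominated_by <- function(p, q)  # q dominates p?
    all(obj[q, ] <= obj[p, ]) && any(obj[q, ] < obj[p, ])
  rank <- integer(n)
  alive <- rep(TRUE, n)
  f <- 0L
  while (any(alive)) {
    f <- f + 1L
    front <- vapply(seq_len(n), function(p) {
      alive[p] && !any(vapply(which(alive), function(q)
        q != p && dominated_by(p, q), TRUE))
    }, TRUE)
    rank[front] <- f
    alive[front] <- FALSE
  }
  rank
}

# first-principles angle computation (written against the geometry, not
# the package's vector helpers)
oracle_kappa <- function(p_prev2, p, p_next2) {
  u <- p_prev2 - p; v <- p_next2 - p
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

oracle_alpha <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) return(NA_real_)
  atan2(sum(cr(n1, n2) * b2 / sqrt(sum(b2^2))), sum(n1 * n2)) * 180 / pi
}

# independent K^KA recomputation from raw coordinates
oracle_ka_energy <- function(coords, pref) {
  n <- nrow(coords)
  if (n < 5) return(0)
  centers_a <- c(60, 80, 180, -130, -110, -10)
  total <- 0
  for (i in 3:(n - 2)) {
    k <- oracle_kappa(coords[i - 2, ], coords[i, ], coords[i + 2, ])
    a <- oracle_alpha(coords[i - 1, ], coords[i, ], coords[i + 1, ],
                      coords[i + 2, ])
    if (is.na(a)) next
    kb <- round(k / 10) * 10
    if (kb < 30 || kb > 150) next
    gap <- abs((a - centers_a + 180) %% 360 - 180)
    ab <- centers_a[which.min(gap)]
    total <- total + pref[as.character(kb), as.character(ab)]
  }
  -total
}

# a random rigid motion: lattice-independent rotation + translation
random_rigid <- function() {
  th <- stats::runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]),
                 0, -sin(th[1]), cos(th[1])), 3, 3)
  Ry <- matrix(c(cos(th[2]), 0, -sin(th[2]), 0, 1, 0,
                 sin(th[2]), 0, cos(th[2])), 3, 3)
  Rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]), cos(th[3]), 0,
                 0, 0, 1), 3, 3)
  list(R = Rx %*% Ry %*% Rz, t = stats::runif(3, -5, 5))
}

apply_rigid <- function(coords, rt) sweep(coords %*% t(rt$R), 2, rt$t, "+")

# the packaged preference table, re-transcribed here for fidelity checks
expected_preferences <- function() {
  vals <- c(
    0,     0,    0,    0,    0,    0,
    0,     0.05, 0.01, 0,    0,    0,
    0.21,  0.73, 0.18, 0.06, 0,    0.05,
    1.24,  1.5,  0.34, 0.49, 0,    0.38,
    17.87, 1.76, 0.14, 0.55, 0,    0.95,
    11.08, 0.59, 0.21, 0.51, 0.02, 1.65,
    1.28,  0.58, 0.31, 0.64, 0.25, 2.44,
    0.87,  0.68, 0.39, 0.98, 0.56, 2.98,
    0.72,  0.70, 0.47, 1.29, 0.96, 2.14,
    0.28,  0.56, 0.57, 1.22, 1.78, 1.04,
    0.08,  0.24, 0.47, 1.39, 2.08, 0.57,
    0.04,  0.10, 0.40, 1.99, 2.03, 0.43,
    0.02,  0.02, 0.21, 7.43, 17.46, 0.60)
  matrix(vals, nrow = 13, byrow = TRUE,
         dimnames = list(seq(30, 150, 10), c(60, 80, 180, -130, -110, -10)))
}
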