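# Independent brute-force oracles and small fixtures used across the suite.
# Everything here is deliberately naive (dense matrices, double loops,
# closed forms) and shares no code with the implementation under test.

# ---- graph oracles (adjacency-matrix based) --------------------------------

floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

oracle_clustering <- function(A, scale10 = TRUE) {
  n <- nrow(A)
  sapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    closed <- 0
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) closed <- closed + (A[nb[i], nb[j]] > 0)
    }
    (if (scale10) 10 else 1) * closed / choose(k, 2)
  })
}

oracle_closeness <- function(A, scale10 = TRUE) {
  n <- nrow(A)
  D <- floyd_warshall(A)
  sapply(seq_len(n), function(v) {
    reach <- is.finite(D[v, ])
    r <- sum(reach)
    if (r <= 1 || n == 1) return(0)
    s <- sum(D[v, reach])
    (if (scale10) 10 else 1) * ((r - 1) / s) * ((r - 1) / (n - 1))
  })
}

# shortest-path counts via adjacency powers: walks of length d(s,t) are
# exactly the shortest paths
oracle_betweenness <- function(A, scale10 = TRUE) {
  n <- nrow(A)
  if (n < 3) return(rep(0, n))
  D <- floyd_warshall(A)
  maxd <- max(D[is.finite(D)])
  pow <- vector("list", max(maxd, 1) + 1)
  pow[[1]] <- diag(n)
  for (l in seq_len(max(maxd, 1))) pow[[l + 1]] <- pow[[l]] %*% A
  nsp <- function(s, t) {
    d <- D[s, t]
    if (!is.finite(d)) return(0)
    pow[[d + 1]][s, t]
  }
  b <- rep(0, n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(D[s, t]) || D[s, t] == 0) next
      tot <- nsp(s, t)
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == D[s, t]) {
          b[v] <- b[v] + nsp(s, v) * nsp(v, t) / tot
        }
      }
    }
  }
  (if (scale10) 10 else 1) * b / ((n - 1) * (n - 2) / 2)
}

oracle_gini_degree <- function(deg, scale10 = TRUE) {
  deg <- unname(as.numeric(deg))
  n <- length(deg)
  if (all(deg == 0)) return(0)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(deg[i] - deg[j])
  (if (scale10) 10 else 1) * s / (2 * n^2 * mean(deg))
}

# dense eigen-decomposition check: impl must be a non-negative unit-norm
# eigenvector of the leading eigenvalue
expect_leading_eigenvector <- function(A, v, tol = 1e-8) {
  lam <- max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  expect_true(all(v >= -tol))
  expect_equal(sqrt(sum(v^2)), 1, tolerance = tol)
  expect_lt(max(abs(A %*% v - lam * v)), tol)
}

random_adjacency <- function(n, p) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up] <- rbinom(length(up), 1, p)
  A + t(A)
}

# a year_network built from an undirected adjacency matrix (one directed
# nomination per undirected edge; union projection recovers the adjacency)
net_from_adjacency <- function(A) {
  n <- nrow(A)
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  noms <- data.frame(nominator_id = idx[, 1], nominee_id = idx[, 2],
                     wave = rep(0, nrow(idx)))
  build_network(noms, roster = seq_len(n), wave = 0, symmetrization = "union")
}

net_from_edges <- function(edges, roster, symmetrization = "union") {
  noms <- data.frame(nominator_id = sapply(edges, `[`, 1),
                     nominee_id = sapply(edges, `[`, 2), wave = 0)
  build_network(noms, roster = roster, wave = 0,
                symmetrization = symmetrization)
}

# ---- regression oracles -----------------------------------------------------

# explicit matrix-algebra sandwich: (X'X)^-1 X' diag(e^2) X (X'X)^-1 with
# the HC1 factor n/(n-k); X includes the intercept column
oracle_ols_hc1 <- function(X, y) {
  X1 <- cbind(1, X)
  n <- nrow(X1); k <- ncol(X1)
  XtXi <- solve(t(X1) %*% X1)
  beta <- XtXi %*% t(X1) %*% y
  e <- as.numeric(y - X1 %*% beta)
  meat <- t(X1) %*% (X1 * e^2)
  V <- (n / (n - k)) * XtXi %*% meat %*% XtXi
  list(coefficients = as.numeric(beta), se = unname(sqrt(diag(V))), vcov = V)
}

# minimal model_design wrapper so fitters can be unit-tested on arbitrary
# data frames (response column must be named y)
manual_design <- function(df, moderator_type = "continuous",
                          level0 = NA, level1 = NA) {
  structure(list(
    spec = model_spec("y_out", "friends", 0L, "m_mod"),
    moderator_type = moderator_type, level0 = level0, level1 = level1,
    n = nrow(df), n_dropped = 0L,
    sd_exposure = if ("peer_exposure" %in% names(df)) sd(df$peer_exposure) else NA,
    sd_outcome = sd(df$y),
    moderator_sd = if ("moderator" %in% names(df)) sd(df$moderator) else NA,
    moderator_range = if ("moderator" %in% names(df)) range(df$moderator) else c(NA, NA),
    data = df, unfit_reason = NULL), class = "model_design")
}

# random moderated-regression dataset with named design columns
random_moderation_data <- function(n, b1 = 0.3, b3 = 0.2, noise = 1) {
  x <- rnorm(n)
  w <- rnorm(n)
  y <- 0.5 + b1 * x + 0.2 * w + b3 * x * w + rnorm(n, 0, noise)
  data.frame(y = y, peer_exposure = x - mean(x), moderator = w - mean(w),
             peer_x_moderator = (x - mean(x)) * (w - mean(w)))
}

# ---- cohort fixtures --------------------------------------------------------

small_cohort_config <- function(seed, n_schools = 2L, classes_per_school = 2L,
                                pupils_per_class = 15L, ...) {
  cohort_config(seed = seed, n_schools = n_schools,
                classes_per_school = classes_per_school,
                pupils_per_class = pupils_per_class, ...)
}

# hand-built six-pupil cohort for exposure arithmetic
toy_cohort <- function() {
  data.frame(
    pupil_id = 1:6,
    school_id = c(1, 1, 1, 1, 1, 1),
    class_id = c("A", "A", "A", "B", "B", "B"),
    setting = "NI", intervention = "ASSIST",
    gender = c("boy", "girl_pnts", "boy", "girl_pnts", "boy", "girl_pnts"),
    age_band = "13", ethnicity = "majority", ses_individual = 1,
    score_w0 = c(2, 4, 6, NA, 1, 3),
    score_w1 = c(1, 2, 3, 4, 5, 6),
    flag_w0 = c(1, 0, 1, 1, NA, 0),
    flag_w1 = c(0, 0, 1, 1, 0, 1),
    stringsAsFactors = FALSE)
}

toy_nominations <- function() {
  data.frame(
    nominator_id = c(1, 1, 1, 1, 2, 5),
    nominee_id   = c(2, 3, 4, 5, 1, 6),
    wave = 0)
}
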