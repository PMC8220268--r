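# Independent oracles and fixture builders used across the suite. These
# deliberately use naive formulations (nested loops, closed forms, dense
# matrix algebra) so they stay independent of the vectorized code paths
# they check.

# --- connectedness ----------------------------------------------------

# Triple-loop pBC: for every taxon x region pair, scan all occupants of the
# region for the nearest patristic neighbour.
pbc_oracle <- function(M, D, mu) {
  N <- nrow(M)
  L <- ncol(M)
  O <- 0
  for (i in seq_len(N)) {
    for (k in seq_len(L)) {
      if (M[i, k] > 0) {
        O <- O + 1
      } else {
        dmin <- Inf
        for (j in seq_len(N)) {
          if (M[j, k] > 0 && D[i, j] < dmin) dmin <- D[i, j]
        }
        O <- O + exp(-dmin / mu)
      }
    }
  }
  (O - N) / (L * N - N)
}

bc_oracle <- function(M) {
  links <- 0
  for (i in seq_len(nrow(M))) {
    for (k in seq_len(ncol(M))) {
      if (M[i, k] > 0) links <- links + 1
    }
  }
  (links - nrow(M)) / (ncol(M) * nrow(M) - nrow(M))
}

# Random taxon x region instance on a random tree; guarantees every taxon
# occupies >= 1 region and >= 2 regions are occupied. Branch lengths are
# bounded away from zero and the tree is rescaled to diameter 0.5 so that
# the mu -> 0 and mu -> Inf limit checks are sharp at their stated
# tolerances regardless of tree shape.
random_pbc_instance <- function(n_max = 30, l_max = 4) {
  N <- sample(4:n_max, 1)
  L <- sample(2:l_max, 1)
  tree <- ape::rtree(N)
  tree$edge.length <- runif(nrow(tree$edge), 0.1, 1)
  taxa <- tree$tip.label
  D <- as.matrix(stats::cophenetic(tree))[taxa, taxa]
  scale <- 2 * max(D)
  tree$edge.length <- tree$edge.length / scale
  D <- D / scale
  repeat {
    M <- matrix(rbinom(N * L, 1, 0.4), N, L,
                dimnames = list(taxa, paste0("r", seq_len(L))))
    none <- rowSums(M) == 0
    M[cbind(which(none), sample(L, sum(none), replace = TRUE))] <- 1L
    if (sum(colSums(M) > 0) >= 2) break
  }
  M <- M[, colSums(M) > 0, drop = FALSE]
  list(M = M, D = D, tree = tree)
}

# --- rank statistics --------------------------------------------------

# Pair-enumeration Kendall tau-b.
tau_oracle <- function(a, b) {
  n <- length(a)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(a[j] - a[i]) * sign(b[j] - b[i])
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tie_term <- function(x) {
    t <- table(x)
    sum(t * (t - 1) / 2)
  }
  (conc - disc) / sqrt((n0 - tie_term(a)) * (n0 - tie_term(b)))
}

rho_oracle <- function(a, b) {
  stats::cor(rank(a), rank(b))
}

# Count-of-pairs Mann-Whitney statistic: #(x > y) + ties / 2.
w_oracle <- function(x, y) {
  w <- 0
  for (xi in x) {
    for (yj in y) {
      if (xi > yj) w <- w + 1
      if (xi == yj) w <- w + 0.5
    }
  }
  w
}

# --- trees --------------------------------------------------------------

# Edge-count depth of every node (root = 0).
edge_count_depth <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  depth <- integer(n_nodes)
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  for (e in seq_len(nrow(edges))) {
    depth[edges[e, 2]] <- depth[edges[e, 1]] + 1L
  }
  depth
}

# Closed-form oracle for minimum-branch-length node ages:
# age(v) = max over descendant tips t of tip_age(t) + mbl * edges(v, t).
mbl_age_oracle <- function(tree, tip_age, mbl) {
  ntip <- ape::Ntip(tree)
  ecd <- edge_count_depth(tree)
  clades <- ape::prop.part(tree)
  ages <- numeric(tree$Nnode)
  for (v in seq_len(tree$Nnode)) {
    tips <- clades[[v]]
    node_id <- ntip + v
    ages[v] <- max(tip_age[tree$tip.label[tips]] +
                     mbl * (ecd[tips] - ecd[node_id]))
  }
  ages
}

# Patristic distance by summing edge lengths along the node path.
patristic_oracle <- function(tree) {
  n <- ape::Ntip(tree)
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  edge_len <- function(a, b) {
    hit <- (tree$edge[, 1] == a & tree$edge[, 2] == b) |
      (tree$edge[, 1] == b & tree$edge[, 2] == a)
    tree$edge.length[which(hit)]
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      path <- ape::nodepath(tree, i, j)
      d <- 0
      for (s in seq_len(length(path) - 1)) d <- d + edge_len(path[s], path[s + 1])
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

# --- GLS ----------------------------------------------------------------

# Dense-covariance profile log-likelihood at fixed phi (beta and sigma2
# profiled out with the full matrix inverse).
dense_ar1_loglik <- function(y, X, phi) {
  n <- length(y)
  R <- phi^abs(outer(seq_len(n), seq_len(n), "-"))
  Ri <- solve(R)
  beta <- solve(t(X) %*% Ri %*% X, t(X) %*% Ri %*% y)
  r <- y - X %*% beta
  sigma2 <- as.numeric(t(r) %*% Ri %*% r) / n
  as.numeric(-0.5 * (n * log(2 * pi * sigma2) + determinant(R)$modulus + n))
}

# Simulate one AR(1) regression dataset on the ln scale.
sim_ar1_regression <- function(n = 25, beta = c(2, 0.5), phi = 0.6,
                               sigma = 0.3, n_covariates = 1) {
  X <- matrix(rlnorm(n * n_covariates, meanlog = 3, sdlog = 0.5), n)
  colnames(X) <- paste0("x", seq_len(n_covariates))
  noise <- if (phi == 0) {
    rnorm(n, sd = sigma)
  } else {
    as.numeric(arima.sim(list(ar = phi), n, sd = sigma * sqrt(1 - phi^2)))
  }
  slopes <- beta[-1]
  y <- beta[1] + log(X[, seq_along(slopes), drop = FALSE]) %*% slopes + noise
  d <- as.data.frame(log(X))
  names(d) <- paste0("l", colnames(X))
  d$y <- as.numeric(y)
  d
}

# --- small fixtures ------------------------------------------------------

toy_tree <- function() pbcnet::parse_newick("((A:1,B:1):1,C:2);")

# Ten-taxon two-region dataset in which the only region-bridging taxa sit
# inside the 35-50 degree band; removing them segregates the fauna.
band_bridge_occurrences <- function() {
  dplyr::bind_rows(
    tibble::tibble(taxon = paste0("n", 1:4), region = "north", latitude = 55),
    tibble::tibble(taxon = paste0("s", 1:4), region = "south", latitude = 28),
    tibble::tibble(taxon = rep(c("b1", "b2"), each = 2),
                   region = rep(c("north", "south"), 2),
                   latitude = c(44, 42, 45, 41))
  )
}

band_bridge_tree <- function() {
  pbcnet::parse_newick(paste0(
    "(((n1:2,n2:2):2,(n3:2,n4:2):2):6,",
    "((s1:2,s2:2):2,(s3:2,s4:2):2):6,",
    "(b1:5,b2:5):5);"
  ))
}
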