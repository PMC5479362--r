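# Independent oracles used to freeze expected values: deliberately naive
# implementations that share no code with the package internals.

# All labeled DAGs on n nodes by brute force: iterate every digraph on
# n*(n-1) ordered pairs and keep the acyclic ones (no 2-cycles by
# construction of acyclicity).  Only feasible for n <= 4.
brute_force_dags <- function(nodes) {
  n <- length(nodes)
  pairs <- which(diag(n) == 0, arr.ind = TRUE)
  np <- nrow(pairs)
  out <- list()
  for (mask in 0:(2^np - 1)) {
    amat <- matrix(0L, n, n, dimnames = list(nodes, nodes))
    bits <- bitwAnd(mask, bitwShiftL(1L, seq_len(np) - 1L)) > 0
    amat[pairs[bits, , drop = FALSE]] <- 1L
    # acyclicity via repeated matrix powers
    acyclic <- TRUE
    p <- amat
    for (step in seq_len(n)) {
      if (any(diag(p) > 0)) { acyclic <- FALSE; break }
      p <- p %*% amat
    }
    if (acyclic) out[[length(out) + 1]] <- amat
  }
  out
}

# d-separation by exhaustive path enumeration: x and y are d-separated by z
# unless some undirected simple path between them is active.
path_enum_dsep <- function(amat, x, y, z) {
  n <- nrow(amat)
  sym <- (amat + t(amat)) > 0
  desc <- function(v) {
    # v plus all descendants
    seen <- rep(FALSE, n); frontier <- v; seen[v] <- TRUE
    while (length(frontier)) {
      nxt <- unique(unlist(lapply(frontier, function(u) which(amat[u, ] == 1L))))
      nxt <- nxt[!seen[nxt]]
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    which(seen)
  }
  active_path <- function(path) {
    if (length(path) <= 2) return(TRUE)
    for (i in 2:(length(path) - 1)) {
      v <- path[i]
      into_v <- amat[path[i - 1], v] == 1L && amat[path[i + 1], v] == 1L
      if (into_v) {
        if (!any(desc(v) %in% z)) return(FALSE)  # blocked collider
      } else {
        if (v %in% z) return(FALSE)              # blocked non-collider
      }
    }
    TRUE
  }
  found <- FALSE
  walk <- function(path) {
    if (found) return()
    v <- path[length(path)]
    if (v == y) {
      if (active_path(path)) found <<- TRUE
      return()
    }
    for (u in which(sym[v, ])) {
      if (!u %in% path) walk(c(path, u))
    }
  }
  walk(x)
  !found
}

# Exact correlation matrix of a linear-Gaussian DAG given coefficient matrix
# b (b[i, j] = coefficient of i in j's equation) and noise variances.
linear_gaussian_corr <- function(b, noise_var = rep(1, nrow(b))) {
  n <- nrow(b)
  a <- solve(diag(n) - t(b))          # x = a %*% eps
  cov <- a %*% diag(noise_var) %*% t(a)
  dimnames(cov) <- dimnames(b)
  stats::cov2cor(cov)
}

# Small benchmark DAGs with matching oracle correlations.
benchmark_cases <- function() {
  mk <- function(nodes, edges, coefs) {
    b <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
    for (i in seq_len(nrow(edges))) b[edges[i, 1], edges[i, 2]] <- coefs[i]
    list(dag = dag(nodes, edges), corr = linear_gaussian_corr(b))
  }
  list(
    chain3 = mk(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")), c(0.8, 0.8)),
    collider3 = mk(c("A", "B", "C"), rbind(c("A", "B"), c("C", "B")), c(0.7, 0.7)),
    chain4 = mk(c("A", "B", "C", "D"),
                rbind(c("A", "B"), c("B", "C"), c("C", "D")), c(0.8, 0.7, 0.8)),
    collider_tail4 = mk(c("A", "B", "C", "D"),
                        rbind(c("A", "B"), c("C", "B"), c("B", "D")), c(0.7, 0.7, 0.8)),
    diamond4 = mk(c("A", "B", "C", "D"),
                  rbind(c("A", "B"), c("A", "C"), c("B", "D"), c("C", "D")),
                  c(0.7, 0.6, 0.6, 0.5))
  )
}

# Markov equivalence of two DAG adjacency matrices: same skeleton and same
# unshielded colliders.
same_equivalence_class <- function(a1, a2) {
  sk1 <- (a1 + t(a1)) > 0; sk2 <- (a2 + t(a2)) > 0
  if (!identical(sk1, sk2)) return(FALSE)
  vstr <- function(a) {
    out <- character()
    n <- nrow(a)
    for (z in seq_len(n)) {
      pa <- which(a[, z] == 1L)
      for (i in pa) for (j in pa) {
        if (i < j && a[i, j] == 0L && a[j, i] == 0L) {
          out <- c(out, paste(i, z, j))
        }
      }
    }
    sort(out)
  }
  identical(vstr(a1), vstr(a2))
}
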