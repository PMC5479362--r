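#' Conditional-Gaussian network
#'
#' A DAG in which discrete nodes have only discrete parents and continuous
#' nodes follow linear-Gaussian equations whose intercept shifts with the
#' configuration of their discrete parents:
#' `X = base + sum(effect_d * z_d) + sum(coef_c * X_c) + eps`,
#' with `z_d` the 0/1-coded level of discrete parent `d` (so each discrete
#' configuration carries its own intercept) and `eps ~ N(0, var)`.
#' Because the per-configuration intercepts are additive in the parent
#' indicators, the whole system is a linear structural-equation model in the
#' indicators and noises, and its second moments -- hence the exact
#' correlation matrix -- are available in closed form.
#'
#' @param dag a [dag()].
#' @param discrete named list: for each discrete node, a probability vector
#'   over its category codes `1..K` (discrete nodes must be roots or have
#'   only discrete parents; the presets use root binaries).
#' @param continuous named list: for each continuous node, a list with
#'   `base`, `disc_effect` (named additive effects of the discrete parents'
#'   indicators), `coef` (named coefficients of the continuous parents) and
#'   `var` (noise variance).
#' @return an object of class `cmx_cgnet`.
#' @export
cg_network <- function(dag, discrete, continuous) {
  stopifnot(inherits(dag, "cmx_dag"))
  if (!setequal(c(names(discrete), names(continuous)), dag$nodes)) {
    stop("every node must be declared discrete or continuous")
  }
  for (d in names(discrete)) {
    pa <- dag$nodes[dag$amat[, match(d, dag$nodes)] == 1L]
    if (any(pa %in% names(continuous))) {
      stop("conditional-Gaussian constraint violated: discrete node '", d,
           "' has a continuous parent")
    }
    if (abs(sum(discrete[[d]]) - 1) > 1e-8) stop("probabilities for '", d, "' must sum to 1")
  }
  for (cn in names(continuous)) {
    pa <- dag$nodes[dag$amat[, match(cn, dag$nodes)] == 1L]
    spec <- continuous[[cn]]
    declared <- c(names(spec$disc_effect), names(spec$coef))
    if (!setequal(declared, pa)) {
      stop("parent coefficients for '", cn, "' do not match its parents in the DAG")
    }
  }
  structure(list(dag = dag, discrete = discrete, continuous = continuous),
            class = "cmx_cgnet")
}

#' @export
print.cmx_cgnet <- function(x, ...) {
  cat("Conditional-Gaussian network:", length(x$dag$nodes), "nodes (",
      length(x$discrete), "discrete,", length(x$continuous), "continuous ),",
      sum(x$dag$amat), "arcs\n")
  invisible(x)
}

#' The Waste Incinerator benchmark network
#'
#' The classic nine-node, ten-arc emission-control network: burning regime
#' (B), filter state (F) and waste type (W) are binary roots; filter
#' efficiency (E), CO2 concentration (C), metals in waste (MW), dust
#' emission (D), light penetrability (L) and metals emission (ME) are
#' conditional-Gaussian.  Two parameter presets are shipped: `"medium"`,
#' with moderate dependencies and a well-conditioned correlation matrix,
#' and `"high"`, where the dust/light/metals equations are almost
#' deterministic so the correlation matrix is close to singular.  Both
#' presets are overridable by editing the returned object.
#'
#' @param regime `"medium"` or `"high"` correlation preset.
#' @return a [cg_network()].
#' @export
waste_incinerator <- function(regime = c("medium", "high")) {
  regime <- match.arg(regime)
  nodes <- c("B", "F", "W", "C", "E", "MW", "D", "L", "ME")
  arcs <- rbind(
    c("F", "E"), c("W", "E"), c("W", "MW"), c("B", "C"),
    c("B", "D"), c("W", "D"), c("E", "D"), c("D", "L"),
    c("D", "ME"), c("MW", "ME"))
  g <- dag(nodes, arcs)
  discrete <- list(B = c(0.6, 0.4), F = c(0.7, 0.3), W = c(0.5, 0.5))
  if (regime == "medium") {
    noise <- c(C = 0.30, E = 0.30, MW = 0.35, D = 0.50, L = 0.60, ME = 0.60)
    coefL <- c(D = -0.7); coefME <- c(MW = 0.7, D = 0.55)
  } else {
    noise <- c(C = 0.30, E = 0.05, MW = 0.30, D = 0.005, L = 0.005, ME = 0.005)
    coefL <- c(D = -0.8); coefME <- c(MW = 0.9, D = 0.7)
  }
  continuous <- list(
    C  = list(base = -2,  disc_effect = c(B = 1.0),           coef = NULL,       var = noise[["C"]]),
    E  = list(base = -1,  disc_effect = c(F = -1.0, W = 1.2), coef = NULL,       var = noise[["E"]]),
    MW = list(base = 0.5, disc_effect = c(W = 1.0),           coef = NULL,       var = noise[["MW"]]),
    D  = list(base = 2,   disc_effect = c(B = 0.8, W = 0.6),  coef = c(E = 0.9), var = noise[["D"]]),
    L  = list(base = 3,   disc_effect = NULL,                 coef = coefL,      var = noise[["L"]]),
    ME = list(base = 0,   disc_effect = NULL,                 coef = coefME,     var = noise[["ME"]])
  )
  cg_network(g, discrete, continuous)
}

topological_order <- function(g) {
  amat <- g$amat
  ord <- integer(0)
  alive <- rep(TRUE, length(g$nodes))
  while (any(alive)) {
    indeg <- colSums(amat[alive, , drop = FALSE])
    src <- which(alive & indeg == 0)
    ord <- c(ord, src[1])
    alive[src[1]] <- FALSE
  }
  g$nodes[ord]
}

#' Forward-sample a conditional-Gaussian network
#'
#' Ancestral-order sampling: discrete nodes are drawn as category codes,
#' continuous nodes from their linear-Gaussian equations.  Identical seeds
#' give identical datasets.
#'
#' @param net a [cg_network()].
#' @param n number of rows.
#' @param seed optional integer seed.
#' @return a [mixed_data()] with the network's node order and types.
#' @export
sample_network <- function(net, n, seed = NULL) {
  if (n < 1) stop("n must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  nodes <- net$dag$nodes
  x <- matrix(NA_real_, n, length(nodes), dimnames = list(NULL, nodes))
  for (v in topological_order(net$dag)) {
    if (v %in% names(net$discrete)) {
      p <- net$discrete[[v]]
      x[, v] <- sample.int(length(p), n, replace = TRUE, prob = p)
    } else {
      spec <- net$continuous[[v]]
      mu <- rep(spec$base, n)
      for (d in names(spec$disc_effect)) mu <- mu + spec$disc_effect[[d]] * (x[, d] - 1)
      for (cc in names(spec$coef)) mu <- mu + spec$coef[[cc]] * x[, cc]
      x[, v] <- mu + stats::rnorm(n, 0, sqrt(spec$var))
    }
  }
  mixed_data(x, ifelse(nodes %in% names(net$discrete), "discrete", "continuous"))
}

#' Exact correlation matrix of a conditional-Gaussian network
#'
#' Closed-form second moments of the linear structural-equation system in
#' the discrete indicators and Gaussian noises (discrete codes enter as
#' numeric values).  Because every equation is exactly linear in its
#' parents' codes with independent errors, partial correlations vanish
#' exactly where the DAG implies d-separation, so this matrix serves as the
#' independence oracle for the benchmark.
#'
#' @param net a [cg_network()] whose discrete nodes are binary roots.
#' @return correlation matrix over the network's nodes.
#' @export
true_correlation <- function(net) {
  nodes <- net$dag$nodes
  k <- length(nodes)
  disc <- names(net$discrete)
  for (d in disc) {
    if (length(net$discrete[[d]]) != 2 || any(net$dag$amat[, match(d, nodes)] == 1L)) {
      stop("exact moments are implemented for binary root discrete nodes")
    }
  }
  # covariance of the code vector: codes = c(z + 1 for discrete, X for continuous)
  cov <- matrix(0, k, k, dimnames = list(nodes, nodes))
  # total-effect representation: value_v = const + sum_r w[v, r] * source_r
  # over independent sources (discrete indicators and per-node noises)
  sources <- c(disc, names(net$continuous))
  w <- matrix(0, k, length(sources), dimnames = list(nodes, sources))
  src_var <- c(vapply(disc, function(d) {
    p <- net$discrete[[d]][2]; p * (1 - p)
  }, numeric(1)),
  vapply(names(net$continuous), function(v) net$continuous[[v]]$var, numeric(1)))
  names(src_var) <- sources
  for (v in topological_order(net$dag)) {
    if (v %in% disc) {
      w[v, v] <- 1
    } else {
      spec <- net$continuous[[v]]
      w[v, v] <- 1  # own noise
      for (d in names(spec$disc_effect)) w[v, ] <- w[v, ] + spec$disc_effect[[d]] * w[d, ]
      for (cc in names(spec$coef)) w[v, ] <- w[v, ] + spec$coef[[cc]] * w[cc, ]
    }
  }
  cov <- w %*% (src_var * t(w))
  stats::cov2cor(cov)
}
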