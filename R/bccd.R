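#' Bayesian adjacency search
#'
#' Starts from the complete graph and deletes the edge between two variables
#' as soon as some conditional-independence statement about them reaches a
#' posterior reliability above `threshold`.  Conditioning sets are tried in
#' order of increasing size (0 up to `max_cond`, so scored windows never
#' exceed five variables), drawn from the variables currently adjacent to
#' either endpoint, with the adjacency structure frozen within each level so
#' the result does not depend on variable order.  Every scored window also
#' yields the posterior reliabilities of the ancestral ("cause") statements
#' between its members, which the orientation stage reuses.
#'
#' @param corr a [correlation_matrix()] (or named matrix, with `M` given).
#' @param M sample size; defaults to the matrix's recorded effective size.
#' @param threshold reliability above which an independence deletes an edge
#'   (strictly greater; recommended in (0.5, 1]).
#' @param max_cond largest conditioning-set size (capped at 3).
#' @return a list of class `cmx_skeleton`: `adjacency` (logical matrix),
#'   `statements` (reliability table, one row per evaluated statement),
#'   `sepsets`, `windows` (per-window cause reliabilities), `M`.
#' @export
adjacency_search <- function(corr, M = NULL, threshold = 0.6, max_cond = 3) {
  cm <- corr_of(corr)
  if (is.null(M)) {
    if (!inherits(corr, "cmx_corr")) stop("M is required when corr is a plain matrix")
    M <- corr$sample_size
  }
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  max_cond <- min(max_cond, 3)
  vars <- rownames(cm)
  k <- length(vars)
  adj <- matrix(TRUE, k, k, dimnames = list(vars, vars))
  diag(adj) <- FALSE
  sepsets <- list()
  cache <- new.env(parent = emptyenv())
  stmts <- list()

  for (level in 0:max_cond) {
    adj_frozen <- adj
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (!adj[i, j]) next
      cand <- vars[(adj_frozen[i, ] | adj_frozen[j, ])]
      cand <- setdiff(cand, vars[c(i, j)])
      if (length(cand) < level) next
      for (z in subsets_of_size(cand, level)) {
        win <- sort(c(vars[i], vars[j], z))
        sc <- window_scores(cache, cm, win, M)
        px <- match(vars[i], win); py <- match(vars[j], win)
        rel <- sc$indep[pair_index(length(win), min(px, py), max(px, py))]
        stmts[[length(stmts) + 1]] <- data.frame(
          kind = "independence", x = vars[i], y = vars[j],
          cond = paste(z, collapse = ";"), reliability = rel,
          window = paste(win, collapse = ";"), stringsAsFactors = FALSE)
        if (rel > threshold) {
          adj[i, j] <- adj[j, i] <- FALSE
          sepsets[[paste(vars[i], vars[j])]] <- z
          break
        }
      }
    }
  }

  structure(list(adjacency = adj,
                 statements = do.call(rbind, stmts),
                 sepsets = sepsets,
                 cache = cache, M = M, corr = cm, threshold = threshold),
            class = "cmx_skeleton")
}

# Score a window (sorted variable subset) once, caching the posterior summaries:
# indep[p]   reliability of "pair p independent given the window's rest"
# cause[i,j] reliability of "window[i] is an ancestor of window[j]"
window_scores <- function(cache, cm, win, M) {
  key <- paste(win, collapse = "\r")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  sc <- score_subset(cm, win, M)
  k <- length(win)
  indep <- as.vector(crossprod(sc$tables$dsep_rest + 0, sc$posterior))
  causevec <- as.vector(crossprod(sc$tables$ancestor + 0, sc$posterior))
  cause <- matrix(NA_real_, k, k, dimnames = list(win, win))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j) cause[i, j] <- causevec[ordered_pair_index(k, i, j)]
  }
  out <- list(indep = indep, cause = cause, win = win)
  cache[[key]] <- out
  out
}

#' Background knowledge: forbidden causes
#'
#' Builds the constraint object used by [orient_edges()].  Each rule forbids
#' one variable (or every variable, `"*"`) from being a cause -- an ancestor
#' -- of another, e.g. the prior that no variable in a study can cause
#' gender.  A forbidden cause both vetoes the corresponding "cause"
#' statements and injects the complementary non-cause statement with
#' reliability 1, which places an arrowhead at the forbidden tail.
#'
#' @param from,to character vectors (recycled) of rule endpoints; `"*"` in
#'   `from` means every other variable.
#' @param nodes optional node universe used to expand `"*"` and validate names.
#' @return a two-column character matrix of class `cmx_background`.
#' @export
forbid_cause <- function(from, to, nodes = NULL) {
  rules <- cbind(from = as.character(from), to = as.character(to))
  if (any(rules[, 1] == rules[, 2])) stop("inconsistent background: a rule forbids X -> X")
  if (!is.null(nodes)) {
    named <- setdiff(unique(c(rules)), "*")
    if (!all(named %in% nodes)) {
      stop("background rule names unknown variable(s): ",
           paste(setdiff(named, nodes), collapse = ", "))
    }
    expanded <- do.call(rbind, lapply(seq_len(nrow(rules)), function(r) {
      if (rules[r, 1] == "*") {
        cbind(from = setdiff(nodes, rules[r, 2]), to = rules[r, 2])
      } else {
        rules[r, , drop = FALSE]
      }
    }))
    rules <- unique(expanded)
  }
  structure(rules, class = c("cmx_background", class(rules)))
}

#' Reliability-ranked edge orientation
#'
#' Turns a learned skeleton into a PAG.  For every ordered adjacent pair the
#' reliability of the ancestral statement "x causes y" is taken from its most
#' decisive scored window (the window whose posterior is furthest from the
#' uninformative 1/2); statements are then processed in decreasing
#' reliability (ties broken lexicographically), and an accepted statement
#' sets a tail at the cause and an arrowhead at the effect.  Statements that
#' conflict with marks fixed by earlier (more reliable) statements are
#' skipped, and endpoints never touched remain circles.  Background rules
#' veto forbidden "cause" statements and contribute certain non-cause
#' statements (arrowhead at the forbidden tail).  By default only "cause"
#' statements learned from data orient edges; data-derived non-cause
#' statements are reported but do not orient unless `use_noncause = TRUE`,
#' because with a DAG-only hypothesis space they over-commit on equivalence
#' classes (every member of a chain's class, say, leaves each single
#' ancestral statement a minority).
#'
#' @param skeleton a `cmx_skeleton` from [adjacency_search()].
#' @param orient_threshold minimum reliability (strict) for a statement to
#'   orient; at the default 0.5, exactly tied evidence orients nothing.
#' @param background a [forbid_cause()] object, or `NULL`.
#' @param use_noncause also let data-derived non-cause statements place
#'   arrowheads.
#' @return a [pag()] with a `reliability` attribute (per-edge dependence
#'   reliability) and a `statements` attribute (the full reliability table).
#' @export
orient_edges <- function(skeleton, orient_threshold = 0.5, background = NULL,
                         use_noncause = FALSE) {
  adj <- skeleton$adjacency
  vars <- rownames(adj)
  k <- length(vars)
  if (!is.null(background)) background <- forbid_cause(background[, 1], background[, 2], vars)

  # make sure every surviving edge has at least one dedicated window that
  # includes its most connected neighbours (collider context)
  deg <- rowSums(adj)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!adj[i, j]) next
    nb <- setdiff(vars[adj[i, ] | adj[j, ]], vars[c(i, j)])
    nb <- nb[order(-deg[nb], nb)]
    win <- sort(c(vars[i], vars[j], utils::head(nb, 3)))
    window_scores(skeleton$cache, skeleton$corr, win, skeleton$M)
  }

  # most decisive window per ordered adjacent pair
  best <- array(NA_real_, c(k, k), dimnames = list(vars, vars))
  for (key in ls(skeleton$cache)) {
    sc <- skeleton$cache[[key]]
    win <- sc$win
    for (a in win) for (b in win) {
      if (a == b || !adj[a, b]) next
      r <- sc$cause[a, b]
      if (is.na(best[a, b]) || abs(r - 0.5) > abs(best[a, b] - 0.5)) best[a, b] <- r
    }
  }

  # candidate statements
  cand <- list()
  add <- function(kind, x, y, rel) {
    cand[[length(cand) + 1]] <<- data.frame(kind = kind, x = x, y = y,
                                            reliability = rel,
                                            stringsAsFactors = FALSE)
  }
  forbidden <- function(x, y) {
    !is.null(background) && any(background[, 1] == x & background[, 2] == y)
  }
  for (x in vars) for (y in vars) {
    if (x == y || !adj[x, y] || is.na(best[x, y])) next
    if (forbidden(x, y)) {
      add("noncause", x, y, 1)                    # background certainty
    } else {
      add("cause", x, y, best[x, y])
      if (use_noncause) add("noncause", x, y, 1 - best[x, y])
    }
  }
  stmts <- if (length(cand)) do.call(rbind, cand) else
    data.frame(kind = character(), x = character(), y = character(),
               reliability = numeric())
  stmts <- stmts[order(-stmts$reliability, stmts$kind, stmts$x, stmts$y), , drop = FALSE]

  # process in decreasing reliability
  amat <- matrix(0L, k, k, dimnames = list(vars, vars))
  amat[adj] <- MARK_CIRCLE
  fixed <- matrix(FALSE, k, k, dimnames = list(vars, vars))
  for (r in seq_len(nrow(stmts))) {
    s <- stmts[r, ]
    if (s$reliability <= orient_threshold) break
    if (s$kind == "cause") {
      # tail at x, arrowhead at y
      ok <- (!fixed[s$y, s$x] || amat[s$y, s$x] == MARK_TAIL) &&
            (!fixed[s$x, s$y] || amat[s$x, s$y] == MARK_ARROW)
      if (ok) {
        amat[s$y, s$x] <- MARK_TAIL; amat[s$x, s$y] <- MARK_ARROW
        fixed[s$y, s$x] <- fixed[s$x, s$y] <- TRUE
      }
    } else {
      # non-cause: arrowhead at x
      ok <- !fixed[s$y, s$x] || amat[s$y, s$x] == MARK_ARROW
      if (ok) {
        amat[s$y, s$x] <- MARK_ARROW
        fixed[s$y, s$x] <- TRUE
      }
    }
  }

  out <- pag(vars, amat)
  attr(out, "reliability") <- edge_reliabilities(skeleton)
  attr(out, "statements") <- orientation_table(skeleton, stmts)
  out
}

# Dependence reliability per surviving edge: one minus the strongest
# independence evidence seen for the pair.
edge_reliabilities <- function(skeleton) {
  adj <- skeleton$adjacency
  vars <- rownames(adj)
  tab <- skeleton$statements
  out <- numeric(0)
  for (i in seq_len(length(vars) - 1)) for (j in (i + 1):length(vars)) {
    if (!adj[i, j]) next
    sel <- (tab$x == vars[i] & tab$y == vars[j]) | (tab$x == vars[j] & tab$y == vars[i])
    key <- paste(min(vars[i], vars[j]), max(vars[i], vars[j]))
    out[key] <- 1 - if (any(sel)) max(tab$reliability[sel]) else 0
  }
  out
}

orientation_table <- function(skeleton, orient_stmts) {
  a <- skeleton$statements
  if (nrow(orient_stmts)) {
    b <- data.frame(kind = orient_stmts$kind, x = orient_stmts$x, y = orient_stmts$y,
                    cond = "", reliability = orient_stmts$reliability, window = "",
                    stringsAsFactors = FALSE)
    rbind(a, b)
  } else a
}

#' Causal discovery for mixed data with missing values
#'
#' The full pipeline: copula transform to normal scores, correlation
#' estimation (EM by default), Bayesian adjacency search, and
#' reliability-ranked orientation.  The result is a PAG whose edges carry
#' dependence reliabilities, together with the full statement table.
#'
#' @param data a [mixed_data()] object (or matrix with `NA`s).
#' @param estimator correlation estimator, see [estimate_correlation()].
#' @param threshold independence reliability above which an edge is deleted.
#' @param orient_threshold see [orient_edges()].
#' @param max_cond largest conditioning-set size.
#' @param background a [forbid_cause()] object or `NULL`.
#' @param use_noncause see [orient_edges()].
#' @param ... passed to the correlation estimator.
#' @return a list of class `cmx_bccd`: `pag`, `statements`, `correlation`,
#'   `skeleton`.
#' @export
run_bccd <- function(data, estimator = "em", threshold = 0.6,
                     orient_threshold = 0.5, max_cond = 3, background = NULL,
                     use_noncause = FALSE, ...) {
  corr <- estimate_correlation(data, estimator, ...)
  sk <- adjacency_search(corr, threshold = threshold, max_cond = max_cond)
  p <- orient_edges(sk, orient_threshold = orient_threshold,
                    background = background, use_noncause = use_noncause)
  structure(list(pag = p, statements = attr(p, "statements"),
                 correlation = corr, skeleton = sk),
            class = "cmx_bccd")
}

#' @export
print.cmx_bccd <- function(x, ...) {
  cat("BCCD result (estimator:", x$correlation$estimator,
      "| effective n =", x$correlation$sample_size, ")\n")
  print(x$pag)
  invisible(x)
}

#' BCCD from a known correlation matrix
#'
#' Oracle entry point: runs adjacency search and orientation directly from a
#' correlation matrix (e.g. the exact correlation of a benchmark network)
#' at a chosen score sample size.
#'
#' @inheritParams adjacency_search
#' @inheritParams orient_edges
#' @return a `cmx_bccd` list, as [run_bccd()].
#' @export
bccd_from_correlation <- function(corr, M = NULL, threshold = 0.6,
                                  orient_threshold = 0.5, max_cond = 3,
                                  background = NULL, use_noncause = FALSE) {
  if (!inherits(corr, "cmx_corr")) corr <- correlation_matrix(corr, M, "oracle")
  sk <- adjacency_search(corr, M = M, threshold = threshold, max_cond = max_cond)
  p <- orient_edges(sk, orient_threshold = orient_threshold,
                    background = background, use_noncause = use_noncause)
  structure(list(pag = p, statements = attr(p, "statements"),
                 correlation = corr, skeleton = sk),
            class = "cmx_bccd")
}
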