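#' Ground-truth PAG of a DAG
#'
#' Builds the partial ancestral graph of the Markov-equivalence class of the
#' maximal ancestral graph obtained by marginalizing `latent` out of `g`,
#' using an exact d-separation oracle: two observed variables are adjacent
#' when no subset of the remaining observed variables d-separates them;
#' unshielded colliders are oriented from the recorded separating sets; and
#' the complete orientation rules (R1-R4 and the tail rules R8-R10; no
#' selection bias is modeled) are applied to a fixpoint.  For a latent-free
#' benchmark this yields the DAG's skeleton with invariant endpoints oriented
#' and all others circled.
#'
#' @param g the generating [dag()].
#' @param latent character vector of latent (marginalized) variables;
#'   empty for the fully observed benchmark.
#' @return a [pag()] over the observed variables.
#' @examples
#' g <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("C", "B")))
#' ground_truth_pag(g)  # A o-> B <-o C
#' @export
ground_truth_pag <- function(g, latent = character()) {
  latent <- as.character(latent)
  if (!all(latent %in% g$nodes)) stop("latent names must be nodes of the DAG")
  obs <- setdiff(g$nodes, latent)
  if (length(obs) < 1) stop("no observed variables left")
  k <- length(obs)
  amat <- matrix(0L, k, k, dimnames = list(obs, obs))
  sepset <- vector("list", k * k)
  dim(sepset) <- c(k, k)

  # skeleton: oracle adjacency over all observed conditioning subsets
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      others <- setdiff(obs, c(obs[i], obs[j]))
      sep <- NULL
      for (sz in 0:length(others)) {
        for (z in subsets_of_size(others, sz)) {
          if (d_separated(g, obs[i], obs[j], z)) { sep <- z; break }
        }
        if (!is.null(sep)) break
      }
      if (is.null(sep)) {
        amat[i, j] <- amat[j, i] <- MARK_CIRCLE
      } else {
        sepset[[i, j]] <- sepset[[j, i]] <- sep
      }
    }
  }

  # unshielded colliders: x *-> z <-* y when z is outside sepset(x, y)
  for (z in seq_len(k)) {
    nb <- which(amat[, z] != 0L)
    if (length(nb) < 2) next
    for (x in nb) for (y in nb) {
      if (x < y && amat[x, y] == 0L && !(obs[z] %in% sepset[[x, y]])) {
        amat[x, z] <- MARK_ARROW
        amat[y, z] <- MARK_ARROW
      }
    }
  }

  amat <- apply_fci_rules(amat, sepset)
  pag(obs, amat)
}

subsets_of_size <- function(x, n) {
  if (n == 0) return(list(character()))
  if (length(x) < n) return(list())
  apply(utils::combn(length(x), n), 2, function(i) x[i], simplify = FALSE)
}

# Zhang's orientation rules on a mark matrix (amat[i, j] = mark at j).
# R5-R7 concern selection bias (undirected edges) and are not needed here.
apply_fci_rules <- function(amat, sepset) {
  k <- nrow(amat)
  adj <- function(i, j) amat[i, j] != 0L
  repeat {
    changed <- FALSE
    set <- function(i, j, mark) {
      if (amat[i, j] != mark) { amat[i, j] <<- mark; changed <<- TRUE }
    }

    for (b in seq_len(k)) {
      for (a in seq_len(k)) {
        if (a == b || !adj(a, b)) next
        for (c in seq_len(k)) {
          if (c == a || c == b || !adj(b, c)) next

          # R1: a *-> b o-* c, a and c non-adjacent  =>  b --> c
          if (!adj(a, c) && amat[a, b] == MARK_ARROW && amat[c, b] == MARK_CIRCLE) {
            set(b, c, MARK_ARROW); set(c, b, MARK_TAIL)
          }
          # R2: a -> b *-> c  or  a *-> b -> c, with a o-* c  =>  a *-> c
          if (adj(a, c) && amat[a, c] == MARK_CIRCLE) {
            if ((amat[a, b] == MARK_ARROW && amat[b, a] == MARK_TAIL &&
                 amat[b, c] == MARK_ARROW) ||
                (amat[a, b] == MARK_ARROW && amat[b, c] == MARK_ARROW &&
                 amat[c, b] == MARK_TAIL)) {
              set(a, c, MARK_ARROW)
            }
          }
          # R3: a *-> b <-* c, a *-o d o-* c, a,c non-adjacent, d *-o b => d *-> b
          if (!adj(a, c) && amat[a, b] == MARK_ARROW && amat[c, b] == MARK_ARROW) {
            for (d in seq_len(k)) {
              if (d %in% c(a, b, c)) next
              if (adj(a, d) && adj(c, d) &&
                  amat[a, d] == MARK_CIRCLE && amat[c, d] == MARK_CIRCLE &&
                  adj(d, b) && amat[d, b] == MARK_CIRCLE) {
                set(d, b, MARK_ARROW)
              }
            }
          }
        }
      }
    }

    # R4: discriminating paths
    for (b in seq_len(k)) for (c in seq_len(k)) {
      if (b == c || !adj(b, c) || amat[c, b] != MARK_CIRCLE) next
      for (a in seq_len(k)) {
        if (a %in% c(b, c) || !adj(a, b)) next
        if (amat[b, a] != MARK_ARROW) next  # a is a collider on the path
        if (!(adj(a, c) && amat[a, c] == MARK_ARROW && amat[c, a] == MARK_TAIL)) next
        d <- find_discriminating_origin(amat, a, b, c)
        if (!is.null(d)) {
          if (colnames(amat)[b] %in% sepset[[d, c]]) {
            set(b, c, MARK_ARROW); set(c, b, MARK_TAIL)
          } else {
            set(a, b, MARK_ARROW); set(b, a, MARK_ARROW)
            set(b, c, MARK_ARROW); set(c, b, MARK_ARROW)
          }
          break
        }
      }
    }

    # R8-R10: turn circles at the tail end of a o-> c into tails
    for (a in seq_len(k)) for (c in seq_len(k)) {
      if (a == c || !adj(a, c)) next
      if (!(amat[a, c] == MARK_ARROW && amat[c, a] == MARK_CIRCLE)) next
      # R8: a -> b -> c (or a -o b -> c)
      done <- FALSE
      for (b in seq_len(k)) {
        if (b %in% c(a, c) || !adj(a, b) || !adj(b, c)) next
        ab_dir <- amat[b, a] == MARK_TAIL && amat[a, b] %in% c(MARK_ARROW, MARK_CIRCLE)
        bc_dir <- amat[c, b] == MARK_TAIL && amat[b, c] == MARK_ARROW
        if (ab_dir && bc_dir) { set(c, a, MARK_TAIL); done <- TRUE; break }
      }
      if (done) next
      # R9: uncovered potentially-directed path a, b, ..., c with b not adjacent to c
      if (exists_upd_path(amat, a, c)) { set(c, a, MARK_TAIL); next }
      # R10: two uncovered p.d. paths from a into distinct non-adjacent parents of c
      parents_c <- which(vapply(seq_len(k), function(b) {
        b != c && adj(b, c) && amat[b, c] == MARK_ARROW && amat[c, b] == MARK_TAIL
      }, logical(1)))
      parents_c <- setdiff(parents_c, a)
      if (length(parents_c) >= 2) {
        hit <- FALSE
        for (bi in seq_along(parents_c)) {
          for (di in seq_along(parents_c)) {
            if (bi >= di) next
            s1 <- upd_path_starts(amat, a, parents_c[bi])
            s2 <- upd_path_starts(amat, a, parents_c[di])
            for (m1 in s1) for (m2 in s2) {
              if (m1 != m2 && !adj(m1, m2)) { hit <- TRUE; break }
            }
            if (hit) break
          }
          if (hit) break
        }
        if (hit) set(c, a, MARK_TAIL)
      }
    }

    if (!changed) break
  }
  amat
}

# Search for the far end d of a discriminating path <d, ..., a, b, c>: every
# interior vertex is a collider on the path and a parent of c, and d is not
# adjacent to c.  Returns d's index or NULL.
find_discriminating_origin <- function(amat, a, b, c) {
  k <- nrow(amat)
  visited <- rep(FALSE, k)
  visited[c(a, b, c)] <- TRUE
  frontier <- a
  while (length(frontier)) {
    nxt <- integer()
    for (v in frontier) {
      # v is a collider-parent on the path; extend with u *-> v
      for (u in seq_len(k)) {
        if (visited[u] || amat[u, v] == 0L) next
        if (amat[u, v] != MARK_ARROW) next
        if (amat[u, c] == 0L) return(u)  # u not adjacent to c: discriminating
        # otherwise u must itself be a collider-parent of c to extend
        if (amat[u, c] == MARK_ARROW && amat[c, u] == MARK_TAIL &&
            amat[v, u] == MARK_ARROW) {
          visited[u] <- TRUE
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- nxt
  }
  NULL
}

# Potentially-directed edge u ~ v: no arrowhead at u, no tail at v.
pd_edge <- function(amat, u, v) {
  amat[u, v] != 0L && amat[v, u] != MARK_ARROW && amat[u, v] != MARK_TAIL
}

# Is there an uncovered potentially-directed path from a to c whose first
# intermediate vertex is not adjacent to c (R9's condition)?
exists_upd_path <- function(amat, a, c) {
  length(upd_path_starts(amat, a, c, require_start_nonadjacent = TRUE)) > 0
}

# First intermediate vertices b of uncovered potentially-directed paths
# a, b, ..., target (used by R9 and R10).
upd_path_starts <- function(amat, a, target, require_start_nonadjacent = FALSE) {
  k <- nrow(amat)
  starts <- integer()
  for (b in seq_len(k)) {
    if (b %in% c(a, target) || !pd_edge(amat, a, b)) next
    if (require_start_nonadjacent && amat[b, target] != 0L) next
    if (upd_reaches(amat, a, b, target)) starts <- c(starts, b)
  }
  starts
}

upd_reaches <- function(amat, prev, cur, target) {
  if (cur == target) return(TRUE)
  if (pd_edge(amat, cur, target) && amat[prev, target] == 0L) return(TRUE)
  k <- nrow(amat)
  # depth-first over uncovered p.d. extensions
  rec <- function(p, v, seen) {
    for (w in seq_len(k)) {
      if (seen[w] || w == p || !pd_edge(amat, v, w)) next
      if (amat[p, w] != 0L) next  # covered triple
      if (w == target) return(TRUE)
      seen2 <- seen; seen2[w] <- TRUE
      if (rec(v, w, seen2)) return(TRUE)
    }
    FALSE
  }
  seen <- rep(FALSE, nrow(amat)); seen[c(prev, cur)] <- TRUE
  rec(prev, cur, seen)
}
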