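# Dense linear-assignment solver (Hungarian algorithm with potentials,
# shortest-augmenting-path formulation, O(n^2 m)). Track linking poses small
# square problems (tens to a couple hundred nodes per frame pair), for which
# this is ample. Verified in the tests against exhaustive enumeration.

#' Solve a linear assignment problem
#'
#' Finds, for an `n x m` cost matrix with `n <= m`, the column assignment
#' `j(i)` minimizing `sum_i cost[i, j(i)]` with all `j(i)` distinct.
#'
#' @param cost numeric matrix, `nrow(cost) <= ncol(cost)`, finite entries.
#' @return integer vector of length `nrow(cost)`: the column matched to each
#'   row.
#' @keywords internal
solve_assignment <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  stopifnot(n >= 1L, n <= m, all(is.finite(cost)))
  inf <- .Machine$double.xmax / 4
  u <- numeric(n + 1L)            # row potentials, index 1 = virtual row 0
  v <- numeric(m + 1L)            # column potentials, index 1 = virtual col 0
  p <- integer(m + 1L)            # p[j + 1]: row matched to column j
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(inf, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      jfree <- which(!used[-1L])
      cur <- cost[i0, jfree] - u[i0 + 1L] - v[jfree + 1L]
      upd <- cur < minv[jfree + 1L]
      if (any(upd)) {
        minv[jfree[upd] + 1L] <- cur[upd]
        way[jfree[upd] + 1L] <- j0
      }
      k <- which.min(minv[jfree + 1L])
      j1 <- jfree[k]
      delta <- minv[j1 + 1L]
      usedj <- which(used) - 1L
      u[p[usedj + 1L] + 1L] <- u[p[usedj + 1L] + 1L] + delta
      v[usedj + 1L] <- v[usedj + 1L] - delta
      minv[jfree + 1L] <- minv[jfree + 1L] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  match <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) match[p[j + 1L]] <- j
  match
}
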