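#' Minimum-cost assignment (Hungarian algorithm)
#'
#' Solves the rectangular assignment problem min sum_i cost[i, a(i)] over
#' injective assignments a, for n <= m, using the Kuhn-Munkres algorithm
#' with row/column potentials and shortest augmenting paths (O(n^2 m)).
#' Deterministic: ties are resolved by the lowest column index.
#'
#' @param cost numeric n x m matrix of finite costs, n <= m.
#' @return list with `assignment` (integer n-vector, column for each row)
#'   and `cost` (the optimal total cost).
#' @export
#' @examples
#' solveAssignment(rbind(c(4, 1, 3), c(2, 0, 5), c(3, 2, 2)))
solveAssignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L) return(list(assignment = integer(), cost = 0))
  if (n > m) stop("cost matrix must have nrow <= ncol")
  if (any(!is.finite(cost))) stop("costs must be finite")

  u <- numeric(n)          # row potentials
  v <- numeric(m + 1L)     # column potentials; index j+1, col 0 is virtual
  p <- integer(m + 1L)     # p[j+1] = row currently assigned to column j

  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    way <- integer(m)
    used <- logical(m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])
      cur <- cost[i0, free] - u[i0] - v[free + 1L]
      imp <- cur < minv[free]
      if (any(imp)) {
        minv[free[imp]] <- cur[imp]
        way[free[imp]] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedCols <- which(used)
      u[p[usedCols]] <- u[p[usedCols]] + delta
      v[usedCols] <- v[usedCols] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {                      # augment along the alternating path
      j1 <- way[j0]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) assignment[p[j + 1L]] <- j
  list(assignment = assignment,
       cost = sum(cost[cbind(seq_len(n), assignment)]))
}
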