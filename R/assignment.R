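#' Solve the linear assignment problem (Hungarian method)
#'
#' Minimum-cost perfect matching on a square cost matrix via the
#' shortest-augmenting-path formulation with dual potentials
#' (Jonker-Volgenant style, O(n^3)). For maximum-weight matching pass
#' `maximize = TRUE`.
#'
#' @param cost square numeric matrix; `cost[i, j]` is the cost of assigning
#'   row i to column j.
#' @param maximize if TRUE, maximize total weight instead.
#' @return list with `assignment` (integer vector: column matched to each
#'   row) and `total` (the optimal total of the original matrix entries).
#' @export
solve_assignment <- function(cost, maximize = FALSE) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(n == ncol(cost), n >= 1, all(is.finite(cost)))
  orig <- cost
  if (maximize) cost <- -cost
  np1 <- n + 1L  # virtual column
  u <- numeric(np1); v <- numeric(np1)
  p <- integer(np1)   # p[j]: row currently assigned to column j (0 = none)
  way <- integer(np1)
  for (i in seq_len(n)) {
    p[np1] <- i
    j0 <- np1
    minv <- rep(Inf, n)
    used <- rep(FALSE, np1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(np1)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else if (j <= n) {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == np1) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j]] <- j
  list(assignment = assignment,
       total = sum(orig[cbind(seq_len(n), assignment)]))
}
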