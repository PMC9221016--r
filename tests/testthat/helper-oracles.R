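# Independent oracles and small fixture builders shared across tests.

# All permutations of a vector (for brute-force assignment enumeration).
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# Brute-force minimum assignment cost over all row->column injections
# (enumerates every permutation of the columns; n <= m required).
brute_force_assignment_cost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  best <- Inf
  for (p in all_perms(seq_len(m))) {
    a <- p[seq_len(n)]
    cst <- sum(cost[cbind(seq_len(n), a)])
    if (cst < best) best <- cst
  }
  best
}

# Greedy matching: repeatedly take the closest remaining admissible pair.
# Returns the total matched distance and the number of pairs formed.
greedy_match_distance <- function(d, radius) {
  total <- 0
  nMatched <- 0L
  while (length(d) && any(d <= radius)) {
    k <- which(d == min(d), arr.ind = TRUE)[1, ]
    total <- total + d[k[1], k[2]]
    nMatched <- nMatched + 1L
    d <- d[-k[1], -k[2], drop = FALSE]
  }
  list(total = total, nMatched = nMatched)
}

# Hand product-limit estimator (no censoring adjustment shortcuts).
hand_km <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  data.frame(time = ut, surv = out)
}

# Hand two-group log-rank statistic: sum of observed-minus-expected events
# in group 1 at each event time, squared over the hypergeometric variance.
hand_log_rank <- function(times, events, groups) {
  g <- as.integer(factor(groups)) - 1L   # 0 / 1
  ut <- sort(unique(times[events == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ut) {
    n <- sum(times >= t)
    n1 <- sum(times >= t & g == 1L)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1L)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (O - E)^2 / V
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}

# The worked five-cell scenario: 3 inflammatory + 2 cancer ground-truth
# cells, one detection misclassified, one spurious detection, two misses.
worked_scenario <- function() {
  gt <- cellRecords(1:5,
                    row = c(10, 40, 70, 10, 60),
                    col = c(10, 40, 70, 60, 10),
                    class = c("inflammatory", "inflammatory", "inflammatory",
                              "cancer", "cancer"),
                    area = rep(50L, 5))
  pred <- cellRecords(1:4,
                      row = c(10, 40, 10, 90),
                      col = c(10, 40, 60, 90),
                      class = c("inflammatory", "cancer", "cancer",
                                "inflammatory"),
                      area = rep(50L, 4))
  list(gt = gt, pred = pred, radius = 5)
}

# A small patch spec that renders quickly and keeps ground-truth centroids
# far enough apart that corruption bookkeeping maps 1:1 onto matching.
small_patch_spec <- function(seed = NULL, nInflam = 8, nCancer = 4,
                             nOther = 3, sizePx = 192) {
  patchSpec(sizePx = sizePx, seed = seed, minSeparation = 10,
            nuclei = list(
              inflammatory = list(n = nInflam, radius = c(3.5, 5),
                                  axisRatio = c(0.75, 1),
                                  hOd = c(0.85, 1.0), eOd = c(0.05, 0.15)),
              cancer = list(n = nCancer, radius = c(7.5, 10),
                            axisRatio = c(0.8, 1),
                            hOd = c(0.45, 0.65), eOd = c(0.1, 0.2)),
              other = list(n = nOther, radius = c(7, 9),
                           axisRatio = c(0.3, 0.42),
                           hOd = c(0.6, 0.8), eOd = c(0.1, 0.2))))
}

# Per-patient one-row-per-patient view of a long cohort table.
patient_view <- function(cohort) {
  u <- cohort[!duplicated(cohort$patient_id), ]
  u[order(u$patient_id), ]
}
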