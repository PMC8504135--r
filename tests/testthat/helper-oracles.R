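# Independent brute-force oracles. These deliberately use naive double loops
# and explicit formulas so they share no code path with the package.

# negative log partial likelihood, Breslow risk sets {j : T_j >= T_i}
brute_cox_loss <- function(scores, time, event) {
  loss <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      rs <- which(time >= time[i])
      loss <- loss - (scores[i] - log(sum(exp(scores[rs]))))
    }
  }
  loss
}

# Harrell's C by pair enumeration
brute_cindex <- function(scores, time, event) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      permissible <- event[i] == 1 &&
        (time[i] < time[j] || (time[i] == time[j] && event[j] == 0))
      if (permissible) {
        den <- den + 1
        if (scores[i] > scores[j]) num <- num + 1
        else if (scores[i] == scores[j]) num <- num + 0.5
      }
    }
  }
  if (den == 0) stop("no permissible pairs")
  num / den
}

# two-group log-rank chi-square from the explicit at-risk table
brute_logrank <- function(time, event, group) {
  g1 <- levels(factor(group))[1L]
  ev_times <- sort(unique(time[event == 1]))
  U <- 0; V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    U <- U + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  U^2 / V
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / choose2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# central finite differences of f at x
num_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1L))
}

# quick survival_table from vectors
make_surv <- function(time, event, ids = paste0("s", seq_along(time)), ...) {
  as_survival_table(data.frame(sample_id = ids,
                               time = time, event = event, ...))
}

# random censored survival instance with possible tied times; always has at
# least one permissible pair (an event at the earliest distinct time)
random_instance <- function(n, tie_prob = 0.3) {
  time <- round(rexp(n, 0.2) + 0.1, digits = if (runif(1) < tie_prob) 0 else 3)
  time <- pmax(time, 0.1)
  if (length(unique(time)) == 1L) time[1L] <- time[1L] / 2
  event <- rbinom(n, 1, 0.7)
  event[which.min(time)] <- 1L
  list(time = time, event = event, scores = rnorm(n))
}

# small cohort with planted linear risk on the first gene
toy_cohort <- function(name = "toy", n = 60, n_genes = 8, seed = 1,
                       censor_frac = 0.25) {
  set.seed(seed)
  x <- matrix(rnorm(n * n_genes), nrow = n_genes,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0(name, "_s", seq_len(n))))
  h <- x[1L, ]
  time <- rexp(n, rate = 0.2 * exp(h))
  cens <- runif(n) < censor_frac
  event <- as.integer(!cens)
  if (sum(event) == 0) event[1L] <- 1L
  cohort(name, x - min(x),
         make_surv(pmax(time, 1e-6), event, ids = colnames(x)))
}
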