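# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: density metrics via a full distance matrix,
# model enumeration via a filter over an explicit truth table, likelihoods
# via generic numerical optimization.

# exhaustive all-pairs NND/NTND for a single farm-year point set
oracle_density <- function(x, y, k = 3, cap = 1000) {
  n <- length(x)
  D <- as.matrix(dist(cbind(x, y)))
  diag(D) <- Inf
  nnd <- numeric(n); ntnd <- numeric(n)
  for (i in seq_len(n)) {
    d <- pmin(sort(D[i, ]), cap)
    nnd[i] <- if (n > 1) d[1] else cap
    dk <- if (n > 1) d[seq_len(min(k, n - 1))] else numeric(0)
    ntnd[i] <- mean(c(dk, rep(cap, k - length(dk))))
  }
  list(nnd = nnd, ntnd = ntnd)
}

# parent terms, written independently of the package's parser
oracle_parents <- function(tm) {
  if (grepl(":", tm)) return(unlist(strsplit(tm, ":")))
  if (startsWith(tm, "I(") && endsWith(tm, "^2)"))
    return(substr(tm, 3, nchar(tm) - 3))
  character(0)
}

# brute-force enumeration + lm/AICc ranking for a gaussian global model
oracle_dredge_gaussian <- function(response, free, locked, data) {
  m <- length(free)
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), m))
  models <- list()
  for (r in seq_len(nrow(grid))) {
    terms_in <- c(locked, free[unlist(grid[r, ])])
    ok <- TRUE
    for (tm in terms_in)
      if (!all(oracle_parents(tm) %in% terms_in)) ok <- FALSE
    if (!ok) next
    fo <- if (length(terms_in))
      as.formula(paste(response, "~", paste(terms_in, collapse = "+")))
    else as.formula(paste(response, "~ 1"))
    fit <- lm(fo, data = data)
    ll <- logLik(fit)
    k <- attr(ll, "df"); n <- nobs(fit)
    models[[length(models) + 1]] <- data.frame(
      sig = paste(sort(terms_in), collapse = "&"),
      aicc = -2 * as.numeric(ll) + 2 * k + 2 * k * (k + 1) / (n - k - 1))
  }
  out <- do.call(rbind, models)
  out[order(out$aicc), , drop = FALSE]
}

# random global-model structure with at most max_free free terms
random_structure <- function(max_free = 6) {
  vars <- c("A", "B", "C", "D")
  mains <- sample(vars, sample(2:4, 1))
  extras <- character(0)
  if (length(mains) >= 2) {
    pairs <- combn(mains, 2, FUN = function(p) paste(p, collapse = ":"))
    extras <- sample(pairs, min(length(pairs), sample(0:2, 1)))
  }
  quad <- if (runif(1) < 0.5) paste0("I(", sample(mains, 1), "^2)")
  terms <- c(mains, extras, quad)
  terms[seq_len(min(length(terms), max_free))]
}

# visit-history builder
visits_df <- function(days, statuses, n_nestlings = NULL) {
  v <- data.frame(day = days, status = statuses)
  if (!is.null(n_nestlings)) v$n_nestlings <- n_nestlings
  v
}
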