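# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: least squares goes through base qr()/lm.fit and
# selection through exhaustive refitting.

rms_of <- function(x) sqrt(mean(x^2))

# Exhaustive greedy center selection: at each step refit the full
# least-squares problem for every remaining candidate and keep the one with
# the largest SSE decrease (equivalently smallest SSE). Ties within 1e-12
# relative break toward the smaller candidate index.
oracle_greedy_centers <- function(y, sigma, M) {
  p <- length(y)
  phi_all <- outer(seq_len(p), seq_len(p),
                   function(n, c) exp(-(n - c)^2 / (2 * sigma^2)))
  selected <- integer(0)
  sse_prev <- sum(y^2)
  for (L in seq_len(M)) {
    cand <- setdiff(seq_len(p), selected)
    sse <- vapply(cand, function(k) {
      X <- phi_all[, c(selected, k), drop = FALSE]
      fit <- lm.fit(X, y)
      sum(fit$residuals^2)
    }, numeric(1))
    dec <- (sse_prev - sse) / sum(y^2)
    dmax <- max(dec)
    tie <- which(dec >= dmax - 1e-12 * abs(dmax))
    j <- tie[which.min(cand[tie])]
    selected <- c(selected, cand[j])
    sse_prev <- sse[j]
  }
  selected
}

# AUC by exhaustive pairwise comparison of all (vt, normal) score pairs.
oracle_pairwise_auc <- function(scores, labels) {
  sv <- scores[labels == "vt"]
  sn <- scores[labels == "normal"]
  total <- 0
  for (a in sv) for (b in sn)
    total <- total + (if (a > b) 1 else if (a == b) 0.5 else 0)
  100 * total / (length(sv) * length(sn))
}

# Best-TPA threshold by exhaustive scan over all cutoffs (every score value
# and values beyond the range).
oracle_best_tpa <- function(scores, labels) {
  cands <- c(sort(unique(scores)), min(scores) - 1, max(scores) + 1)
  max(vapply(cands, function(t) {
    pred <- scores >= t
    100 * mean((pred & labels == "vt") | (!pred & labels == "normal"))
  }, numeric(1)))
}

# Energy-conservation check (orthogonal decomposition): returns the relative
# error of sum(g^2 h) + e'e against y'y for an OLS fit.
energy_relerr <- function(fit, y) {
  if (inherits(y, "beat_signal")) y <- y$samples
  yty <- sum(y^2)
  abs(sum(fit$trace$gains^2 * fit$trace$ortho_norms) + fit$sse - yty) / yty
}
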