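# Brute-force oracle for the ordered-state HMM posterior: enumerate every
# monotone state path that starts in state 1, ends in state K, and advances
# by at most one state per step, and sum path probabilities directly.
# Independent of the package's forward-backward implementation.

oracle_posterior <- function(recall, template, p_stay = NULL) {
  mu <- template$patterns
  k <- nrow(mu)
  tt <- nrow(recall)
  if (is.null(p_stay)) p_stay <- if (tt == 1) 1 else 1 - (k - 1) / (tt - 1)
  zrow <- function(m) t(apply(m, 1, function(r) (r - mean(r)) / sd(r)))
  x <- zrow(recall)
  muz <- zrow(mu)
  logem <- sapply(seq_len(k), function(j)
    -colSums((t(x) - muz[j, ])^2) / (2 * template$sigma2))
  logem <- matrix(logem, nrow = tt)

  paths <- if (k == 1) {
    matrix(1L, 1, tt)
  } else {
    adv <- utils::combn(tt - 1, k - 1)  # transition indices where state advances
    t(apply(adv, 2, function(pos) {
      s <- integer(tt)
      s[1] <- 1L
      for (t in 2:tt) s[t] <- s[t - 1] + as.integer((t - 1) %in% pos)
      s
    }))
  }
  lw <- apply(paths, 1, function(s) {
    em <- sum(logem[cbind(seq_len(tt), s)])
    if (tt == 1) return(em)
    steps <- diff(s)
    em + sum(ifelse(steps == 0, log(p_stay), log(1 - p_stay)))
  })
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  gamma <- matrix(0, tt, k)
  for (i in seq_len(nrow(paths)))
    gamma[cbind(seq_len(tt), paths[i, ])] <-
      gamma[cbind(seq_len(tt), paths[i, ])] + w[i]
  gamma
}
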