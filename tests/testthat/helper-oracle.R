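# Independent oracle: exhaustive enumeration of the per-chromosome
# outcome tree through meiosis I, meiosis II and fertilisation. Built
# from first principles (probability bookkeeping over small discrete
# states), never from the simulator under test.

# Convolve two discrete pmfs given as data.frames of state columns + prob.
conv_pmf <- function(a, b, cols) {
  out <- merge(a, b, by = NULL, suffixes = c(".a", ".b"))
  for (cl in cols) out[[cl]] <- out[[paste0(cl, ".a")]] + out[[paste0(cl, ".b")]]
  out$prob <- out$prob.a * out$prob.b
  stats::aggregate(prob ~ ., data = out[, c(cols, "prob")], FUN = sum)
}

# Pmf of one univalent's MI contribution to the egg: (dyads, singles).
univalent_pmf <- function(p_pssc) {
  intact <- data.frame(d = c(1, 0), s = c(0, 0), prob = c(0.5, 0.5))
  sep <- data.frame(d = c(0, 0, 0), s = c(0, 1, 2),
                    prob = c(0.25, 0.5, 0.25))
  intact$prob <- intact$prob * (1 - p_pssc)
  sep$prob <- sep$prob * p_pssc
  stats::aggregate(prob ~ d + s, data = rbind(intact, sep), FUN = sum)
}

# Pmf of the egg content (dyads d, singles s) of one chromosome.
egg_pmf <- function(p_bivalent, p_pssc) {
  uni <- conv_pmf(univalent_pmf(p_pssc), univalent_pmf(p_pssc), c("d", "s"))
  uni$prob <- uni$prob * (1 - p_bivalent)
  biv <- data.frame(d = 1, s = 0, prob = p_bivalent)
  stats::aggregate(prob ~ d + s, data = rbind(biv, uni), FUN = sum)
}

# Pmf of (zygote maternal chromatids z, pb2 chromatids b) given egg (d, s).
mii_pmf_given <- function(d, s, p_ndj) {
  pmf <- data.frame(z = 0, b = 0, prob = 1)
  dyad <- data.frame(z = c(1, 2, 0), b = c(1, 0, 2),
                     prob = c(1 - p_ndj, p_ndj / 2, p_ndj / 2))
  single <- data.frame(z = c(1, 0), b = c(0, 1), prob = c(0.5, 0.5))
  for (i in seq_len(d)) pmf <- conv_pmf(pmf, dyad, c("z", "b"))
  for (i in seq_len(s)) pmf <- conv_pmf(pmf, single, c("z", "b"))
  pmf[pmf$prob > 0, ]
}

# Full per-chromosome joint pmf over (egg d, egg s, zygote maternal z,
# pb2 b) for one chromosome under the given parameters.
enumerate_chromosome <- function(p_bivalent, p_pssc, p_mii_ndj) {
  eg <- egg_pmf(p_bivalent, p_pssc)
  rows <- lapply(seq_len(nrow(eg)), function(i) {
    m <- mii_pmf_given(eg$d[i], eg$s[i], p_mii_ndj)
    data.frame(d = eg$d[i], s = eg$s[i], z = m$z, b = m$b,
               prob = eg$prob[i] * m$prob)
  })
  out <- do.call(rbind, rows)
  stats::aggregate(prob ~ d + s + z + b, data = out, FUN = sum)
}

# Marginal pmf of a derived integer statistic, small probabilities pooled.
marginal_pmf <- function(joint, value, pool_below = 0) {
  df <- stats::aggregate(prob ~ v, data = data.frame(v = value,
                                                     prob = joint$prob),
                         FUN = sum)
  if (pool_below > 0) {
    keep <- df$prob >= pool_below
    pooled <- sum(df$prob[!keep])
    df <- df[keep, ]
    if (pooled > 0) df <- rbind(df, data.frame(v = NA, prob = pooled))
  }
  df
}

# Check empirical frequencies of an integer vector against an oracle pmf
# within k binomial standard errors per category (pooled tail = NA row).
expect_freqs_match <- function(x, pmf, k = 3) {
  n <- length(x)
  for (i in seq_len(nrow(pmf))) {
    v <- pmf$v[i]; p <- pmf$prob[i]
    obs <- if (is.na(v)) mean(!x %in% pmf$v[!is.na(pmf$v)]) else mean(x == v)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(obs - p), k * se + 1e-12,
              label = sprintf("freq of outcome %s (obs %.4f vs %.4f)",
                              v, obs, p))
  }
}

# Exact mean reciprocity fraction E[R/K | K > 0] over n_chrom iid
# chromosomes, where per chromosome R (reciprocal) and K (polar-body
# aneuploid) events have the category probabilities implied by truth
# calls: zygote aneuploid iff z != 1, pb aneuploid iff b != 1, signs
# from the deviation direction. Dynamic programming over (r, k).
oracle_mean_reciprocity <- function(params, n_chrom = 20) {
  joint <- enumerate_chromosome(params$p_bivalent, params$p_pssc,
                                params$p_mii_ndj)
  pb_aneu <- joint$b != 1
  recip <- pb_aneu & ((joint$z > 1 & joint$b < 1) | (joint$z < 1 & joint$b > 1))
  pA <- sum(joint$prob[recip])                 # pb aneuploid & reciprocal
  pB <- sum(joint$prob[pb_aneu & !recip])      # pb aneuploid, not reciprocal
  pC <- 1 - pA - pB                            # pb neutral
  dp <- matrix(0, nrow = n_chrom + 1, ncol = n_chrom + 1)  # [r+1, k+1]
  dp[1, 1] <- 1
  for (i in seq_len(n_chrom)) {
    nd <- matrix(0, nrow = n_chrom + 1, ncol = n_chrom + 1)
    for (r in 0:(i - 1)) for (kk in r:(i - 1)) {
      p <- dp[r + 1, kk + 1]
      if (p == 0) next
      nd[r + 2, kk + 2] <- nd[r + 2, kk + 2] + p * pA
      nd[r + 1, kk + 2] <- nd[r + 1, kk + 2] + p * pB
      nd[r + 1, kk + 1] <- nd[r + 1, kk + 1] + p * pC
    }
    dp <- nd
  }
  num <- 0; pk_pos <- 0
  for (r in 0:n_chrom) for (kk in max(r, 1):n_chrom) {
    num <- num + dp[r + 1, kk + 1] * r / kk
    pk_pos <- pk_pos + dp[r + 1, kk + 1]
  }
  list(mean = num / pk_pos, p_defined = pk_pos)
}
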