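# Independent brute-force oracles used to cross-check the package's
# implementations, plus small fixture builders.

# Welch t via stats::t.test, gene by gene
welch_oracle <- function(a, b) {
  out <- lapply(seq_len(nrow(a)), function(i) {
    tt <- t.test(a[i, ], b[i, ], var.equal = FALSE)
    c(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
  })
  do.call(rbind, out)
}

# Benjamini-Hochberg step-up by the definition: sort ascending, q_(i) =
# min_{j >= i} m p_(j) / j, capped at 1, mapped back to input order
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- pmin(1, rev(cummin(rev(m * p[ord] / seq_len(m)))))
  out <- numeric(m)
  out[ord] <- q
  out
}

# two-sided exact binomial p by full enumeration (minimum-likelihood rule)
binom_oracle <- function(k, n, p0) {
  probs <- dbinom(0:n, n, p0)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# naive ward.D2 agglomeration: merge the closest pair, Lance-Williams update
# on squared dissimilarities, heights on the original distance scale
ward_d2_heights_oracle <- function(x) {
  s <- as.matrix(dist(x))^2
  n <- nrow(s)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1L) {
    sub <- s[active, active, drop = FALSE]
    diag(sub) <- Inf
    ij <- which(sub == min(sub), arr.ind = TRUE)[1L, ]
    i <- active[ij[1L]]; j <- active[ij[2L]]
    heights <- c(heights, sqrt(s[i, j]))
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      s_new <- ((ni + nk) * s[i, k] + (nj + nk) * s[j, k] - nk * s[i, j]) /
        (ni + nj + nk)
      s[i, k] <- s_new; s[k, i] <- s_new
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  sort(heights)
}

# sample coordinates from a direct eigendecomposition of the gene covariance
# (v is genes x samples; genes are centered across samples, as in pca_embed)
pca_oracle <- function(v) {
  xc <- scale(t(v), center = TRUE, scale = FALSE)   # samples x genes
  cov_g <- crossprod(xc) / (nrow(xc) - 1)
  eig <- eigen(cov_g, symmetric = TRUE)
  list(scores = xc %*% eig$vectors, values = pmax(eig$values, 0))
}

# adjusted Rand index between two labelings
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# small deterministic expression matrix fixture
toy_expression <- function(values, unit = "LOG2_TPM1",
                           sample_class = "CELL_LINE",
                           gene_prefix = "g", sample_prefix = "s") {
  if (is.null(rownames(values)))
    rownames(values) <- paste0(gene_prefix, seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0(sample_prefix, seq_len(ncol(values)))
  expression_matrix(values, unit = unit, sample_class = sample_class)
}
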