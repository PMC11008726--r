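# shared fixture builders and independent oracles

# tiny recording whose samples are planted templates (optionally noisy)
make_template_eeg <- function(templates, labels, amplitude = NULL,
                              noise_sd = 0, sfreq = 250, seed = 1) {
  if (is.null(amplitude)) amplitude <- rep(1, length(labels))
  generate_eeg(templates, labels, amplitude, noise_sd = noise_sd,
               sfreq = sfreq, seed = seed)
}

# brute-force windowed pair count: number of consecutive pairs (L_u = i,
# L_{u+1} in to_set) with both samples inside [t - w + 1, t]
naive_pair_count <- function(labels, i, to_set, w, t) {
  a <- max(1, t - w + 1)
  if (t - a < 1) return(0L)
  u <- a:(t - 1)
  sum(labels[u] == i & labels[u + 1] %in% to_set)
}

# brute-force per-sample global explained variance (independent of the
# package's vectorized implementation)
naive_gev <- function(data, templates, labels) {
  x <- sweep(data, 2, colMeans(data))
  n <- ncol(x); p <- nrow(x)
  num <- 0; den <- 0
  for (t in seq_len(n)) {
    v <- x[, t]
    gfp2 <- mean(v^2)
    den <- den + gfp2
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) {
      tpl <- templates[labels[t], ]
      num <- num + gfp2 * (sum(v * tpl) / nrm)^2
    }
  }
  num / den
}

# exhaustive best 2-partition of maps by total explained variance
# (leading-eigenvector centroids); returns assignment in {1,2}
exhaustive_two_partition <- function(maps) {
  m <- nrow(maps)
  ev_of <- function(members) {
    if (length(members) == 0) return(0)
    M <- maps[members, , drop = FALSE]
    sum(eigen(crossprod(M), symmetric = TRUE, only.values = TRUE)$values[1])
  }
  best <- -Inf; best_assign <- NULL
  for (code in 0:(2^(m - 1) - 1)) {       # map 1 fixed in cluster 1
    assign_vec <- c(1L, as.integer(bitwAnd(code, 2^(0:(m - 2))) > 0) + 1L)
    if (!any(assign_vec == 2)) next
    ev <- ev_of(which(assign_vec == 1)) + ev_of(which(assign_vec == 2))
    if (ev > best) { best <- ev; best_assign <- assign_vec }
  }
  list(assignment = best_assign, ev = best)
}

# match recovered templates to planted ones: best absolute correlation
# assignment (greedy over the small K! permutation set)
template_match <- function(recovered, planted) {
  k <- nrow(planted)
  cors <- abs(recovered %*% t(planted))
  perms <- msbold:::permutations_of(k)
  scores <- apply(perms, 1, function(pm) sum(cors[cbind(pm, seq_len(k))]))
  pm <- perms[which.max(scores), ]
  cors[cbind(pm, seq_len(k))]               # |corr| per planted template
}

# mean dwell time of a label sequence, in samples
mean_dwell_samples <- function(labels) {
  mean(rle(as.integer(labels))$lengths)
}
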