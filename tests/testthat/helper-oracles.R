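# shared fixtures and slow-path oracles for the test suite

# cache enumerated path sets per (n, m, mode, restrict): the set depends only
# on the shape and mode, so random-instance sweeps can reuse it
path_cache <- new.env(parent = emptyenv())

cached_paths <- function(n, m, params) {
  key <- paste(n, m, params$align_mode, params$restrict_turns, sep = "|")
  if (is.null(path_cache[[key]])) {
    path_cache[[key]] <- enumerate_paths(n, m, params)
  }
  path_cache[[key]]
}

# fast oracle: score every enumerated path on a score matrix
oracle_scores <- function(a, paths, params) {
  vapply(paths, function(p) {
    s <- if (nrow(p$matches) > 0) sum(a[p$matches + 1L]) else 0
    s + p$n_open * params$open + p$n_extend * params$extend
  }, numeric(1))
}

oracle_smooth <- function(a, params, paths = NULL) {
  if (is.null(paths)) paths <- cached_paths(nrow(a), ncol(a), params)
  sc <- oracle_scores(a, paths, params)
  params$temperature * smurf:::logsumexp(sc / params$temperature)
}

oracle_posterior <- function(a, params, paths = NULL) {
  if (is.null(paths)) paths <- cached_paths(nrow(a), ncol(a), params)
  sc <- oracle_scores(a, paths, params)
  w <- sc / params$temperature
  w <- exp(w - smurf:::logsumexp(w))
  P <- matrix(0, nrow(a), ncol(a))
  for (t in seq_along(paths)) {
    mt <- paths[[t]]$matches
    if (nrow(mt) > 0) P[mt + 1L] <- P[mt + 1L] + w[t]
  }
  P
}

all_mode_params <- function(temperature = 1) {
  out <- list()
  for (mode in c("local", "global")) {
    for (gm in c("linear", "affine")) {
      for (rt in c(FALSE, TRUE)) {
        p <- if (gm == "linear") {
          align_params(temperature = temperature, gap = -1.1,
                       align_mode = mode, restrict_turns = rt)
        } else {
          align_params(temperature = temperature, gap_mode = "affine",
                       open = -2.3, extend = -0.4, align_mode = mode,
                       restrict_turns = rt)
        }
        out[[length(out) + 1L]] <- p
      }
    }
  }
  out
}

# ground-truth match-pair recovery of an A3M against a synthetic family
family_match_recovery <- function(msa, fam) {
  paths <- a3m_paths(msa)[-1]
  tot <- 0
  hit <- 0
  for (k in seq_along(paths)) {
    tp <- fam$true_alignment[[k + 1L]]
    hp <- paths[[k]]
    tkey <- tp[, 1] * 10000 + tp[, 2]
    hkey <- hp[, 1] * 10000 + hp[, 2]
    tot <- tot + length(tkey)
    hit <- hit + sum(tkey %in% hkey)
  }
  hit / tot
}

# independent mean-top-t-precision implementation (metric oracle), written
# directly from the definition with its own ranking code
oracle_contact_auc <- function(scores, truth_df, L, min_sep = 6L) {
  ii <- c(); jj <- c(); ss <- c()
  for (i in seq_len(L - 1L)) {
    for (j in seq(i + 1L, L)) {
      if (j - i >= min_sep) {
        ii <- c(ii, i); jj <- c(jj, j); ss <- c(ss, scores[i, j])
      }
    }
  }
  ord <- order(-ss, ii, jj)
  ii <- ii[ord]; jj <- jj[ord]
  tkey <- paste(pmin(truth_df$i, truth_df$j), pmax(truth_df$i, truth_df$j))
  tkey <- tkey[abs(truth_df$j - truth_df$i) >= min_sep]
  correct <- paste(ii, jj) %in% tkey
  prec <- numeric(L)
  for (t in seq_len(L)) {
    k <- min(t, length(correct))
    prec[t] <- sum(correct[seq_len(k)]) / t
  }
  mean(prec)
}

random_onehot_seq <- function(len, alphabet = "protein") {
  a <- smurf::smurf_alphabet(alphabet)
  paste(sample(a$letters, len, replace = TRUE), collapse = "")
}
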