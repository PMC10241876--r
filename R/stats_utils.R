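# Shared pairwise-comparison machinery: Tukey-Kramer studentized-range
# p-values on group data and the insert-and-absorb compact letter display.

# Compact letter display. `sig` is a k x k logical matrix (TRUE = pair
# significantly different); groups sharing a letter are not significantly
# different. Letters are assigned so the group with the highest mean gets
# "a". Classic insert-and-absorb: start from one column holding everyone,
# split any column containing a significant pair, absorb subset columns.
.cld <- function(labels, means, sig) {
  k <- length(labels)
  stopifnot(nrow(sig) == k, ncol(sig) == k)
  ord <- order(-means)
  cols <- list(seq_len(k))
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  if (nrow(pairs)) {
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      new_cols <- list()
      for (col in cols) {
        if (i %in% col && j %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, i)), list(setdiff(col, j)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb: drop any column that is a subset of another
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) {
        for (b in seq_along(new_cols)) {
          if (a != b && keep[b] &&
              all(new_cols[[a]] %in% new_cols[[b]]) &&
              !(all(new_cols[[b]] %in% new_cols[[a]]) && a < b)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      cols <- unique(new_cols[keep])
    }
  }
  # order columns by the best (highest-mean) group they contain
  rank_of <- match(seq_len(k), ord)  # rank 1 = highest mean
  best <- vapply(cols, function(col) min(rank_of[col]), numeric(1))
  cols <- cols[order(best)]
  letts <- vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(cols, function(col) g %in% col, logical(1)))],
          collapse = "")
  }, character(1))
  letts
}

# Tukey-Kramer pairwise comparisons from group summaries. `df` and `s2` are
# the error degrees of freedom and pooled variance; q = |mi - mj| /
# sqrt(s2/2 (1/ni + 1/nj)), referred to the studentized range with k means.
.tukey_pairwise <- function(labels, means, ns, s2, df, alpha = 0.05) {
  k <- length(labels)
  sig <- matrix(FALSE, k, k, dimnames = list(labels, labels))
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se_ij <- sqrt(s2 / 2 * (1 / ns[i] + 1 / ns[j]))
      q <- if (se_ij > 0) abs(means[i] - means[j]) / se_ij else
        if (means[i] == means[j]) 0 else Inf
      p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
      sig[i, j] <- sig[j, i] <- is.finite(q) && p < alpha || is.infinite(q)
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = labels[i], group2 = labels[j],
        diff = means[i] - means[j], q = q, p = p,
        significant = sig[i, j], stringsAsFactors = FALSE)
    }
  }
  list(pairwise = do.call(rbind, rows), sig = sig,
       letters = .cld(labels, means, sig))
}

.se <- function(x) stats::sd(x) / sqrt(length(x))
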