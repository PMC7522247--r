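# Independent oracles used to validate the implementation: brute-force
# enumerations and literal transcriptions, deliberately written without
# reference to the package internals.

# Brute-force window counting: a double loop over (sample, window) with an
# explicit overlap test per SV record.
oracle_count_samples <- function(svs, windows, chrom) {
  chrom_len <- windows$end[nrow(windows)]
  n_win <- nrow(windows)
  count <- integer(n_win)
  count_by_type <- matrix(0L, nrow = 5, ncol = n_win,
                          dimnames = list(sv_types(), NULL))
  footprint <- function(row) {
    iv <- list()
    if (row$svtype %in% c("DUP", "DEL")) {
      if (row$chrom1 == chrom) {
        iv[[1]] <- c(min(row$start1, row$start2), max(row$end1, row$end2))
      }
    } else {
      if (row$chrom1 == chrom) iv[[length(iv) + 1]] <- c(row$start1, row$end1)
      if (row$chrom2 == chrom) iv[[length(iv) + 1]] <- c(row$start2, row$end2)
    }
    lapply(iv, function(x) c(x[1], max(x[2], x[1] + 1)))
  }
  for (w in seq_len(n_win)) {
    ws <- windows$start[w]; we <- windows$end[w]
    for (s in unique(svs$sample)) {
      hit_types <- character()
      rows <- which(svs$sample == s)
      for (r in rows) {
        for (iv in footprint(svs[r, ])) {
          if (iv[1] < we && iv[2] > ws && iv[1] < chrom_len && iv[2] > 0) {
            hit_types <- c(hit_types, svs$svtype[r])
          }
        }
      }
      if (length(hit_types)) {
        count[w] <- count[w] + 1L
        for (t in unique(hit_types)) {
          count_by_type[t, w] <- count_by_type[t, w] + 1L
        }
      }
    }
  }
  list(count = count, count_by_type = count_by_type)
}

# Literal simulation of the cluster / top-peak / k-delta merge procedure on
# a list of candidate peaks (each a list with start, end, count, samples).
oracle_merge <- function(cands, d, k, delta) {
  if (!length(cands)) return(list())
  ord <- order(vapply(cands, `[[`, 0, "start"))
  cands <- cands[ord]
  # single-linkage clustering by inter-peak gap
  clusters <- list()
  current <- list(cands[[1]])
  for (i in seq_along(cands)[-1]) {
    prev_end <- current[[length(current)]]$end
    if (cands[[i]]$start - prev_end <= d) {
      current[[length(current) + 1]] <- cands[[i]]
    } else {
      clusters[[length(clusters) + 1]] <- current
      current <- list(cands[[i]])
    }
  }
  clusters[[length(clusters) + 1]] <- current
  out <- list()
  for (cluster in clusters) {
    remaining <- cluster
    while (length(remaining)) {
      counts <- vapply(remaining, `[[`, 0, "count")
      starts <- vapply(remaining, `[[`, 0, "start")
      best <- which(counts == max(counts))
      top_i <- best[which.min(starts[best])]
      top <- remaining[[top_i]]
      merged_idx <- top_i
      for (dir in c(-1, 1)) {
        walk <- if (dir < 0) rev(seq_len(top_i - 1)) else
          seq_along(remaining)[seq_along(remaining) > top_i]
        consecutive_bad <- 0
        for (i in walk) {
          change <- abs(top$count - remaining[[i]]$count) / top$count
          if (change < delta) {
            merged_idx <- c(merged_idx, i)
            consecutive_bad <- 0
          } else {
            consecutive_bad <- consecutive_bad + 1
            if (consecutive_bad >= k) break
          }
        }
      }
      members <- remaining[merged_idx]
      samples <- sort(unique(unlist(lapply(members, `[[`, "samples"))))
      out[[length(out) + 1]] <- list(
        start = min(vapply(members, `[[`, 0, "start")),
        end = max(vapply(members, `[[`, 0, "end")),
        count = length(samples),
        samples = samples
      )
      remaining <- remaining[-merged_idx]
    }
  }
  out[order(vapply(out, `[[`, 0, "start"))]
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# choose(n, n_a) assignments of the pooled (tie-free) values.
oracle_wilcoxon_exact <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  n_a <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combos <- utils::combn(length(pooled), n_a)
  u_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n_a * (n_a + 1) / 2
  })
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Literal Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running <- 1
  for (i in rev(seq_len(m))) {
    running <- min(running, m * p[ord[i]] / i)
    q[ord[i]] <- running
  }
  q
}

# Hypergeometric upper tail P(X >= x) by direct summation of point masses.
oracle_hyper_tail <- function(x, size_a, size_b, n) {
  ks <- seq(max(0, x), min(size_a, size_b))
  if (x > min(size_a, size_b)) return(0)
  sum(exp(lchoose(size_a, ks) + lchoose(n - size_a, size_b - ks) -
            lchoose(n, size_b)))
}

# Chi-square upper tail by numerical integration of the density.
oracle_chisq_upper <- function(stat, df) {
  stats::integrate(function(x) stats::dchisq(x, df), stat, Inf,
                   rel.tol = 1e-12)$value
}

# Random SV sets for counting properties.
random_sv_set <- function(n_sv, samples, chroms, chrom_len) {
  types <- sv_types()
  rows <- lapply(seq_len(n_sv), function(i) {
    svtype <- sample(types, 1)
    c1 <- sample(chroms, 1)
    if (svtype == "BND") {
      c2 <- sample(chroms, 1)
    } else {
      c2 <- c1
    }
    s1 <- sample.int(chrom_len - 2, 1)
    e1 <- s1 + sample.int(min(200000, chrom_len - s1), 1)
    s2 <- sample.int(chrom_len - 2, 1)
    e2 <- s2 + sample.int(min(200000, chrom_len - s2), 1)
    tibble::tibble(chrom1 = c1, start1 = s1, end1 = e1, chrom2 = c2,
                   start2 = s2, end2 = e2,
                   sample = sample(samples, 1), svtype = svtype)
  })
  dplyr::bind_rows(rows)
}
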