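# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and the stats:: shortcuts behind them): ranks, tie corrections,
# tail sums and the greedy clustering rule are all spelled out from first
# principles so the implementation can be checked against them.

midranks <- function(x) {
  # average-rank computation by explicit counting
  sapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2)
}

oracle_kruskal <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- midranks(values)
  H <- 0
  for (g in levels(groups)) {
    idx <- groups == g
    H <- H + sum(idx) * (mean(r[idx]) - (N + 1) / 2)^2
  }
  H <- H * 12 / (N * (N + 1))
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- H / C
  list(H = H, p = pchisq(H, df = nlevels(groups) - 1, lower.tail = FALSE))
}

oracle_dunn <- function(values, groups) {
  groups <- factor(as.character(groups), levels = c("L", "N", "F"))
  N <- length(values)
  r <- midranks(values)
  ties <- table(values)
  sumT <- sum(ties^3 - ties)
  v <- N * (N + 1) / 12 - sumT / (12 * (N - 1))
  pair <- function(i, j) {
    ni <- sum(groups == i); nj <- sum(groups == j)
    z <- (mean(r[groups == j]) - mean(r[groups == i])) /
      sqrt(v * (1 / ni + 1 / nj))
    z
  }
  z <- c(LN = pair("L", "N"), NF = pair("N", "F"), LF = pair("L", "F"))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

# Upper-tail hypergeometric P(X >= k) by direct summation of the pmf,
# choose() only.
oracle_hyper_upper <- function(k, bg_size, bg_hits, fg_size) {
  kmax <- min(bg_hits, fg_size)
  if (k > kmax) return(0)
  ks <- max(k, max(0, fg_size - (bg_size - bg_hits))):kmax
  sum(choose(bg_hits, ks) * choose(bg_size - bg_hits, fg_size - ks)) /
    choose(bg_size, fg_size)
}

# BH step-up by the definition q_(i) = min_{j>=i} p_(j) m / j.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(p[ord][i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Literal emulation of the greedy longest-first clustering rule: a plain
# double loop over contigs in (length desc, id asc) order.
oracle_greedy_clusters <- function(contig_ids, lengths, edge_list,
                                   min_identity = 95, min_coverage = 0.85) {
  qualifies <- function(a, b) {
    best_i <- -Inf; best_l <- -Inf
    for (e in edge_list) {
      if ((e$q == a && e$t == b) || (e$q == b && e$t == a)) {
        if (e$id > best_i || (e$id == best_i && e$len > best_l)) {
          best_i <- e$id; best_l <- e$len
        }
      }
    }
    if (!is.finite(best_i)) return(FALSE)
    shorter <- min(lengths[match(a, contig_ids)], lengths[match(b, contig_ids)])
    best_i >= min_identity && best_l / shorter >= min_coverage
  }
  ord <- order(-lengths, contig_ids)
  reps <- character(0)
  assignment <- character(length(contig_ids))
  names(assignment) <- contig_ids
  for (i in ord) {
    cid <- contig_ids[i]
    placed <- FALSE
    for (rp in reps) {
      if (qualifies(cid, rp)) { assignment[cid] <- rp; placed <- TRUE; break }
    }
    if (!placed) { reps <- c(reps, cid); assignment[cid] <- cid }
  }
  assignment
}

# Canonical cluster signature (sorted member sets) for comparing partitions.
cluster_signature <- function(assignment) {
  parts <- split(names(assignment), assignment)
  paste(sort(vapply(parts, function(m) paste(sort(m), collapse = ","),
                    character(1))), collapse = ";")
}

catalog_signature <- function(catalog) {
  paste(sort(vapply(catalog$members, function(m) paste(sort(m), collapse = ","),
                    character(1))), collapse = ";")
}

# Adjacency-matrix variant of the greedy oracle, for exhaustive graph
# enumeration where every present edge qualifies at the thresholds.
oracle_greedy_adj <- function(contig_ids, lengths, adj) {
  ord <- order(-lengths, contig_ids)
  reps <- integer(0)
  assignment <- character(length(contig_ids))
  names(assignment) <- contig_ids
  for (i in ord) {
    placed <- FALSE
    for (r in reps) {
      if (adj[i, r]) { assignment[contig_ids[i]] <- contig_ids[r]; placed <- TRUE; break }
    }
    if (!placed) { reps <- c(reps, i); assignment[contig_ids[i]] <- contig_ids[i] }
  }
  assignment
}
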