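# Independent brute-force oracles and random-input generators used across the
# suite. These deliberately share no code with the package implementations.

BASES <- c("A", "C", "G", "T")

random_dna <- function(len, n_prob = 0) {
  letters <- if (n_prob > 0) c(BASES, "N") else BASES
  prob <- if (n_prob > 0) c(rep((1 - n_prob) / 4, 4), n_prob) else rep(0.25, 4)
  paste(sample(letters, len, replace = TRUE, prob = prob), collapse = "")
}

revcomp_chr <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# all k-tuples, lexicographic over A < C < G < T (ASCII radix sort)
oracle_tuples <- function(k) {
  g <- do.call(expand.grid,
               c(rep(list(BASES), k), stringsAsFactors = FALSE))
  sort(apply(g, 1, paste, collapse = ""), method = "radix")
}

# naive sliding-window k-tuple counter; windows containing N skipped
oracle_count <- function(seqs, k, use_complement = TRUE) {
  tup <- oracle_tuples(k)
  counts <- setNames(numeric(length(tup)), tup)
  all_seqs <- seqs
  if (use_complement) all_seqs <- c(all_seqs, vapply(seqs, revcomp_chr, ""))
  for (s in all_seqs) {
    L <- nchar(s)
    if (L < k) next
    for (i in seq_len(L - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (!grepl("N", w, fixed = TRUE)) counts[w] <- counts[w] + 1
    }
  }
  counts
}

# naive Markov estimation: transition[u, b] from (r+1)-tuple window counts
# over seqs (+ reverse complements), pseudocount s; initial from r-tuples
oracle_markov <- function(seqs, r, pseudocount = 0) {
  c1 <- oracle_count(seqs, r + 1)
  ctx <- if (r == 0) "" else oracle_tuples(r)
  trans <- matrix(0, length(ctx), 4, dimnames = list(ctx, BASES))
  for (i in seq_along(ctx)) for (b in BASES) {
    trans[i, b] <- c1[paste0(ctx[i], b)] + pseudocount
  }
  rs <- rowSums(trans)
  trans <- trans / ifelse(rs == 0, 1, rs)
  trans[rowSums(trans) == 0, ] <- 0.25
  initial <- if (r == 0) 1 else {
    c0 <- oracle_count(seqs, r)
    c0 / sum(c0)
  }
  list(transitions = trans, initial = initial, order = r)
}

oracle_tuple_prob <- function(m, w) {
  r <- m$order
  p <- if (r == 0) 1 else unname(m$initial[substr(w, 1, r)])
  for (i in seq_len(nchar(w) - r)) {
    ctx <- if (r == 0) 1 else substr(w, i, i + r - 1)
    p <- p * m$transitions[ctx, substr(w, i + r, i + r)]
  }
  unname(p)
}

# independent un-binned d2S / d2* on two read sets: naive counts, naive
# order-r sample background, naive per-tuple probabilities, direct formulas
oracle_d2_nobin <- function(reads_x, reads_y, k, r) {
  stat <- function(reads) {
    cnt <- oracle_count(reads, k)
    m <- oracle_markov(reads, r)
    p <- vapply(names(cnt), function(w) oracle_tuple_prob(m, w), numeric(1))
    e <- sum(cnt) * p
    list(xbar = cnt - e, e = e)
  }
  X <- stat(reads_x)
  Y <- stat(reads_y)
  den <- sqrt(X$xbar^2 + Y$xbar^2)
  ok <- den > 0
  num <- sum((X$xbar * Y$xbar / den)[ok])
  nx <- sqrt(sum((X$xbar^2 / den)[ok]))
  ny <- sqrt(sum((Y$xbar^2 / den)[ok]))
  d2s_val <- 0.5 * (1 - num / (nx * ny))
  ok2 <- X$e > 0 & Y$e > 0
  num2 <- sum((X$xbar * Y$xbar / sqrt(X$e * Y$e))[ok2])
  nx2 <- sqrt(sum((X$xbar^2 / X$e)[ok2]))
  ny2 <- sqrt(sum((Y$xbar^2 / Y$e)[ok2]))
  d2star_val <- 0.5 * (1 - num2 / (nx2 * ny2))
  c(d2s = d2s_val, d2star = d2star_val)
}

# triplet topology oracle from leaf-descendant sets: {a,b} resolve against c
# iff some node's descendant leaf set contains a and b but not c
oracle_triplet_codes <- function(tree, labels, idx) {
  ntip <- length(tree$tip.label)
  desc <- vector("list", max(tree$edge))
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  po <- reorder(tree, "postorder")
  for (e in seq_len(nrow(po$edge)))
    desc[[po$edge[e, 1]]] <- c(desc[[po$edge[e, 1]]], desc[[po$edge[e, 2]]])
  internal <- desc[(ntip + 1):length(desc)]
  pair_resolves <- function(x, y, z) {
    any(vapply(internal, function(s)
      x %in% s && y %in% s && !(z %in% s), logical(1)))
  }
  apply(idx, 2, function(t3) {
    a <- labels[t3[1]]; b <- labels[t3[2]]; c3 <- labels[t3[3]]
    if (pair_resolves(a, b, c3)) 1L
    else if (pair_resolves(a, c3, b)) 2L
    else if (pair_resolves(b, c3, a)) 3L
    else 0L
  })
}

oracle_triplet_distance <- function(t1, t2, unresolved = "compatible") {
  labels <- sort(t1$tip.label)
  idx <- combn(length(labels), 3)
  c1 <- oracle_triplet_codes(t1, labels, idx)
  c2 <- oracle_triplet_codes(t2, labels, idx)
  if (unresolved == "mismatch") sum(c1 != c2)
  else sum(c1 != c2 & c1 > 0 & c2 > 0)
}

# random rooted tree on n sorted labels; optionally collapse short branches
# into polytomies
random_rooted_tree <- function(n, polytomies = FALSE) {
  tr <- ape::rtree(n, rooted = TRUE)
  tr$tip.label <- sample(paste0("L", sprintf("%02d", seq_len(n))))
  if (polytomies) tr <- ape::di2multi(tr, tol = stats::quantile(tr$edge.length, 0.3))
  tr
}

# small read sets drawn from a composition-biased generator (for pipeline
# equivalence tests)
random_reads <- function(n, len, gc = 0.5) {
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n), function(i)
    paste(sample(BASES, len, replace = TRUE, prob = prob), collapse = ""), "")
}
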