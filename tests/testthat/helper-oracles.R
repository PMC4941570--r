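# Brute-force oracles shared across test files.

# minimum number of valid clusters (each cluster has a member at >=
# threshold identity to all others) by branch-and-bound over assignments
oracle_min_partition <- function(sim) {
  n <- nrow(sim)
  best <- list(k = n + 1, assign = NULL)
  assign <- integer(n)
  recurse <- function(i, k) {
    if (k >= best$k) return()
    if (i > n) {
      best <<- list(k = k, assign = assign[1:n])
      return()
    }
    for (c in seq_len(k)) {
      members <- which(assign[seq_len(i - 1)] == c)
      cand <- c(members, i)
      # cluster stays valid iff some member covers all others
      valid <- any(vapply(cand, function(ctr) all(sim[ctr, cand]), TRUE))
      if (valid) {
        assign[i] <<- c
        recurse(i + 1, k)
      }
    }
    assign[i] <<- k + 1
    recurse(i + 1, k + 1)
    assign[i] <<- 0L
  }
  recurse(1L, 0L)
  best
}

# canonical partition representation for set comparison
canon_partition <- function(ids, groups) {
  sort(unname(vapply(split(ids, groups), function(g) {
    paste(sort(g), collapse = ",")
  }, "")))
}


# independent two-segment oracle: split the query at a crossover grid and
# align the two pieces separately
oracle_two_segment <- function(q, refs, step = 10) {
  best <- list(identity = -Inf)
  L <- nchar(q)
  for (a in names(refs)) for (b in names(refs)) {
    if (a == b) next
    for (cx in seq(50, L - 50, by = step)) {
      r1 <- globalIdentity(substr(q, 1, cx), refs[[a]])
      r2 <- globalIdentity(substr(q, cx + 1, L), refs[[b]])
      iden <- 100 * (r1$matches + r2$matches) / L
      if (iden > best$identity) {
        best <- list(identity = iden, parent_a = a, parent_b = b,
                     crossover = cx)
      }
    }
  }
  best
}

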