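# Independent oracles used to cross-check the package implementations.
# They deliberately take different algorithmic routes: the SSR oracle
# tests every (start, unit, count) triple by substring comparison, the
# PIC oracle evaluates both sums of the Botstein formula with explicit
# double loops, and the UPGMA oracle is average-linkage hclust via
# phangorn.

# reducibility by direct positional comparison (independent of the
# package's rep_len-based check)
oracle_reducible <- function(motif) {
  ch <- strsplit(motif, "")[[1]]
  switch(as.character(length(ch)),
         "2" = ch[1] == ch[2],
         "3" = ch[1] == ch[2] && ch[2] == ch[3],
         "4" = ch[1] == ch[3] && ch[2] == ch[4],
         FALSE)
}

# exhaustive enumeration: for every start and unit size, the repeat
# count is the largest r with s[start, start + r*u) == motif repeated r
# times; a hit must be left-maximal (the base one position before the
# start does not continue the periodicity)
oracle_find_ssrs <- function(s, params = markermine::ssr_params()) {
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  hits <- list()
  for (u in params$min_unit:params$max_unit) {
    if (n < 2L * u) next
    starts <- seq_len(n - 2L * u + 1L)
    motifs <- substring(s, starts, starts + u - 1L)
    ok <- !grepl("N", motifs, fixed = TRUE)
    reps <- rep(1L, length(starts))
    r <- 2L
    active <- ok
    while (any(active)) {
      idx <- which(active & starts + u * r - 1L <= n)
      if (length(idx) == 0L) break
      match_r <- substring(s, starts[idx], starts[idx] + u * r - 1L) ==
        strrep(motifs[idx], r)
      reps[idx[match_r]] <- r
      active[] <- FALSE
      active[idx[match_r]] <- TRUE
      r <- r + 1L
    }
    for (ii in which(ok & reps >= params$min_repeats)) {
      i <- starts[ii]
      span <- reps[ii] * u
      if (span < params$min_length) next
      if (oracle_reducible(motifs[ii])) next
      # left-maximality: the periodicity must not continue at i - 1
      if (i > 1L && i - 1L + u <= n &&
          ch[i - 1L] != "N" && ch[i - 1L] == ch[i - 1L + u]) next
      hits[[length(hits) + 1L]] <- data.frame(
        start = i - 1L, end = i - 1L + span, motif = motifs[ii],
        unit = u, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), unit = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$unit, out$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    overl <- keep & out$unit > out$unit[i] &
      out$start < out$end[i] & out$end > out$start[i]
    keep[overl] <- FALSE
  }
  out <- out[keep, c("start", "end", "motif")]
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}

# Botstein PIC by explicit double loop over allele index pairs
oracle_pic <- function(p) {
  k <- length(p)
  s1 <- 0
  for (i in seq_len(k)) s1 <- s1 + p[i]^2
  s2 <- 0
  if (k >= 2) for (i in seq_len(k - 1)) for (j in (i + 1):k)
    s2 <- s2 + 2 * p[i]^2 * p[j]^2
  1 - s1 - s2
}

random_dna <- function(n, with_n = FALSE) {
  alph <- c("A", "C", "G", "T", if (with_n) "N")
  prob <- if (with_n) c(rep(0.245, 4), 0.02) else rep(0.25, 4)
  paste(sample(alph, n, replace = TRUE, prob = prob), collapse = "")
}

ssr_key <- function(df) {
  if (nrow(df) == 0L) return(character())
  sort(paste(df$start, df$end, df$motif))
}

random_distance_matrix <- function(n) {
  m <- matrix(stats::runif(n * n, 0.05, 1), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(paste0("S", seq_len(n)), paste0("S", seq_len(n)))
  m
}

random_motif_nonreducible <- function(u) {
  repeat {
    m <- paste(sample(c("A", "C", "G", "T"), u, replace = TRUE),
               collapse = "")
    if (!oracle_reducible(m)) return(m)
  }
}
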