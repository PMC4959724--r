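#' Identity-by-state genetic distance
#'
#' For each sample pair, over loci where both calls are present, the IBS
#' similarity of two diploid calls is (number of shared alleles)/2 (1 for
#' identical genotypes, 0.5 for one shared allele, 0 for none).  Distance
#' is one minus the mean similarity.
#'
#' @param gm A \code{\link{genotype_matrix}}.
#' @return A symmetric \code{dist}-convertible matrix with zero diagonal,
#'   entries in [0, 1], sample IDs as dimnames.
#' @export
ibs_distance <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- length(gm$sample_ids)
  # per-sample allele matrices, loci x 2
  alleles <- lapply(seq_len(n), function(i) split_calls(gm$calls[i, ]))
  d <- matrix(0, n, n, dimnames = list(gm$sample_ids, gm$sample_ids))
  for (i in seq_len(n - 1L)) {
    ai <- alleles[[i]]
    for (j in (i + 1L):n) {
      aj <- alleles[[j]]
      ok <- !is.na(ai[, 1]) & !is.na(aj[, 1])
      if (!any(ok))
        stop("samples ", gm$sample_ids[i], " and ", gm$sample_ids[j],
             " share no non-missing locus")
      # shared alleles between unordered pairs {a1,a2} and {b1,b2}
      shared <- pair_shared(ai[ok, , drop = FALSE], aj[ok, , drop = FALSE])
      d[i, j] <- d[j, i] <- 1 - mean(shared) / 2
    }
  }
  d
}

# multiset intersection size (0/1/2) of unordered allele pairs, rowwise
pair_shared <- function(a, b) {
  direct <- (a[, 1] == b[, 1]) + (a[, 2] == b[, 2])
  crossed <- (a[, 1] == b[, 2]) + (a[, 2] == b[, 1])
  pmax(direct, crossed)
}

#' UPGMA clustering
#'
#' Average-linkage agglomeration of a distance matrix into a rooted
#' ultrametric tree: each merge joins the pair of clusters with the
#' smallest average distance, at a node height of half that distance.
#' Ties are broken by the lexicographically smallest pair of cluster
#' labels (a cluster is labelled by its smallest member ID), making the
#' result deterministic.
#'
#' @param d Symmetric distance matrix with sample IDs as dimnames (or a
#'   \code{dist} object).
#' @param ladderize_outgroup Optional sample ID rotated to be the first
#'   child of the root for display; UPGMA trees are already rooted, so
#'   this affects drawing order only.
#' @return An \code{ape} \code{phylo} tree (ultrametric, with branch
#'   lengths).
#' @export
upgma <- function(d, ladderize_outgroup = NULL) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (any(is.na(d))) stop("distance matrix contains NA")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("S", seq_len(nrow(d)))
  n <- nrow(d)
  if (n < 2L) stop("need at least two taxa")
  labels <- rownames(d)
  # active clusters: list of (newick, height, size, min_label)
  clus <- lapply(labels, function(l) list(nwk = l, h = 0, size = 1L, min = l))
  names(clus) <- labels
  dm <- d
  while (length(clus) > 1L) {
    m <- length(clus)
    ids <- names(clus)
    best <- NULL; bestd <- Inf
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      dij <- dm[i, j]
      if (dij < bestd - 1e-12) {
        bestd <- dij; best <- c(i, j)
      } else if (abs(dij - bestd) <= 1e-12) {
        # tie: lexicographically smallest (sorted) pair of cluster labels
        cand <- sort(c(clus[[i]]$min, clus[[j]]$min))
        cur <- sort(c(clus[[best[1]]]$min, clus[[best[2]]]$min))
        if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])) {
          bestd <- dij; best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    h <- bestd / 2
    ci <- clus[[i]]; cj <- clus[[j]]
    merged <- list(
      nwk = sprintf("(%s:%.10g,%s:%.10g)", ci$nwk, h - ci$h, cj$nwk, h - cj$h),
      h = h, size = ci$size + cj$size, min = min(ci$min, cj$min))
    # UPGMA average linkage update
    newrow <- (ci$size * dm[i, ] + cj$size * dm[j, ]) / (ci$size + cj$size)
    keep <- setdiff(seq_len(m), c(i, j))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], newrow[keep]),
                c(newrow[keep], 0))
    clus <- c(clus[keep], list(merged))
    names(clus) <- c(ids[keep], merged$min)
    dimnames(dm) <- list(names(clus), names(clus))
  }
  tree <- ape::read.tree(text = paste0(clus[[1]]$nwk, ";"))
  if (!is.null(ladderize_outgroup)) {
    if (!ladderize_outgroup %in% tree$tip.label)
      stop("outgroup not among tips: ", ladderize_outgroup)
    tree <- ape::rotateConstr(tree,
      c(ladderize_outgroup, setdiff(tree$tip.label, ladderize_outgroup)))
  }
  tree
}

# integer-coded genotype array for the admixture sampler:
# list(geno: n x L x 2 integer array of allele indices (NA = missing),
#      n_alleles: per-locus allele count, alleles: per-locus codes)
encode_genotypes <- function(gm) {
  n <- length(gm$sample_ids); L <- length(gm$locus_ids)
  geno <- array(NA_integer_, dim = c(n, L, 2))
  alleles <- vector("list", L)
  for (l in seq_len(L)) {
    sp <- split_calls(gm$calls[, l])
    codes <- sort(unique(as.vector(sp[!is.na(sp[, 1]), , drop = FALSE])))
    alleles[[l]] <- codes
    geno[, l, 1] <- match(sp[, 1], codes)
    geno[, l, 2] <- match(sp[, 2], codes)
  }
  list(geno = geno, n_alleles = lengths(alleles), alleles = alleles)
}

rdirichlet1 <- function(shape) {
  g <- stats::rgamma(length(shape), shape = shape, rate = 1)
  if (sum(g) == 0) g <- g + 1e-300
  g / sum(g)
}

#' Gibbs sampler for the admixture model
#'
#' STRUCTURE-style admixture model with independent allele frequencies:
#' each of the two allele copies an individual carries at a locus
#' descends from one of K ancestral populations, chosen with the
#' individual's admixture proportions Q; conditional on its population of
#' origin the allele is drawn from that population's frequencies P.  The
#' sampler alternates (i) drawing each allele copy's population of origin
#' given Q and P, (ii) drawing P from its Dirichlet posterior under a
#' uniform prior, and (iii) drawing each Q row from
#' Dirichlet(alpha + origin counts).  Missing calls contribute no origin
#' counts and are skipped in the likelihood.
#'
#' @param gm A QC-passed \code{\link{genotype_matrix}}.
#' @param K Number of ancestral populations.
#' @param burnin,reps Burn-in and retained MCMC sweeps.  Defaults are
#'   desk-scale (1,000 / 5,000); classic STRUCTURE practice is
#'   10,000 / 100,000.
#' @param alpha Dirichlet admixture parameter (default 1).
#' @param seed Integer seed; the run is seed-deterministic.
#' @return A \code{structure_run} list: posterior-mean \code{Q} (n x K),
#'   \code{P} (list per locus of K x alleles matrices),
#'   \code{loglik_trace} (per retained sweep), and the call parameters.
#' @export
gibbs_admixture <- function(gm, K, burnin = 1000L, reps = 5000L,
                            alpha = 1, seed = 1L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  K <- as.integer(K)
  n <- length(gm$sample_ids)
  if (K < 1L) stop("K must be >= 1")
  if (K > n) stop("K exceeds the number of samples")
  if (alpha <= 0) stop("alpha must be positive")
  if (reps < 1L) stop("reps must be >= 1")
  enc <- encode_genotypes(gm)
  L <- dim(enc$geno)[2]

  # flatten observed allele copies
  obs <- which(!is.na(enc$geno))                   # linear indices in n x L x 2
  idx <- arrayInd(obs, dim(enc$geno))
  samp <- idx[, 1]; locus <- idx[, 2]
  allele <- enc$geno[obs]                          # allele index within locus
  ncopy <- length(obs)
  # per-copy column index into the K x sum(n_alleles) frequency table
  offs <- c(0L, cumsum(enc$n_alleles))
  pcol <- offs[locus] + allele
  J <- sum(enc$n_alleles)

  set.seed(as.integer(seed))
  Q <- matrix(1 / K, n, K)
  P <- matrix(0, K, J)
  for (k in seq_len(K)) for (l in seq_len(L)) {
    j <- (offs[l] + 1L):offs[l + 1L]
    P[k, j] <- rdirichlet1(rep(1, length(j)))
  }

  Qsum <- matrix(0, n, K)
  Psum <- matrix(0, K, J)
  trace <- numeric(reps)
  lgroup <- factor(locus, levels = seq_len(L))     # for origin-count tallies

  for (it in seq_len(burnin + reps)) {
    # (i) origins: prob[c, k] ∝ Q[samp, k] * P[k, pcol]
    w <- Q[samp, , drop = FALSE] * t(P[, pcol, drop = FALSE])
    rs <- rowSums(w)
    u <- stats::runif(ncopy) * rs
    z <- rep(1L, ncopy)
    if (K > 1L) {
      acc <- w[, 1]
      for (k in seq_len(K - 1L)) {
        z <- z + (u > acc)
        if (k < K - 1L) acc <- acc + w[, k + 1L]
      }
    }
    # (ii) P | z: Dirichlet(1 + allele counts per population)
    for (k in seq_len(K)) {
      sel <- z == k
      cnt <- tabulate(pcol[sel], nbins = J)
      for (l in seq_len(L)) {
        j <- (offs[l] + 1L):offs[l + 1L]
        P[k, j] <- rdirichlet1(1 + cnt[j])
      }
    }
    # (iii) Q | z: Dirichlet(alpha + origin counts per individual)
    ocnt <- matrix(0, n, K)
    for (k in seq_len(K)) {
      sel <- z == k
      ocnt[, k] <- tabulate(samp[sel], nbins = n)
    }
    for (i in seq_len(n)) Q[i, ] <- rdirichlet1(alpha + ocnt[i, ])
    if (K == 1L) Q[] <- 1

    if (it > burnin) {
      r <- it - burnin
      # data log-likelihood under current (P, Q), marginal over origins
      trace[r] <- sum(log(rowSums(
        Q[samp, , drop = FALSE] * t(P[, pcol, drop = FALSE]))))
      Qsum <- Qsum + Q
      Psum <- Psum + P
    }
  }
  Qmean <- Qsum / reps
  Pmean <- Psum / reps
  Plist <- lapply(seq_len(L), function(l) {
    j <- (offs[l] + 1L):offs[l + 1L]
    m <- Pmean[, j, drop = FALSE]
    colnames(m) <- enc$alleles[[l]]
    m
  })
  names(Plist) <- gm$locus_ids
  rownames(Qmean) <- gm$sample_ids
  structure(list(K = K, Q = Qmean, P = Plist, alpha = alpha,
                 loglik_trace = trace, burnin = burnin, reps = reps,
                 seed = as.integer(seed)),
            class = "structure_run")
}

#' @exportS3Method base::print
print.structure_run <- function(x, ...) {
  cat("structure_run: K =", x$K, ",", nrow(x$Q), "samples,",
      length(x$P), "loci;", x$reps, "retained sweeps\n")
  cat("LnP(D) =", format(lnpd(x), digits = 6), "\n")
  invisible(x)
}

#' Model evidence estimate LnP(D)
#'
#' The estimator used by the original admixture-model software: the mean
#' of the post-burn-in log-likelihood trace minus half its variance.
#'
#' @param run A \code{structure_run}, or a numeric log-likelihood trace.
#' @return A single number; higher is better.
#' @export
lnpd <- function(run) {
  trace <- if (inherits(run, "structure_run")) run$loglik_trace else run
  if (length(trace) < 1L) stop("empty log-likelihood trace")
  if (length(trace) == 1L) return(trace)
  mean(trace) - stats::var(trace) / 2
}

#' Evanno delta-K table
#'
#' From LnP(D) values over replicate runs at consecutive K, computes the
#' first differences L'(K) of the mean, the absolute second differences
#' |L''(K)|, and \eqn{\Delta K = |L''(K)| / sd(L(K))}.  The K with the
#' largest defined \eqn{\Delta K} is the suggested number of
#' subpopulations.
#'
#' @param lnpd_table A data.frame with columns \code{K} and \code{lnpd}
#'   (one row per run), covering at least three consecutive K with at
#'   least two runs each.
#' @return A data.frame per K: \code{K}, \code{n_runs}, \code{mean_lnpd},
#'   \code{sd_lnpd}, \code{lprime}, \code{lsecond}, \code{delta_k}; the
#'   attribute \code{"best_K"} holds the argmax of \code{delta_k}.
#' @export
delta_k <- function(lnpd_table) {
  stopifnot(all(c("K", "lnpd") %in% names(lnpd_table)))
  Ks <- sort(unique(lnpd_table$K))
  if (length(Ks) < 3L) stop("need at least three consecutive K values")
  if (any(diff(Ks) != 1L)) stop("K values must be consecutive")
  mu <- vapply(Ks, function(k) mean(lnpd_table$lnpd[lnpd_table$K == k]), 0)
  sdv <- vapply(Ks, function(k) stats::sd(lnpd_table$lnpd[lnpd_table$K == k]), 0)
  nr <- vapply(Ks, function(k) sum(lnpd_table$K == k), 0L)
  if (any(nr < 2L)) stop("need at least two runs per K")
  m <- length(Ks)
  lprime <- c(NA, diff(mu))                        # L'(K) = mu(K) - mu(K-1)
  lsecond <- rep(NA_real_, m)
  lsecond[2:(m - 1)] <- abs(diff(lprime[-1]))      # |L'(K+1) - L'(K)|
  dk <- lsecond / sdv
  dk[!is.na(sdv) & sdv == 0] <- NA                 # undefined at zero spread
  out <- data.frame(K = Ks, n_runs = nr, mean_lnpd = mu, sd_lnpd = sdv,
                    lprime = lprime, lsecond = lsecond, delta_k = dk)
  best <- if (all(is.na(dk))) NA_integer_ else Ks[which.max(dk)]
  attr(out, "best_K") <- best
  out
}

# all permutations of 1..k (k! rows)
all_perms <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(k - 1L)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1L)))
  }
  out
}

# best column permutation of Q aligning it to ref (minimal squared error)
best_permutation <- function(ref, Q, exhaustive = TRUE) {
  K <- ncol(ref)
  score <- function(perm) sum((ref - Q[, perm, drop = FALSE])^2)
  if (exhaustive && K <= 8L) {
    perms <- all_perms(K)
    sc <- apply(perms, 1, score)
    perms[which.min(sc), ]
  } else {
    # greedy: repeatedly match the closest (ref column, Q column) pair
    perm <- integer(K)
    used_ref <- logical(K); used_q <- logical(K)
    cost <- vapply(seq_len(K), function(j)
      vapply(seq_len(K), function(i) sum((ref[, i] - Q[, j])^2), 0),
      numeric(K))                                  # cost[i, j]
    for (step in seq_len(K)) {
      cur <- cost
      cur[used_ref, ] <- Inf
      cur[, used_q] <- Inf
      w <- which(cur == min(cur), arr.ind = TRUE)[1, , drop = TRUE]
      perm[w[1]] <- w[2]
      used_ref[w[1]] <- TRUE
      used_q[w[2]] <- TRUE
    }
    perm
  }
}

#' Align and average replicate admixture runs
#'
#' Cluster labels in the admixture model are arbitrary (label switching),
#' so replicate runs must be aligned before averaging.  For each run this
#' finds the column permutation of Q that best matches the first run
#' (exhaustively over permutations for K <= 8, greedily beyond) and
#' averages the aligned Q matrices.
#'
#' @param runs List of \code{structure_run} objects (or bare Q matrices)
#'   sharing K and sample set.
#' @return The aligned, averaged Q matrix; rows sum to 1.
#' @export
align_runs <- function(runs) {
  Qs <- lapply(runs, function(r)
    if (inherits(r, "structure_run")) r$Q else as.matrix(r))
  K <- unique(vapply(Qs, ncol, 0L))
  if (length(K) != 1L) stop("runs have mixed K")
  n <- unique(vapply(Qs, nrow, 0L))
  if (length(n) != 1L) stop("runs have mixed sample sets")
  ref <- Qs[[1]]
  acc <- ref
  for (r in Qs[-1]) {
    perm <- best_permutation(ref, r)
    acc <- acc + r[, perm, drop = FALSE]
  }
  acc / length(Qs)
}
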