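#' Random SSR planting templates
#'
#' Draws non-overlapping SSR templates across contigs with a fixed motif
#' unit-size mix.  The default mix (80% di-, 18.3% tri-, 1.2%
#' tetra-nucleotide) reflects the class abundances typical of grass
#' genome surveys; counts per class are fixed (largest-remainder
#' rounding), so the planted class proportions are exact, not sampled.
#'
#' @param n_ssrs Number of templates.
#' @param n_contigs,contig_length Contig layout the templates must fit.
#' @param class_mix Named proportions for unit sizes \code{di},
#'   \code{tri}, \code{tetra}; must sum to 1.
#' @param repeat_range Inclusive range of repeat counts to draw from.
#' @param seed Integer seed.
#' @return A data.frame of templates: \code{contig_id}, \code{start}
#'   (0-based), \code{motif}, \code{n_repeats}.
#' @export
random_ssr_specs <- function(n_ssrs, n_contigs, contig_length,
                             class_mix = c(di = 0.80, tri = 0.183,
                                           tetra = 0.012),
                             repeat_range = c(5L, 12L), seed = 1L) {
  stopifnot(n_ssrs >= 1, all(class_mix >= 0), sum(class_mix) > 0)
  if (abs(sum(class_mix) - 1) > 0.02)
    stop("class_mix proportions must sum to ~1")
  class_mix <- class_mix / sum(class_mix)  # printed survey percentages
                                           # often sum to 99-100%
  set.seed(as.integer(seed))
  units <- c(di = 2L, tri = 3L, tetra = 4L)[names(class_mix)]
  counts <- floor(n_ssrs * class_mix)
  rem <- n_ssrs - sum(counts)
  if (rem > 0) {
    frac <- n_ssrs * class_mix - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  unit_of <- rep(unname(units), counts)
  specs <- list()
  occupied <- lapply(seq_len(n_contigs), function(i) integer())
  for (u in unit_of) {
    reps <- sample(seq(repeat_range[1], repeat_range[2]), 1L)
    span <- u * reps
    placed <- FALSE
    for (try in seq_len(200L)) {
      ci <- sample.int(n_contigs, 1L)
      st <- sample.int(contig_length - span - 2L, 1L)  # leave flank room
      cells <- (st - u):(st + span + u)                # pad by one unit
      if (!any(cells %in% occupied[[ci]])) {
        occupied[[ci]] <- c(occupied[[ci]], cells)
        motif <- random_motif(u)
        specs[[length(specs) + 1L]] <- data.frame(
          contig_id = paste0("contig", ci), start = st, motif = motif,
          n_repeats = reps, stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place all SSR templates; reduce n_ssrs")
  }
  out <- do.call(rbind, specs)
  rownames(out) <- NULL
  out
}

random_motif <- function(u) {
  repeat {
    m <- paste(sample(c("A", "C", "G", "T"), u, replace = TRUE),
               collapse = "")
    if (!is_reducible_motif(m)) return(m)
  }
}

#' Plant perfect SSRs into synthetic contigs
#'
#' Generates i.i.d. background sequence at the given base composition and
#' writes each template motif run at its stated coordinates.  Background
#' windows that by chance form a qualifying SSR run (or extend a planted
#' one beyond its truth coordinates) are rejected and resampled, so the
#' returned truth table is exact: mining the sequences at \code{params}
#' recovers precisely the planted loci.
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of every contig (bp).
#' @param ssr_specs Template data.frame (\code{contig_id}, \code{start}
#'   0-based, \code{motif}, \code{n_repeats}), e.g. from
#'   \code{\link{random_ssr_specs}}; may have zero rows.
#' @param base_composition Probabilities for A, C, G, T (default
#'   uniform).
#' @param seed Integer seed.
#' @param params The \code{\link{ssr_params}} defining a "qualifying" run
#'   for rejection sampling.
#' @return A list: \code{sequences} (named character vector) and
#'   \code{truth} (data.frame \code{contig_id}, \code{start},
#'   \code{end}, \code{motif}, \code{n_repeats}).
#' @export
plant_ssrs <- function(n_contigs, contig_length, ssr_specs = NULL,
                       base_composition = rep(0.25, 4), seed = 1L,
                       params = ssr_params()) {
  stopifnot(n_contigs >= 1, contig_length >= 1,
            length(base_composition) == 4,
            abs(sum(base_composition) - 1) < 1e-9)
  if (is.null(ssr_specs) || nrow(ssr_specs) == 0L) {
    ssr_specs <- data.frame(contig_id = character(), start = integer(),
                            motif = character(), n_repeats = integer(),
                            stringsAsFactors = FALSE)
  }
  ids <- paste0("contig", seq_len(n_contigs))
  if (nrow(ssr_specs) > 0L) {
    if (!all(ssr_specs$contig_id %in% ids))
      stop("ssr_specs reference unknown contigs")
    u <- nchar(ssr_specs$motif)
    if (any(u < 2L | u > 4L) || any(grepl("[^ACGT]", ssr_specs$motif)))
      stop("motifs must be 2-4 bp over ACGT")
    if (any(vapply(ssr_specs$motif, is_reducible_motif, TRUE)))
      stop("motif reduces to a shorter unit")
    span <- u * ssr_specs$n_repeats
    if (any(ssr_specs$start < 0L | ssr_specs$start + span > contig_length))
      stop("planted span does not fit within its contig")
    for (id in unique(ssr_specs$contig_id)) {
      sub <- ssr_specs[ssr_specs$contig_id == id, , drop = FALSE]
      sp <- span[ssr_specs$contig_id == id]
      o <- order(sub$start)
      if (nrow(sub) > 1L &&
          any(sub$start[o][-1] < (sub$start + sp)[o][-nrow(sub)]))
        stop("planted spans overlap on ", id)
    }
  }
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  seqs <- stats::setNames(vector("character", n_contigs), ids)
  truth <- ssr_specs
  truth$end <- truth$start + nchar(truth$motif) * truth$n_repeats
  truth <- truth[, c("contig_id", "start", "end", "motif", "n_repeats")]

  for (ci in seq_len(n_contigs)) {
    id <- ids[ci]
    ch <- sample(bases, contig_length, replace = TRUE,
                 prob = base_composition)
    tr <- truth[truth$contig_id == id, , drop = FALSE]
    planted <- rep(FALSE, contig_length)
    for (r in seq_len(nrow(tr))) {
      u <- nchar(tr$motif[r])
      pos <- (tr$start[r] + 1L):tr$end[r]
      ch[pos] <- rep_len(strsplit(tr$motif[r], "")[[1]], length(pos))
      planted[pos] <- TRUE
    }
    # rejection: resample background wherever mining disagrees with truth
    for (iter in seq_len(200L)) {
      mined <- find_ssrs(paste(ch, collapse = ""), params, contig_id = id)
      key_m <- paste(mined$start, mined$end, mined$motif)
      key_t <- paste(tr$start, tr$end, tr$motif)
      extra <- mined[!(key_m %in% key_t), , drop = FALSE]
      if (nrow(extra) == 0L && all(key_t %in% key_m)) break
      if (!all(key_t %in% key_m) && nrow(extra) == 0L)
        stop("planted SSR lost during generation on ", id)
      for (r in seq_len(nrow(extra))) {
        u <- nchar(extra$motif[r])
        pos <- max(1L, extra$start[r] + 1L - u):
          min(contig_length, extra$end[r] + u)
        pos <- pos[!planted[pos]]
        ch[pos] <- sample(bases, length(pos), replace = TRUE,
                          prob = base_composition)
      }
      if (iter == 200L)
        stop("rejection sampling failed to clean background on ", id)
    }
    seqs[[id]] <- paste(ch, collapse = "")
  }
  list(sequences = seqs, truth = truth)
}

# default strand-collapsed substitution class weights for homeologous
# sites; the CT/AG and CG weights follow the spectra reported for
# allotetraploid finger millet (~62% and ~7.5%), the remainder is split
# evenly between the two unspecified transversion classes
default_class_weights <- c("CT/AG" = 0.62, "AC/GT" = 0.1525,
                           "AT" = 0.1525, "CG" = 0.075)

draw_substitutions <- function(n, class_weights) {
  cls <- sample(names(class_weights), n, replace = TRUE,
                prob = class_weights)
  members <- list("CT/AG" = list(c("C", "T"), c("A", "G")),
                  "AC/GT" = list(c("A", "C"), c("G", "T")),
                  "AT" = list(c("A", "T")), "CG" = list(c("C", "G")))
  ref <- character(n); alt <- character(n)
  for (i in seq_len(n)) {
    pair <- members[[cls[i]]][[sample.int(length(members[[cls[i]]]), 1L)]]
    pair <- sample(pair)
    ref[i] <- pair[1]; alt[i] <- pair[2]
  }
  data.frame(ref = ref, alt = alt, stringsAsFactors = FALSE)
}

#' Simulate allotetraploid variant sets
#'
#' Emulates variant discovery in a highly inbred allotetraploid: a
#' "self-mapped" variant set per genotype exposing homeologous
#' (sub-genome) divergence as heterozygous-like sites, and a combined
#' candidate set over all genotypes containing both the homeologous
#' sites and true allelic SNPs between genotypes.  Each base pair
#' carries at most one truth; positions are drawn without replacement.
#' The default homeologous rate of 1/657 bp matches the denser of the
#' two sub-genome divergence rates reported for finger millet; the
#' default allelic rate of 1/3300 bp matches the genome-wide
#' non-homeologous SNP frequency (1 per 3.3 kb).
#'
#' @param contig_length Simulated contig length (bp); all sites sit on
#'   one contig named \code{"contig1"}.
#' @param n_genotypes Number of genotypes.
#' @param homeolog_rate,allelic_rate Per-bp probabilities in [0, 1).
#' @param class_weights Substitution-class weights for homeologous sites
#'   (see Details); allelic sites use a milder transition bias (2:1).
#' @param degrade_frac Fraction of combined candidate sites degraded
#'   below the quality/depth thresholds, for filter testing (default 0).
#' @param seed Integer seed.
#' @return A list: \code{self_sets} (list of per-genotype variant site
#'   tables), \code{combined} (candidate variant site table with
#'   per-genotype GT columns), \code{truth} (data.frame
#'   \code{contig_id}, \code{position}, \code{kind}, \code{ref},
#'   \code{alt}, \code{degraded}).
#' @export
simulate_allotetraploid_variants <- function(contig_length, n_genotypes,
                                             homeolog_rate = 1 / 657,
                                             allelic_rate = 1 / 3300,
                                             class_weights = default_class_weights,
                                             degrade_frac = 0,
                                             seed = 1L) {
  if (homeolog_rate < 0 || homeolog_rate >= 1 ||
      allelic_rate < 0 || allelic_rate >= 1)
    stop("rates must lie in [0, 1)")
  stopifnot(n_genotypes >= 1, contig_length >= 1)
  set.seed(as.integer(seed))
  gids <- paste0("G", seq_len(n_genotypes))

  n_hom <- stats::rbinom(1L, contig_length, homeolog_rate)
  n_all <- stats::rbinom(1L, contig_length, allelic_rate)
  pos <- sample.int(contig_length, n_hom + n_all)  # no collisions
  hom_pos <- sort(pos[seq_len(n_hom)])
  all_pos <- sort(pos[n_hom + seq_len(n_all)])

  hom_sub <- draw_substitutions(n_hom, class_weights)
  all_sub <- draw_substitutions(n_all, c("CT/AG" = 2 / 3, "AC/GT" = 1 / 9,
                                         "AT" = 1 / 9, "CG" = 1 / 9))
  truth <- rbind(
    if (n_hom > 0) data.frame(contig_id = "contig1", position = hom_pos,
                              kind = "homeologous", hom_sub,
                              stringsAsFactors = FALSE),
    if (n_all > 0) data.frame(contig_id = "contig1", position = all_pos,
                              kind = "allelic", all_sub,
                              stringsAsFactors = FALSE))
  if (is.null(truth))
    truth <- data.frame(contig_id = character(), position = integer(),
                        kind = character(), ref = character(),
                        alt = character(), stringsAsFactors = FALSE)
  truth <- truth[order(truth$position), , drop = FALSE]
  rownames(truth) <- NULL

  site_support <- function(n) data.frame(
    quality = round(stats::runif(n, 30, 60), 1),
    depth = 3L + stats::rpois(n, 17))

  # homeologous sites appear in the self set of a nonempty genotype subset
  carriers <- lapply(seq_len(n_hom), function(i) {
    repeat {
      inc <- stats::runif(n_genotypes) < 0.6
      if (any(inc)) return(which(inc))
    }
  })
  self_sets <- stats::setNames(lapply(seq_len(n_genotypes), function(g) {
    sel <- vapply(carriers, function(cc) g %in% cc, TRUE)
    n <- sum(sel)
    df <- data.frame(contig_id = rep("contig1", n),
                     position = hom_pos[sel],
                     ref = hom_sub$ref[sel], alt = hom_sub$alt[sel],
                     site_support(n), stringsAsFactors = FALSE)
    df[[paste0("gt_", gids[g])]] <- rep("0/1", n)
    df
  }), gids)

  # combined candidate set: homeologs look heterozygous in every carrier,
  # allelic SNPs segregate as alternative homozygotes between genotypes
  combined <- data.frame(contig_id = rep("contig1", nrow(truth)),
                         position = truth$position, ref = truth$ref,
                         alt = truth$alt, site_support(nrow(truth)),
                         stringsAsFactors = FALSE)
  gt <- matrix("0/0", nrow(truth), n_genotypes,
               dimnames = list(NULL, paste0("gt_", gids)))
  is_hom <- truth$kind == "homeologous"
  hom_rows <- which(is_hom)
  for (r in seq_along(hom_rows))
    gt[hom_rows[r], carriers[[r]]] <- "0/1"
  for (r in which(!is_hom)) {
    repeat {
      alt_carrier <- stats::runif(n_genotypes) < 0.5
      if (any(alt_carrier) && !all(alt_carrier)) break
    }
    gt[r, alt_carrier] <- "1/1"
  }
  combined <- cbind(combined, as.data.frame(gt, stringsAsFactors = FALSE))

  truth$degraded <- rep(FALSE, nrow(truth))
  n_deg <- floor(degrade_frac * nrow(combined))
  if (n_deg > 0) {
    deg <- sample.int(nrow(combined), n_deg)
    low_q <- stats::runif(n_deg) < 0.5
    combined$quality[deg[low_q]] <- round(stats::runif(sum(low_q), 0, 29.9), 1)
    combined$depth[deg[!low_q]] <- sample(0:2, sum(!low_q), replace = TRUE)
    truth$degraded[deg] <- TRUE
  }
  list(self_sets = self_sets, combined = combined, truth = truth)
}

#' Simulate an admixed genotype matrix with known structure
#'
#' Draws per-population allele frequencies under a Balding--Nichols
#' divergence model, per-sample admixture proportions from a Dirichlet
#' centred on the sample's home population, and diploid bi-allelic calls
#' with partial selfing (a selfed sample copies its first allele, so
#' \code{selfing = 1} forces complete homozygosity, emulating a highly
#' inbred crop).
#'
#' @param K Number of ancestral populations.
#' @param n_per_pop Samples per population.
#' @param n_loci Number of bi-allelic loci.
#' @param divergence Allele-frequency spread in [0, 1]: 0 gives identical
#'   populations, values towards 1 push population frequencies apart
#'   (at 1 exactly, frequencies are fixed at 0 or 1 and alternate
#'   between neighbouring populations).
#' @param alpha Dirichlet admixture parameter (> 0); small values give
#'   nearly pure ancestry.
#' @param selfing Probability a sample's second allele copies the first.
#' @param missing_rate Probability a call is missing.
#' @param seed Integer seed.
#' @return A list: \code{matrix} (a \code{\link{genotype_matrix}} with
#'   groups \code{"pop1"}, ...) and \code{truth} (list \code{K},
#'   \code{Q_true}, \code{P_true} (K x loci matrix of allele-"B"
#'   frequencies), \code{selfing}).
#' @export
simulate_genotype_matrix <- function(K, n_per_pop, n_loci,
                                     divergence = 0.3, alpha = 0.1,
                                     selfing = 0.95, missing_rate = 0.07,
                                     seed = 1L) {
  stopifnot(K >= 1, n_loci >= 1, n_per_pop >= 1,
            divergence >= 0, divergence <= 1,
            selfing >= 0, selfing <= 1,
            missing_rate >= 0, missing_rate < 1)
  if (alpha <= 0) stop("alpha must be positive")
  set.seed(as.integer(seed))
  n <- K * n_per_pop
  pop <- rep(seq_len(K), each = n_per_pop)

  P <- matrix(0, K, n_loci)
  if (divergence >= 1) {
    for (k in seq_len(K)) P[k, ] <- (k + seq_len(n_loci)) %% 2
  } else if (divergence == 0) {
    P[] <- rep(stats::runif(n_loci, 0.05, 0.95), each = K)
  } else {
    p0 <- stats::runif(n_loci, 0.05, 0.95)
    f <- (1 - divergence) / divergence
    for (k in seq_len(K))
      P[k, ] <- stats::rbeta(n_loci, p0 * f, (1 - p0) * f)
  }

  Q <- do.call(rbind, lapply(seq_len(n), function(i) {
    shape <- rep(alpha, K)
    shape[pop[i]] <- shape[pop[i]] + 1
    rdirichlet1(shape)
  }))

  calls <- matrix(NA_character_, n, n_loci)
  for (i in seq_len(n)) {
    z1 <- sample.int(K, n_loci, replace = TRUE, prob = Q[i, ])
    a1 <- stats::runif(n_loci) < P[cbind(z1, seq_len(n_loci))]
    z2 <- sample.int(K, n_loci, replace = TRUE, prob = Q[i, ])
    a2 <- stats::runif(n_loci) < P[cbind(z2, seq_len(n_loci))]
    selfed <- stats::runif(n_loci) < selfing
    a2[selfed] <- a1[selfed]
    code <- function(x) ifelse(x, "B", "A")
    calls[i, ] <- paste(pmin(code(a1), code(a2)),
                        pmax(code(a1), code(a2)), sep = ":")
  }
  calls[matrix(stats::runif(n * n_loci) < missing_rate, n, n_loci)] <- NA
  sample_ids <- paste0("S", seq_len(n))
  locus_ids <- paste0("L", seq_len(n_loci))
  dimnames(calls) <- list(sample_ids, locus_ids)
  rownames(Q) <- sample_ids
  gm <- genotype_matrix(calls, groups = paste0("pop", pop))
  list(matrix = gm,
       truth = list(K = K, Q_true = Q, P_true = P, selfing = selfing))
}
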