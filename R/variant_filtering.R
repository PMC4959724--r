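#' Classify a single-nucleotide substitution
#'
#' Transitions are the purine--purine (A<->G) and pyrimidine--pyrimidine
#' (C<->T) exchanges; every other base pair is a transversion.
#'
#' @param ref,alt Single bases in ACGT, distinct.
#' @return \code{"transition"} or \code{"transversion"}.
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("ref and alt must be single ACGT bases")
  if (any(ref == alt)) stop("ref and alt must differ")
  pair <- paste(pmin(ref, alt), pmax(ref, alt))
  ifelse(pair %in% c("A G", "C T"), "transition", "transversion")
}

#' Transition/transversion ratio
#'
#' @param n_transitions,n_transversions Substitution counts.
#' @param digits Decimals in the returned ratio (default 1, the usual
#'   reporting precision).
#' @return Numeric Ts/Tv ratio.
#' @export
tstv_ratio <- function(n_transitions, n_transversions, digits = 1) {
  if (n_transversions == 0) return(NA_real_)
  round(n_transitions / n_transversions, digits)
}

#' Filter candidate SNP sites on quality, allele number and depth
#'
#' Retains sites with \code{quality >= min_quality}, at most
#' \code{max_alleles} total alleles (reference plus alternates) and
#' \code{depth >= min_depth}.  All thresholds are inclusive.  A missing
#' (\code{NA}) quality or depth fails its filter: a site whose support is
#' unknown is not trusted.
#'
#' @param sites A variant site table (see \code{\link{read_vcf}}): columns
#'   \code{contig_id}, \code{position}, \code{ref}, \code{alt}
#'   (comma-separated for multi-allelic sites), \code{quality},
#'   \code{depth}, plus any genotype columns.
#' @param min_quality Minimum phred-scaled site quality (default 30).
#' @param max_alleles Maximum total alleles (default 2, i.e. bi-allelic).
#' @param min_depth Minimum site read depth (default 3).
#' @return The retained rows, in input order.
#' @export
filter_sites <- function(sites, min_quality = 30, max_alleles = 2,
                         min_depth = 3) {
  if (nrow(sites) == 0L) return(sites)
  n_alleles <- 1L + vapply(strsplit(sites$alt, ",", fixed = TRUE),
                           length, 0L)
  ok <- !is.na(sites$quality) & sites$quality >= min_quality &
    n_alleles <= max_alleles &
    !is.na(sites$depth) & sites$depth >= min_depth
  out <- sites[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Union of homeologous positions over per-genotype self-mapped sets
#'
#' In an allotetraploid, mapping a genotype's reads back to its own
#' assembly exposes divergence between the AA and BB sub-genomes as
#' heterozygous-looking "self" variants.  These positions are homeologous,
#' not allelic, and the union over all genotypes defines the exclusion
#' set.
#'
#' @param self_sets A list of variant site tables, one per genotype.
#' @return A character vector of \code{"contig:position"} keys.
#' @export
homeolog_positions <- function(self_sets) {
  if (length(self_sets) == 0L) return(character())
  keys <- unlist(lapply(self_sets, function(s)
    if (nrow(s) == 0L) character()
    else paste(s$contig_id, s$position, sep = ":")))
  sort(unique(keys))
}

#' Remove homeologous positions from a candidate SNP set
#'
#' A position flagged homeologous in any genotype is removed for all
#' genotypes; allele identity at the position is not considered.
#'
#' @param candidates A variant site table.
#' @param homeologs Position keys from \code{\link{homeolog_positions}}.
#' @return Candidates whose (contig, position) is not in the homeolog set.
#' @export
subtract_homeologs <- function(candidates, homeologs) {
  if (nrow(candidates) == 0L) return(candidates)
  keys <- paste(candidates$contig_id, candidates$position, sep = ":")
  out <- candidates[!(keys %in% homeologs), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Strand-collapsed class of an unordered bi-allelic substitution.
# {C,T}~{A,G} -> "CT/AG" (the transition class); {A,C}~{G,T} -> "AC/GT";
# {A,T} and {C,G} are their own reverse complements.
substitution_class <- function(ref, alt) {
  pair <- paste0(pmin(ref, alt), pmax(ref, alt))
  c(AG = "CT/AG", CT = "CT/AG",
    AC = "AC/GT", GT = "AC/GT",
    AT = "AT", CG = "CG")[pair]
}

#' Substitution spectrum of a bi-allelic SNP set
#'
#' Assigns each site to one of the four strand-collapsed substitution
#' classes (CT/AG, AC/GT, AT, CG) and returns the class fractions.
#'
#' @param sites A variant site table; all sites must be bi-allelic single
#'   bases.
#' @return A named numeric vector of fractions summing to 1 (empty for an
#'   empty input).
#' @export
substitution_spectrum <- function(sites) {
  if (nrow(sites) == 0L) return(stats::setNames(numeric(), character()))
  if (any(grepl(",", sites$alt, fixed = TRUE)))
    stop("multi-allelic site in spectrum input")
  if (any(nchar(sites$ref) != 1L | nchar(sites$alt) != 1L))
    stop("spectrum input must be single-base substitutions")
  cls <- substitution_class(toupper(sites$ref), toupper(sites$alt))
  tab <- table(factor(cls, levels = c("CT/AG", "AC/GT", "AT", "CG")))
  frac <- as.numeric(tab) / sum(tab)
  stats::setNames(frac, names(tab))
}

#' Summarize a filtered SNP set
#'
#' Transition/transversion counts and ratio, the substitution spectrum,
#' and the per-bp marker frequency.
#'
#' @param sites A bi-allelic variant site table.
#' @param total_bp Searched sequence length (bp).
#' @return A list: \code{n_sites}, \code{n_transitions},
#'   \code{n_transversions}, \code{tstv}, \code{spectrum},
#'   \code{frequency}, and frequencies for the transition and
#'   transversion subsets.
#' @export
summarize_variants <- function(sites, total_bp) {
  if (nrow(sites) > 0L) {
    kind <- classify_substitution(sites$ref, sites$alt)
    n_ts <- sum(kind == "transition")
    n_tv <- sum(kind == "transversion")
  } else {
    n_ts <- n_tv <- 0L
  }
  list(n_sites = nrow(sites),
       n_transitions = n_ts,
       n_transversions = n_tv,
       tstv = tstv_ratio(n_ts, n_tv),
       spectrum = substitution_spectrum(sites),
       frequency = marker_frequency(nrow(sites), total_bp),
       transition_frequency = marker_frequency(n_ts, total_bp),
       transversion_frequency = marker_frequency(n_tv, total_bp))
}
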