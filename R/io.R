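#' Read a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of upper-cased sequences, in file
#'   order.  Duplicate record IDs are an error; an empty file returns an
#'   empty vector with a warning.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) {
    warning("no records in ", path)
    return(stats::setNames(character(), character()))
  }
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate record IDs in ", path)
  stats::setNames(toupper(as.character(ss)), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write a variant site table as VCF 4.2
#'
#' Site depth goes to \code{INFO/DP}; genotype columns (\code{gt_*}) are
#' written as a \code{GT} FORMAT field with \code{"./."} for missing.
#'
#' @param sites Variant site table (\code{contig_id}, \code{position},
#'   \code{ref}, \code{alt}, \code{quality}, \code{depth}, optional
#'   \code{gt_<sample>} columns).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(sites, path) {
  gt_cols <- grep("^gt_", names(sites), value = TRUE)
  samples <- sub("^gt_", "", gt_cols)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=markermine",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Site read depth">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t"))
  if (nrow(sites) > 0L) {
    info <- ifelse(is.na(sites$depth), ".", paste0("DP=", sites$depth))
    qual <- ifelse(is.na(sites$quality), ".",
                   format(sites$quality, trim = TRUE))
    fields <- cbind(sites$contig_id, sites$position, ".", sites$ref,
                    sites$alt, qual, "PASS", info)
    if (length(gt_cols)) {
      gt <- as.matrix(sites[, gt_cols, drop = FALSE])
      gt[is.na(gt)] <- "./."
      fields <- cbind(fields, "GT", gt)
    }
    body <- apply(fields, 1, paste, collapse = "\t")
  } else body <- character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read SNP records from a VCF file
#'
#' Parses SNP records (single-base REF and ALT alleles) into the variant
#' site table used throughout the package; indel and symbolic records are
#' skipped and counted.  A missing QUAL or INFO/DP becomes \code{NA},
#' which downstream filtering treats as failing.
#'
#' @param path VCF file (4.x, plain or bgzipped).
#' @return A list: \code{sites} (data.frame with \code{contig_id},
#'   \code{position}, \code{ref}, \code{alt}, \code{quality},
#'   \code{depth}, and \code{gt_<sample>} columns) and
#'   \code{n_skipped} (non-SNP record count).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L)
    return(list(sites = data.frame(contig_id = character(),
                                   position = integer(), ref = character(),
                                   alt = character(), quality = numeric(),
                                   depth = integer(),
                                   stringsAsFactors = FALSE),
                n_skipped = 0L))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  # a SNP record: 1-bp REF, every ALT allele 1 bp and non-symbolic
  alt_split <- strsplit(ifelse(is.na(alt), "", alt), ",", fixed = TRUE)
  is_snp <- nchar(ref) == 1L & !is.na(alt) &
    vapply(alt_split, function(a)
      length(a) > 0L && all(nchar(a) == 1L & a %in% c("A", "C", "G", "T")),
      TRUE)
  n_skipped <- sum(!is_snp)
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  dp <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))
  sites <- data.frame(contig_id = fix[is_snp, "CHROM"],
                      position = as.integer(fix[is_snp, "POS"]),
                      ref = ref[is_snp], alt = alt[is_snp],
                      quality = qual[is_snp], depth = dp[is_snp],
                      stringsAsFactors = FALSE)
  gt <- tryCatch(vcfR::extract.gt(v, "GT"), error = function(e) NULL)
  if (!is.null(gt)) {
    gt[gt %in% c("./.", ".|.", ".")] <- NA
    for (s in colnames(gt)) sites[[paste0("gt_", s)]] <- gt[is_snp, s]
  }
  rownames(sites) <- NULL
  list(sites = sites, n_skipped = n_skipped)
}

#' Write a genotype matrix as CSV
#'
#' Samples in rows, loci in columns, calls \code{"A:G"}, missing
#' \code{NA}.  The group labels go to a companion two-column CSV when
#' \code{groups_path} is given.
#'
#' @param gm A \code{\link{genotype_matrix}}.
#' @param path Calls CSV path.
#' @param groups_path Optional groups CSV path (\code{sample,group}).
#' @return \code{path}, invisibly.
#' @export
write_genotype_csv <- function(gm, path, groups_path = NULL) {
  df <- data.frame(sample = gm$sample_ids, gm$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  if (!is.null(groups_path))
    utils::write.csv(data.frame(sample = gm$sample_ids,
                                group = unname(gm$groups)),
                     groups_path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a genotype matrix from CSV
#'
#' @param path Calls CSV (first column \code{sample}, remaining columns
#'   loci with \code{"A:G"} calls).
#' @param groups_path Optional groups CSV (\code{sample,group}).
#' @return A \code{\link{genotype_matrix}}.
#' @export
read_genotype_csv <- function(path, groups_path = NULL) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE, na.strings = "NA")
  calls <- as.matrix(df[, -1, drop = FALSE])
  rownames(calls) <- df[[1]]
  groups <- NULL
  if (!is.null(groups_path)) {
    g <- utils::read.csv(groups_path, stringsAsFactors = FALSE,
                         na.strings = "NA")
    groups <- g$group[match(df[[1]], g$sample)]
  }
  genotype_matrix(calls, groups = groups)
}

pipeline_defaults <- function() list(
  seed = 1L,
  out_dir = ".",
  stages = "simulate,mine_ssr,filter_snps,diversity,structure",
  # synthetic-data conditions
  n_contigs = 5L, contig_length = 10000L, n_ssrs = 20L,
  n_genotypes = 2L, homeolog_rate = 1 / 657, allelic_rate = 1 / 3300,
  K = 2L, n_per_pop = 15L, n_loci = 60L, divergence = 0.3,
  alpha = 0.1, selfing = 0.95, missing_rate = 0.07,
  # mining and filtering thresholds
  min_repeats = 5L, min_length = 10L,
  min_quality = 30, max_alleles = 2L, min_depth = 3L,
  # diversity QC
  max_sample_missing = 0.80, max_locus_missing = 0.90,
  # structure analysis
  K_range = "1,4", n_runs = 2L, burnin = 200L, reps = 1000L,
  struct_alpha = 1)

#' Read a flat key=value pipeline configuration
#'
#' Unknown keys are rejected; missing keys take the package defaults.
#'
#' @param path Config file: one \code{key=value} per line, \code{#}
#'   comments allowed.
#' @return A named list of configuration values.
#' @export
read_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- pipeline_defaults()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    cfg[[key]] <- if (is.numeric(cfg[[key]]))
      as.numeric(val) else val
  }
  cfg
}

#' Run the synthetic end-to-end marker pipeline
#'
#' Generates synthetic inputs (contigs with planted SSRs, allotetraploid
#' variant sets, an admixed genotype matrix), then runs the enabled
#' stages -- SSR mining, SNP filtering with homeolog subtraction,
#' diversity statistics, and structure/UPGMA analysis -- writing every
#' intermediate artifact plus a run log under \code{out_dir}.  Identical
#' configuration and seed give identical outputs.
#'
#' @param config A configuration list from \code{\link{read_config}}, or
#'   individual overrides of the defaults passed as a list.
#' @return Invisibly, a bundle list with the in-memory results of each
#'   stage and the paths written.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(pipeline_defaults(), config)
  stages <- strsplit(as.character(cfg$stages), ",")[[1]]
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  logf <- function(...) cat(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "),
                            sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("markermine %s; R %s.%s", as.character(utils::packageVersion("markermine")),
       R.version$major, R.version$minor)
  for (k in names(cfg)) logf("config %s=%s", k, paste(cfg[[k]], collapse = ","))
  bundle <- list(config = cfg, paths = character())
  emit <- function(name) bundle$paths <<- c(bundle$paths,
                                            file.path(cfg$out_dir, name))
  run_stage <- function(name, expr) {
    logf("stage %s: start", name)
    res <- tryCatch(expr, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
    logf("stage %s: done", name)
    res
  }

  if ("simulate" %in% stages) {
    bundle$simulate <- run_stage("simulate", {
      specs <- random_ssr_specs(cfg$n_ssrs, cfg$n_contigs,
                                cfg$contig_length, seed = cfg$seed)
      contigs <- plant_ssrs(cfg$n_contigs, cfg$contig_length, specs,
                            seed = cfg$seed + 1L)
      vars <- simulate_allotetraploid_variants(
        cfg$n_contigs * cfg$contig_length, cfg$n_genotypes,
        cfg$homeolog_rate, cfg$allelic_rate, seed = cfg$seed + 2L)
      gm <- simulate_genotype_matrix(cfg$K, cfg$n_per_pop, cfg$n_loci,
                                     cfg$divergence, cfg$alpha,
                                     cfg$selfing, cfg$missing_rate,
                                     seed = cfg$seed + 3L)
      write_fasta(contigs$sequences, file.path(cfg$out_dir, "contigs.fasta"))
      emit("contigs.fasta")
      utils::write.csv(contigs$truth,
                       file.path(cfg$out_dir, "ssr_truth.csv"),
                       row.names = FALSE)
      emit("ssr_truth.csv")
      for (g in names(vars$self_sets)) {
        write_vcf(vars$self_sets[[g]],
                  file.path(cfg$out_dir, paste0("self_", g, ".vcf")))
        emit(paste0("self_", g, ".vcf"))
      }
      write_vcf(vars$combined, file.path(cfg$out_dir, "combined.vcf"))
      emit("combined.vcf")
      utils::write.csv(vars$truth,
                       file.path(cfg$out_dir, "variant_truth.csv"),
                       row.names = FALSE)
      emit("variant_truth.csv")
      write_genotype_csv(gm$matrix, file.path(cfg$out_dir, "calls.csv"),
                         file.path(cfg$out_dir, "groups.csv"))
      emit("calls.csv"); emit("groups.csv")
      jsonlite::write_json(
        list(K = gm$truth$K, Q_true = gm$truth$Q_true,
             P_true = gm$truth$P_true, selfing = gm$truth$selfing),
        file.path(cfg$out_dir, "population_truth.json"),
        digits = NA, matrix = "rowmajor")
      emit("population_truth.json")
      list(contigs = contigs, variants = vars, genotypes = gm)
    })
  }

  if ("mine_ssr" %in% stages) {
    bundle$ssr <- run_stage("mine_ssr", {
      seqs <- read_fasta(file.path(cfg$out_dir, "contigs.fasta"))
      params <- ssr_params(min_repeats = cfg$min_repeats,
                           min_length = cfg$min_length)
      loci <- find_ssrs_set(seqs, params)
      summ <- summarize_ssrs(loci, sum(nchar(seqs)))
      report <- loci
      report$start_1based <- report$start + 1L  # human-readable coords
      utils::write.table(report, file.path(cfg$out_dir, "ssr_loci.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      emit("ssr_loci.tsv")
      utils::write.table(summ$by_unit,
                         file.path(cfg$out_dir, "ssr_summary.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      emit("ssr_summary.tsv")
      logf("mined %d SSR loci (%s)", summ$total,
           if (is.na(summ$total_frequency)) "none" else summ$total_frequency)
      list(loci = loci, summary = summ)
    })
  }

  if ("filter_snps" %in% stages) {
    bundle$snps <- run_stage("filter_snps", {
      self_paths <- list.files(cfg$out_dir, "^self_.*\\.vcf$",
                               full.names = TRUE)
      selfs <- lapply(self_paths, function(p) read_vcf(p)$sites)
      comb <- read_vcf(file.path(cfg$out_dir, "combined.vcf"))
      logf("combined set: %d SNPs, %d non-SNP records skipped",
           nrow(comb$sites), comb$n_skipped)
      filtered <- filter_sites(comb$sites, cfg$min_quality,
                               cfg$max_alleles, cfg$min_depth)
      hom <- homeolog_positions(selfs)
      retained <- subtract_homeologs(filtered, hom)
      write_vcf(retained, file.path(cfg$out_dir, "snps_filtered.vcf"))
      emit("snps_filtered.vcf")
      summ <- summarize_variants(retained,
                                 cfg$n_contigs * cfg$contig_length)
      logf("retained %d allelic SNPs (Ts/Tv %.1f)", summ$n_sites,
           summ$tstv)
      list(retained = retained, homeologs = hom, summary = summ)
    })
  }

  if ("diversity" %in% stages) {
    bundle$diversity <- run_stage("diversity", {
      gm <- read_genotype_csv(file.path(cfg$out_dir, "calls.csv"),
                              file.path(cfg$out_dir, "groups.csv"))
      qc <- qc_filter(gm, cfg$max_sample_missing, cfg$max_locus_missing)
      summ <- locus_summary(qc$matrix)
      utils::write.table(summ, file.path(cfg$out_dir, "diversity.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      emit("diversity.tsv")
      logf("diversity: %d loci after QC, mean PIC %.3f", nrow(summ),
           mean(summ$pic))
      list(qc = qc, summary = summ)
    })
  }

  if ("structure" %in% stages) {
    bundle$structure <- run_stage("structure", {
      gm <- read_genotype_csv(file.path(cfg$out_dir, "calls.csv"),
                              file.path(cfg$out_dir, "groups.csv"))
      qc <- qc_filter(gm, cfg$max_sample_missing, cfg$max_locus_missing)
      d <- ibs_distance(qc$matrix)
      tree <- upgma(d)
      ape::write.tree(tree, file.path(cfg$out_dir, "upgma.nwk"))
      emit("upgma.nwk")
      kr <- as.integer(strsplit(as.character(cfg$K_range), ",")[[1]])
      lnpd_rows <- list()
      runs_by_k <- list()
      for (K in seq(kr[1], kr[2])) {
        runs <- lapply(seq_len(cfg$n_runs), function(r)
          gibbs_admixture(qc$matrix, K, cfg$burnin, cfg$reps,
                          cfg$struct_alpha,
                          seed = cfg$seed + 100L * K + r))
        runs_by_k[[as.character(K)]] <- runs
        for (r in seq_along(runs))
          lnpd_rows[[length(lnpd_rows) + 1L]] <-
            data.frame(K = K, run = r, lnpd = lnpd(runs[[r]]))
        Qbar <- align_runs(runs)
        utils::write.csv(data.frame(sample = rownames(Qbar), Qbar),
                         file.path(cfg$out_dir, sprintf("Q_K%d.csv", K)),
                         row.names = FALSE)
        emit(sprintf("Q_K%d.csv", K))
      }
      lnpd_tab <- do.call(rbind, lnpd_rows)
      dk <- if (length(unique(lnpd_tab$K)) >= 3L) delta_k(lnpd_tab) else NULL
      if (!is.null(dk)) {
        utils::write.table(dk, file.path(cfg$out_dir, "delta_k.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        emit("delta_k.tsv")
        logf("delta-K suggests K = %s", attr(dk, "best_K"))
      }
      list(tree = tree, lnpd = lnpd_tab, delta_k = dk,
           runs = runs_by_k)
    })
  }
  logf("pipeline complete")
  bundle$paths <- c(bundle$paths, log_path)
  invisible(bundle)
}
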