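#' Run the full fingerprinting pipeline
#'
#' Chains the stages end to end and writes every artifact plus a
#' machine-readable run manifest. With `simulate = TRUE` (the default
#' configuration) the input population, genome and amplicon depths are
#' generated by the simulator and written alongside the results; otherwise
#' the configured input paths (FASTA, VCF, depth TSV, subgroup TSV) are
#' read.
#'
#' Stages: panel discovery (perfect-SNP filter), genotype calling, QC with
#' locus exclusion (low PIC or high missing rate), per-locus and
#' per-subpopulation diversity, AMOVA, pairwise Fst, kinship
#' (differential-genotype matrix), core SNP selection with saturation
#' curve, and core-variety selection.
#'
#' @param config A list (or path to a YAML file) with optional entries
#'   `sim` (arguments to [sim_config()]), `simulate` (logical, default
#'   TRUE), `filter` (arguments to [filter_thresholds()]), `call`
#'   (arguments to [call_thresholds()]), `qc` (`pic_min`, `miss_max`),
#'   `core_fraction`, and -- when `simulate` is FALSE -- `paths` with
#'   `fasta`, `vcf`, `depths`, `subgroups`.
#' @param out_dir Output directory (created if needed).
#' @param seed Overrides the simulation seed when non-NULL.
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("sim", "simulate", "filter", "call", "qc", "core_fraction",
             "paths")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fpath <- function(f) file.path(out_dir, f)

  sim_args <- config[["sim"]]
  if (is.null(sim_args)) sim_args <- list()
  if (!is.null(seed)) sim_args$seed <- as.integer(seed)
  cfg <- do.call(sim_config, sim_args)
  fth <- do.call(filter_thresholds,
                 if (is.null(config[["filter"]])) list() else
                   config[["filter"]])
  cth <- do.call(call_thresholds,
                 if (is.null(config[["call"]])) list() else config[["call"]])
  qc_cfg <- config[["qc"]]
  pic_min <- if (is.null(qc_cfg$pic_min)) 0.1 else qc_cfg$pic_min
  miss_max <- if (is.null(qc_cfg$miss_max)) 0.1 else qc_cfg$miss_max
  core_fraction <- if (is.null(config[["core_fraction"]])) 0.1 else
    config[["core_fraction"]]

  simulate <- if (is.null(config[["simulate"]])) TRUE else
    isTRUE(config[["simulate"]])
  if (simulate) {
    truth <- simulate_population(cfg)
    depths <- simulate_depths(truth, cfg)
    genome <- truth$genome
    vt <- truth$variants
    subgroups <- truth$subgroups
    write_fasta(genome, fpath("genome.fasta"))
    write_vcf(vt, fpath("variants.vcf"))
    write_depth_table(depths, fpath("depths.tsv"))
    write_subgroups(subgroups, fpath("subgroups.tsv"))
    write_genotype_matrix(truth$truth, fpath("truth_genotypes.tsv"))
    inputs <- fpath(c("genome.fasta", "variants.vcf", "depths.tsv",
                      "subgroups.tsv"))
  } else {
    p <- config$paths
    need <- c("fasta", "vcf", "depths", "subgroups")
    miss <- setdiff(need, names(p))
    if (length(miss)) stop("missing input path(s): ",
                           paste(miss, collapse = ", "))
    for (f in need) if (!file.exists(p[[f]])) stop("no such file: ", p[[f]])
    genome <- read_fasta(p$fasta)
    subgroups <- read_subgroups(p$subgroups)
    vt <- read_vcf(p$vcf, subgroups = subgroups)
    depths <- read_depth_table(p$depths)
    inputs <- unlist(p[need], use.names = FALSE)
  }

  panel <- select_perfect_snps(vt, genome, fth, subgroups = subgroups)
  write.table(panel$audit, fpath("panel_audit.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_panel_bed(panel$audit[panel$audit$final, ], fpath("panel.bed"))

  calls <- call_genotypes(depths, cth)
  panel_loci <- intersect(unique(calls$locus), panel$panel)
  if (!length(panel_loci)) panel_loci <- unique(calls$locus)
  gm <- suppressWarnings(
    build_matrix(calls, panel = panel_loci, varieties = names(subgroups)))
  write_genotype_matrix(gm, fpath("genotypes.tsv"))

  stats <- locus_stats(gm)
  qc <- qc_summaries(calls[calls$locus %in% panel_loci, ], stats,
                     pic_min = pic_min, miss_max = miss_max,
                     thresholds = cth)
  write.table(qc$locus_qc, fpath("locus_qc.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  keep <- setdiff(colnames(gm), qc$excluded)
  gm_f <- genotype_matrix(unclass(gm)[, keep, drop = FALSE])
  stats_f <- stats[stats$locus %in% keep, ]
  write.table(stats_f, fpath("locus_stats.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  km <- differential_matrix(gm_f)
  write.table(km$diff, fpath("kinship.tsv"), sep = "\t", quote = FALSE)
  sub_sum <- subpop_summary(gm_f, subgroups, kinship = km)
  write.table(sub_sum, fpath("subpop_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  am <- amova(gm_f, subgroups)
  write.table(am$table, fpath("amova.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  fst <- pairwise_fst(gm_f, subgroups)
  write.table(fst$pairs, fpath("fst_pairs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  core <- select_core_snps(gm_f, mode = "greedy", stats = stats_f)
  write.table(core$curve, fpath("core_snps.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  corev <- select_core_varieties(km, subgroups, fraction = core_fraction)
  write.table(corev, fpath("core_varieties.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  outputs <- c("panel_audit.tsv", "panel.bed", "genotypes.tsv",
               "locus_qc.tsv", "locus_stats.tsv", "kinship.tsv",
               "subpop_summary.tsv", "amova.tsv", "fst_pairs.tsv",
               "core_snps.tsv", "core_varieties.tsv")
  manifest <- list(
    package = "snppanel",
    version = as.character(utils::packageVersion("snppanel")),
    seed = cfg$seed,
    simulate = simulate,
    sim_config = unclass(cfg),
    filter_thresholds = unclass(fth)[names(fth) != "ssr_min_copies"],
    ssr_min_copies = fth$ssr_min_copies,
    call_thresholds = unclass(cth),
    qc = list(pic_min = pic_min, miss_max = miss_max),
    core_fraction = core_fraction,
    inputs = as.list(setNames(tools::md5sum(inputs), basename(inputs))),
    outputs = as.list(setNames(tools::md5sum(fpath(outputs)), outputs)))
  jsonlite::write_json(manifest, fpath("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(panel = panel, calls = calls, genotypes = gm_f,
                 stats = stats_f, qc = qc, kinship = km, amova = am,
                 fst = fst, core_snps = core, core_varieties = corev,
                 subpop_summary = sub_sum, manifest = manifest))
}
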