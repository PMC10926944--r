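#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with its default.
#' `run_pipeline()` writes the resolved configuration next to its outputs
#' so every run is self-describing.
#'
#' @param outdir output directory.
#' @param seed master seed; all stage seeds derive from it.
#' @param n_chrom,chrom_length,island_fraction synthetic genome shape.
#' @param depth,read_span,miss_rate read simulation settings.
#' @param est_span,sub_span partition spans (bp).
#' @param min_region_reads,min_sub_reads depth filters.
#' @param n_genes,n_planted synthetic gene table size.
#' @param window promoter window (bp each side of the TSS).
#' @param n_perm permutations per tested gene; `top_n_perm` genes tested.
#' @param top_n_perm number of top-ranked genes given permutation p-values.
#' @param normal_reads,tumor_reads optional epiread TSV paths; when set,
#'   simulation is skipped and these inputs are analysed instead (requires
#'   `map_file`).
#' @param map_file optional CpG map TSV (as written by a previous run).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 1, n_chrom = 2,
                            chrom_length = 7e5, island_fraction = 0.06,
                            depth = 10, read_span = 8, miss_rate = 0.05,
                            est_span = 3000, sub_span = 150,
                            min_region_reads = 20, min_sub_reads = 5,
                            n_genes = 500, n_planted = 10, window = 2000,
                            n_perm = 199, top_n_perm = 10,
                            normal_reads = NULL, tumor_reads = NULL,
                            map_file = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' simulate (or load) paired read sets, partition the genome, fit per-region
#' Ising parameters for both samples, compute MML/NME tracks and the
#' differential dMML/dNME/JSD track, summarize by genomic feature, rank
#' genes by promoter discordance with permutation significance for the top
#' genes, and write meta-profiles around TSSs.  Deterministic given the
#' config seeds.  Every output file is listed in a MANIFEST; the resolved
#' config, package version and config hash go to the run log.
#'
#' @param config a `pipeline_config`.
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  log_path <- file.path(outdir, "run.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  emit <- function(path) {
    manifest <<- c(manifest, path)
    path
  }
  write_manifest <- function(complete) {
    lines <- c(sprintf("# complete: %s", complete),
               sprintf("%s\t%s", basename(manifest),
                       unname(tools::md5sum(manifest))))
    writeLines(lines, file.path(outdir, "MANIFEST"))
  }

  cfg_path <- file.path(outdir, "config.txt")
  keep <- !vapply(config, is.null, logical(1))
  writeLines(sprintf("%s=%s", names(config)[keep],
                     vapply(config[keep], function(x)
                       paste(format(x, scientific = FALSE), collapse = ","),
                       character(1))),
             cfg_path)
  emit(cfg_path)
  logf("methpel ", as.character(packageVersion("methpel")),
       " | config md5 ", unname(tools::md5sum(cfg_path)))

  result <- tryCatch({
    set.seed(config$seed)
    stage_seeds <- sample.int(.Machine$integer.max - 1L, 4)

    if (is.null(config$normal_reads)) {
      logf("stage simulate: generating CpG map and paired read sets")
      map <- generate_cpg_map(n_chrom = config$n_chrom,
                              chrom_length = config$chrom_length,
                              island_fraction = config$island_fraction,
                              seed = stage_seeds[1])
      pair <- make_tumor_normal_pair(map, seed = stage_seeds[2],
                                     est_span = config$est_span,
                                     sub_span = config$sub_span,
                                     depth = config$depth,
                                     read_span = config$read_span,
                                     miss_rate = config$miss_rate)
      normal <- pair$normal
      tumor <- pair$tumor
      partition <- pair$partition
      write_epireads(normal, emit(file.path(outdir, "normal.epireads.tsv")))
      write_epireads(tumor, emit(file.path(outdir, "tumor.epireads.tsv")))
      write.table(map$sites, emit(file.path(outdir, "cpg_map.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_bed(map$segments, emit(file.path(outdir, "features.bed")))
    } else {
      logf("stage load: reading provided epiread inputs")
      for (f in c(config$normal_reads, config$tumor_reads,
                  config$map_file)) {
        if (is.null(f) || !file.exists(f))
          stop("input stage failed: missing input file ",
               if (is.null(f)) "(unset path)" else f)
      }
      sites <- read.table(config$map_file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
      map <- structure(
        list(sites = sites,
             segments = data.frame(chrom = character(), start = integer(),
                                   end = integer(), label = character()),
             chrom_lengths = tapply(sites$pos, sites$chrom, max)),
        class = "cpg_map")
      normal <- read_epireads(config$normal_reads)
      tumor <- read_epireads(config$tumor_reads)
      partition <- partition_genome(map, config$est_span, config$sub_span)
    }

    logf("stage fit: ", nrow(partition$regions),
         " estimation regions per sample")
    fit_n <- fit_sample(normal, map, partition,
                        min_region_reads = config$min_region_reads)
    fit_t <- fit_sample(tumor, map, partition,
                        min_region_reads = config$min_region_reads)
    write_parameter_table(fit_n, emit(file.path(outdir, "normal.params.tsv")))
    write_parameter_table(fit_t, emit(file.path(outdir, "tumor.params.tsv")))

    logf("stage metrics: level distributions, MML/NME tracks")
    track_n <- landscape_track(fit_n, map, partition,
                               min_sub_reads = config$min_sub_reads)
    track_t <- landscape_track(fit_t, map, partition,
                               min_sub_reads = config$min_sub_reads)
    write_track(partition, track_n$mml,
                emit(file.path(outdir, "normal.mml.bedGraph")), "normal MML")
    write_track(partition, track_n$nme,
                emit(file.path(outdir, "normal.nme.bedGraph")), "normal NME")
    write_track(partition, track_t$mml,
                emit(file.path(outdir, "tumor.mml.bedGraph")), "tumor MML")
    write_track(partition, track_t$nme,
                emit(file.path(outdir, "tumor.nme.bedGraph")), "tumor NME")

    logf("stage differential: dMML/dNME/JSD")
    diff <- differential_track(track_t, track_n)
    write_track(partition, diff$dmml,
                emit(file.path(outdir, "dmml.bedGraph")), "dMML")
    write_track(partition, diff$dnme,
                emit(file.path(outdir, "dnme.bedGraph")), "dNME")
    write_track(partition, diff$jsd,
                emit(file.path(outdir, "jsd.bedGraph")), "JSD")
    gsum <- genome_summary(track_t, track_n)
    write.table(gsum, emit(file.path(outdir, "genome_summary.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)

    logf("stage summarize: feature classes and TSS meta-profiles")
    fsum <- feature_summary(diff, map$segments)
    write.table(fsum, emit(file.path(outdir, "feature_summary.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    genes <- synthesize_genes(map, n_genes = config$n_genes,
                              n_planted = config$n_planted,
                              seed = stage_seeds[3])
    write_bed(genes, emit(file.path(outdir, "genes.bed")))
    for (val in c("nme", "mml")) {
      prof_t <- meta_profile(track_t, val, genes, window = config$window)
      prof_n <- meta_profile(track_n, val, genes, window = config$window)
      prof <- data.frame(bin_center = prof_t$bin_center,
                         tumor = prof_t$mean, normal = prof_n$mean,
                         n = prof_t$n)
      write.table(prof,
                  emit(file.path(outdir,
                                 sprintf("tss_profile_%s.tsv", val))),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }

    logf("stage rank: promoter JSD / dNME gene rankings")
    for (mode in c("promoter_jsd", "promoter_dnme")) {
      ranking <- rank_genes(diff, genes, mode = mode,
                            window = config$window)
      if (mode == "promoter_jsd" && config$top_n_perm > 0) {
        ranking <- add_gene_significance(ranking, diff, tumor, normal, map,
                                         partition,
                                         top_n = config$top_n_perm,
                                         n_perm = config$n_perm,
                                         seed = stage_seeds[4])
      }
      write.table(as.data.frame(ranking),
                  emit(file.path(outdir, sprintf("ranking_%s.tsv", mode))),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_manifest(TRUE)
    logf("pipeline complete: ", length(manifest), " output files")
    TRUE
  }, error = function(e) {
    write_manifest(FALSE)
    logf("pipeline FAILED: ", conditionMessage(e))
    stop(e)
  })
  invisible(outdir)
}
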