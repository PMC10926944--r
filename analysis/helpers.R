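# Shared glue for the numbered analysis drivers: paths and re-loading of
# intermediate text outputs.  Every driver can be re-run independently.

res_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

load_sim <- function(dir = file.path("results", "sim")) {
  map <- read_cpg_map(file.path(dir, "cpg_map.tsv"),
                      file.path(dir, "features.bed"))
  list(
    map = map,
    partition = partition_genome(map),
    normal = read_epireads(file.path(dir, "normal.epireads.tsv")),
    tumor = read_epireads(file.path(dir, "tumor.epireads.tsv")),
    genes = read.table(file.path(dir, "genes.tsv"), sep = "\t",
                       header = TRUE, stringsAsFactors = FALSE)
  )
}

# rebuild a landscape_fit from a written parameter table plus the reads
load_fit <- function(params_path, reads, map, partition) {
  df <- read.table(params_path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  structure(df, assembled = assemble_region_reads(reads, map, partition),
            class = c("landscape_fit", "data.frame"))
}

load_tracks <- function(sim, fit_dir = file.path("results", "fits")) {
  fit_n <- load_fit(file.path(fit_dir, "normal.params.tsv"), sim$normal,
                    sim$map, sim$partition)
  fit_t <- load_fit(file.path(fit_dir, "tumor.params.tsv"), sim$tumor,
                    sim$map, sim$partition)
  list(normal = landscape_track(fit_n, sim$map, sim$partition),
       tumor = landscape_track(fit_t, sim$map, sim$partition))
}
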