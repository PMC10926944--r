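#!/usr/bin/env Rscript

# Stage 1 — simulate the study's paired data: a synthetic genome with
# CGI/open-sea structure and a normal/tumor read-set pair in which the
# tumor is globally hypomethylated with elevated methylation entropy and
# focally hypermethylated at bivalent promoters.  All downstream stages
# work only from the text files written here.

suppressPackageStartupMessages(library(methpel))
source(file.path("analysis", "helpers.R"))

out <- res_dir("sim")
map_seed <- 101
pair_seed <- 202
gene_seed <- 303

map <- generate_cpg_map(seed = map_seed)
message(sprintf("genome: %d CpGs on %d chromosomes", nrow(map$sites),
                length(map$chrom_lengths)))
print(table(map$sites$label))

pair <- make_tumor_normal_pair(map, seed = pair_seed)
message(sprintf("reads: %d normal / %d tumor", nrow(pair$normal),
                nrow(pair$tumor)))

genes <- synthesize_genes(map, n_genes = 500, n_planted = 10,
                          seed = gene_seed)
message(sprintf("genes: %d total, %d planted on bivalent promoters",
                nrow(genes), sum(genes$planted)))

write_cpg_map(map, file.path(out, "cpg_map.tsv"),
              file.path(out, "features.bed"))
write_epireads(pair$normal, file.path(out, "normal.epireads.tsv"))
write_epireads(pair$tumor, file.path(out, "tumor.epireads.tsv"))
write.table(genes, file.path(out, "genes.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(pair$truth$regions, file.path(out, "truth_regions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(pair$truth$normal_subs, file.path(out, "truth_normal.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(pair$truth$tumor_subs, file.path(out, "truth_tumor.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(sprintf("%s=%s", c("map_seed", "pair_seed", "gene_seed"),
                   c(map_seed, pair_seed, gene_seed)),
           file.path(out, "seeds.txt"))

# ground-truth sanity: the planted directions hold in the exact model
tn <- pair$truth
lab <- tn$regions$label[match(tn$normal_subs$region_id,
                              tn$regions$region_id)]
message(sprintf("truth medians: dMML = %+.3f, dNME = %+.3f, bivalent dMML = %+.3f",
                median(tn$tumor_subs$mml - tn$normal_subs$mml),
                median(tn$tumor_subs$nme - tn$normal_subs$nme),
                median((tn$tumor_subs$mml - tn$normal_subs$mml)[
                  lab == "bivalent_promoter"])))
message("wrote ", out)
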