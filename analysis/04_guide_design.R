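#!/usr/bin/env Rscript
# Safe-site and guide design on a fresh synthetic genome: convergent 300-600
# nt intergenic regions, 5'-CN-3' PAM scan, 32-nt guides filtered on GC and
# insertion-locus placement, off-target-ranked, three guides per site.

suppressPackageStartupMessages(library(castworks))
dir.create("results", showWarnings = FALSE)

genome <- make_genome(length = 50000, n_converging_pairs = 4,
                      mask_spec = list(
                        ncRNA = data.frame(start = 100, end = 200)),
                      seed = 20260401)
dg <- design_guides(genome, k = 3)

write.table(dg$sites, "results/safe_sites.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(dg$guides[, c("site", "rank", "protospacer", "pam", "strand",
                          "pam_start", "gc_pct", "locus_start", "locus_end",
                          "seed_matches", "best_score",
                          "n_hits_above_floor")],
            "results/guides.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(sprintf(">site%d_rank%d\n%s", dg$guides$site, dg$guides$rank,
                   dg$guides$protospacer), "results/guides.fasta")

cat(sprintf("%d candidate convergent gaps, %d accepted\n",
            nrow(dg$sites), sum(dg$sites$accepted)))
print(as.data.frame(dg$sites[, c("site", "length", "accepted",
                                 "exclusion_flags")]))
cat(sprintf("%d guides selected (3 per site), GC %.1f-%.1f%%\n",
            nrow(dg$guides), min(dg$guides$gc_pct), max(dg$guides$gc_pct)))
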