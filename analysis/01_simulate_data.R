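#!/usr/bin/env Rscript

# Step 1 — simulate the study's raw material at desk scale and export it
# in standard formats: a multi-chromosome genome with assembly-gap runs
# (chrom.sizes + gap BED) and one truly-null pair of gap-avoiding tracks
# (BED). Later steps regenerate data internally; these files document what
# the generator produces and make the objects inspectable with standard
# tools (awk, bedtools, IGV).

library(gapcoloc)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# hg19-like geometry at 1/100 scale: 22 chromosomes, 7.6% of bases in gaps
gspec <- genome_sim_spec(
  n_chromosomes = 22,
  chromosome_length = round(3.0e9 / 22 / 100),
  gap_fraction = 0.076,
  seed = 101
)
sim <- simulate_genome(gspec)
message(sprintf("genome: %d chromosomes, %.1f Mbp total",
                length(sim$genome$names), sim$genome$total / 1e6))
message(sprintf("gaps:   %d runs, %.2f Mbp (%.2f%% of the genome)",
                n_intervals(sim$gaps), total_bp(sim$gaps) / 1e6,
                100 * total_bp(sim$gaps) / sim$genome$total))

write_chrom_sizes(sim$genome, file.path(out, "synthetic_genome.chrom.sizes"))
write_bed(sim$gaps, file.path(out, "synthetic_gaps.bed"))

# one truly-null pair: both tracks avoid gaps, share nothing else
tspec <- track_sim_spec(500, list(law = "fixed", length = 2114))
pair <- simulate_null_pair(tspec, tspec, sim$genome, sim$gaps, seed = 102)
for (nm in c("a", "b")) {
  tr <- pair[[nm]]
  message(sprintf("track %s: %d elements x %d bp, %.2f Mbp, %d bp inside gaps",
                  toupper(nm), n_intervals(tr), 2114, total_bp(tr) / 1e6,
                  base_overlap(tr, sim$gaps)))
  write_bed(tr, file.path(out, sprintf("synthetic_track_%s.bed", nm)))
}
message(sprintf("observed base overlap of the pair: %.0f bp",
                base_overlap(pair$a, pair$b)))
message("wrote ", out, "/")
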