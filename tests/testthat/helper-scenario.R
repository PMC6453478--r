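# The demo scenario shared by the pipeline tests: a small genome with three
# planted read-through regions. The DoG and PoG are present in both
# conditions with IP-boosted coverage in the stressed condition, so the
# interaction LRT can detect them; the ADoG is condition-specific (a novel
# region absent from the reference, where enrichment is unidentifiable
# because the reference IP/input ratio is 0/0).
demo_scenario <- function(seed = 101L) {
  dog_scenario(
    seed = seed, n_genes = 12,
    planted = data.frame(gene_index = c(2, 5, 8),
                         category = c("DoG", "ADoG", "PoG"),
                         length = c(1200, 800, 600),
                         depth = c(20, 15, 12),
                         condition_specific = c(FALSE, TRUE, FALSE)),
    ip_boost = 4)
}

write_demo <- function(dir, seed = 101L) {
  write_scenario_files(demo_scenario(seed), dir)
}
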