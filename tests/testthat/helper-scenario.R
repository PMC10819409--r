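# shared wiring of a simulated scenario into a pipeline configuration
scenario_config <- function(scen, out) {
  run_config(genome = scen$genome, guides = scen$guides, vcf = scen$vcf,
             clone_sample = "clone", parent_sample = "parent",
             target_bed = scen$target_bed, cnv_a = scen$cnv_a,
             cnv_b = scen$cnv_b, cnv_parent = scen$cnv_parent,
             exons = scen$exons, out = out, seed = 1L)
}
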