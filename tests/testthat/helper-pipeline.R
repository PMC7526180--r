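# Simulate a genome pair, write its reads, run the full pipeline and score
# the selected contigs against truth. Shared by pipeline and acceptance
# tests.
run_sim_pipeline <- function(params, out_root = NULL,
                             top_n = 1000L, min_contig_length = 80L,
                             rng_seed = params$rng_seed) {
  if (is.null(out_root)) {
    out_root <- tempfile("ksub_sim_")
    dir.create(out_root)
  }
  pair <- simulate_genome_pair(params)
  for (sex in c("male", "female")) {
    rd <- simulate_reads(pair[[paste0(sex, "_genome")]], params,
                         rng_seed = params$rng_seed +
                           if (sex == "male") 1L else 2L,
                         id_prefix = sex)
    write_fastq(rd$r1, file.path(out_root, paste0(sex, "_1.fq.gz")))
    write_fastq(rd$r2, file.path(out_root, paste0(sex, "_2.fq.gz")))
  }
  cfg <- pipeline_config(
    file.path(out_root, "male_1.fq.gz"), file.path(out_root, "male_2.fq.gz"),
    file.path(out_root, "female_1.fq.gz"),
    file.path(out_root, "female_2.fq.gz"),
    out_dir = file.path(out_root, "out"), top_n = top_n,
    min_contig_length = min_contig_length, rng_seed = rng_seed)
  manifest <- suppressWarnings(run_pipeline(cfg, force = TRUE))
  sel <- read_fasta(file.path(out_root, "out", "contigs_selected.fa"))
  contigs <- data.frame(id = names(sel), sequence = unname(sel),
                        length = nchar(sel), stringsAsFactors = FALSE)
  list(pair = pair, manifest = manifest, contigs = contigs,
       eval = evaluate_against_truth(contigs, pair, k = 27L),
       out_dir = file.path(out_root, "out"))
}
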